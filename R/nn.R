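# Native neural-network layers. Each layer is an environment holding its
# parameters (W, b), accumulated gradients (dW, db), Adam moments and the
# per-sample forward cache. Samples are processed one at a time; gradients
# accumulate across a mini-batch and are averaged inside the optimizer step.
# Feature maps are dense arrays dim c(H, W, C); vectors are plain numerics.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

he_init <- function(n_out, n_in) {
  matrix(rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in)
}

layer_conv <- function(cin, cout, k = 3L, stride = 1L, pad = 1L,
                       bias = TRUE) {
  new_layer("conv",
            W = he_init(cout, cin * k * k), b = numeric(cout),
            cin = cin, cout = cout, k = as.integer(k),
            stride = as.integer(stride), pad = as.integer(pad),
            use_bias = isTRUE(bias),
            param_names = if (bias) c("W", "b") else "W")
}

layer_dense <- function(n_in, n_out) {
  new_layer("dense", W = he_init(n_out, n_in), b = numeric(n_out),
            param_names = c("W", "b"))
}

layer_relu    <- function() new_layer("relu", param_names = character())
layer_sigmoid <- function() new_layer("sigmoid", param_names = character())
layer_maxpool <- function() new_layer("maxpool", param_names = character())
layer_dropout <- function(p) new_layer("dropout", p = p, active = FALSE,
                                       param_names = character())

nn_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      layer$cache <- x
      conv2d_forward_cpp(x, layer$W, layer$b, layer$k, layer$stride, layer$pad)
    },
    dense = {
      layer$cache <- x
      drop(layer$W %*% x) + layer$b
    },
    relu = {
      layer$cache <- x > 0
      x * layer$cache
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      layer$cache <- y
      y
    },
    maxpool = {
      res <- maxpool2_forward_cpp(x)
      layer$cache <- list(idx = res$idx, H = dim(x)[1], W = dim(x)[2])
      res$out
    },
    dropout = {
      if ((training || isTRUE(layer$active)) && layer$p > 0) {
        m <- (runif(length(x)) >= layer$p) / (1 - layer$p)
        layer$cache <- m
        x * m
      } else {
        layer$cache <- NULL
        x
      }
    },
    stop("unknown layer type ", layer$type)
  )
}

add_grad <- function(layer, p, g) {
  gn <- paste0("d", p)
  if (!exists(gn, layer)) assign(gn, 0 * get(p, layer), envir = layer)
  assign(gn, get(gn, layer) + g, envir = layer)
}

nn_backward <- function(layer, dy) {
  switch(layer$type,
    conv = {
      res <- conv2d_backward_cpp(dy, layer$cache, layer$W,
                                 layer$k, layer$stride, layer$pad)
      add_grad(layer, "W", res$dW)
      if (layer$use_bias) add_grad(layer, "b", res$db)
      res$dx
    },
    dense = {
      add_grad(layer, "W", outer(dy, layer$cache))
      add_grad(layer, "b", dy)
      drop(crossprod(layer$W, dy))
    },
    relu = dy * layer$cache,
    sigmoid = dy * layer$cache * (1 - layer$cache),
    maxpool = maxpool2_backward_cpp(dy, layer$cache$idx,
                                    layer$cache$H, layer$cache$W),
    dropout = if (is.null(layer$cache)) dy else dy * layer$cache,
    stop("unknown layer type ", layer$type)
  )
}

# forward/backward through an ordered list of layers
seq_forward <- function(layers, x, training = FALSE) {
  for (l in layers) x <- nn_forward(l, x, training)
  x
}

seq_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- nn_backward(l, dy)
  dy
}

gap_forward <- function(x) apply(x, 3L, mean)

gap_backward <- function(dy, h, w) {
  # distribute each channel's gradient uniformly over its h*w cells
  aperm(array(rep(dy, each = h * w) / (h * w), dim = c(h, w, length(dy))),
        c(1L, 2L, 3L))
}

nn_param_layers <- function(layers) {
  Filter(function(l) length(l$param_names) > 0, layers)
}

nn_zero_grad <- function(layers) {
  for (l in nn_param_layers(layers)) {
    for (p in l$param_names) assign(paste0("d", p), 0 * get(p, l), envir = l)
  }
  invisible(NULL)
}

nn_count_params <- function(layers) {
  sum(vapply(nn_param_layers(layers),
             function(l) sum(vapply(l$param_names,
                                    function(p) length(get(p, l)), 0)), 0))
}

# clip the global gradient norm over all layers (standard stabilizer for
# the ratio-form alignment loss, whose gradient is unbounded as sum(A) -> 0)
clip_global_grad_norm <- function(layers, max_norm) {
  sq <- 0
  pls <- nn_param_layers(layers)
  for (l in pls)
    for (p in l$param_names) sq <- sq + sum(get(paste0("d", p), l)^2)
  nrm <- sqrt(sq)
  if (is.finite(nrm) && nrm > max_norm) {
    sc <- max_norm / nrm
    for (l in pls)
      for (p in l$param_names) {
        gn <- paste0("d", p)
        assign(gn, get(gn, l) * sc, envir = l)
      }
  }
  invisible(nrm)
}

#' @noRd
adamw_step <- function(layers, lr, n_accum = 1L, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-4, t = 1L) {
  for (l in nn_param_layers(layers)) {
    for (p in l$param_names) {
      g <- get(paste0("d", p), l) / n_accum
      mn <- paste0("m_", p); vn <- paste0("v_", p)
      if (!exists(mn, l)) {
        assign(mn, 0 * g, l); assign(vn, 0 * g, l)
      }
      m <- beta1 * get(mn, l) + (1 - beta1) * g
      v <- beta2 * get(vn, l) + (1 - beta2) * g^2
      assign(mn, m, l); assign(vn, v, l)
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      val <- get(p, l)
      assign(p, val - lr * (mh / (sqrt(vh) + eps) + weight_decay * val), l)
    }
  }
  invisible(NULL)
}

cosine_lr <- function(epoch, max_epochs, lr0, lr_min = lr0 * 0.01) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (epoch - 1) / max(1, max_epochs - 1)))
}

# serialize parameters to a plain list (for JSON checkpoints)
nn_get_state <- function(layers) {
  lapply(layers, function(l) {
    st <- lapply(l$param_names, function(p) get(p, l))
    names(st) <- l$param_names
    st
  })
}

nn_set_state <- function(layers, state) {
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in l$param_names) {
      v <- state[[i]][[p]]
      cur <- get(p, l)
      if (is.matrix(cur)) v <- matrix(unlist(v), nrow(cur), ncol(cur))
      else v <- as.numeric(unlist(v))
      assign(p, v, l)
    }
  }
  invisible(NULL)
}
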