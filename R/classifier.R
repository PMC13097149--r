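# Attention-based classification of the background-suppressed lesion image:
# a small convolutional backbone, squeeze-excite channel attention plus a
# channel-pooled convolutional spatial attention (both sigmoid-gated), a
# pooled/projected softmax head, and the composite training objective
# weighting segmentation, classification, attention-alignment and
# confidence-calibration terms.

bc_channel <- function(v, h, w) array(rep(v, each = h * w), dim = c(h, w, length(v)))
bc_spatial <- function(m, C) array(rep(m, times = C), dim = c(dim(m), C))

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Build an untrained attention classifier
#'
#' "Tiny" 4-block convolutional backbone (stride 8 overall), channel and
#' spatial attention gates, global average pooling, a projection layer with
#' dropout (kept active at inference for MC-dropout), and a linear softmax
#' head. With `use_attention = FALSE` both gates are bypassed and the model
#' reduces to a plain CNN classifier (the ablation baseline).
#'
#' @param n_classes number of classes.
#' @param seed seed for weight initialization.
#' @param in_ch input channels.
#' @param base base channel width.
#' @param size working resolution.
#' @param dropout dropout probability in the head.
#' @param use_attention logical; gate the features with attention.
#' @param backbone_dropout dropout probability on the mid-backbone feature
#'   map (kept active for MC sampling; epistemic uncertainty over features,
#'   which head-only dropout cannot provide).
#' @return object of class `lesion_classifier`.
#' @export
classifier_new <- function(n_classes, seed = 1L, in_ch = 3L, base = 16L,
                           size = 64L, dropout = 0.25, use_attention = TRUE,
                           backbone_dropout = 0.1) {
  run_seeded(seed, {
    b <- as.integer(base); C <- 4L * b
    L <- list(
      # bias-free backbone (like BN-folded convs): a masked-to-zero
      # background yields exactly zero features, so attribution maps carry
      # no background plateau
      c1 = layer_conv(in_ch, b, bias = FALSE), r1 = layer_relu(),
      p1 = layer_maxpool(),
      c2 = layer_conv(b, 2L * b, bias = FALSE), r2 = layer_relu(),
      p2 = layer_maxpool(),
      c3 = layer_conv(2L * b, C, bias = FALSE), r3 = layer_relu(),
      p3 = layer_maxpool(),
      fdrop = layer_dropout(backbone_dropout),   # feature-space MC dropout
      c4 = layer_conv(C, C, bias = FALSE), r4 = layer_relu(),
      # channel attention: squeeze-excite bottleneck
      fc1 = layer_dense(C, max(4L, C %/% 4L)), rc = layer_relu(),
      fc2 = layer_dense(max(4L, C %/% 4L), C), sc = layer_sigmoid(),
      # spatial attention: conv over channel mean/max descriptors
      sconv = layer_conv(2L, 1L, k = 3L, pad = 1L), ss = layer_sigmoid(),
      # head
      psi = layer_dense(C, C), rp = layer_relu(),
      drop = layer_dropout(dropout),
      fc = layer_dense(C, as.integer(n_classes))
    )
    L$fc2$b[] <- 1; L$sconv$b[] <- 1  # sigmoid(1) ~ 0.73: gates open at init
    m <- new.env(parent = emptyenv())
    m$layers <- L; m$n_classes <- as.integer(n_classes)
    m$size <- as.integer(size); m$feat_ch <- C
    m$stride <- 8L  # three 2x2 poolings
    m$use_attention <- isTRUE(use_attention)
    class(m) <- "lesion_classifier"
    m
  })
}

backbone_names <- c("c1", "r1", "p1", "c2", "r2", "p2", "c3", "r3", "p3",
                    "fdrop", "c4", "r4")

#' Extract backbone features from a masked image
#'
#' @param model a `lesion_classifier`.
#' @param x_m masked image at the working resolution.
#' @param training logical; training mode.
#' @return h x w x C feature array (spatial dims = input dims / 8).
#' @export
extract_features <- function(model, x_m, training = FALSE) {
  stopifnot(inherits(model, "lesion_classifier"))
  seq_forward(model$layers[backbone_names], x_m, training)
}

#' Apply channel and spatial attention to a feature map
#'
#' Channel weights come from globally pooled descriptors passed through a
#' sigmoid-gated bottleneck; the spatial map from channel mean/max
#' descriptors through a small sigmoid-gated convolution. The refined
#' features are `f * A_c * A_s` with broadcasting.
#'
#' @param model a `lesion_classifier` (holds the attention parameters).
#' @param f raw feature array.
#' @param training logical.
#' @return list (`attention_bundle`) with `spatial_map` (h x w in \[0, 1\]),
#'   `channel_weights` (length C in \[0, 1\]), `refined_features`,
#'   `raw_features`.
#' @export
attend <- function(model, f, training = FALSE) {
  L <- model$layers
  h <- dim(f)[1]; w <- dim(f)[2]; C <- dim(f)[3]
  if (!model$use_attention) {
    out <- list(spatial_map = matrix(1, h, w), channel_weights = rep(1, C),
                refined_features = f, raw_features = f)
    class(out) <- "attention_bundle"
    return(out)
  }
  s <- gap_forward(f)
  Ac <- seq_forward(L[c("fc1", "rc", "fc2", "sc")], s, training)
  ch_mean <- apply(f, c(1, 2), mean)
  mx_idx <- apply(f, c(1, 2), which.max)
  ch_max <- apply(f, c(1, 2), max)
  pooled <- array(c(ch_mean, ch_max), dim = c(h, w, 2L))
  As <- seq_forward(L[c("sconv", "ss")], pooled, training)[, , 1]
  fa <- f * bc_channel(Ac, h, w) * bc_spatial(As, C)
  model$att_cache <- list(f = f, Ac = Ac, As = As, mx_idx = mx_idx)
  out <- list(spatial_map = As, channel_weights = Ac,
              refined_features = fa, raw_features = f)
  class(out) <- "attention_bundle"
  out
}

#' Classification head: pooled, projected, softmax
#'
#' @param model a `lesion_classifier`.
#' @param fa refined feature array.
#' @param training logical (activates dropout).
#' @return list (`class_probabilities`) with `probs`, `logits`, `embedding`.
#' @export
classify <- function(model, fa, training = FALSE) {
  L <- model$layers
  g <- gap_forward(fa)
  e <- seq_forward(L[c("psi", "rp")], g, training)
  d <- nn_forward(L$drop, e, training)
  logits <- nn_forward(L$fc, d, training)
  probs <- softmax_vec(logits)
  model$head_cache <- list(h = dim(fa)[1], w = dim(fa)[2])
  out <- list(probs = probs, logits = logits, embedding = e)
  class(out) <- "class_probabilities"
  out
}

# full forward through the classifier (not the segmenter); caches everything
# needed for classifier_backward
classifier_forward <- function(model, x_m, training = FALSE) {
  f <- extract_features(model, x_m, training)
  bundle <- attend(model, f, training)
  cls <- classify(model, bundle$refined_features, training)
  c(cls, list(bundle = bundle))
}

# backward from d(logits) (+ optional gradient on the spatial attention map
# at feature resolution); accumulates parameter gradients, returns d(x_m)
classifier_backward <- function(model, dlogits, dAs_extra = NULL) {
  L <- model$layers
  hc <- model$head_cache
  dd <- nn_backward(L$fc, dlogits)
  de <- nn_backward(L$drop, dd)
  dg <- seq_backward(L[c("psi", "rp")], de)
  dfa <- gap_backward(dg, hc$h, hc$w)
  if (model$use_attention) {
    ac <- model$att_cache
    f <- ac$f; Ac <- ac$Ac; As <- ac$As
    h <- dim(f)[1]; w <- dim(f)[2]; C <- dim(f)[3]
    Acb <- bc_channel(Ac, h, w); Asb <- bc_spatial(As, C)
    df <- dfa * Acb * Asb
    dAc <- vapply(seq_len(C), function(cc) sum(dfa[, , cc] * f[, , cc] * As), 0)
    dAs <- matrix(0, h, w)
    for (cc in seq_len(C)) dAs <- dAs + dfa[, , cc] * f[, , cc] * Ac[cc]
    if (!is.null(dAs_extra)) dAs <- dAs + dAs_extra
    # channel branch
    ds <- seq_backward(L[c("fc1", "rc", "fc2", "sc")], dAc)
    df <- df + gap_backward(ds, h, w)
    # spatial branch
    dpool <- seq_backward(L[c("sconv", "ss")], array(dAs, dim = c(h, w, 1L)))
    df <- df + bc_spatial(dpool[, , 1] / C, C)
    dmax <- dpool[, , 2]
    for (cc in seq_len(C)) df[, , cc] <- df[, , cc] + dmax * (ac$mx_idx == cc)
    dfa <- df
  } else if (!is.null(dAs_extra)) {
    warning("attention disabled; alignment gradient ignored")
  }
  seq_backward(L[backbone_names], dfa)
}

#' Cross-entropy loss for a single prediction
#'
#' `-log p_y` with the probability floored at 1e-12.
#'
#' @param probs probability vector (or a `class_probabilities` object).
#' @param y 0-based true class label.
#' @return nonnegative scalar.
#' @export
cross_entropy <- function(probs, y) {
  if (inherits(probs, "class_probabilities")) probs <- probs$probs
  if (y < 0 || y >= length(probs)) stop("label out of range")
  -log(max(probs[y + 1L], 1e-12))
}

#' Attention-morphology alignment loss
#'
#' `1 - sum(A * M) / sum(A)`: the fraction of attention mass falling outside
#' the lesion mask. Scale-free in A (invariant to positive rescaling). A
#' degenerate all-zero map returns 0 with a warning.
#'
#' @param A nonnegative attention map (upsampled to mask resolution).
#' @param M soft or binary lesion mask, same dimensions.
#' @return scalar in \[0, 1\].
#' @export
attention_alignment_loss <- function(A, M) {
  if (!all(dim(A) == dim(M))) stop("attention map and mask dimensions differ")
  if (any(A < 0)) stop("attention map must be nonnegative")
  sA <- sum(A)
  if (sA == 0) {
    warning("attention map has zero mass; alignment loss undefined, returning 0")
    return(0)
  }
  1 - sum(A * M) / sA
}

attention_alignment_grad <- function(A, M) {
  sA <- max(sum(A), 1e-6)  # clamp: the ratio gradient is unbounded at 0 mass
  sAM <- sum(A * M)
  (sAM - M * sA) / sA^2
}

#' Confidence-penalty calibration loss
#'
#' The study's objective includes an uncertainty-calibration term without a
#' stated formula; this package's default is a shifted confidence penalty,
#' `log(C) - H(p)`, which is zero for a uniform prediction and grows as the
#' prediction sharpens. Switch it off via its lambda weight.
#'
#' @param probs probability vector.
#' @return nonnegative scalar.
#' @export
confidence_penalty <- function(probs) {
  if (inherits(probs, "class_probabilities")) probs <- probs$probs
  p <- pmax(probs, 1e-12)
  log(length(p)) + sum(p * log(p))
}

# d(confidence_penalty)/d(logits)
confidence_penalty_grad_logits <- function(probs) {
  lp <- log(pmax(probs, 1e-12))
  probs * (lp - sum(probs * lp))
}

#' Compose the total training loss
#'
#' `l_total = lambda1*l_seg + lambda2*l_cls + lambda3*l_att + lambda4*l_unc`,
#' with all components and weights recorded for logging and ablation.
#'
#' @param l_seg,l_cls,l_att,l_unc nonnegative loss components.
#' @param lambdas numeric length-4 weights (nonnegative).
#' @return list of class `loss_breakdown`.
#' @export
total_loss <- function(l_seg, l_cls, l_att, l_unc, lambdas = c(1, 1, 0.5, 0.01)) {
  if (length(lambdas) != 4 || any(lambdas < 0))
    stop("lambdas must be 4 nonnegative weights")
  if (any(c(l_seg, l_cls, l_att, l_unc) < 0))
    stop("loss components must be nonnegative")
  out <- list(l_seg = l_seg, l_cls = l_cls, l_att = l_att, l_unc = l_unc,
              lambdas = lambdas,
              l_total = sum(lambdas * c(l_seg, l_cls, l_att, l_unc)))
  class(out) <- "loss_breakdown"
  out
}

#' Classifier training configuration
#'
#' Defaults are the desk-scale test profile (64 x 64 inputs, 20 epochs,
#' patience 5, raised learning rate for from-scratch training). The
#' full-scale study protocol (AdamW 1e-4, cosine annealing, batch 16, max
#' 150 epochs, patience 25) is reachable by overriding `lr`, `epochs` and
#' `patience`.
#'
#' @param epochs maximum epochs.
#' @param patience early-stopping patience on validation accuracy.
#' @param batch_size mini-batch size.
#' @param lr initial AdamW learning rate (cosine-annealed).
#' @param weight_decay AdamW weight decay.
#' @param lambdas length-4 loss weights (seg, cls, att, unc).
#' @param background_attenuation passed to [apply_mask()].
#' @param use_segmentation logical; mask the input with the segmenter's
#'   prediction (all-ones mask when `FALSE` -- ablation).
#' @param use_attention logical; enable the attention gates.
#' @param dropout head dropout probability.
#' @param size working resolution.
#' @param base backbone base width.
#' @param val_fraction validation split fraction.
#' @param uncertainty_loss `"confidence_penalty"` or `"off"`.
#' @param grad_clip maximum global gradient norm per sample (the ratio-form
#'   alignment loss has an unbounded gradient as attention mass vanishes;
#'   clipping prevents gate collapse).
#' @param backbone_dropout feature-space dropout probability (see
#'   [classifier_new()]).
#' @return list of class `cls_config`.
#' @export
cls_config <- function(epochs = 20L, patience = 5L, batch_size = 16L,
                       lr = 2e-3, weight_decay = 1e-4,
                       lambdas = c(1, 1, 0.5, 0.01),
                       background_attenuation = 0,
                       use_segmentation = TRUE, use_attention = TRUE,
                       dropout = 0.25, size = 64L, base = 16L,
                       val_fraction = 0.15,
                       uncertainty_loss = c("confidence_penalty", "off"),
                       grad_clip = 5, backbone_dropout = 0.1) {
  uncertainty_loss <- match.arg(uncertainty_loss)
  if (length(lambdas) != 4 || any(lambdas < 0)) stop("invalid lambdas")
  structure(list(epochs = as.integer(epochs), patience = as.integer(patience),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, lambdas = lambdas,
                 background_attenuation = background_attenuation,
                 use_segmentation = isTRUE(use_segmentation),
                 use_attention = isTRUE(use_attention), dropout = dropout,
                 size = as.integer(size), base = as.integer(base),
                 val_fraction = val_fraction,
                 uncertainty_loss = uncertainty_loss,
                 grad_clip = grad_clip,
                 backbone_dropout = backbone_dropout),
            class = "cls_config")
}

#' Epoch at which early stopping halts
#'
#' Training halts after `patience` consecutive epochs without improvement of
#' the monitored metric over its running best (higher is better).
#'
#' @param metrics per-epoch validation metric sequence.
#' @param patience integer patience.
#' @return the epoch index at which training stops (length of the sequence
#'   if the criterion never triggers).
#' @export
early_stopping_epoch <- function(metrics, patience) {
  best <- -Inf; best_i <- 0L
  for (i in seq_along(metrics)) {
    if (metrics[i] > best) {
      best <- metrics[i]; best_i <- i
    } else if (i - best_i >= patience) {
      return(i)
    }
  }
  length(metrics)
}

# one full pipeline forward for a [0,1] image: normalize -> predict_mask ->
# apply_mask -> features -> attention -> head
model_forward <- function(model, image01, training = FALSE) {
  cfg <- model$config
  x <- normalize_image(image01, size = model$size)
  M <- if (isTRUE(cfg$use_segmentation) && !is.null(model$segmenter))
    predict_mask(model$segmenter, x) else matrix(1, model$size, model$size)
  xm <- apply_mask(x, M, cfg$background_attenuation %||% 0)
  out <- classifier_forward(model, xm, training)
  c(out, list(mask = M, x_norm = x, x_masked = xm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class probabilities for one image
#'
#' Runs the full pipeline (normalize, segment, mask, attend, classify) in
#' evaluation mode.
#'
#' @param model a trained `lesion_classifier` (with attached segmenter).
#' @param image H x W x 3 image in \[0, 1\].
#' @return list with `probs`, `logits`, `embedding`, `bundle`, `mask`.
#' @export
predict_lesion <- function(model, image) {
  model_forward(model, image, training = FALSE)
}

#' Train the attention classifier on segmenter-masked images
#'
#' Staged pipeline: the segmenter is trained first and frozen here; each
#' training step runs normalize -> predict_mask -> apply_mask -> features ->
#' attention -> head and optimizes the composite objective (weighted Dice,
#' cross-entropy, attention alignment, confidence penalty). Early stopping
#' monitors validation accuracy; the best checkpoint is restored.
#'
#' @param dataset metadata table with attached samples (labels required).
#' @param segmenter trained `unet_model`, or `NULL` when
#'   `config$use_segmentation` is `FALSE`.
#' @param config a [cls_config()].
#' @param seed integer seed.
#' @return trained `lesion_classifier` with `$segmenter`, `$config`,
#'   `$history` (epoch, tr_loss, val_loss, tr_acc, val_acc, lr) and
#'   `$best_epoch`.
#' @export
train_classifier <- function(dataset, segmenter, config = cls_config(),
                             seed = 1L) {
  samples <- dataset_samples(dataset)
  labels <- vapply(samples, function(s) s$label, 0L)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes to train")
  n_classes <- length(classes)
  if (config$use_segmentation && is.null(segmenter))
    stop("use_segmentation = TRUE requires a trained segmenter")
  lam <- config$lambdas
  run_seeded(seed, {
    model <- classifier_new(n_classes, seed = derive_seed(seed, 2L),
                            base = config$base, size = config$size,
                            dropout = config$dropout,
                            use_attention = config$use_attention,
                            backbone_dropout = config$backbone_dropout)
    model$segmenter <- segmenter
    model$config <- config
    model$classes <- classes
    # segmenter frozen: precompute normalized image, mask, masked input, G
    prep <- lapply(samples, function(s) {
      x <- normalize_image(s$image, size = config$size)
      M <- if (config$use_segmentation) predict_mask(segmenter, x)
           else matrix(1, config$size, config$size)
      list(xm = apply_mask(x, M, config$background_attenuation), M = M,
           g = resize_mask(s$mask, config$size),
           y = match(s$label, classes) - 1L)
    })
    n <- length(prep)
    n_val <- max(1L, round(config$val_fraction * n))
    perm <- sample(n)
    val_idx <- perm[seq_len(n_val)]; tr_idx <- perm[-seq_len(n_val)]
    layers <- model$layers
    hist <- data.frame()
    best <- list(acc = -Inf, state = NULL, epoch = 0L)
    step_t <- 0L
    use_att_loss <- config$use_attention && lam[3] > 0
    use_unc <- config$uncertainty_loss == "confidence_penalty" && lam[4] > 0
    S <- config$size
    for (ep in seq_len(config$epochs)) {
      lr <- cosine_lr(ep, config$epochs, config$lr)
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_correct <- 0L
      for (bs in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        nn_zero_grad(layers)
        for (i in bs) {
          pp <- prep[[i]]
          out <- classifier_forward(model, pp$xm, training = TRUE)
          y1 <- pp$y + 1L
          l_cls <- cross_entropy(out$probs, pp$y)
          l_seg <- if (config$use_segmentation) dice_loss(pp$M, pp$g) else 0
          dAs_extra <- NULL
          l_att <- 0
          if (use_att_loss) {
            As <- out$bundle$spatial_map
            A_up <- resize_bilinear_cpp(array(As, dim = c(dim(As), 1L)),
                                        S, S)[, , 1]
            if (sum(A_up) > 0) {
              l_att <- 1 - sum(A_up * pp$M) / sum(A_up)
              dA_up <- lam[3] * attention_alignment_grad(A_up, pp$M)
              dAs_extra <- resize_bilinear_backward_cpp(
                array(dA_up, dim = c(S, S, 1L)), dim(As)[1], dim(As)[2])[, , 1]
            }
          }
          l_unc <- if (use_unc) confidence_penalty(out$probs) else 0
          lb <- total_loss(l_seg, l_cls, l_att, l_unc, lam)
          ep_loss <- ep_loss + lb$l_total
          if (which.max(out$probs) == y1) ep_correct <- ep_correct + 1L
          onehot <- numeric(n_classes); onehot[y1] <- 1
          dlogits <- lam[2] * (out$probs - onehot)
          if (use_unc)
            dlogits <- dlogits + lam[4] * confidence_penalty_grad_logits(out$probs)
          classifier_backward(model, dlogits, dAs_extra)
        }
        step_t <- step_t + 1L
        clip_global_grad_norm(layers, config$grad_clip * length(bs))
        adamw_step(layers, lr, n_accum = length(bs),
                   weight_decay = config$weight_decay, t = step_t)
      }
      # validation pass (evaluation mode)
      val_loss <- 0; val_correct <- 0L
      for (i in val_idx) {
        out <- classifier_forward(model, prep[[i]]$xm, training = FALSE)
        val_loss <- val_loss + cross_entropy(out$probs, prep[[i]]$y)
        if (which.max(out$probs) == prep[[i]]$y + 1L)
          val_correct <- val_correct + 1L
      }
      val_acc <- val_correct / length(val_idx)
      hist <- rbind(hist, data.frame(
        epoch = ep, tr_loss = ep_loss / length(tr_idx),
        val_loss = val_loss / length(val_idx),
        tr_acc = ep_correct / length(tr_idx), val_acc = val_acc, lr = lr))
      if (val_acc > best$acc)
        best <- list(acc = val_acc, state = nn_get_state(layers), epoch = ep)
      if (ep - best$epoch >= config$patience) break
    }
    nn_set_state(layers, best$state)
    model$history <- hist
    model$best_epoch <- best$epoch
    model
  })
}
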