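# Gradient-based attribution: Grad-CAM over the attention-refined feature
# map, pixel-level saliency, mask alignment of explanation maps, and a
# quantitative in-mask coverage metric.

relu_mat <- function(x) pmax(x, 0)

max_normalize <- function(m) {
  mx <- max(m)
  if (mx > 0) m / mx else m   # all-zero maps are left as zeros
}

# gradient of the target-class logit w.r.t. the refined features f_a,
# through the head only (GAP -> projection -> linear); dropout inactive
head_feature_grad <- function(model, target_class) {
  L <- model$layers
  onehot <- numeric(model$n_classes)
  onehot[target_class + 1L] <- 1
  dd <- nn_backward(L$fc, onehot)
  de <- nn_backward(L$drop, dd)
  dg <- seq_backward(L[c("psi", "rp")], de)
  gap_backward(dg, model$head_cache$h, model$head_cache$w)
}

#' Assemble a Grad-CAM map from features and their gradients
#'
#' `alpha_k` is the spatial mean of the gradient of the target logit with
#' respect to feature channel k; the map is `ReLU(sum_k alpha_k * F_k)`
#' (not yet upsampled or normalized).
#'
#' @param features h x w x C feature array (the target layer's activations).
#' @param grads gradient array of the target-class logit w.r.t. `features`,
#'   same dims.
#' @return h x w nonnegative matrix.
#' @export
gradcam_map <- function(features, grads) {
  if (!all(dim(features) == dim(grads))) stop("dimension mismatch")
  alpha <- apply(grads, 3L, mean)
  map <- matrix(0, dim(features)[1], dim(features)[2])
  for (k in seq_len(dim(features)[3])) map <- map + alpha[k] * features[, , k]
  relu_mat(map)
}

#' Grad-CAM explanation map
#'
#' Channel weights are the spatial means of the target-class logit gradient
#' over the refined feature map f_a; the map is the ReLU of the weighted
#' feature sum, bilinearly upsampled to the working resolution and
#' max-normalized (all-zero maps stay zero).
#'
#' @param model a trained `lesion_classifier`.
#' @param image H x W x 3 image in \[0, 1\].
#' @param target_class 0-based class to explain; defaults to the predicted
#'   class.
#' @return object of class `explanation_map` with `raw_map` (values in
#'   \[0, 1\]), `target_class`, `method`, and the pipeline's predicted `mask`.
#' @export
grad_cam <- function(model, image, target_class = NULL) {
  out <- model_forward(model, image, training = FALSE)
  if (is.null(target_class)) target_class <- which.max(out$probs) - 1L
  if (target_class < 0 || target_class >= model$n_classes)
    stop("target_class out of range")
  fa <- out$bundle$refined_features
  dfa <- head_feature_grad(model, target_class)
  map <- gradcam_map(fa, dfa)
  S <- model$size
  map <- resize_bilinear_cpp(array(map, dim = c(dim(map), 1L)), S, S)[, , 1]
  structure(list(raw_map = max_normalize(map),
                 target_class = as.integer(target_class), method = "gradcam",
                 mask = out$mask),
            class = "explanation_map")
}

#' Align an explanation map with the lesion mask
#'
#' Elementwise product of the explanation map and the (soft or binarized)
#' segmentation mask, so attributions outside the lesion are suppressed.
#' Never increases attribution mass.
#'
#' @param M_exp an `explanation_map` or a nonnegative matrix.
#' @param M soft mask matrix; when `M_exp` carries its pipeline mask this
#'   may be omitted.
#' @param binarize logical; threshold the mask at 0.5 before aligning (hard
#'   clipping for figures).
#' @return for an `explanation_map` input, the object with `aligned_map`
#'   filled in; for a matrix input, the aligned matrix.
#' @export
align_explanation <- function(M_exp, M = NULL, binarize = FALSE) {
  if (inherits(M_exp, "explanation_map")) {
    if (is.null(M)) M <- M_exp$mask
    if (binarize) M <- binarize_mask(M)
    if (!all(dim(M_exp$raw_map) == dim(M))) stop("dimension mismatch")
    M_exp$aligned_map <- M_exp$raw_map * M
    return(M_exp)
  }
  if (is.null(M)) stop("a mask is required")
  if (binarize) M <- binarize_mask(M)
  if (!all(dim(M_exp) == dim(M))) stop("dimension mismatch")
  M_exp * M
}

#' Pixel saliency map
#'
#' Maximum over channels of the absolute gradient of the top-class logit
#' with respect to the (working-resolution, normalized) input, max-
#' normalized. Deterministic: dropout is inactive.
#'
#' @param model a `lesion_classifier` or [linear_probe()].
#' @param image input image in \[0, 1\].
#' @param ... unused.
#' @return H x W nonnegative matrix with maximum 1.
#' @export
saliency <- function(model, image, ...) UseMethod("saliency")

#' @export
saliency.lesion_classifier <- function(model, image, ...) {
  out <- model_forward(model, image, training = FALSE)
  onehot <- numeric(model$n_classes)
  onehot[which.max(out$probs)] <- 1
  dxm <- classifier_backward(model, onehot)
  gate <- out$mask + (model$config$background_attenuation %||% 0) * (1 - out$mask)
  dx <- dxm
  for (ch in seq_len(dim(dx)[3])) dx[, , ch] <- dx[, , ch] * gate
  max_normalize(apply(abs(dx), c(1, 2), max))
}

#' Linear probe model (single linear layer on flattened pixels)
#'
#' A minimal model satisfying the saliency interface, mostly useful as an
#' analytic oracle: its top-class saliency is exactly `|w|` reshaped to the
#' image plane.
#'
#' @param W C x (H*W*ch) weight matrix.
#' @param b length-C bias.
#' @param dims input dims c(H, W, channels).
#' @return object of class `linear_probe`.
#' @export
linear_probe <- function(W, b, dims) {
  structure(list(W = W, b = b, dims = dims), class = "linear_probe")
}

#' @export
saliency.linear_probe <- function(model, image, ...) {
  x <- as.numeric(image)
  logits <- drop(model$W %*% x) + model$b
  g <- model$W[which.max(logits), ]
  garr <- array(abs(g), dim = model$dims)
  if (length(model$dims) == 3L && model$dims[3] > 1L)
    max_normalize(apply(garr, c(1, 2), max))
  else max_normalize(garr[, , 1, drop = TRUE])
}

#' Fraction of attribution mass inside a reference mask
#'
#' `sum(map * mask) / sum(map)`. Complementary masks satisfy
#' `coverage(map, M) + coverage(map, 1 - M) = 1`. Equals one minus the
#' attention-alignment loss applied to the map.
#'
#' @param map nonnegative attribution map with positive total mass.
#' @param reference_mask binary or soft mask, same dims.
#' @return scalar in \[0, 1\].
#' @export
explanation_coverage <- function(map, reference_mask) {
  if (inherits(map, "explanation_map")) map <- map$raw_map
  if (!all(dim(map) == dim(reference_mask))) stop("dimension mismatch")
  if (any(map < 0)) stop("map must be nonnegative")
  s <- sum(map)
  if (s == 0) stop("zero-mass map: coverage undefined")
  sum(map * reference_mask) / s
}

heat_colors <- function(v) {
  # piecewise-linear blue -> cyan -> yellow -> red ramp, v in [0,1]
  r <- pmin(pmax(3 * v - 1.5, 0), 1)
  g <- pmin(pmax(1.5 - abs(3 * v - 1.5), 0), 1)
  b <- pmin(pmax(1.5 - 3 * v, 0), 1)
  list(r = r, g = g, b = b)
}

#' Render a heatmap overlay as a PNG file
#'
#' Alpha-blends a normalized attribution map (as a blue-to-red heatmap)
#' over the RGB image. With `alpha = 0` the written image equals the input.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param map normalized map in \[0, 1\], same spatial dims.
#' @param out_path output PNG path.
#' @param alpha blend weight of the heatmap in \[0, 1\].
#' @return `out_path`, invisibly.
#' @export
render_overlay <- function(image, map, out_path, alpha = 0.45) {
  if (inherits(map, "explanation_map"))
    map <- if (!is.null(map$aligned_map)) map$aligned_map else map$raw_map
  if (!all(dim(image)[1:2] == dim(map))) stop("dimension mismatch")
  hc <- heat_colors(pmin(pmax(map, 0), 1))
  out <- image
  out[, , 1] <- (1 - alpha) * image[, , 1] + alpha * hc$r
  out[, , 2] <- (1 - alpha) * image[, , 2] + alpha * hc$g
  out[, , 3] <- (1 - alpha) * image[, , 3] + alpha * hc$b
  write_png(out, out_path)
}
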