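# Monte Carlo dropout predictive distributions, scalar uncertainty,
# rejection (selective prediction) analysis, threshold selection and
# calibration reporting.

#' Monte Carlo dropout prediction
#'
#' Keeps the model's dropout layers active at inference and draws `T`
#' stochastic forward passes through the classifier (the segmenter and the
#' masking are deterministic and computed once). The head dropout and the
#' feature-space backbone dropout both stay active, so the samples carry
#' epistemic uncertainty over features, not just over the final embedding.
#' Fully seeded.
#'
#' @param model a trained `lesion_classifier` (contains dropout layers).
#' @param image H x W x 3 image in \[0, 1\].
#' @param T number of stochastic passes (>= 1).
#' @param seed integer seed.
#' @return object of class `mc_prediction`: `samples` (T x C, rows on the
#'   simplex), `mean`, `variance` (population moments), `T`.
#' @export
mc_predict <- function(model, image, T = 25L, seed = 1L) {
  if (T < 1) stop("T must be >= 1")
  cfg <- model$config
  x <- normalize_image(image, size = model$size)
  M <- if (isTRUE(cfg$use_segmentation) && !is.null(model$segmenter))
    predict_mask(model$segmenter, x) else matrix(1, model$size, model$size)
  xm <- apply_mask(x, M, cfg$background_attenuation %||% 0)
  mc_stochastic_samples(model, list(xm), T, seed)
}

# T dropout-active classifier passes per masked input, stacked. The trunk
# up to the first stochastic layer (fdrop) is deterministic, so it is
# evaluated once per input and only the stochastic tail is resampled.
mc_stochastic_samples <- function(model, xms, T, seed) {
  L <- model$layers
  pre <- c("c1", "r1", "p1", "c2", "r2", "p2", "c3", "r3", "p3")
  tail_names <- c("fdrop", "c4", "r4")
  mc_layers <- Filter(function(l) l$type == "dropout" && l$p > 0, L)
  for (l in mc_layers) l$active <- TRUE
  on.exit(for (l in mc_layers) l$active <- FALSE)
  run_seeded(seed, {
    samples <- matrix(0, T * length(xms), model$n_classes)
    r <- 0L
    for (xm in xms) {
      f3 <- seq_forward(L[pre], xm, training = FALSE)
      for (t in seq_len(T)) {
        r <- r + 1L
        f <- seq_forward(L[tail_names], f3, training = FALSE)
        bundle <- attend(model, f, training = FALSE)
        samples[r, ] <- classify(model, bundle$refined_features,
                                 training = FALSE)$probs
      }
    }
    mom <- predictive_moments(samples)
    structure(list(samples = samples, mean = mom$mean,
                   variance = mom$variance, T = nrow(samples)),
              class = "mc_prediction")
  })
}

#' Predictive mean and variance of MC samples
#'
#' Population moments over the `T` rows: `mean = colMeans(samples)`,
#' `variance = colMeans((samples - mean)^2)` (divide by T, not T - 1).
#'
#' @param samples T x C matrix of probability vectors.
#' @return list with `mean` and `variance` (length-C vectors).
#' @export
predictive_moments <- function(samples) {
  if (is.null(dim(samples)) || nrow(samples) < 1) stop("empty sample matrix")
  mu <- colMeans(samples)
  v <- colMeans(sweep(samples, 2, mu)^2)
  list(mean = mu, variance = v)
}

#' Scalar uncertainty of an MC prediction
#'
#' `class_variance` (default): predictive variance of the argmax class of
#' the mean; `entropy`: Shannon entropy of the predictive mean.
#'
#' @param pred an `mc_prediction`.
#' @param method `"class_variance"` or `"entropy"`.
#' @return nonnegative scalar.
#' @export
uncertainty_score <- function(pred, method = c("class_variance", "entropy")) {
  method <- match.arg(method)
  if (method == "class_variance") {
    pred$variance[which.max(pred$mean)]
  } else {
    p <- pmax(pred$mean, 1e-12)
    -sum(p * log(p))
  }
}

#' Uncertainty-based rejection analysis
#'
#' At each threshold, samples with `score > threshold` are rejected
#' (strict inequality). Reports the rejected percentage, accuracy over the
#' accepted subset, the fraction of incorrect predictions rejected, and the
#' fraction of correct predictions rejected, all as percentages.
#'
#' @param scores per-sample uncertainty scores.
#' @param correct logical vector, prediction correctness.
#' @param thresholds sorted candidate thresholds.
#' @return data.frame of class `rejection_curve` with columns `threshold`,
#'   `reject_pct`, `accepted_accuracy_pct`, `incorrect_rejected_pct`,
#'   `correct_rejected_pct`.
#' @export
rejection_analysis <- function(scores, correct, thresholds) {
  if (length(scores) != length(correct)) stop("length mismatch")
  if (is.unsorted(thresholds)) stop("thresholds must be sorted")
  correct <- as.logical(correct)
  rows <- lapply(thresholds, function(th) {
    rej <- scores > th
    acc <- if (all(rej)) {
      warning("all samples rejected at threshold ", th,
              "; accepted accuracy undefined")
      NA_real_
    } else 100 * mean(correct[!rej])
    data.frame(
      threshold = th,
      reject_pct = 100 * mean(rej),
      accepted_accuracy_pct = acc,
      incorrect_rejected_pct =
        if (any(!correct)) 100 * sum(rej & !correct) / sum(!correct) else 0,
      correct_rejected_pct =
        if (any(correct)) 100 * sum(rej & correct) / sum(correct) else 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rejection_curve", "data.frame")
  out
}

#' Select an uncertainty rejection threshold on validation data
#'
#' Over the grid of unique score values, returns the threshold maximizing
#' accepted accuracy subject to the fraction of correct predictions
#' rejected not exceeding `max_correct_rejection`; ties are broken towards
#' the largest threshold (least rejection). If no threshold is feasible the
#' maximum score is returned (reject nothing) with a warning.
#'
#' @param scores validation uncertainty scores.
#' @param correct logical correctness on validation.
#' @param max_correct_rejection maximum tolerated correct-rejection
#'   fraction (in \[0, 1\]).
#' @return the selected threshold.
#' @export
select_threshold <- function(scores, correct, max_correct_rejection = 0.05) {
  if (!length(scores)) stop("empty validation arrays")
  correct <- as.logical(correct)
  cand <- sort(unique(scores))
  best_acc <- -Inf; best_th <- NA_real_
  for (th in cand) {
    rej <- scores > th
    if (all(rej)) next
    cr <- if (any(correct)) sum(rej & correct) / sum(correct) else 0
    if (cr > max_correct_rejection) next
    acc <- mean(correct[!rej])
    if (acc > best_acc || (acc == best_acc && th > best_th)) {
      best_acc <- acc; best_th <- th
    }
  }
  if (!is.finite(best_acc)) {
    warning("no feasible threshold; rejecting nothing")
    return(max(scores))
  }
  best_th
}

#' Calibration report: reliability bins, ECE and Brier score
#'
#' Equal-width bins on \[0, 1\]. `ECE = sum_b w_b |acc_b - conf_b|` with
#' `w_b` the fraction of samples in bin b. The Brier score is the mean
#' squared error between the full probability vector and the one-hot label
#' (multi-class form) when `probs`/`labels` are supplied, else the binary
#' form `mean((confidence - correct)^2)`.
#'
#' @param confidences per-sample confidence in \[0, 1\] (max predictive mean).
#' @param correct logical correctness.
#' @param n_bins number of equal-width bins (>= 1).
#' @param probs optional n x C matrix of predicted probability vectors.
#' @param labels optional 0-based true labels matching `probs`.
#' @return list of class `calibration_report`: `bin_edges`,
#'   `bin_confidence`, `bin_accuracy`, `bin_weight`, `ece`, `brier`.
#' @export
calibration_report <- function(confidences, correct, n_bins = 10L,
                               probs = NULL, labels = NULL) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (any(confidences < 0 | confidences > 1)) stop("confidences must be in [0, 1]")
  correct <- as.logical(correct)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(confidences, edges, rightmost.closed = TRUE),
                   1L), n_bins)
  n <- length(confidences)
  conf_b <- acc_b <- w_b <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    in_b <- bin == b
    w_b[b] <- sum(in_b) / n
    if (any(in_b)) {
      conf_b[b] <- mean(confidences[in_b])
      acc_b[b] <- mean(correct[in_b])
    }
  }
  nonempty <- w_b > 0
  ece <- sum(w_b[nonempty] * abs(acc_b[nonempty] - conf_b[nonempty]))
  brier <- if (!is.null(probs) && !is.null(labels)) {
    onehot <- matrix(0, nrow(probs), ncol(probs))
    onehot[cbind(seq_len(nrow(probs)), labels + 1L)] <- 1
    mean(rowSums((probs - onehot)^2))
  } else mean((confidences - correct)^2)
  structure(list(bin_edges = edges, bin_confidence = conf_b,
                 bin_accuracy = acc_b, bin_weight = w_b,
                 ece = ece, brier = brier),
            class = "calibration_report")
}

#' MC-dropout prediction with test-time augmentation
#'
#' Averages MC-dropout passes over four deterministic views (identity,
#' horizontal flip, vertical flip, both flips); the stochastic samples from
#' all views are stacked before the moments are computed.
#'
#' @inheritParams mc_predict
#' @param T stochastic passes per view.
#' @return `mc_prediction` with `T * 4` sample rows.
#' @export
tta_predict <- function(model, image, T = 25L, seed = 1L) {
  if (T < 1) stop("T must be >= 1")
  nr <- dim(image)[1]; ncl <- dim(image)[2]
  views <- list(
    image,
    image[, rev(seq_len(ncl)), , drop = FALSE],
    image[rev(seq_len(nr)), , , drop = FALSE],
    image[rev(seq_len(nr)), rev(seq_len(ncl)), , drop = FALSE])
  cfg <- model$config
  xms <- lapply(views, function(v) {
    x <- normalize_image(v, size = model$size)
    M <- if (isTRUE(cfg$use_segmentation) && !is.null(model$segmenter))
      predict_mask(model$segmenter, x) else matrix(1, model$size, model$size)
    apply_mask(x, M, cfg$background_attenuation %||% 0)
  })
  mc_stochastic_samples(model, xms, T, seed)
}
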