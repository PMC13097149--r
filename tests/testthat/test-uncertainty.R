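test_that("mc_predict respects T, dropout rate and seeding", {
  ds <- tiny_dataset(n_per_class = 15L, seed = 55L, image_size = 32L)
  img <- attr(ds, "samples")[[1]]$image
  m <- tiny_model()

  one <- mc_predict(m, img, T = 1L, seed = 3L)
  expect_equal(nrow(one$samples), 1L)
  expect_equal(one$variance, rep(0, 3), tolerance = 1e-12)

  a <- mc_predict(m, img, T = 8L, seed = 3L)
  b <- mc_predict(m, img, T = 8L, seed = 3L)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples[1, ], a$samples[2, ]))
  expect_true(all(abs(rowSums(a$samples) - 1) < 1e-6))
  expect_equal(a$mean, colMeans(a$samples))
  expect_error(mc_predict(m, img, T = 0L), "T must")

  m0 <- tiny_model(dropout = 0)
  z <- mc_predict(m0, img, T = 6L, seed = 3L)
  expect_equal(max(apply(z$samples, 2, stats::sd)), 0)   # no stochasticity
  expect_equal(z$variance, rep(0, 3), tolerance = 1e-15)
})

test_that("predictive_moments are the exact population moments", {
  s <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  mom <- predictive_moments(s)
  expect_equal(mom$mean, c(0.5, 0.5))
  expect_equal(mom$variance, c(0.25, 0.25))

  expect_equal(predictive_moments(matrix(rep(c(0.2, 0.8), 5), 5,
                                         byrow = TRUE))$variance, c(0, 0))
  expect_error(predictive_moments(matrix(nrow = 0, ncol = 3)), "empty")

  # oracle: direct re-summation on random simplex matrices
  set.seed(13)
  for (i in 1:100) {
    Tn <- sample(1:12, 1); C <- sample(2:7, 1)
    x <- matrix(rexp(Tn * C), Tn, C)
    x <- x / rowSums(x)
    mom <- predictive_moments(x)
    mu_direct <- apply(x, 2, function(col) sum(col) / Tn)
    var_direct <- vapply(seq_len(C), function(j)
      sum((x[, j] - mu_direct[j])^2) / Tn, 0)
    expect_equal(mom$mean, mu_direct, tolerance = 1e-12)
    expect_equal(mom$variance, var_direct, tolerance = 1e-12)
    expect_equal(sum(mom$mean), 1, tolerance = 1e-9)
  }
})

test_that("uncertainty_score scalarizes as specified", {
  p <- structure(list(samples = matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
                      mean = c(0.5, 0.5), variance = c(0.25, 0.25), T = 2L),
                 class = "mc_prediction")
  expect_equal(uncertainty_score(p, "class_variance"), 0.25)
  u <- structure(list(mean = rep(1 / 7, 7), variance = rep(0, 7)),
                 class = "mc_prediction")
  expect_equal(uncertainty_score(u, "class_variance"), 0)
  expect_equal(uncertainty_score(u, "entropy"), log(7), tolerance = 1e-10)
  expect_error(uncertainty_score(u, "banana"))
})

brute_force_rejection <- function(scores, correct, thresholds) {
  # independent enumeration oracle
  do.call(rbind, lapply(thresholds, function(th) {
    rej <- which(scores > th)
    keep <- setdiff(seq_along(scores), rej)
    data.frame(threshold = th,
               reject_pct = 100 * length(rej) / length(scores),
               accepted_accuracy_pct = if (!length(keep)) NA_real_
                 else 100 * sum(correct[keep]) / length(keep),
               incorrect_rejected_pct = if (!any(!correct)) 0 else
                 100 * sum(!correct[rej]) / sum(!correct),
               correct_rejected_pct = if (!any(correct)) 0 else
                 100 * sum(correct[rej]) / sum(correct))
  }))
}

test_that("rejection_analysis equals exhaustive enumeration", {
  set.seed(14)
  scores <- runif(200)
  correct <- runif(200) < 0.8
  th <- sort(runif(15))
  got <- rejection_analysis(scores, correct, th)
  expect_equal(as.data.frame(got), brute_force_rejection(scores, correct, th),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(diff(got$reject_pct) <= 0))   # non-increasing in theta

  # hand-listed 10 pairs
  s10 <- c(0.1, 0.9, 0.3, 0.7, 0.2, 0.8, 0.05, 0.6, 0.4, 0.95)
  c10 <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)
  th10 <- c(0.25, 0.5, 0.75)
  expect_equal(as.data.frame(rejection_analysis(s10, c10, th10)),
               brute_force_rejection(s10, c10, th10), ignore_attr = TRUE)

  # threshold above the max score rejects nothing
  top <- rejection_analysis(scores, correct, max(scores) + 1)
  expect_equal(top$reject_pct, 0)
  expect_equal(top$accepted_accuracy_pct, 100 * mean(correct))

  all_correct <- rejection_analysis(scores, rep(TRUE, 200), th)
  expect_true(all(all_correct$accepted_accuracy_pct == 100))

  expect_warning(rejection_analysis(c(1, 2), c(TRUE, TRUE), 0.5), "rejected")
})

test_that("select_threshold maximizes accepted accuracy under the constraint", {
  # perfectly separable: all incorrect scores above all correct scores
  scores <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  correct <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  th <- select_threshold(scores, correct, max_correct_rejection = 0.1)
  expect_true(th >= 0.3 && th < 0.8)
  expect_equal(mean(correct[scores <= th]), 1)

  # zero tolerated correct rejection forces th >= max correct score
  s2 <- c(0.1, 0.5, 0.4, 0.6)
  c2 <- c(TRUE, TRUE, FALSE, FALSE)
  th2 <- select_threshold(s2, c2, max_correct_rejection = 0)
  expect_gte(th2, 0.5)

  expect_equal(select_threshold(c(0.2, 0.7), c(TRUE, TRUE)), 0.7)
  expect_error(select_threshold(numeric(0), logical(0)), "empty")
})

test_that("calibration_report matches its closed forms", {
  perf <- calibration_report(rep(1, 50), rep(TRUE, 50))
  expect_equal(perf$ece, 0)
  expect_equal(perf$brier, 0)

  # single nonempty bin: mean confidence 0.8, accuracy 0.5 -> ECE 0.3
  r <- calibration_report(rep(0.8, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(r$ece, 0.3, tolerance = 1e-12)
  expect_equal(sum(r$bin_weight[r$bin_weight > 0]), 1)

  # multi-class Brier from full probability vectors
  probs <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  rb <- calibration_report(c(1, 1), c(TRUE, TRUE), probs = probs,
                           labels = c(0L, 1L))
  expect_equal(rb$brier, 0)
  rb2 <- calibration_report(c(0.5, 0.5), c(TRUE, FALSE),
                            probs = matrix(0.5, 2, 2), labels = c(0L, 0L))
  expect_equal(rb2$brier, 0.5)   # 2 * 0.25 per sample

  expect_error(calibration_report(c(0.5), c(TRUE), n_bins = 0), "n_bins")
  expect_error(calibration_report(c(1.2), c(TRUE)), "confidences")
})

test_that("a calibrated-by-construction predictor has near-zero ECE", {
  set.seed(15)
  n <- 10000
  conf <- runif(n, 0.5, 1)
  correct <- runif(n) < conf
  r <- calibration_report(conf, correct)
  expect_lt(r$ece, 0.02)
})

test_that("tta_predict stacks views and degenerates correctly", {
  ds <- tiny_dataset(n_per_class = 15L, seed = 55L, image_size = 32L)
  img <- attr(ds, "samples")[[1]]$image
  m0 <- tiny_model(dropout = 0)

  # flip-symmetric input: all four views identical, no view variance
  sym <- img
  sym <- (sym + sym[, rev(seq_len(dim(sym)[2])), , drop = FALSE]) / 2
  sym <- (sym + sym[rev(seq_len(dim(sym)[1])), , , drop = FALSE]) / 2
  p_sym <- tta_predict(m0, sym, T = 2L, seed = 1L)
  expect_equal(max(p_sym$variance), 0, tolerance = 1e-12)

  # dropout 0: moments equal the plain 4-view average
  p <- tta_predict(m0, img, T = 3L, seed = 1L)
  expect_equal(nrow(p$samples), 12L)
  views <- list(img,
                img[, rev(seq_len(dim(img)[2])), , drop = FALSE],
                img[rev(seq_len(dim(img)[1])), , , drop = FALSE],
                img[rev(seq_len(dim(img)[1])), rev(seq_len(dim(img)[2])), ,
                    drop = FALSE])
  avg <- rowMeans(vapply(views, function(v) predict_lesion(m0, v)$probs,
                         numeric(3)))
  expect_equal(p$mean, avg, tolerance = 1e-10)

  m <- tiny_model()
  expect_identical(tta_predict(m, img, T = 4L, seed = 2L)$samples,
                   tta_predict(m, img, T = 4L, seed = 2L)$samples)
})
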