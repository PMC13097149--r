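test_that("attend reproduces the hand-computed sigmoid-gated product", {
  ln <- asNamespace("lesionnet")
  # minimal single-channel attention module with hand-set tiny weights
  m <- new.env()
  m$use_attention <- TRUE
  m$layers <- list(
    fc1 = ln$layer_dense(1L, 2L), rc = ln$layer_relu(),
    fc2 = ln$layer_dense(2L, 1L), sc = ln$layer_sigmoid(),
    sconv = ln$layer_conv(2L, 1L, k = 3L, pad = 1L), ss = ln$layer_sigmoid())
  class(m) <- "lesion_classifier"
  m$layers$fc1$W <- matrix(c(0.3, -0.2), 2, 1); m$layers$fc1$b <- c(0.1, 0)
  m$layers$fc2$W <- matrix(c(0.5, 0.4), 1, 2);  m$layers$fc2$b <- 0.05
  m$layers$sconv$W <- matrix(seq(-0.4, 0.45, by = 0.05), 1, 18)
  m$layers$sconv$b <- 0.02
  f <- array(c(0.6, -0.3, 0.2, 0.9), dim = c(2, 2, 1))

  bundle <- attend(m, f)

  sig <- function(z) 1 / (1 + exp(-z))
  s <- mean(f)                                       # GAP descriptor
  z1 <- pmax(m$layers$fc1$W %*% s + m$layers$fc1$b, 0)
  Ac <- sig(drop(m$layers$fc2$W %*% z1) + m$layers$fc2$b)
  # spatial branch: mean and max over the single channel are f itself
  pooled <- array(c(f[, , 1], f[, , 1]), dim = c(2, 2, 2))
  Wm <- m$layers$sconv$W
  conv <- matrix(0, 2, 2)
  padded <- array(0, dim = c(4, 4, 2))
  padded[2:3, 2:3, ] <- pooled
  for (i in 1:2) for (j in 1:2) {
    patch <- numeric(18)
    for (ci in 1:2) for (kj in 1:3) for (ki in 1:3)
      patch[(ci - 1) * 9 + (kj - 1) * 3 + ki] <- padded[i + ki - 1, j + kj - 1, ci]
    conv[i, j] <- sum(Wm * patch) + m$layers$sconv$b
  }
  As <- sig(conv)
  expect_equal(bundle$channel_weights, Ac, tolerance = 1e-12)
  expect_equal(bundle$spatial_map, As, tolerance = 1e-12)
  expect_equal(bundle$refined_features[, , 1], f[, , 1] * Ac * As,
               tolerance = 1e-12)
})

test_that("zeroed attention parameters gate features by exactly 0.25", {
  ln <- asNamespace("lesionnet")
  m <- ln$classifier_new(3L, seed = 1, base = 4L, size = 16L)
  for (nm in c("fc1", "fc2", "sconv")) {
    m$layers[[nm]]$W[] <- 0
    m$layers[[nm]]$b[] <- 0
  }
  f <- array(rnorm(2 * 2 * 16), dim = c(2, 2, 16))
  bundle <- attend(m, f)
  expect_equal(bundle$channel_weights, rep(0.5, 16))
  expect_equal(bundle$spatial_map, matrix(0.5, 2, 2))
  expect_equal(bundle$refined_features, 0.25 * f)
  expect_true(all(bundle$spatial_map > 0 & bundle$spatial_map < 1))
})

test_that("the bias-free backbone maps zero input to zero features", {
  ln <- asNamespace("lesionnet")
  m <- ln$classifier_new(3L, seed = 2, base = 8L, size = 32L)
  f <- extract_features(m, array(0, dim = c(32, 32, 3)))
  expect_equal(max(abs(f)), 0)
  expect_identical(dim(f), c(4L, 4L, 32L))   # input dims / stride 8
})

test_that("the head yields a simplex, is shift-invariant, and zero-W is uniform", {
  ln <- asNamespace("lesionnet")
  m <- ln$classifier_new(5L, seed = 3, base = 4L, size = 16L)
  fa <- array(rnorm(2 * 2 * 16), dim = c(2, 2, 16))
  out <- classify(m, fa)
  expect_equal(sum(out$probs), 1, tolerance = 1e-6)
  expect_true(all(out$probs >= 0))

  m$layers$fc$b <- m$layers$fc$b + 3.7       # constant logit shift
  out2 <- classify(m, fa)
  expect_equal(out2$probs, out$probs, tolerance = 1e-12)

  m$layers$fc$W[] <- 0; m$layers$fc$b[] <- 0
  expect_equal(classify(m, fa)$probs, rep(0.2, 5), tolerance = 1e-12)
})

test_that("cross_entropy matches its closed forms", {
  expect_equal(cross_entropy(c(0, 1, 0), 1L), 0, tolerance = 1e-10)
  expect_equal(cross_entropy(rep(1 / 7, 7), 3L), log(7), tolerance = 1e-10)
  expect_equal(cross_entropy(c(0.5, 0.5), 0L), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(c(1, 0), 1L), -log(1e-12))  # numerical floor
  expect_error(cross_entropy(c(0.5, 0.5), 2L), "range")
})

test_that("attention_alignment_loss measures out-of-mask mass", {
  M <- matrix(0, 8, 8); M[3:6, 3:6] <- 1
  A_in <- matrix(0, 8, 8); A_in[4:5, 4:5] <- runif(4)
  expect_equal(attention_alignment_loss(A_in, M), 0)
  A_out <- matrix(0, 8, 8); A_out[1, 1:3] <- 1
  expect_equal(attention_alignment_loss(A_out, M), 1)
  A_unif <- matrix(1, 8, 8)
  expect_equal(attention_alignment_loss(A_unif, M), 0.75)  # mask covers 25%
  # invariant to positive rescaling
  A <- matrix(runif(64), 8)
  expect_equal(attention_alignment_loss(A, M),
               attention_alignment_loss(13.7 * A, M), tolerance = 1e-12)
  expect_warning(v <- attention_alignment_loss(matrix(0, 8, 8), M), "zero mass")
  expect_equal(v, 0)
})

test_that("total_loss is the recorded weighted sum", {
  expect_equal(total_loss(1, 2, 3, 4, c(0, 0, 0, 0))$l_total, 0)
  expect_equal(total_loss(0.2, 0.3, 0.9, 0.1, c(1, 1, 0, 0))$l_total, 0.5)
  lb <- total_loss(0.2, 0.3, 0.4, 0.5, c(1, 0.5, 0.25, 2))
  expect_equal(total_loss(0.2, 0.3, 0.4, 0.5, 2 * c(1, 0.5, 0.25, 2))$l_total,
               2 * lb$l_total)
  expect_equal(lb$l_total,
               sum(lb$lambdas * c(lb$l_seg, lb$l_cls, lb$l_att, lb$l_unc)),
               tolerance = 1e-6)
  expect_error(total_loss(1, 1, 1, 1, c(-1, 0, 0, 0)), "nonnegative")
})

test_that("early stopping halts exactly at patience", {
  # 25+ non-improving epochs after an early best
  metrics <- c(0.5, 0.8, rep(0.7, 30))
  expect_equal(early_stopping_epoch(metrics, 25L), 27L)
  expect_equal(early_stopping_epoch(metrics, 5L), 7L)
  expect_equal(early_stopping_epoch(c(0.1, 0.2, 0.3), 5L), 3L)  # never triggers
})

test_that("train_classifier smoke: loss decreases and config is honored", {
  ds <- tiny_dataset(n_per_class = 15L, seed = 55L, image_size = 32L)
  seg <- train_segmenter(ds, seg_config(epochs = 2L, size = 32L, base = 8L),
                         seed = 6L)
  cfg <- cls_config(epochs = 5L, patience = 5L, size = 32L, base = 8L)
  cls <- train_classifier(ds, seg, cfg, seed = 6L)
  h <- cls$history
  expect_lt(h$tr_loss[nrow(h)], h$tr_loss[1])
  expect_equal(cls$best_epoch, which.max(h$val_acc))
  expect_true(all(c("epoch", "tr_loss", "val_loss", "tr_acc", "val_acc",
                    "lr") %in% names(h)))

  # ablation: no attention + no segmentation reduces to a plain CNN
  plain <- train_classifier(ds, NULL,
                            cls_config(epochs = 2L, size = 32L, base = 8L,
                                       use_segmentation = FALSE,
                                       use_attention = FALSE),
                            seed = 6L)
  out <- predict_lesion(plain, attr(ds, "samples")[[1]]$image)
  expect_identical(out$mask, matrix(1, 32, 32))
  expect_identical(out$bundle$refined_features, out$bundle$raw_features)

  one_class <- ds[ds$label == 0, ]
  attr(one_class, "samples") <- attr(ds, "samples")[ds$label == 0]
  expect_error(train_classifier(one_class, seg, cfg), "two classes")
})
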