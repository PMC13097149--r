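test_that("stratified_kfold partitions with balanced class proportions", {
  labels <- rep(c(0L, 1L), each = 10L)
  folds <- stratified_kfold(labels, 5L, seed = 1L)
  vals <- lapply(folds, `[[`, "val")
  expect_setequal(unlist(vals), seq_along(labels))       # union = all
  expect_equal(sum(lengths(vals)), length(labels))       # pairwise disjoint
  for (v in vals) expect_equal(as.integer(table(labels[v])), c(2L, 2L))
  for (f in folds) expect_length(intersect(f$train, f$val), 0)

  expect_identical(stratified_kfold(labels, 5L, seed = 1L), folds)

  # uneven classes: proportions within one sample of the global split
  set.seed(16)
  lab2 <- sample(rep(0:2, times = c(17, 11, 7)))
  f2 <- stratified_kfold(lab2, 3L, seed = 2L)
  for (fold in f2) {
    tt <- table(factor(lab2[fold$val], levels = 0:2))
    expect_true(all(abs(tt - c(17, 11, 7) / 3) <= 1))
  }
  expect_error(stratified_kfold(c(0, 0, 1), 2L, seed = 1), "at least k")
})

test_that("evaluate_predictions matches hand-computed binary metrics", {
  # confusion for class 1 as positive: TP=4, FN=1, FP=2, TN=3
  labels <- c(rep(1L, 5), rep(0L, 5))
  pred <- c(1, 1, 1, 1, 0, 1, 1, 0, 0, 0)
  probs <- cbind(1 - pred, pred) * 0.8 + 0.1
  m <- evaluate_predictions(probs, labels)
  pc <- m$per_class
  expect_equal(pc$precision[pc$class == 1], 2 / 3)
  expect_equal(pc$recall[pc$class == 1], 4 / 5)
  expect_equal(pc$f1[pc$class == 1], 2 * (2 / 3) * (4 / 5) / (2 / 3 + 4 / 5),
               tolerance = 1e-4)
  expect_equal(pc$specificity[pc$class == 1], 3 / 5)
  expect_equal(m$accuracy, 0.7)
  expect_equal(sum(m$confusion), length(labels))
  expect_equal(as.integer(rowSums(m$confusion)),
               as.integer(table(factor(labels, levels = 0:1))))
})

test_that("perfect predictions give unit metrics and diagonal confusion", {
  set.seed(17)
  labels <- sample(0:2, 30, replace = TRUE)
  probs <- matrix(0.05, 30, 3)
  probs[cbind(1:30, labels + 1)] <- 0.9
  m <- evaluate_predictions(probs, labels)
  expect_equal(m$accuracy, 1)
  expect_equal(sum(m$confusion) - sum(diag(m$confusion)), 0)
  expect_true(all(m$per_class$auc == 1))
  expect_equal(m$macro_auc, 1)
})

test_that("class relabeling permutes rows but preserves accuracy", {
  set.seed(18)
  labels <- sample(0:2, 40, replace = TRUE)
  probs <- matrix(rexp(120), 40, 3); probs <- probs / rowSums(probs)
  m1 <- evaluate_predictions(probs, labels)
  perm <- c(2L, 0L, 1L)   # new label = perm[old + 1]
  m2 <- evaluate_predictions(probs[, order(perm)], perm[labels + 1])
  expect_equal(m2$accuracy, m1$accuracy)
  expect_equal(sort(m2$per_class$support), sort(m1$per_class$support))

  expect_warning(evaluate_predictions(matrix(c(0.6, 0.4), 1), 0L), "absent")
})

test_that("one-vs-rest AUC agrees with an independent rank computation", {
  set.seed(19)
  labels <- sample(0:1, 50, replace = TRUE)
  score <- runif(50)
  probs <- cbind(1 - score, score)
  m <- evaluate_predictions(probs, labels)
  w <- stats::wilcox.test(score[labels == 1], score[labels == 0],
                          exact = FALSE)$statistic
  expect_equal(m$per_class$auc[2],
               as.numeric(w) / (sum(labels == 1) * sum(labels == 0)),
               tolerance = 1e-12)
})

test_that("run_experiment honors ablation flags and records artifacts", {
  cfg <- experiment_config(n_per_class = 8L, k = 2L, seed = 5L,
                           seg_epochs = 1L, cls_epochs = 2L, mc_T = 3L,
                           n_explain = 1L, use_attention_loss = FALSE)
  out <- withr::local_tempdir()
  res <- run_experiment(cfg, out_dir = out)
  expect_equal(res$status, 0L)
  mj <- jsonlite::read_json(file.path(out, "metrics.json"),
                            simplifyVector = TRUE)
  expect_equal(mj$lambdas[3], 0)                 # flag -> lambda3 = 0
  expect_equal(mj$name, "standard_attention")
  expect_equal(mj$seed, 5L)
  expect_true(file.exists(file.path(out, "fold1", "predictions.csv")))
  expect_true(file.exists(file.path(out, "fold1", "rejection.csv")))
  expect_true(file.exists(file.path(out, "fold1", "calibration.json")))
  expect_true(file.exists(file.path(out, "fold2", "history.csv")))
  # fold-averaged accuracy equals the mean of the per-fold accuracies
  expect_equal(mj$accuracy, mean(mj$per_fold_accuracy), tolerance = 1e-9)
})

test_that("compare_runs tabulates deltas against the full configuration", {
  mk <- function(name, acc, hash = "abcd1234") {
    d <- withr::local_tempdir(.local_envir = parent.frame(2))
    jsonlite::write_json(list(name = name, dataset_hash = hash,
                              accuracy = acc, precision = acc - 0.01,
                              recall = acc - 0.02, f1 = acc - 0.015),
                         file.path(d, "metrics.json"), auto_unbox = TRUE)
    d
  }
  full <- mk("full", 0.95)
  abl <- mk("no_segmentation", 0.90)
  tab <- compare_runs(c(abl, full))
  expect_equal(tab$name[1], "full")               # sorted by accuracy
  expect_equal(tab$delta_accuracy[tab$name == "full"], 0)
  expect_equal(tab$delta_accuracy[tab$name == "no_segmentation"], -0.05,
               tolerance = 1e-12)
  self <- compare_runs(c(full, full))
  expect_true(all(self$delta_accuracy == 0))

  other <- mk("full", 0.95, hash = "ffff0000")
  expect_error(compare_runs(c(full, other)), "hash")
})

test_that("the CLI generates datasets and reports unknown commands", {
  out <- file.path(withr::local_tempdir(), "ds")
  expect_message(st <- lesionnet_cli(c("generate", "--out", out,
                                       "--n-per-class", "2",
                                       "--image-size", "48",
                                       "--seed", "3")), "6 samples")
  expect_equal(st, 0L)
  meta <- load_dataset(out)
  expect_equal(nrow(meta), 6L)
  expect_message(bad <- lesionnet_cli("frobnicate"), "unknown")
  expect_equal(bad, 1L)
  expect_message(lesionnet_cli(character(0)), "usage")
  expect_true(file.exists(system.file("cli", "lesionnet.R",
                                      package = "lesionnet")))
})
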