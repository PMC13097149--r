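# Experiment orchestration: stratified cross-validation, per-class metrics
# with one-vs-rest ROC, the end-to-end experiment runner with ablation
# switches, run comparison, and a small command-line interface.

#' Stratified k-fold split
#'
#' Partitions indices into k folds preserving class proportions to within
#' one sample per class per fold (seeded shuffle, then round-robin chunking
#' within each class).
#'
#' @param labels class label vector.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of k elements, each `list(train = , val = )` of indices.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  tab <- table(labels)
  if (any(tab < k))
    stop("every class needs at least k members (smallest has ", min(tab), ")")
  run_seeded(seed, {
    fold_of <- integer(length(labels))
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    lapply(seq_len(k), function(f)
      list(train = which(fold_of != f), val = which(fold_of == f)))
  })
}

auc_ovr <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)   # midranks handle ties
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics report
#'
#' Argmax predictions (ties broken towards the lowest class index), C x C
#' confusion matrix (rows = truth, columns = prediction), per-class
#' precision, recall, F1, specificity and one-vs-rest AUC, support-weighted
#' averages, and macro AUC (unweighted mean of per-class AUCs). Classes
#' absent from `labels` get `NA` metrics and are excluded from the weighted
#' averages with a warning.
#'
#' @param probs n x C matrix of predicted probability vectors.
#' @param labels 0-based true labels.
#' @return list of class `metrics_report`.
#' @export
evaluate_predictions <- function(probs, labels) {
  if (nrow(probs) != length(labels)) stop("length mismatch")
  C <- ncol(probs)
  pred <- max.col(probs, ties.method = "first") - 1L
  cm <- matrix(0L, C, C, dimnames = list(truth = 0:(C - 1), pred = 0:(C - 1)))
  for (i in seq_along(labels)) {
    cm[labels[i] + 1L, pred[i] + 1L] <- cm[labels[i] + 1L, pred[i] + 1L] + 1L
  }
  n <- length(labels)
  per <- data.frame(class = 0:(C - 1), precision = NA_real_, recall = NA_real_,
                    f1 = NA_real_, specificity = NA_real_, auc = NA_real_,
                    support = as.integer(rowSums(cm)))
  for (c in seq_len(C)) {
    tp <- cm[c, c]; fn <- sum(cm[c, ]) - tp; fp <- sum(cm[, c]) - tp
    tn <- n - tp - fn - fp
    if (per$support[c] == 0) next
    per$precision[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    per$recall[c] <- tp / (tp + fn)
    per$f1[c] <- if (per$precision[c] + per$recall[c] > 0)
      2 * per$precision[c] * per$recall[c] / (per$precision[c] + per$recall[c])
      else 0
    per$specificity[c] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    per$auc[c] <- auc_ovr(probs[, c], labels == c - 1L)
  }
  present <- per$support > 0
  if (!all(present))
    warning("classes absent from labels: ",
            paste(per$class[!present], collapse = ", "),
            "; excluded from weighted averages")
  w <- per$support[present] / sum(per$support[present])
  out <- list(
    accuracy = sum(diag(cm)) / n,
    confusion = cm,
    per_class = per,
    weighted = c(precision = sum(w * per$precision[present]),
                 recall = sum(w * per$recall[present]),
                 f1 = sum(w * per$f1[present]),
                 specificity = sum(w * per$specificity[present])),
    macro_auc = mean(per$auc[present], na.rm = TRUE),
    n = n)
  class(out) <- "metrics_report"
  out
}

#' Experiment configuration
#'
#' Bundles the generator specs, model/optimizer settings, cross-validation
#' protocol and the ablation switches. Every ablation row of the study
#' (no segmentation, no attention, standard attention without the
#' alignment loss, no uncertainty, no TTA) is reachable by flags.
#'
#' @param class_specs list of [lesion_spec()]; default
#'   [synthetic_class_specs()].
#' @param n_per_class samples generated per class.
#' @param image_size generated image side.
#' @param size working resolution.
#' @param k cross-validation folds (>= 2).
#' @param seed master seed (fixed and logged).
#' @param lambdas loss weights (seg, cls, att, unc).
#' @param seg_epochs,cls_epochs,patience,batch_size,lr optimizer settings.
#' @param base backbone/segmenter base width.
#' @param use_segmentation,use_attention,use_attention_loss,use_uncertainty,use_tta
#'   ablation switches.
#' @param mc_T MC-dropout passes.
#' @param uncertainty_method scalarization, `"class_variance"` or
#'   `"entropy"`.
#' @param n_explain validation samples per fold to render overlays for.
#' @param save_checkpoints write model checkpoints into the run directory.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(class_specs = synthetic_class_specs(),
                              n_per_class = 200L, image_size = 64L,
                              size = 64L, k = 2L, seed = 42L,
                              lambdas = c(1, 1, 0.5, 0.01),
                              seg_epochs = 6L, cls_epochs = 15L,
                              patience = 5L, batch_size = 16L, lr = 2e-3,
                              base = 16L,
                              use_segmentation = TRUE, use_attention = TRUE,
                              use_attention_loss = TRUE,
                              use_uncertainty = TRUE, use_tta = FALSE,
                              mc_T = 25L,
                              uncertainty_method = "class_variance",
                              n_explain = 6L, save_checkpoints = FALSE) {
  if (k < 2) stop("k must be >= 2")
  cfg <- list(class_specs = class_specs, n_per_class = as.integer(n_per_class),
              image_size = as.integer(image_size), size = as.integer(size),
              k = as.integer(k), seed = as.integer(seed), lambdas = lambdas,
              seg_epochs = as.integer(seg_epochs),
              cls_epochs = as.integer(cls_epochs),
              patience = as.integer(patience),
              batch_size = as.integer(batch_size), lr = lr,
              base = as.integer(base),
              use_segmentation = isTRUE(use_segmentation),
              use_attention = isTRUE(use_attention),
              use_attention_loss = isTRUE(use_attention_loss),
              use_uncertainty = isTRUE(use_uncertainty),
              use_tta = isTRUE(use_tta), mc_T = as.integer(mc_T),
              uncertainty_method = uncertainty_method,
              n_explain = as.integer(n_explain),
              save_checkpoints = isTRUE(save_checkpoints))
  class(cfg) <- "experiment_config"
  cfg
}

config_hash <- function(x) {
  sprintf("%08x", as.integer(crc32_cpp(serialize(x, NULL, version = 2)) %% 2^31))
}

dataset_hash <- function(config) {
  config_hash(list(lapply(config$class_specs, unclass), config$n_per_class,
                   config$image_size, config$seed))
}

subset_dataset <- function(meta, idx) {
  out <- meta[idx, , drop = FALSE]
  attr(out, "samples") <- attr(meta, "samples")[idx]
  out
}

#' Run the full cross-validated experiment
#'
#' Per fold: train the segmenter on the training split, train the
#' classifier with the composite objective, evaluate the validation split
#' (per-class metrics, confusion, one-vs-rest ROC), run MC-dropout
#' uncertainty with rejection and calibration analysis, and render
#' explanation overlays for a sampled subset. All artifacts are written
#' under `out_dir`, stamped with the config hash and master seed. Folds
#' that fail are recorded and the run continues.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory for run artifacts.
#' @return (invisibly) list with per-fold results and the fold-averaged
#'   summary; also written as JSON/CSV artifacts.
#' @export
run_experiment <- function(config, out_dir = tempfile("lesionnet_run_")) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(config_hash = config_hash(unclass(config)),
                dataset_hash = dataset_hash(config), seed = config$seed)
  jsonlite::write_json(c(stamp, list(config = serialize_config(config))),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- generate_dataset(config$class_specs, config$n_per_class,
                           config$image_size, config$seed)
  labels <- meta$label
  folds <- stratified_kfold(labels, config$k, config$seed)
  lam <- config$lambdas
  if (!config$use_attention_loss) lam[3] <- 0
  if (!config$use_uncertainty) lam[4] <- 0
  fold_results <- list()
  failures <- 0L
  for (f in seq_along(folds)) {
    fdir <- file.path(out_dir, sprintf("fold%d", f))
    dir.create(fdir, showWarnings = FALSE)
    res <- tryCatch(
      run_fold(config, meta, folds[[f]], lam, fdir,
               seed = derive_seed(config$seed, 100L + f)),
      error = function(e) {
        warning("fold ", f, " failed: ", conditionMessage(e))
        list(error = conditionMessage(e))
      })
    if (!is.null(res$error)) failures <- failures + 1L
    fold_results[[f]] <- res
  }
  ok <- Filter(function(r) is.null(r$error), fold_results)
  summary <- if (length(ok)) {
    list(
      accuracy = mean(vapply(ok, function(r) r$metrics$accuracy, 0)),
      precision = mean(vapply(ok, function(r) r$metrics$weighted["precision"], 0)),
      recall = mean(vapply(ok, function(r) r$metrics$weighted["recall"], 0)),
      f1 = mean(vapply(ok, function(r) r$metrics$weighted["f1"], 0)),
      macro_auc = mean(vapply(ok, function(r) r$metrics$macro_auc, 0)),
      mean_val_dice = mean(vapply(ok, function(r) r$val_dice, 0)),
      per_fold_accuracy = vapply(ok, function(r) r$metrics$accuracy, 0),
      n_folds_ok = length(ok), n_folds_failed = failures)
  } else list(n_folds_ok = 0L, n_folds_failed = failures)
  jsonlite::write_json(c(stamp, summary,
                         list(lambdas = lam,
                              name = experiment_name(config))),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- list(run_dir = out_dir, config = config, folds = fold_results,
              summary = summary, status = if (failures) 1L else 0L)
  invisible(out)
}

experiment_name <- function(config) {
  if (!config$use_segmentation) return("no_segmentation")
  if (!config$use_attention) return("no_attention")
  if (!config$use_attention_loss) return("standard_attention")
  if (!config$use_uncertainty) return("no_uncertainty")
  if (config$use_tta) return("full_tta")
  "full"
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$class_specs <- lapply(out$class_specs, unclass)
  out
}

run_fold <- function(config, meta, fold, lam, fdir, seed) {
  train_meta <- subset_dataset(meta, fold$train)
  val_samples <- attr(meta, "samples")[fold$val]
  seg <- NULL
  if (config$use_segmentation) {
    seg <- train_segmenter(train_meta,
                           seg_config(epochs = config$seg_epochs,
                                      batch_size = config$batch_size,
                                      size = config$size, base = config$base),
                           seed = derive_seed(seed, 1L))
    write.csv(seg$history, file.path(fdir, "seg_history.csv"),
              row.names = FALSE)
  }
  ccfg <- cls_config(epochs = config$cls_epochs, patience = config$patience,
                     batch_size = config$batch_size, lr = config$lr,
                     lambdas = lam, use_segmentation = config$use_segmentation,
                     use_attention = config$use_attention,
                     size = config$size, base = config$base,
                     uncertainty_loss = if (lam[4] > 0) "confidence_penalty"
                                        else "off")
  cls <- train_classifier(train_meta, seg, ccfg, seed = derive_seed(seed, 2L))
  write.csv(cls$history, file.path(fdir, "history.csv"), row.names = FALSE)
  if (config$save_checkpoints) {
    saveRDS(list(state = nn_get_state(cls$layers), config = ccfg, seed = seed),
            file.path(fdir, "classifier.rds"))
    if (!is.null(seg))
      saveRDS(list(state = nn_get_state(seg$layers), config = seg$config),
              file.path(fdir, "segmenter.rds"))
  }
  # validation predictions (MC mean when uncertainty is on)
  nv <- length(val_samples)
  C <- cls$n_classes
  probs <- matrix(0, nv, C)
  scores <- numeric(nv)
  dices <- numeric(nv)
  predict_one <- if (config$use_tta) tta_predict else mc_predict
  for (i in seq_len(nv)) {
    s <- val_samples[[i]]
    if (config$use_uncertainty || config$use_tta) {
      mp <- predict_one(cls, s$image, T = config$mc_T,
                        seed = derive_seed(seed, 1000L + i))
      probs[i, ] <- mp$mean
      scores[i] <- uncertainty_score(mp, config$uncertainty_method)
    } else {
      probs[i, ] <- predict_lesion(cls, s$image)$probs
    }
    if (config$use_segmentation) {
      x <- normalize_image(s$image, size = config$size)
      dices[i] <- dice_coefficient(predict_mask(seg, x),
                                   resize_mask(s$mask, config$size))
    }
  }
  val_labels <- vapply(val_samples, function(s) s$label, 0L)
  metrics <- evaluate_predictions(probs, val_labels)
  pred <- max.col(probs, ties.method = "first") - 1L
  correct <- pred == val_labels
  ptab <- data.frame(sample_id = vapply(val_samples, function(s) s$sample_id, ""),
                     label = val_labels, predicted = pred,
                     confidence = apply(probs, 1, max),
                     uncertainty = scores, correct = correct)
  write.csv(ptab, file.path(fdir, "predictions.csv"), row.names = FALSE)
  rejection <- calib <- theta <- NULL
  if (config$use_uncertainty) {
    thr <- sort(unique(stats::quantile(scores, seq(0.5, 0.98, by = 0.06))))
    rejection <- rejection_analysis(scores, correct, thr)
    write.csv(as.data.frame(rejection), file.path(fdir, "rejection.csv"),
              row.names = FALSE)
    theta <- select_threshold(scores, correct)
    calib <- calibration_report(apply(probs, 1, max), correct,
                                probs = probs, labels = val_labels)
    jsonlite::write_json(unclass(calib), file.path(fdir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  # explanation overlays + coverage records for a sampled subset
  n_exp <- min(config$n_explain, nv)
  if (n_exp > 0) {
    erec <- list()
    for (i in seq_len(n_exp)) {
      s <- val_samples[[i]]
      em <- grad_cam(cls, s$image)
      em <- align_explanation(em)
      g <- resize_mask(s$mask, config$size)
      cov_raw <- if (sum(em$raw_map) > 0)
        explanation_coverage(em$raw_map, g) else NA_real_
      cov_al <- if (sum(em$aligned_map) > 0)
        explanation_coverage(em$aligned_map, g) else NA_real_
      erec[[i]] <- data.frame(sample_id = s$sample_id,
                              target_class = em$target_class,
                              coverage_raw = cov_raw,
                              coverage_aligned = cov_al)
      img_rs <- resize_bilinear_cpp(s$image, config$size, config$size)
      render_overlay(img_rs, em, file.path(fdir, paste0(s$sample_id,
                                                        "_gradcam.png")))
    }
    write.csv(do.call(rbind, erec), file.path(fdir, "explanations.csv"),
              row.names = FALSE)
  }
  fold_json <- list(accuracy = metrics$accuracy,
                    weighted = as.list(metrics$weighted),
                    macro_auc = metrics$macro_auc,
                    val_dice = if (config$use_segmentation) mean(dices) else NA,
                    theta_u = theta,
                    ece = if (!is.null(calib)) calib$ece else NULL,
                    brier = if (!is.null(calib)) calib$brier else NULL,
                    confusion = metrics$confusion)
  jsonlite::write_json(fold_json, file.path(fdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  list(metrics = metrics, val_dice = if (config$use_segmentation) mean(dices)
         else NA_real_,
       scores = scores, correct = correct, probs = probs,
       labels = val_labels, rejection = rejection, calibration = calib,
       theta_u = theta, classifier = cls, segmenter = seg,
       val_indices = fold$val)
}

#' Compare ablation runs
#'
#' Reads the fold-averaged `metrics.json` of each run directory, checks
#' that all runs used the same dataset (hash), and tabulates accuracy,
#' precision, recall, F1 and the accuracy delta against the run named
#' `"full"` (or the first run when no full configuration is present),
#' ordered by descending accuracy.
#'
#' @param run_dirs character vector of run directories.
#' @return data.frame with one row per run.
#' @export
compare_runs <- function(run_dirs) {
  ms <- lapply(run_dirs, function(d)
    jsonlite::read_json(file.path(d, "metrics.json"), simplifyVector = TRUE))
  hashes <- vapply(ms, function(m) m$dataset_hash, "")
  if (length(unique(hashes)) > 1)
    stop("runs were produced on different datasets (hash mismatch)")
  tab <- data.frame(
    name = vapply(ms, function(m) m$name %||% "?", ""),
    run_dir = run_dirs,
    accuracy = vapply(ms, function(m) m$accuracy, 0),
    precision = vapply(ms, function(m) m$precision, 0),
    recall = vapply(ms, function(m) m$recall, 0),
    f1 = vapply(ms, function(m) m$f1, 0))
  ref <- match("full", tab$name)
  if (is.na(ref)) ref <- 1L
  tab$delta_accuracy <- tab$accuracy - tab$accuracy[ref]
  tab[order(-tab$accuracy), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# command-line interface

parse_cli_flags <- function(args) {
  flags <- list(); pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3))
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        flags[[key]] <- args[i + 1L]; i <- i + 2L
      } else {
        flags[[key]] <- TRUE; i <- i + 1L
      }
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  list(flags = flags, positional = pos)
}

cli_int <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.integer(flags[[key]])
}

#' Command-line interface
#'
#' Subcommands: `generate`, `train-seg`, `train-cls`, `predict`, `explain`,
#' `uncertainty`, `evaluate`, `run`, `compare`. See the package README for
#' usage; an executable wrapper is installed under
#' `system.file("cli", "lesionnet.R", package = "lesionnet")`.
#'
#' @param args character vector of arguments (defaults to the command line).
#' @return exit status (0 on success), invisibly.
#' @export
lesionnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: lesionnet.R <generate|train-seg|train-cls|predict|",
            "explain|uncertainty|evaluate|run|compare> [--flags]")
    return(invisible(1L))
  }
  cmd <- args[1]
  p <- parse_cli_flags(args[-1])
  fl <- p$flags
  seed <- cli_int(fl, "seed", 42L)
  status <- 0L
  switch(cmd,
    "generate" = {
      meta <- generate_dataset(synthetic_class_specs(),
                               cli_int(fl, "n_per_class", 20L),
                               cli_int(fl, "image_size", 64L),
                               seed, out_dir = fl$out %||% "dataset")
      message(nrow(meta), " samples written to ", fl$out %||% "dataset")
    },
    "train-seg" = {
      meta <- load_dataset(fl$data)
      seg <- train_segmenter(meta, seg_config(epochs = cli_int(fl, "epochs", 12L)),
                             seed = seed)
      saveRDS(list(state = nn_get_state(seg$layers), config = seg$config,
                   history = seg$history), fl$out %||% "segmenter.rds")
      message("best val dice ", round(max(seg$history$val_dice), 4))
    },
    "train-cls" = {
      meta <- load_dataset(fl$data)
      seg <- cli_load_segmenter(fl$segmenter)
      cls <- train_classifier(meta, seg,
                              cls_config(epochs = cli_int(fl, "epochs", 20L)),
                              seed = seed)
      saveRDS(list(state = nn_get_state(cls$layers), config = cls$config,
                   n_classes = cls$n_classes, classes = cls$classes,
                   history = cls$history,
                   segmenter = if (!is.null(seg))
                     list(state = nn_get_state(seg$layers),
                          config = seg$config)),
              fl$out %||% "classifier.rds")
      message("best val acc ", round(max(cls$history$val_acc), 4))
    },
    "predict" = {
      model <- cli_load_classifier(fl$model)
      img <- read_png(fl$image)
      out <- predict_lesion(model, img)
      res <- list(predicted = which.max(out$probs) - 1L,
                  probs = as.numeric(out$probs))
      if (!is.null(fl$out))
        jsonlite::write_json(res, fl$out, auto_unbox = TRUE, digits = NA)
      message("predicted class ", res$predicted, " (p = ",
              round(max(out$probs), 4), ")")
    },
    "explain" = {
      model <- cli_load_classifier(fl$model)
      img <- read_png(fl$image)
      em <- align_explanation(grad_cam(model, img))
      img_rs <- resize_bilinear_cpp(img, model$size, model$size)
      render_overlay(img_rs, em, fl$out %||% "overlay.png")
      message("overlay written to ", fl$out %||% "overlay.png")
    },
    "uncertainty" = {
      model <- cli_load_classifier(fl$model)
      img <- read_png(fl$image)
      mp <- mc_predict(model, img, T = cli_int(fl, "T", 25L), seed = seed)
      message("mean prediction ", which.max(mp$mean) - 1L,
              "; class variance ",
              signif(uncertainty_score(mp), 4),
              "; entropy ", signif(uncertainty_score(mp, "entropy"), 4))
    },
    "evaluate" = {
      model <- cli_load_classifier(fl$model)
      meta <- load_dataset(fl$data)
      samples <- dataset_samples(meta)
      probs <- t(vapply(samples, function(s) predict_lesion(model, s$image)$probs,
                        numeric(model$n_classes)))
      m <- evaluate_predictions(probs, match(meta$label, model$classes) - 1L)
      if (!is.null(fl$out))
        jsonlite::write_json(list(accuracy = m$accuracy,
                                  weighted = as.list(m$weighted),
                                  macro_auc = m$macro_auc,
                                  confusion = m$confusion),
                             fl$out, auto_unbox = TRUE, digits = NA)
      message("accuracy ", round(m$accuracy, 4))
    },
    "run" = {
      cfg <- if (!is.null(fl$config)) config_from_json(fl$config)
             else experiment_config(seed = seed,
                                    n_per_class = cli_int(fl, "n_per_class", 60L),
                                    k = cli_int(fl, "k", 2L))
      res <- run_experiment(cfg, out_dir = fl$out %||% "run")
      status <- res$status
      message("run complete; fold-mean accuracy ",
              round(res$summary$accuracy, 4))
    },
    "compare" = {
      tab <- compare_runs(p$positional)
      if (!is.null(fl$out)) write.csv(tab, fl$out, row.names = FALSE)
      message(paste(utils::capture.output(print(tab)), collapse = "\n"))
    },
    {
      message("unknown subcommand: ", cmd)
      status <- 1L
    })
  invisible(status)
}

cli_load_segmenter <- function(path) {
  if (is.null(path)) return(NULL)
  ck <- readRDS(path)
  seg <- unet_new(base = ck$config$base, size = ck$config$size)
  nn_set_state(seg$layers, ck$state)
  seg$config <- ck$config
  seg
}

cli_load_classifier <- function(path) {
  ck <- readRDS(path)
  cls <- classifier_new(ck$n_classes, base = ck$config$base,
                        size = ck$config$size, dropout = ck$config$dropout,
                        use_attention = ck$config$use_attention)
  nn_set_state(cls$layers, ck$state)
  cls$config <- ck$config
  cls$classes <- ck$classes
  if (!is.null(ck$segmenter)) {
    seg <- unet_new(base = ck$segmenter$config$base,
                    size = ck$segmenter$config$size)
    nn_set_state(seg$layers, ck$segmenter$state)
    cls$segmenter <- seg
  }
  cls
}

config_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(seq_len(nrow(j$class_specs %||% data.frame())), function(i) {
    row <- j$class_specs[i, ]
    do.call(lesion_spec, as.list(row))
  })
  if (!length(specs)) specs <- synthetic_class_specs()
  experiment_config(class_specs = specs,
                    n_per_class = j$n_per_class %||% 60L,
                    image_size = j$image_size %||% 64L,
                    size = j$size %||% 64L, k = j$k %||% 2L,
                    seed = j$seed %||% 42L,
                    lambdas = j$lambdas %||% c(1, 1, 0.5, 0.1),
                    seg_epochs = j$seg_epochs %||% 8L,
                    cls_epochs = j$cls_epochs %||% 15L,
                    use_segmentation = j$use_segmentation %||% TRUE,
                    use_attention = j$use_attention %||% TRUE,
                    use_attention_loss = j$use_attention_loss %||% TRUE,
                    use_uncertainty = j$use_uncertainty %||% TRUE,
                    use_tta = j$use_tta %||% FALSE)
}
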