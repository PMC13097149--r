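# Synthetic dermoscopy-style data: class-conditional lesion morphology
# (asymmetry, border irregularity, pigment heterogeneity) rendered over a
# skin-tone background, with hair strokes, an illumination gradient and
# sensor noise added AFTER the ground-truth mask is captured, so the mask
# always marks exactly the lesion support.

run_seeded <- function(seed, code) {
  had <- exists(".Random.seed", globalenv())
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

#' Derive a per-sample seed from a master seed
#'
#' Deterministic hash so that growing a dataset never reshuffles the seeds of
#' earlier samples. Result is always a valid 32-bit R seed.
#'
#' @param master_seed integer master seed.
#' @param index sample index (1-based).
#' @return integer seed.
#' @export
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 + as.numeric(index) * 69621 + 11) %%
               2147483587)
}

#' Lesion morphology specification
#'
#' Parameters controlling one synthetic lesion class: overall size, shape
#' asymmetry, border irregularity, pigment palette and mixing, plus the
#' acquisition artifacts (hair, illumination gradient, noise) layered on top.
#'
#' @param class_id integer class label (0-based).
#' @param base_radius_frac lesion radius as a fraction of the image side;
#'   0 disables the lesion entirely (background-only sample).
#' @param asymmetry in \[0, 1\]: 0 gives a circle, larger values squash the
#'   ellipse and bulge one side.
#' @param border_irregularity amplitude of the random radial perturbation on
#'   the boundary; 0 gives a smooth ellipse.
#' @param n_boundary_harmonics number of radial frequencies in the boundary
#'   perturbation.
#' @param color_palette list of RGB triplets (values in \[0, 1\]) used for the
#'   base pigment and intra-lesion patches.
#' @param heterogeneity in \[0, 1\]: mixing strength of the pigment patches.
#' @param hair_count number of hair strokes drawn over the final image.
#' @param illumination_gradient in \[0, 1\]: strength of a linear shading ramp.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(class_id, base_radius_frac = 0.25, asymmetry = 0.1,
                        border_irregularity = 0.1, n_boundary_harmonics = 6L,
                        color_palette = list(c(0.45, 0.30, 0.22),
                                             c(0.30, 0.18, 0.12),
                                             c(0.55, 0.40, 0.30)),
                        heterogeneity = 0.3, hair_count = 2L,
                        illumination_gradient = 0.2, noise_sigma = 0.02) {
  spec <- list(class_id = as.integer(class_id),
               base_radius_frac = base_radius_frac, asymmetry = asymmetry,
               border_irregularity = border_irregularity,
               n_boundary_harmonics = as.integer(n_boundary_harmonics),
               color_palette = lapply(color_palette, as.numeric),
               heterogeneity = heterogeneity, hair_count = as.integer(hair_count),
               illumination_gradient = illumination_gradient,
               noise_sigma = noise_sigma)
  class(spec) <- "lesion_spec"
  validate_lesion_spec(spec)
  spec
}

validate_lesion_spec <- function(spec) {
  in01 <- function(v) is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1
  if (!(is.numeric(spec$base_radius_frac) && spec$base_radius_frac >= 0 &&
        spec$base_radius_frac < 0.5))
    stop("base_radius_frac must be in [0, 0.5)")
  for (f in c("asymmetry", "border_irregularity", "heterogeneity",
              "illumination_gradient"))
    if (!in01(spec[[f]])) stop(f, " must be a scalar in [0, 1]")
  if (spec$noise_sigma < 0) stop("noise_sigma must be nonnegative")
  if (spec$hair_count < 0 || spec$n_boundary_harmonics < 1)
    stop("hair_count must be >= 0 and n_boundary_harmonics >= 1")
  if (!length(spec$color_palette) ||
      any(!vapply(spec$color_palette,
                  function(p) length(p) == 3 && all(p >= 0 & p <= 1), TRUE)))
    stop("color_palette must be RGB triplets in [0, 1]")
  invisible(spec)
}

#' Default synthetic class specifications
#'
#' Three lesion archetypes. Classes 0 and 1 deliberately share the same brown
#' pigment palette and size and differ mainly in morphology (border
#' irregularity, asymmetry, heterogeneity), so a classifier must use shape
#' information rather than colour alone; class 2 is a smaller reddish
#' vascular-like lesion.
#'
#' @return list of [lesion_spec()] objects, one per class.
#' @export
synthetic_class_specs <- function() {
  browns <- list(c(0.45, 0.30, 0.22), c(0.28, 0.16, 0.11), c(0.56, 0.42, 0.30))
  reds <- list(c(0.72, 0.28, 0.26), c(0.55, 0.15, 0.18), c(0.80, 0.45, 0.40))
  list(
    lesion_spec(0L, base_radius_frac = 0.27, asymmetry = 0.08,
                border_irregularity = 0.05, heterogeneity = 0.15,
                color_palette = browns, hair_count = 2L,
                illumination_gradient = 0.2, noise_sigma = 0.02),
    lesion_spec(1L, base_radius_frac = 0.27, asymmetry = 0.5,
                border_irregularity = 0.4, heterogeneity = 0.7,
                color_palette = browns, hair_count = 2L,
                illumination_gradient = 0.2, noise_sigma = 0.02),
    lesion_spec(2L, base_radius_frac = 0.18, asymmetry = 0.15,
                border_irregularity = 0.12, heterogeneity = 0.35,
                color_palette = reds, hair_count = 2L,
                illumination_gradient = 0.2, noise_sigma = 0.02)
  )
}

#' Generate one synthetic dermoscopy-style sample
#'
#' Pure function of `(spec, image_size, seed)`: repeated calls are
#' bit-identical. The lesion is a radially perturbed ellipse filled with
#' blended pigment patches; hair, illumination and noise artifacts are
#' overlaid after the ground-truth mask is captured.
#'
#' @param spec a [lesion_spec()].
#' @param image_size side length in pixels (>= 32).
#' @param seed integer seed.
#' @param sample_id optional sample identifier string.
#' @return list of class `image_sample` with fields `image` (H x W x 3 in
#'   \[0, 1\]), `mask` (H x W binary matrix), `label`, `sample_id`.
#' @export
generate_sample <- function(spec, image_size, seed, sample_id = NULL) {
  validate_lesion_spec(spec)
  if (image_size < 32) stop("image_size must be >= 32")
  S <- as.integer(image_size)
  run_seeded(seed, {
    gx <- matrix(rep((seq_len(S) - 0.5) / S, each = S), S, S)  # x = column
    gy <- matrix(rep((seq_len(S) - 0.5) / S, times = S), S, S) # y = row
    # skin background with low-frequency mottle
    tint <- rnorm(3, sd = 0.02)
    f1 <- runif(2, 1, 3); ph <- runif(2, 0, 2 * pi)
    mottle <- 0.015 * (cos(2 * pi * f1[1] * gx + ph[1]) +
                       cos(2 * pi * f1[2] * gy + ph[2]))
    skin <- c(0.87, 0.72, 0.63)
    img <- array(0, dim = c(S, S, 3))
    for (ch in 1:3) img[, , ch] <- skin[ch] + tint[ch] + mottle

    mask <- matrix(0L, S, S)
    if (spec$base_radius_frac > 0) {
      r0 <- spec$base_radius_frac
      ctr <- c(0.5, 0.5) + spec$asymmetry * 0.06 * runif(2, -1, 1)
      theta <- runif(1, 0, pi)
      ecc <- 1 - 0.45 * spec$asymmetry          # minor/major axis ratio
      u <- cos(theta) * (gx - ctr[1]) + sin(theta) * (gy - ctr[2])
      v <- -sin(theta) * (gx - ctr[1]) + cos(theta) * (gy - ctr[2])
      d <- sqrt(u^2 + (v / ecc)^2)
      phi <- atan2(v, u)
      # radial boundary perturbation: unit-norm random harmonics scaled by
      # border_irregularity, plus a k=1 bulge controlled by asymmetry
      K <- spec$n_boundary_harmonics
      amp <- rnorm(K); amp <- amp / sqrt(sum(amp^2))
      phk <- runif(K, 0, 2 * pi)
      pert <- matrix(0, S, S)
      for (k in seq_len(K))
        pert <- pert + amp[k] * cos((k + 1) * phi + phk[k])
      rphi <- r0 * (1 + spec$border_irregularity * 0.45 * pert +
                      spec$asymmetry * 0.18 * cos(phi + runif(1, 0, 2 * pi)))
      rphi <- pmax(rphi, 0.02)
      mask[d <= rphi] <- 1L

      # pigment fill: base colour + Gaussian patches from the palette
      base_col <- spec$color_palette[[1]]
      npatch <- 2L + round(spec$heterogeneity * 5)
      wsum <- matrix(0, S, S)
      csum <- array(0, dim = c(S, S, 3))
      if (spec$heterogeneity > 0 && npatch > 0) {
        for (i in seq_len(npatch)) {
          ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, 0.7) * r0
          px <- ctr[1] + rad * cos(ang); py <- ctr[2] + rad * sin(ang)
          sig <- r0 * runif(1, 0.25, 0.5)
          wt <- spec$heterogeneity *
            exp(-((gx - px)^2 + (gy - py)^2) / (2 * sig^2))
          col <- spec$color_palette[[1L + (i %% length(spec$color_palette))]]
          wsum <- wsum + wt
          for (ch in 1:3) csum[, , ch] <- csum[, , ch] + wt * col[ch]
        }
      }
      # soft edge for the rendered image only (mask stays hard)
      edge <- 1.2 / S
      alpha <- pmin(pmax((rphi - d) / edge, 0), 1)
      for (ch in 1:3) {
        lesion_col <- (base_col[ch] + csum[, , ch]) / (1 + wsum)
        img[, , ch] <- img[, , ch] * (1 - alpha) + lesion_col * alpha
      }
    }

    # ---- artifacts (mask already captured) ----
    if (spec$illumination_gradient > 0) {
      ang <- runif(1, 0, 2 * pi)
      t <- (gx - 0.5) * cos(ang) + (gy - 0.5) * sin(ang)
      ramp <- 1 + spec$illumination_gradient * 0.5 * t
      for (ch in 1:3) img[, , ch] <- img[, , ch] * ramp
    }
    if (spec$hair_count > 0) {
      for (h in seq_len(spec$hair_count)) {
        p0 <- runif(2, -0.1, 1.1); p2 <- runif(2, -0.1, 1.1)
        p1 <- (p0 + p2) / 2 + runif(2, -0.3, 0.3)
        tt <- seq(0, 1, length.out = 4L * S)
        bx <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
        by <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
        keep <- bx > -0.05 & bx < 1.05 & by > -0.05 & by < 1.05
        if (!any(keep)) next
        dmin <- matrix(Inf, S, S)
        for (i in which(keep))
          dmin <- pmin(dmin, (gx - bx[i])^2 + (gy - by[i])^2)
        wdt <- (0.7 / S)^2
        halpha <- 0.75 * exp(-dmin / (2 * wdt))
        hair_col <- c(0.15, 0.11, 0.08) * runif(1, 0.8, 1.2)
        for (ch in 1:3)
          img[, , ch] <- img[, , ch] * (1 - halpha) + hair_col[ch] * halpha
      }
    }
    if (spec$noise_sigma > 0)
      img <- img + array(rnorm(length(img), sd = spec$noise_sigma), dim = dim(img))
    img <- pmin(pmax(img, 0), 1)

    out <- list(image = img, mask = mask, label = spec$class_id,
                sample_id = if (is.null(sample_id))
                  sprintf("c%d_s%d", spec$class_id, seed) else sample_id)
    class(out) <- "image_sample"
    out
  })
}

validate_sample <- function(sample) {
  stopifnot(inherits(sample, "image_sample"),
            all(is.finite(sample$image)),
            all(sample$mask %in% c(0L, 1L)),
            all(dim(sample$mask) == dim(sample$image)[1:2]))
  invisible(sample)
}

#' Boundary roughness of a binary mask
#'
#' Standard deviation of the centroid-to-boundary radius divided by its mean,
#' computed over the 4-connected boundary pixels of the foreground. Returns
#' `NA` for empty masks.
#'
#' @param mask binary matrix.
#' @return nonnegative scalar (coefficient of variation of the radius).
#' @export
boundary_roughness <- function(mask) {
  fg <- which(mask == 1, arr.ind = TRUE)
  if (nrow(fg) == 0) return(NA_real_)
  S <- dim(mask)
  padded <- matrix(0L, S[1] + 2, S[2] + 2)
  padded[2:(S[1] + 1), 2:(S[2] + 1)] <- mask
  inner <- padded[2:(S[1] + 1), 2:(S[2] + 1)]
  nb <- padded[1:S[1], 2:(S[2] + 1)] & padded[3:(S[1] + 2), 2:(S[2] + 1)] &
        padded[2:(S[1] + 1), 1:S[2]] & padded[2:(S[1] + 1), 3:(S[2] + 2)]
  bd <- which(inner == 1 & !nb, arr.ind = TRUE)
  if (nrow(bd) < 3) return(0)
  ctr <- colMeans(fg)
  r <- sqrt((bd[, 1] - ctr[1])^2 + (bd[, 2] - ctr[2])^2)
  stats::sd(r) / mean(r)
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n_per_class` samples per class with per-sample seeds derived
#' deterministically from the master seed via [derive_seed()]. When
#' `out_dir` is given, writes `images/`, `masks/` (8-bit PNG, mask dialect:
#' 255 = lesion), `metadata.csv` and `config.json`; otherwise keeps samples
#' in memory.
#'
#' @param class_specs list of [lesion_spec()] objects (>= 2 classes).
#' @param n_per_class samples per class (>= 1).
#' @param image_size image side in pixels.
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @return a data.frame (`sample_id`, `image_path`, `mask_path`, `label`);
#'   when `out_dir` is `NULL` the samples are attached as attribute
#'   `"samples"` and the path columns are `NA`.
#' @export
generate_dataset <- function(class_specs, n_per_class, image_size = 64L,
                             seed = 1L, out_dir = NULL) {
  if (length(class_specs) < 2) stop("need at least 2 classes")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  labels <- vapply(class_specs, function(s) s$class_id, 0L)
  if (anyDuplicated(labels)) stop("class_id values must be unique")
  write_out <- !is.null(out_dir)
  if (write_out) {
    ok <- dir.create(file.path(out_dir, "images"), recursive = TRUE,
                     showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
    if (!dir.exists(file.path(out_dir, "images")))
      stop("cannot create output directory: ", out_dir)
  }
  rows <- list(); samples <- list()
  idx <- 0L
  for (ci in seq_along(class_specs)) {
    spec <- class_specs[[ci]]
    for (j in seq_len(n_per_class)) {
      idx <- idx + 1L
      sid <- sprintf("s%04d_c%d", idx, spec$class_id)
      smp <- generate_sample(spec, image_size, derive_seed(seed, idx),
                             sample_id = sid)
      ipath <- mpath <- NA_character_
      if (write_out) {
        ipath <- file.path(out_dir, "images", paste0(sid, ".png"))
        mpath <- file.path(out_dir, "masks", paste0(sid, ".png"))
        write_png(smp$image, ipath)
        write_png(smp$mask * 1.0, mpath)
      } else samples[[idx]] <- smp
      rows[[idx]] <- data.frame(sample_id = sid, image_path = ipath,
                                mask_path = mpath, label = spec$class_id,
                                stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, rows)
  if (write_out) {
    write.csv(meta, file.path(out_dir, "metadata.csv"), row.names = FALSE)
    cfg <- list(master_seed = seed, image_size = image_size,
                class_specs = lapply(class_specs, unclass))
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  } else attr(meta, "samples") <- samples
  meta
}

#' Load a dataset written by [generate_dataset()]
#'
#' Reads `metadata.csv` and the referenced PNGs. Masks are thresholded at
#' 128/255 to recover strict binarity.
#'
#' @param dir dataset directory.
#' @return data.frame with attribute `"samples"` (list of `image_sample`).
#' @export
load_dataset <- function(dir) {
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(meta)), function(i) {
    img <- read_png(meta$image_path[i])
    msk <- read_png(meta$mask_path[i])
    out <- list(image = img, mask = matrix(as.integer(msk >= 128 / 255),
                                           nrow(msk), ncol(msk)),
                label = meta$label[i], sample_id = meta$sample_id[i])
    class(out) <- "image_sample"
    out
  })
  attr(meta, "samples") <- samples
  meta
}

dataset_samples <- function(meta) {
  s <- attr(meta, "samples")
  if (is.null(s)) stop("metadata table has no attached samples; use load_dataset()")
  s
}

#' Augmentation parameters
#'
#' @param p_hflip,p_vflip flip probabilities in \[0, 1\].
#' @param max_rotation_deg maximum absolute rotation angle (degrees).
#' @param brightness_delta,contrast_delta,color_jitter_delta nonnegative
#'   photometric jitter amplitudes.
#' @return object of class `augmentation_params`.
#' @export
augmentation_params <- function(p_hflip = 0.5, p_vflip = 0.5,
                                max_rotation_deg = 15, brightness_delta = 0.1,
                                contrast_delta = 0.1, color_jitter_delta = 0.05) {
  if (p_hflip < 0 || p_hflip > 1 || p_vflip < 0 || p_vflip > 1)
    stop("flip probabilities must be in [0, 1]")
  if (max_rotation_deg < 0 || brightness_delta < 0 || contrast_delta < 0 ||
      color_jitter_delta < 0)
    stop("deltas must be nonnegative")
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip,
                 max_rotation_deg = max_rotation_deg,
                 brightness_delta = brightness_delta,
                 contrast_delta = contrast_delta,
                 color_jitter_delta = color_jitter_delta),
            class = "augmentation_params")
}

rotate_plane <- function(m, angle_deg, nearest = FALSE) {
  a <- angle_deg %% 360
  if (a %% 90 == 0) {  # exact pixel permutations for right angles
    k <- (a %/% 90) %% 4
    out <- m
    for (i in seq_len(k)) out <- t(out)[, rev(seq_len(nrow(out))), drop = FALSE]
    return(out)
  }
  S1 <- nrow(m); S2 <- ncol(m)
  th <- -angle_deg * pi / 180  # inverse mapping
  cy <- (S1 + 1) / 2; cx <- (S2 + 1) / 2
  cols <- rep(seq_len(S2), each = S1); rows <- rep(seq_len(S1), times = S2)
  sy <- cy + cos(th) * (rows - cy) - sin(th) * (cols - cx)
  sx <- cx + sin(th) * (rows - cy) + cos(th) * (cols - cx)
  sy <- pmin(pmax(sy, 1), S1); sx <- pmin(pmax(sx, 1), S2)
  if (nearest) {
    vals <- m[cbind(round(sy), round(sx))]
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- pmin(y0 + 1, S1); x1 <- pmin(x0 + 1, S2)
    fy <- sy - y0; fx <- sx - x0
    vals <- (1 - fy) * (1 - fx) * m[cbind(y0, x0)] +
            (1 - fy) * fx * m[cbind(y0, x1)] +
            fy * (1 - fx) * m[cbind(y1, x0)] +
            fy * fx * m[cbind(y1, x1)]
  }
  matrix(vals, S1, S2)
}

#' Apply a seeded random augmentation to a sample
#'
#' Geometric transforms (flips, rotation) are applied identically to image
#' and mask; the mask uses nearest resampling and is re-binarized, so it
#' stays strictly binary. Photometric jitter touches only the image. With
#' all probabilities and deltas at zero the sample is returned unchanged.
#'
#' @param sample an `image_sample`.
#' @param params an [augmentation_params()].
#' @param seed integer seed.
#' @return augmented `image_sample` (label unchanged).
#' @export
augment <- function(sample, params, seed) {
  stopifnot(inherits(params, "augmentation_params"))
  validate_sample(sample)
  run_seeded(seed, {
    img <- sample$image; msk <- sample$mask
    if (params$p_hflip > 0 && runif(1) < params$p_hflip) {
      img <- img[, rev(seq_len(ncol(msk))), , drop = FALSE]
      msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
    }
    if (params$p_vflip > 0 && runif(1) < params$p_vflip) {
      img <- img[rev(seq_len(nrow(msk))), , , drop = FALSE]
      msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
    }
    if (params$max_rotation_deg > 0) {
      ang <- runif(1, -params$max_rotation_deg, params$max_rotation_deg)
      for (ch in 1:3) img[, , ch] <- rotate_plane(img[, , ch], ang)
      msk <- rotate_plane(msk, ang, nearest = TRUE)
      msk <- matrix(as.integer(msk >= 0.5), nrow(msk), ncol(msk))
    }
    if (params$brightness_delta > 0)
      img <- img + runif(1, -params$brightness_delta, params$brightness_delta)
    if (params$contrast_delta > 0)
      img <- (img - 0.5) * (1 + runif(1, -params$contrast_delta,
                                      params$contrast_delta)) + 0.5
    if (params$color_jitter_delta > 0)
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] *
          (1 + runif(1, -params$color_jitter_delta, params$color_jitter_delta))
    img <- pmin(pmax(img, 0), 1)
    out <- list(image = img, mask = msk, label = sample$label,
                sample_id = sample$sample_id)
    class(out) <- "image_sample"
    out
  })
}

#' ImageNet channel statistics
#'
#' @return list with `mean` and `std`, the conventional ImageNet RGB
#'   normalization constants.
#' @export
imagenet_stats <- function() {
  list(mean = c(0.485, 0.456, 0.406), std = c(0.229, 0.224, 0.225))
}

#' Normalize (and optionally resize) an image
#'
#' Computes `(x - mean) / std` per channel. When `size` is given the image
#' is first resized bilinearly to `size x size` (the configured working
#' resolution).
#'
#' @param image H x W x 3 array.
#' @param stats list with per-channel `mean` and `std` (std > 0); defaults
#'   to [imagenet_stats()].
#' @param size optional target side length.
#' @return normalized array.
#' @export
normalize_image <- function(image, stats = imagenet_stats(), size = NULL) {
  stopifnot(length(dim(image)) == 3)
  nc <- dim(image)[3]
  if (length(stats$mean) != nc || length(stats$std) != nc)
    stop("channel count mismatch between image and stats")
  if (any(stats$std <= 0)) stop("std must be strictly positive")
  if (!is.null(size) && any(dim(image)[1:2] != size))
    image <- resize_bilinear_cpp(image, as.integer(size), as.integer(size))
  for (ch in seq_len(nc))
    image[, , ch] <- (image[, , ch] - stats$mean[ch]) / stats$std[ch]
  image
}

#' Resize a binary mask with nearest resampling
#'
#' @param mask binary matrix.
#' @param size target side length.
#' @return binary matrix `size x size`.
#' @export
resize_mask <- function(mask, size) {
  if (all(dim(mask) == size)) return(mask)
  out <- resize_nearest_cpp(array(mask, dim = c(dim(mask), 1L)),
                            as.integer(size), as.integer(size))[, , 1]
  matrix(as.integer(out >= 0.5), size, size)
}
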