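test_that("generate_sample handles the degenerate lesion-free spec", {
  s <- generate_sample(lesion_spec(0L, base_radius_frac = 0), 64, 5)
  expect_identical(sum(s$mask), 0L)
  expect_true(all(is.finite(s$image)))
  expect_true(all(s$image >= 0 & s$image <= 1))
})

test_that("generation is a pure function of (spec, size, seed)", {
  sp <- synthetic_class_specs()[[2]]
  a <- generate_sample(sp, 64, 7)
  b <- generate_sample(sp, 64, 7)
  expect_identical(a, b)
  expect_false(identical(a$image, generate_sample(sp, 64, 8)$image))
})

test_that("smooth symmetric specs produce low boundary roughness", {
  sp <- lesion_spec(0L, border_irregularity = 0, asymmetry = 0)
  for (seed in 1:5) {
    r <- boundary_roughness(generate_sample(sp, 64, seed)$mask)
    expect_lt(r, 0.05)
  }
})

test_that("border irregularity is recoverable from generated masks", {
  rough <- function(irr, seeds) {
    sp <- lesion_spec(0L, border_irregularity = irr)
    vapply(seeds, function(s) boundary_roughness(generate_sample(sp, 64, s)$mask), 0)
  }
  r_lo <- rough(0.05, 1:20)
  r_hi <- rough(0.40, 21:40)
  expect_lt(mean(r_lo), mean(r_hi))  # strict ordering of the class means
  # a single threshold separates the two morphologies with >= 95% accuracy
  # over 100 samples
  r_lo <- rough(0.05, 1:50)
  r_hi <- rough(0.40, 51:100)
  thr <- seq(min(r_lo, r_hi), max(r_lo, r_hi), length.out = 200)
  acc <- vapply(thr, function(t) (sum(r_lo <= t) + sum(r_hi > t)) / 100, 0)
  expect_gte(max(acc), 0.95)
})

test_that("every generated sample satisfies the mask/image invariants", {
  specs <- synthetic_class_specs()
  for (seed in 1:12) {
    s <- generate_sample(specs[[1 + seed %% 3]], 48, seed)
    expect_true(all(s$mask %in% c(0L, 1L)))
    expect_true(all(is.finite(s$image)))
    expect_identical(dim(s$mask), dim(s$image)[1:2])
  }
})

test_that("generate_dataset writes a loadable on-disk dataset", {
  out <- withr::local_tempdir()
  specs <- synthetic_class_specs()[1:2]
  meta <- generate_dataset(specs, 5L, 48L, seed = 3L, out_dir = out)
  expect_equal(nrow(meta), 10L)
  expect_equal(as.integer(table(meta$label)), c(5L, 5L))
  expect_setequal(names(meta), c("sample_id", "image_path", "mask_path", "label"))
  expect_true(file.exists(file.path(out, "config.json")))

  back <- load_dataset(out)
  s_mem <- generate_sample(specs[[1]], 48L, derive_seed(3L, 1L),
                           sample_id = meta$sample_id[1])
  s_disk <- attr(back, "samples")[[1]]
  # PNG round-trip is exact up to 8-bit quantization
  expect_lt(max(abs(s_disk$image - s_mem$image)), 1 / 255)
  expect_identical(s_disk$mask, s_mem$mask)
  expect_identical(s_disk$label, s_mem$label)
})

test_that("per-sample seeds are stable under dataset growth", {
  specs <- synthetic_class_specs()[1:2]
  small <- generate_dataset(specs, 2L, 48L, seed = 9L)
  big <- generate_dataset(specs, 3L, 48L, seed = 9L)
  # first class's samples are identical in both datasets
  expect_identical(attr(small, "samples")[[1]]$image,
                   attr(big, "samples")[[1]]$image)
  expect_identical(attr(small, "samples")[[2]]$image,
                   attr(big, "samples")[[2]]$image)
})

test_that("spec validation rejects out-of-range morphology parameters", {
  expect_error(lesion_spec(0L, base_radius_frac = 0.6), "base_radius_frac")
  expect_error(lesion_spec(0L, asymmetry = 1.5), "asymmetry")
  expect_error(lesion_spec(0L, border_irregularity = -0.1), "border_irregularity")
  expect_error(lesion_spec(0L, color_palette = list(c(2, 0, 0))), "palette")
  expect_error(generate_dataset(synthetic_class_specs()[1], 5L), "2 classes")
})

test_that("augmentation honors identity, involution and right angles", {
  s <- generate_sample(synthetic_class_specs()[[1]], 64, 11)
  p0 <- augmentation_params(0, 0, 0, 0, 0, 0)
  expect_identical(augment(s, p0, 1), s)

  ph <- augmentation_params(1, 0, 0, 0, 0, 0)
  twice <- augment(augment(s, ph, 1), ph, 2)
  expect_identical(twice$image, s$image)
  expect_identical(twice$mask, s$mask)

  rot90 <- lesionnet:::rotate_plane(s$mask, 90)
  expect_identical(sum(rot90), sum(s$mask))  # pixel permutation
})

test_that("random augmentation keeps the mask binary and geometry shared", {
  s <- generate_sample(synthetic_class_specs()[[2]], 64, 3)
  p <- augmentation_params(0.5, 0.5, 25, 0.1, 0.1, 0.05)
  for (seed in 1:6) {
    a <- augment(s, p, seed)
    expect_identical(augment(s, p, seed), a)   # seeded determinism
    expect_true(all(a$mask %in% c(0L, 1L)))
    expect_identical(a$label, s$label)
    # lesion area is approximately preserved by rigid transforms
    expect_lt(abs(sum(a$mask) - sum(s$mask)) / sum(s$mask), 0.1)
  }
})

test_that("normalization centres, scales and resizes as specified", {
  st <- imagenet_stats()
  img <- array(0, dim = c(8, 8, 3))
  for (ch in 1:3) img[, , ch] <- st$mean[ch]
  expect_equal(normalize_image(img), array(0, dim = c(8, 8, 3)))

  ident <- list(mean = c(0, 0, 0), std = c(1, 1, 1))
  x <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  expect_identical(normalize_image(x, ident), x)

  # hand-evaluated: (0.785 - 0.485) / 0.229
  x1 <- array(0.785, dim = c(4, 4, 3))
  expect_equal(normalize_image(x1)[1, 1, 1], 1.31004, tolerance = 1e-5)

  expect_error(normalize_image(x, list(mean = c(0, 0, 0), std = c(1, 0, 1))),
               "positive")
  expect_error(normalize_image(x, list(mean = 0, std = 1)), "channel count")

  big <- normalize_image(x, ident, size = 16)
  expect_identical(dim(big), c(16L, 16L, 3L))
  m <- matrix(as.integer(matrix(runif(64), 8) > 0.5), 8)
  rm2 <- resize_mask(m, 16)
  expect_true(all(rm2 %in% c(0L, 1L)))
  expect_identical(resize_mask(rm2, 8), m)  # nearest 2x is invertible here
})
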