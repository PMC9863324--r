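test_that("min-max normalization follows the direct formula", {
  f <- matrix(c(0, 50, 100, 50), 2, 2)
  expect_equal(minmax_normalize(f), matrix(c(0, 0.5, 1, 0.5), 2, 2))
  expect_equal(minmax_normalize(matrix(7, 3, 3)), matrix(0, 3, 3))
  g <- matrix(runif(64), 8, 8); g[1] <- 0; g[2] <- 1
  expect_equal(minmax_normalize(g), g)
})

test_that("histogram stretching clips percentile outliers into [0,1]", {
  set.seed(1)
  body <- runif(9900, 0, 100)
  f <- matrix(c(body, rep(1000, 100)), 100, 100)
  s <- histogram_stretch(f, 1, 99)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(sum(s == 1), sum(f >= quantile(f, 0.99)))
  # oracle: explicit percentile map
  q <- quantile(f, c(0.01, 0.99), names = FALSE)
  expect_equal(s, pmin(pmax((f - q[1]) / (q[2] - q[1]), 0), 1))
  # degenerate limits coincide with plain min-max scaling
  expect_equal(histogram_stretch(f, 0, 100), minmax_normalize(f))
  expect_equal(histogram_stretch(matrix(3, 4, 4)), matrix(0, 4, 4))
})

test_that("center crop/pad preserves the image center", {
  big <- matrix(seq_len(300^2), 300, 300)
  out <- center_crop_pad(big, 256)
  expect_identical(dim(out), c(256L, 256L))
  expect_equal(out, big[23:278, 23:278] + 0)
  small <- matrix(1, 200, 200)
  pad <- center_crop_pad(small, 256)
  expect_equal(sum(pad), 200^2)
  expect_identical(pad[29:228, 29:228], small)
  expect_identical(center_crop_pad(small, 200), small)
  # odd difference: extra pixel trails
  odd <- center_crop_pad(matrix(1, 3, 3), 6)
  expect_equal(which(rowSums(odd) > 0), 2:4)
})

test_that("null augmentation is the identity and flips reflect the centroid", {
  f <- matrix(runif(64^2), 64, 64)
  m <- raster_ellipse(64, 10, 8, center = c(40, 25))
  id <- augment_pair(f, m, params = list(rotation_deg = 0, flip_h = FALSE,
                                         flip_v = FALSE,
                                         scale_range = c(1, 1),
                                         translate_frac = 0), seed = 3)
  expect_equal(id$frame, f, tolerance = 1e-10)
  expect_equal(id$mask, m)
  # deterministic horizontal flip: force it by trying seeds
  p_flip <- list(rotation_deg = 0, flip_h = TRUE, flip_v = FALSE,
                 scale_range = c(1, 1), translate_frac = 0)
  got <- FALSE
  for (s in 1:10) {
    out <- augment_pair(f, m, params = p_flip, seed = s)
    if (!identical(out$mask, m)) {
      c0 <- mask_centroid(m); c1 <- mask_centroid(out$mask)
      expect_equal(c1[["col"]], 65 - c0[["col"]], tolerance = 0.51)
      expect_equal(c1[["row"]], c0[["row"]], tolerance = 0.51)
      got <- TRUE
      break
    }
  }
  expect_true(got)
})

test_that("augmentation preserves binarity and approximate mask area", {
  f <- matrix(runif(64^2), 64, 64)
  m <- raster_ellipse(64, 9, 9, center = c(30, 38))
  for (s in 1:8) {
    out <- augment_pair(f, m, seed = s)  # default ranges
    expect_true(all(out$mask %in% c(0, 1)))
    scale_used <- sum(out$mask) / sum(m)
    expect_lt(abs(sqrt(scale_used) - 1), 0.13)  # |rot|<=15deg, scale 0.9-1.1
  }
  # pure 90-degree rotation of an off-center disk preserves area within 1%
  rot90 <- augment_pair(f, m, params = list(rotation_deg = 90, flip_h = FALSE,
                                            flip_v = FALSE,
                                            scale_range = c(1, 1),
                                            translate_frac = 0), seed = 1)
  # draw until the sampled angle is near the range edge is not needed:
  # apply a fixed rotation through the same machinery at scale 1
  expect_lt(abs(sum(rot90$mask) / sum(m) - 1), 0.05)
})

test_that("sequence preprocessing keeps frame count and spacing", {
  ph <- generate_phantom(phantom_config(grid_size = 96, n_frames = 4,
                                        semi_axes_dia = c(14, 12)))
  pp <- preprocess_sequence(ph$cine, target = 64)
  expect_equal(dim(pp$frames), c(4, 64, 64))
  expect_identical(pp$pixel_spacing, ph$cine$pixel_spacing)
  expect_true(all(pp$frames >= 0 & pp$frames <= 1))
})

test_that("loading a frame directory with mixed shapes names the offender", {
  d <- tempfile(); dir.create(d)
  for (i in 1:3) {
    img <- RNifti::asNifti(matrix(runif(16 * 16), 16, 16))
    RNifti::writeNifti(img, file.path(d, sprintf("f%02d.nii.gz", i)))
  }
  bad <- RNifti::asNifti(matrix(0, 8, 8))
  RNifti::writeNifti(bad, file.path(d, "f04.nii.gz"))
  yaml::write_yaml(list(exam_id = "e", pixel_spacing_mm = c(1, 1)),
                   file.path(d, "sequence.yaml"))
  expect_error(load_sequence(d), "f04")
})

test_that("missing pixel spacing is an error, not a guess", {
  d <- tempfile(); dir.create(d)
  img <- RNifti::asNifti(matrix(runif(16 * 16), 16, 16))
  RNifti::writeNifti(img, file.path(d, "f01.nii.gz"))
  expect_error(load_sequence(d), "spacing")
})

test_that("NIfTI header spacing is honored", {
  arr <- array(runif(3 * 16 * 16), c(3, 16, 16))
  x <- cine_sequence(arr, pixel_spacing = 1.25)
  tmp <- tempfile(fileext = ".nii.gz")
  write_sequence(x, tmp)
  file.remove(paste0(tmp, ".yaml"))  # force header-only path
  back <- load_sequence(tmp)
  expect_equal(back$pixel_spacing, c(1.25, 1.25))
})
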