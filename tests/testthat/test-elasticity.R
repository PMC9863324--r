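test_that("centroid is the unweighted mean of mask pixels", {
  m <- matrix(0, 32, 32); m[10, 20] <- 1
  expect_equal(mask_centroid(m), c(row = 10, col = 20))
  m2 <- matrix(0, 32, 32); m2[1, 1] <- 1; m2[11, 11] <- 1
  expect_equal(mask_centroid(m2), c(row = 6, col = 6))
  disk <- raster_ellipse(64, 12, 12)
  expect_equal(mask_centroid(disk), c(row = 32.5, col = 32.5),
               tolerance = 0.5)
  expect_error(mask_centroid(matrix(0, 4, 4)), "empty")
})

test_that("quadrant partition covers the mask exactly with four sectors", {
  m <- raster_ellipse(64, 14, 11)
  part <- partition_quadrants(m, rotation_deg = 60)
  expect_true(all((part$sector > 0) == (m > 0)))
  counts <- tabulate(part$sector[part$sector > 0], 4)
  expect_true(all(counts > 0))
  expect_equal(sum(counts), sum(m))
  # full disk: each sector within 2% of a quarter
  disk <- raster_ellipse(64, 15, 15)
  pd <- partition_quadrants(disk, rotation_deg = 60)
  cd <- tabulate(pd$sector[pd$sector > 0], 4)
  expect_true(all(abs(cd / (sum(disk) / 4) - 1) < 0.02))
  # oracle: brute-force per-pixel sector count with the same convention
  px <- which(disk > 0, arr.ind = TRUE)
  cent <- mask_centroid(disk)
  ang <- (atan2(-(px[, 1] - cent[1]), px[, 2] - cent[2]) * 180 / pi) %% 360
  oracle <- tabulate(floor(((ang - 60) %% 360) / 90) + 1, 4)
  expect_equal(cd, oracle)
})

test_that("rotation by 90 degrees cyclically shifts the partition", {
  m <- raster_ellipse(64, 14, 10)
  p60 <- partition_quadrants(m, rotation_deg = 60)$sector
  p150 <- partition_quadrants(m, rotation_deg = 150)$sector
  inside <- m > 0
  # rotating the sector boundaries forward by 90 deg shifts every pixel's
  # sector index back by one
  expect_true(all(((p60[inside] - 2) %% 4 + 1) == p150[inside]))
})

test_that("area curve follows pixel count times pixel area", {
  m <- matrix(0, 32, 32); m[5:14, 5:14] <- 1          # 100 px
  ms <- mask_sequence(array(m, c(1, 32, 32)), 1.25)
  ac <- area_curve(ms)
  expect_equal(ac$total, 100 * 1.25^2)
  expect_equal(sum(ac$quadrant[1, ]), ac$total)
  circ <- mask_sequence(array(raster_ellipse(64, 20), c(1, 64, 64)), 1)
  expect_lt(abs(area_curve(circ)$total / (pi * 400) - 1), 0.01)
  bad <- mask_sequence(array(0L, c(2, 8, 8)), 1)
  expect_error(area_curve(bad), "frame 1")
})

test_that("compliance and strain formulas are exact on hand cases", {
  pp <- pressure_pair(120, 80)
  expect_equal(global_compliance(c(900, 950, 1000, 940), pp), 2.5)
  expect_equal(global_compliance(rep(800, 5), pp), 0)
  expect_equal(global_strain(c(100, 104, 110, 103)), 0.1)
  expect_equal(global_strain(rep(90, 4)), 0)
  expect_error(pressure_pair(100, 100))
})

test_that("sub-pixel perimeter of a rasterized circle is within 2% of 2 pi r", {
  circ <- mask_sequence(array(raster_ellipse(64, 20), c(1, 64, 64)), 1)
  pc <- perimeter_curve(circ)
  expect_lt(abs(pc$total / (2 * pi * 20) - 1), 0.02)
  # quadrant arcs of a centered disk: each within 2% of total/4, sum exact
  expect_true(all(abs(pc$quadrant[1, ] / (pc$total / 4) - 1) < 0.02))
  expect_equal(sum(pc$quadrant[1, ]), pc$total, tolerance = 1e-9)
  # doubling the spacing doubles every perimeter
  circ2 <- mask_sequence(array(raster_ellipse(64, 20), c(1, 64, 64)), 2)
  expect_equal(perimeter_curve(circ2)$total, 2 * pc$total, tolerance = 1e-9)
})

test_that("phantom truth is recovered from ground-truth masks", {
  ph <- generate_phantom(phantom_config(n_frames = 12))
  pp <- phantom_config()$pressures
  rep <- elasticity_report(ph$masks, pp)
  expect_lt(abs(rep$global_compliance / ph$truth$true_compliance - 1), 0.02)
  expect_lt(abs(rep$global_strain / ph$truth$true_strain - 1), 0.02)
  expect_gte(rep$max_area, rep$min_area)
  expect_gte(rep$max_perimeter, rep$min_perimeter)
  expect_true(all(rep$local_compliance >= 0))
  # per-quadrant extrema can exceed synchronized extrema
  expect_gte(sum(rep$local_compliance) + 1e-9, rep$global_compliance)
  rep2 <- elasticity_report(ph$masks, pp)
  expect_identical(rep, rep2)
})

test_that("static masks give zero local compliance and strain", {
  m <- raster_ellipse(64, 14, 12)
  ms <- mask_sequence(aperm(array(rep(m, 3), c(64, 64, 3)), c(3, 1, 2)), 1.1)
  expect_equal(unname(local_compliance(ms, pressure_pair(120, 80))), rep(0, 4))
  expect_equal(unname(local_strain(ms)), rep(0, 4))
})

test_that("single-axis pulsation concentrates strain in that axis' sectors", {
  cfg <- phantom_config(grid_size = 128, pixel_spacing = 1, n_frames = 10,
                        semi_axes_dia = c(22, 22),
                        pulsation_fraction = c(0.12, 0),
                        motion_amplitude_mm = 0)
  ph <- generate_phantom(cfg)
  ls <- local_strain(ph$masks, rotation_deg = 60)
  # the +/- column axis (0 and 180 deg) lies in sectors 4 and 2
  # ("posterior" and "anterior" under the default labelling)
  expect_gt(min(ls[c("posterior", "anterior")]),
            max(ls[c("lateral", "medial")]))
  # analytic truth agrees on the ordering
  tls <- ph$truth$true_local_strain
  expect_gt(min(tls[c("posterior", "anterior")]),
            max(tls[c("lateral", "medial")]))
})

test_that("uniformly pulsating centered disk splits compliance evenly", {
  cfg <- phantom_config(grid_size = 128, pixel_spacing = 1.17, n_frames = 10,
                        semi_axes_dia = c(22, 22), motion_amplitude_mm = 0)
  ph <- generate_phantom(cfg)
  lc <- local_compliance(ph$masks, cfg$pressures)
  gc <- global_compliance(area_curve(ph$masks), cfg$pressures)
  expect_true(all(abs(lc / (gc / 4) - 1) < 0.03))
  ls <- local_strain(ph$masks)
  expect_true(all(abs(ls / ls[1] - 1) < 1e-6))  # exact by grid symmetry
})

test_that("elasticity report serializes to JSON and CSV", {
  ph <- generate_phantom(phantom_config(grid_size = 96, n_frames = 5,
                                        semi_axes_dia = c(14, 12)))
  rep <- elasticity_report(ph$masks, pressure_pair(130, 75))
  pre <- tempfile()
  paths <- write_elasticity_report(rep, pre, curves = TRUE)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[1])
  expect_equal(js$global_compliance_mm2_mmHg, rep$global_compliance,
               tolerance = 1e-12)
  df <- read.csv(paths[2])
  expect_true(all(c("compliance_medial", "strain_posterior") %in% names(df)))
})

test_that("compliance and strain are invariant to joint translation and rotation", {
  ph <- generate_phantom(phantom_config(grid_size = 96, n_frames = 5,
                                        semi_axes_dia = c(14, 12),
                                        motion_amplitude_mm = 0.8))
  pp <- pressure_pair(125, 78)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  moved <- ph$masks
  for (t in 1:5) moved$frames[t, , ] <- shift(ph$masks$frames[t, , ], 6, 9)
  expect_equal(global_compliance(area_curve(moved), pp),
               global_compliance(area_curve(ph$masks), pp))
  expect_equal(global_strain(perimeter_curve(moved)),
               global_strain(perimeter_curve(ph$masks)), tolerance = 1e-9)
  # 90 deg image rotation with correspondingly rotated sector offset
  rot <- ph$masks
  for (t in 1:5) rot$frames[t, , ] <- t(ph$masks$frames[t, 96:1, ])
  ls0 <- local_strain(ph$masks, rotation_deg = 60)
  ls90 <- local_strain(rot, rotation_deg = 150)
  expect_equal(sort(unname(ls0)), sort(unname(ls90)), tolerance = 1e-6)
})
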