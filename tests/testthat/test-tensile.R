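test_that("engineering strain and stress follow their definitions", {
  expect_equal(engineering_strain(11, 10), 0.1)
  expect_equal(engineering_strain(10, 10), 0)
  expect_equal(engineering_strain(15, 10), 0.5)
  expect_error(engineering_strain(10, 0))
  expect_equal(engineering_stress(3, 30), 0.1)  # 3 N over 15x2 mm^2 section
  expect_equal(engineering_stress(0, 30), 0)
  expect_error(engineering_stress(1, -1))
})

test_that("noiseless linear records recover their modulus", {
  rec <- generate_tensile(tensile_sim_config(
    modulus_segments = data.frame(strain_from = 0, strain_to = 0.4,
                                  E_MPa = 0.5), n_samples = 200))
  curve <- stress_strain_curve(rec)
  fit <- coef(lm(curve$stress ~ curve$strain))
  expect_lt(abs(fit[2] / 0.5 - 1), 0.01)          # least-squares slope oracle
  mr <- modulus_curve(curve, smoothing_window = 1)
  expect_true(all(abs(mr$modulus - 0.5) < 1e-9))
  expect_equal(max_youngs_modulus(mr), 0.5, tolerance = 1e-9)
})

test_that("tangent modulus tracks a known analytic derivative", {
  eps <- seq(0, 1, length.out = 401)
  rec <- tensile_record(displacement = eps * 10, force = eps^2 * 20,
                        l0 = 10, thickness = 2)   # sigma = eps^2, A0 = 20
  mr <- modulus_curve(stress_strain_curve(rec), smoothing_window = 1)
  mid <- 30:370
  expect_true(all(abs(mr$modulus[mid] - 2 * eps[mid]) < 0.01))
  # monotone convex curve attains its maximum tangent at the largest strain
  expect_equal(which.max(mr$modulus), length(mr$modulus))
})

test_that("bilinear curves yield the stiffer branch as maximum modulus", {
  segs <- data.frame(strain_from = c(0, 0.1), strain_to = c(0.1, 0.3),
                     E_MPa = c(0.3, 1.2))
  rec <- generate_tensile(tensile_sim_config(modulus_segments = segs,
                                             n_samples = 300))
  mr <- modulus_curve(stress_strain_curve(rec), smoothing_window = 5)
  expect_lt(abs(max_youngs_modulus(mr) / 1.2 - 1), 0.02)
})

test_that("noisy records recover the modulus within 2% after smoothing", {
  rec <- generate_tensile(tensile_sim_config(
    modulus_segments = data.frame(strain_from = 0, strain_to = 0.4,
                                  E_MPa = 0.5),
    n_samples = 400, noise_sd = 0.005, seed = 21))
  mr <- modulus_curve(stress_strain_curve(rec), smoothing_window = 11)
  # average over samples whose smoothing window is fully interior: the
  # one-sided endpoint estimates otherwise dominate the mean's variance
  n <- length(mr$modulus)
  expect_lt(abs(mean(mr$modulus[7:(n - 6)]) / 0.5 - 1), 0.02)
})

test_that("physiological modulus averages the pressure-derived window", {
  # sigma(P) = P r / t: 120 mmHg, r = 20, t = 2 -> 0.160 MPa
  expect_equal(mmhg_to_mpa(120) * 20 / 2, 0.16, tolerance = 0.001)
  segs <- data.frame(strain_from = c(0, 0.2), strain_to = c(0.2, 0.6),
                     E_MPa = c(0.4, 1.5))
  rec <- generate_tensile(tensile_sim_config(modulus_segments = segs,
                                             n_samples = 500))
  mr <- modulus_curve(stress_strain_curve(rec), smoothing_window = 1)
  # soft branch spans sigma in [0, 0.08]; a window inside it returns 0.4
  ph <- physiological_youngs_modulus(mr, pressure_pair(110, 70),
                                     radius = 10, wall_thickness = 2)
  expect_lt(abs(ph$E_phys / 0.4 - 1), 0.05)
  expect_lte(ph$E_phys, max_youngs_modulus(mr) + 1e-9)
  # linear curve: E_phys equals the single modulus regardless of window
  lin <- modulus_curve(stress_strain_curve(generate_tensile(
    tensile_sim_config(modulus_segments = data.frame(
      strain_from = 0, strain_to = 0.5, E_MPa = 0.7)))), smoothing_window = 1)
  phl <- physiological_youngs_modulus(lin, pressure_pair(120, 80),
                                      radius = 15, wall_thickness = 2)
  expect_equal(phl$E_phys, 0.7, tolerance = 1e-6)
  expect_error(physiological_youngs_modulus(lin, pressure_pair(120, 80),
                                            radius = 500, wall_thickness = 1),
               "window")
})

test_that("E_phys never exceeds E_max and scaling laws hold", {
  set.seed(3)
  for (i in 1:5) {
    e1 <- runif(1, 0.2, 0.8); e2 <- e1 + runif(1, 0.1, 1)
    segs <- data.frame(strain_from = c(0, 0.15), strain_to = c(0.15, 0.5),
                       E_MPa = c(e1, e2))
    rec <- generate_tensile(tensile_sim_config(modulus_segments = segs,
                                               n_samples = 300))
    mr <- modulus_curve(stress_strain_curve(rec), smoothing_window = 7)
    ph <- physiological_youngs_modulus(mr, pressure_pair(130, 70),
                                       radius = 12, wall_thickness = 2)
    expect_lte(ph$E_phys, mr$E_max + 1e-9)
    # doubling all forces doubles stress and modulus
    rec2 <- tensile_record(rec$displacement, 2 * rec$force, rec$l0,
                           rec$thickness)
    mr2 <- modulus_curve(stress_strain_curve(rec2), smoothing_window = 7)
    expect_equal(mr2$E_max, 2 * mr$E_max, tolerance = 1e-9)
  }
})

test_that("secant method implements the literal stress/strain ratio", {
  eps <- seq(0, 0.4, length.out = 100)
  rec <- tensile_record(eps * 15, (0.05 + 0.5 * eps) * 30, l0 = 15,
                        thickness = 2)
  mr <- modulus_curve(stress_strain_curve(rec), smoothing_window = 1,
                      method = "secant")
  i <- 50
  expect_equal(mr$modulus[i], mr$stress[i] / mr$strain[i])
})

test_that("preconditioning cycles are trimmed at the last zero-force return", {
  ramp <- seq(0, 5, length.out = 50)
  pre_d <- c(seq(0, 1, length.out = 10), seq(1, 0.01, length.out = 10))
  disp <- c(pre_d, pre_d + 0.01, 1 + ramp)
  disp <- cummax(disp)
  force <- c(abs(sin(seq(0, pi, length.out = 20))) * 0.3,
             abs(sin(seq(0, pi, length.out = 20))) * 0.3,
             ramp * 0.8)
  rec <- tensile_record(disp, force, l0 = 15, thickness = 2)
  trimmed <- trim_preconditioning(rec, zero_tol = 0.02)
  expect_equal(trimmed$displacement[1], 0)
  expect_true(all(diff(trimmed$force) >= -1e-9))
  expect_lt(length(trimmed$force), length(force))
})

test_that("tensile records round-trip through CSV with metadata", {
  rec <- generate_tensile(tensile_sim_config(n_samples = 50, seed = 2,
                                             noise_sd = 0.002))
  tmp <- tempfile(fileext = ".csv")
  write_tensile_record(rec, tmp)
  back <- read_tensile_record(tmp)
  expect_equal(back$displacement, rec$displacement)
  expect_equal(back$force, rec$force)
  expect_equal(back$l0, rec$l0)
  expect_equal(back$axis, rec$axis)
})
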