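#' Phantom configuration
#'
#' Parameters of the synthetic pulsating-vessel phantom. The phantom
#' emulates an axial cine acquisition at the level of the pulmonary trunk:
#' a bright quasi-elliptical lumen whose semi-axes follow a smooth
#' systolic-diastolic cycle, surrounded by darker tissue, optionally with a
#' neighboring vessel and flow-artifact corruption. Defaults correspond to
#' a dilated ascending aorta imaged at 1.17 mm/pixel with 30 frames per
#' cardiac cycle.
#'
#' @param grid_size frame side length in pixels (>= 64).
#' @param pixel_spacing isotropic pixel spacing in mm/pixel.
#' @param n_frames frames per cardiac cycle (>= 2).
#' @param semi_axes_dia length-2 numeric, diastolic semi-axes (a, b) in mm;
#'   `a` lies along the column (x) axis, `b` along the row (y) axis.
#' @param pulsation_fraction peak fractional radial dilation over the cycle
#'   (`0 <= f < 0.5`). A length-2 vector pulses the two semi-axes by
#'   different amounts (anisotropic pulsation).
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param artifact_level amount of flow-artifact corruption in `[0, 1]`
#'   (intra-lumen dropout patches and ghosting streaks).
#' @param neighbor_structures logical: render an adjacent circular vessel
#'   (pulmonary-artery analog) abutting the lumen.
#' @param motion_amplitude_mm in-plane translation of the vessel center over
#'   the cardiac cycle (deterministic, waveform-locked); the ascending aorta
#'   moves by a few millimetres between frames in real cine acquisitions.
#' @param pressures [pressure_pair()] recorded during the exam.
#' @param seed integer seed for the stochastic intensity components.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_size = 256L, pixel_spacing = 1.17,
                           n_frames = 30L, semi_axes_dia = c(25, 22),
                           pulsation_fraction = 0.09, noise_sd = 0.03,
                           artifact_level = 0.3, neighbor_structures = TRUE,
                           motion_amplitude_mm = 1.5,
                           pressures = pressure_pair(120, 80), seed = 1L) {
  stop_if(grid_size < 64, "grid_size must be >= 64")
  stop_if(n_frames < 2, "n_frames must be >= 2")
  pf <- rep_len(as.numeric(pulsation_fraction), 2L)
  stop_if(any(pf < 0) || any(pf >= 0.5),
          "pulsation_fraction must be in [0, 0.5)")
  stop_if(length(semi_axes_dia) != 2L || any(semi_axes_dia <= 0),
          "semi_axes_dia must be two positive lengths in mm")
  stopifnot(inherits(pressures, "pressure_pair"))
  stop_if(motion_amplitude_mm < 0, "motion_amplitude_mm must be >= 0")
  peak_px <- (max(semi_axes_dia * (1 + pf)) + motion_amplitude_mm) /
    pixel_spacing
  stop_if(peak_px > grid_size / 2 - 4,
          "vessel exceeds the grid at peak dilation (%.1f px semi-axis vs %d px grid)",
          peak_px, grid_size)
  structure(list(grid_size = as.integer(grid_size),
                 pixel_spacing = pixel_spacing, n_frames = as.integer(n_frames),
                 semi_axes_dia = as.numeric(semi_axes_dia),
                 pulsation_fraction = pf, noise_sd = noise_sd,
                 artifact_level = artifact_level,
                 neighbor_structures = isTRUE(neighbor_structures),
                 motion_amplitude_mm = motion_amplitude_mm,
                 pressures = pressures, seed = as.integer(seed)),
            class = "phantom_config")
}

# Raised-cosine pulsation waveform in [0, 1]: fast systolic rise to a single
# peak, slower diastolic decay. The peak frame lands exactly on the grid so
# the extremal semi-axes (and hence strain) are attained exactly.
pulse_waveform <- function(n_frames, peak_frac = 0.3) {
  u <- (seq_len(n_frames) - 1) / n_frames
  tp <- round(peak_frac * n_frames) / n_frames
  if (tp <= 0) tp <- 1 / n_frames
  ifelse(u <= tp, 0.5 * (1 - cos(pi * u / tp)),
         0.5 * (1 + cos(pi * (u - tp) / (1 - tp))))
}

# Ramanujan's second approximation to the ellipse perimeter.
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Per-sector area and outer arc length of an axis-aligned ellipse, sectors
# bounded at rotation_deg + k*90 (counterclockwise from +x with +y up).
# Dense polygonal quadrature; error is negligible at this resolution.
ellipse_sector_truth <- function(a, b, rotation_deg, n_pts = 20000L) {
  th <- seq(0, 2 * pi, length.out = n_pts + 1L)[-(n_pts + 1L)]
  r <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  x <- r * cos(th); y <- r * sin(th)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  seg_len <- sqrt((xn - x)^2 + (yn - y)^2)
  tri_area <- 0.5 * abs(x * yn - xn * y)
  mid_th <- atan2((y + yn) / 2, (x + xn) / 2) * 180 / pi
  sector <- floor(((mid_th - rotation_deg) %% 360) / 90) + 1L
  list(area = vapply(1:4, function(k) sum(tri_area[sector == k]), 0),
       arc = vapply(1:4, function(k) sum(seg_len[sector == k]), 0))
}

#' Generate a synthetic pulsating-vessel phantom
#'
#' Renders a cine sequence of a bright quasi-elliptical lumen whose
#' semi-axes follow the raised-cosine cardiac waveform, together with the
#' exact rasterized ground-truth masks and an analytic truth record: the
#' per-frame areas (`pi*a*b`), outer perimeters (Ramanujan approximation),
#' per-quadrant sector areas/arcs, and the compliance and strain they imply.
#' Noise and artifacts only perturb intensities; masks and truth are
#' analytic and unaffected. Identical configurations (including seed) give
#' bit-identical outputs.
#'
#' @param config a [phantom_config()].
#' @param rotation_deg quadrant sector offset in degrees used for the
#'   per-quadrant truth (default 60).
#' @param exam_id identifier stored on the sequences.
#' @return `list(cine = cine_sequence, masks = mask_sequence,
#'   truth = phantom_truth)`.
#' @export
generate_phantom <- function(config = phantom_config(), rotation_deg = 60,
                             exam_id = "phantom") {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$grid_size; nt <- config$n_frames; sp <- config$pixel_spacing
  w <- pulse_waveform(nt)
  a_mm <- config$semi_axes_dia[1] * (1 + config$pulsation_fraction[1] * w)
  b_mm <- config$semi_axes_dia[2] * (1 + config$pulsation_fraction[2] * w)

  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)            # row index grid
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)

  # In-plane cardiac motion of the vessel center: systolic displacement
  # along the rows, a slower sweep along the columns. Deterministic and
  # waveform-locked; makes the sub-pixel rasterization phase vary between
  # frames as it does in real acquisitions.
  u <- (seq_len(nt) - 1) / nt
  amp_px <- config$motion_amplitude_mm / sp
  crs <- ctr + amp_px * w
  ccs <- ctr + 0.6 * amp_px * sin(2 * pi * u)

  cine <- array(0, c(nt, n, n))
  masks <- array(0L, c(nt, n, n))
  wall_mm <- 2.2                               # rendered wall thickness

  # Neighbor vessel: circle abutting the lumen on the -x (medial) side at
  # peak dilation, constant over the cycle.
  nb_r <- 12
  nb_cx <- -(max(a_mm) + nb_r + 1.5 + config$motion_amplitude_mm)
  dy0 <- (rows - ctr) * sp
  dx0 <- (cols - ctr) * sp
  nb <- if (config$neighbor_structures)
    ((dx0 - nb_cx)^2 + dy0^2) <= nb_r^2 else matrix(FALSE, n, n)

  intens <- with_seed(config$seed, {
    lapply(seq_len(nt), function(t) {
      dy <- (rows - crs[t]) * sp               # mm offsets from center
      dx <- (cols - ccs[t]) * sp
      e2 <- (dx / a_mm[t])^2 + (dy / b_mm[t])^2
      lumen <- e2 <= 1
      wall <- !lumen & ((dx / (a_mm[t] + wall_mm))^2 +
                          (dy / (b_mm[t] + wall_mm))^2 <= 1)
      img <- matrix(0.25, n, n)
      img[nb] <- 0.8
      img[wall] <- 0.45
      img[lumen] <- 0.9
      lv <- config$artifact_level
      if (lv > 0) {
        # intra-lumen signal dropout patches (turbulent-flow analog)
        n_patch <- stats::rpois(1, lv * 3)
        for (q in seq_len(n_patch)) {
          pr <- stats::runif(1, 0.15, 0.45) * min(a_mm[t], b_mm[t])
          px <- stats::runif(1, -0.6, 0.6) * a_mm[t]
          py <- stats::runif(1, -0.6, 0.6) * b_mm[t]
          patch <- lumen & ((dx - px)^2 + (dy - py)^2 <= pr^2)
          img[patch] <- img[patch] * stats::runif(1, 0.35, 0.6)
        }
        # ghosting: faint copy of the frame displaced along the phase axis
        shift <- max(4L, round(n / 8))
        ghost <- img * 0
        ghost[seq_len(n - shift) + shift, ] <- img[seq_len(n - shift), ]
        img <- img + lv * 0.12 * ghost
      }
      if (config$noise_sd > 0)
        img <- img + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
      list(img = img, mask = lumen)
    })
  })
  for (t in seq_len(nt)) {
    cine[t, , ] <- intens[[t]]$img
    masks[t, , ] <- intens[[t]]$mask * 1L
  }

  area <- pi * a_mm * b_mm
  perim <- ellipse_perimeter(a_mm, b_mm)
  qt <- lapply(seq_len(nt), function(t)
    ellipse_sector_truth(a_mm[t], b_mm[t], rotation_deg))
  q_area <- t(vapply(qt, `[[`, numeric(4), "area"))
  q_arc <- t(vapply(qt, `[[`, numeric(4), "arc"))
  colnames(q_area) <- colnames(q_arc) <- quadrant_labels(rotation_deg)

  pp <- config$pressures$systolic - config$pressures$diastolic
  truth <- structure(list(
    area_per_frame = area, perimeter_per_frame = perim,
    centroid_per_frame = cbind(row = crs, col = ccs),
    quadrant_areas = q_area, quadrant_arcs = q_arc,
    true_compliance = (max(area) - min(area)) / pp,
    true_strain = (max(perim) - min(perim)) / min(perim),
    true_local_compliance = (apply(q_area, 2, max) - apply(q_area, 2, min)) / pp,
    true_local_strain = (apply(q_arc, 2, max) - apply(q_arc, 2, min)) /
      apply(q_arc, 2, min),
    rotation_deg = rotation_deg, semi_axes_mm = cbind(a = a_mm, b = b_mm),
    pressures = config$pressures), class = "phantom_truth")

  ft <- seq(0, by = 1000 / nt, length.out = nt)  # ~1 s cycle
  list(cine = cine_sequence(cine, sp, frame_times = ft, exam_id = exam_id),
       masks = mask_sequence(masks, sp, exam_id = exam_id),
       truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(paste0("<phantom_truth: %d frames, compliance %.3f mm^2/mmHg, ",
                     "strain %.4f>\n"),
              length(x$area_per_frame), x$true_compliance, x$true_strain))
  invisible(x)
}

#' Write phantom truth curves to CSV
#' @param truth a `phantom_truth`; @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phantom_truth <- function(truth, path) {
  df <- data.frame(frame = seq_along(truth$area_per_frame),
                   area_mm2 = truth$area_per_frame,
                   perimeter_mm = truth$perimeter_per_frame)
  qa <- truth$quadrant_areas; colnames(qa) <- paste0("area_", colnames(qa))
  qp <- truth$quadrant_arcs; colnames(qp) <- paste0("arc_", colnames(qp))
  utils::write.csv(cbind(df, qa, qp), path, row.names = FALSE)
  invisible(path)
}

#' Write a phantom configuration as YAML
#' @param config a `phantom_config`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_phantom_config <- function(config, path) {
  lst <- unclass(config)
  lst$pressures <- list(systolic = config$pressures$systolic,
                        diastolic = config$pressures$diastolic)
  yaml::write_yaml(lst, path)
  invisible(path)
}

# ---- Tensile simulator -----------------------------------------------------

#' Tensile simulation configuration
#'
#' Describes a piecewise-linear stress-strain law used to simulate a
#' uniaxial record from a biaxial tensile test of a square aortic-wall
#' sample. Defaults emulate the test protocol of 15 mm x 15 mm samples with
#' an aorta-like bilinear response: a compliant elastin-dominated toe
#' region up to ~50% strain, then a stiffer collagen-recruited branch, so
#' that physiological wall stresses fall near the transition.
#'
#' @param modulus_segments data.frame with columns `strain_from`,
#'   `strain_to`, `E_MPa`: contiguous strain intervals starting at 0 and
#'   their tangent moduli (all positive).
#' @param strain_max maximum simulated strain (defaults to the last segment
#'   end; values beyond the last segment extend it).
#' @param n_samples number of displacement samples.
#' @param l0 rest length after preconditioning, mm (sample side).
#' @param thickness wall thickness, mm; the loaded section is
#'   `A0 = thickness * l0`.
#' @param noise_sd additive stress noise, MPa.
#' @param seed integer seed for the noise.
#' @param axis label of the stretching axis.
#' @return An object of class `tensile_sim_config`.
#' @export
tensile_sim_config <- function(modulus_segments = data.frame(
                                 strain_from = c(0, 0.5),
                                 strain_to = c(0.5, 0.8),
                                 E_MPa = c(0.35, 1.1)),
                               strain_max = NULL, n_samples = 400L,
                               l0 = 15, thickness = 2, noise_sd = 0,
                               seed = 1L, axis = "circumferential") {
  stop_if(is.null(modulus_segments) || nrow(modulus_segments) == 0,
          "modulus_segments must contain at least one segment")
  ms <- modulus_segments
  stop_if(abs(ms$strain_from[1]) > 1e-12, "segments must start at strain 0")
  if (nrow(ms) > 1)
    stop_if(any(abs(ms$strain_from[-1] - ms$strain_to[-nrow(ms)]) > 1e-12),
            "strain intervals must be contiguous")
  stop_if(any(ms$E_MPa <= 0), "all moduli must be positive")
  stop_if(l0 <= 0 || thickness <= 0, "l0 and thickness must be positive")
  strain_max <- strain_max %||% max(ms$strain_to)
  structure(list(modulus_segments = ms, strain_max = strain_max,
                 n_samples = as.integer(n_samples), l0 = l0,
                 thickness = thickness, noise_sd = noise_sd,
                 seed = as.integer(seed), axis = axis),
            class = "tensile_sim_config")
}

#' Simulate a tensile force-displacement record
#'
#' Evaluates the configured piecewise-linear stress-strain law on a uniform
#' strain grid and inverts the engineering stress/strain definitions to
#' machine coordinates: displacement `= strain * l0` and force
#' `= stress * A0` with `A0 = thickness * l0`. Gaussian stress noise is
#' added with the configured seed.
#'
#' @param config a [tensile_sim_config()].
#' @return A [tensile_record()].
#' @export
generate_tensile <- function(config = tensile_sim_config()) {
  stopifnot(inherits(config, "tensile_sim_config"))
  eps <- seq(0, config$strain_max, length.out = config$n_samples)
  sig <- piecewise_stress(eps, config$modulus_segments)
  if (config$noise_sd > 0)
    sig <- sig + with_seed(config$seed,
                           stats::rnorm(length(sig), 0, config$noise_sd))
  a0 <- config$thickness * config$l0
  tensile_record(displacement = eps * config$l0, force = sig * a0,
                 l0 = config$l0, thickness = config$thickness,
                 axis = config$axis)
}

# Continuous piecewise-linear stress from tangent-modulus segments.
piecewise_stress <- function(eps, segments) {
  knots <- c(segments$strain_from[1], segments$strain_to)
  sig_knots <- cumsum(c(0, segments$E_MPa * diff(knots)))
  out <- numeric(length(eps))
  last <- nrow(segments)
  for (i in seq_along(eps)) {
    e <- eps[i]
    k <- findInterval(e, knots, rightmost.closed = TRUE)
    k <- min(max(k, 1L), last)
    out[i] <- sig_knots[k] + segments$E_MPa[k] * (e - knots[k])
  }
  out
}
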