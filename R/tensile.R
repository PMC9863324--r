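#' Tensile force-displacement record
#'
#' One axis of a biaxial tensile test: machine displacement and load
#' samples, with the rest length after preconditioning and the specimen
#' thickness needed to convert to engineering stress and strain.
#'
#' @param displacement non-decreasing displacement samples, mm (deformed
#'   length minus `l0`, i.e. `l - l0`).
#' @param force load samples, N, same length as `displacement`.
#' @param l0 rest specimen length after preconditioning, mm.
#' @param thickness load-free specimen thickness, mm.
#' @param axis label of the stretching axis.
#' @return An object of class `tensile_record`.
#' @export
tensile_record <- function(displacement, force, l0, thickness,
                           axis = "circumferential") {
  stop_if(length(displacement) != length(force),
          "displacement and force must have equal length")
  stop_if(any(diff(displacement) < 0), "displacement must be non-decreasing")
  stop_if(l0 <= 0 || thickness <= 0, "l0 and thickness must be positive")
  structure(list(displacement = as.numeric(displacement),
                 force = as.numeric(force), l0 = l0, thickness = thickness,
                 axis = as.character(axis)),
            class = "tensile_record")
}

#' @export
print.tensile_record <- function(x, ...) {
  cat(sprintf("<tensile_record '%s': %d samples, l0 %.3g mm, t %.3g mm>\n",
              x$axis, length(x$force), x$l0, x$thickness))
  invisible(x)
}

#' Engineering strain
#'
#' `(l - l0) / l0`: relative elongation of the specimen with respect to its
#' rest length after preconditioning.
#'
#' @param l deformed length, mm; @param l0 rest length, mm (> 0).
#' @return Dimensionless strain.
#' @export
engineering_strain <- function(l, l0) {
  stop_if(any(l0 <= 0), "l0 must be positive")
  (l - l0) / l0
}

#' Engineering stress
#'
#' `F / A0` with the load-free cross-section `A0`; N/mm^2 is MPa.
#'
#' @param force load, N; @param a0 load-free cross-sectional area, mm^2 (> 0).
#' @return Stress in MPa.
#' @export
engineering_stress <- function(force, a0) {
  stop_if(any(a0 <= 0), "A0 must be positive")
  force / a0
}

#' Convert a tensile record to an engineering stress-strain curve
#'
#' Strain is `displacement / l0` and stress `force / A0` with
#' `A0 = thickness * l0`. Samples sharing a strain value (machine dwell)
#' are collapsed by averaging their stress so strain is strictly
#' increasing.
#'
#' @param record a [tensile_record()].
#' @return An object of class `stress_strain_curve` with fields `strain`,
#'   `stress` (MPa), `a0` (mm^2).
#' @export
stress_strain_curve <- function(record) {
  stopifnot(inherits(record, "tensile_record"))
  a0 <- record$thickness * record$l0
  eps <- engineering_strain(record$displacement + record$l0, record$l0)
  sig <- engineering_stress(record$force, a0)
  agg <- tapply(sig, eps, mean)
  eps_u <- as.numeric(names(agg))
  stop_if(length(eps_u) < 2, "record has no strain variation")
  o <- order(eps_u)
  structure(list(strain = eps_u[o], stress = as.numeric(agg)[o], a0 = a0),
            class = "stress_strain_curve")
}

#' Tangent-modulus curve of a stress-strain record
#'
#' The Young's modulus at each strain level is the first derivative of
#' stress with respect to strain, estimated by central finite differences
#' after moving-average smoothing of the stress samples (derivatives
#' amplify measurement noise). The literal stress/strain ratio (secant
#' modulus) is available via `method = "secant"`.
#'
#' @param curve a [stress_strain_curve()].
#' @param smoothing_window odd moving-average window length in samples
#'   (1 = no smoothing).
#' @param method `"tangent"` (derivative, default) or `"secant"`
#'   (`stress / strain`).
#' @return An object of class `modulus_result` with `strain`, `stress`,
#'   `modulus` (MPa per unit strain), `E_max` and the `method` used.
#' @export
modulus_curve <- function(curve, smoothing_window = 11L,
                          method = c("tangent", "secant")) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  method <- match.arg(method)
  n <- length(curve$strain)
  stop_if(n < 3, "need at least 3 samples for a modulus curve")
  sig <- moving_average(curve$stress, smoothing_window)
  eps <- curve$strain
  if (method == "tangent") {
    E <- numeric(n)
    E[1] <- (sig[2] - sig[1]) / (eps[2] - eps[1])
    E[n] <- (sig[n] - sig[n - 1]) / (eps[n] - eps[n - 1])
    mid <- 2:(n - 1)
    E[mid] <- (sig[mid + 1] - sig[mid - 1]) / (eps[mid + 1] - eps[mid - 1])
  } else {
    E <- ifelse(eps > 0, sig / eps, NA_real_)
    E[1] <- E[which(eps > 0)[1]]
  }
  structure(list(strain = eps, stress = sig, modulus = E,
                 E_max = max(E, na.rm = TRUE), method = method),
            class = "modulus_result")
}

moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1) return(x)
  if (window %% 2 == 0) window <- window + 1L
  h <- window %/% 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' @export
print.modulus_result <- function(x, ...) {
  cat(sprintf("<modulus_result (%s): E_max %.4g MPa over %d samples>\n",
              x$method, x$E_max, length(x$modulus)))
  invisible(x)
}

#' Maximum Young's modulus
#'
#' The maximum of the modulus curve: for the default tangent method, the
#' steepest local slope of the stress-strain curve (attained on the
#' stiffest, collagen-recruited branch of aortic tissue).
#'
#' @param result a [modulus_curve()] result.
#' @return `E_max` in MPa.
#' @export
max_youngs_modulus <- function(result) {
  stopifnot(inherits(result, "modulus_result"))
  result$E_max
}

#' Physiological Young's modulus
#'
#' Mean tangent modulus over the samples whose stress lies in the wall
#' stress window spanned by the patient's diastolic and systolic blood
#' pressures. The pressure-to-wall-stress mapping uses the thin-wall
#' (Laplace) hoop stress `sigma = P * r / t` with the supplied lumen radius
#' and wall thickness; pressures are converted at
#' 1 mmHg = 1.33322e-4 MPa.
#'
#' @param result a [modulus_curve()] result.
#' @param pressures a [pressure_pair()].
#' @param radius lumen radius, mm.
#' @param wall_thickness aortic wall thickness, mm.
#' @return List with `E_phys` (MPa) and the stress window
#'   `c(sigma_low, sigma_high)` in MPa.
#' @export
physiological_youngs_modulus <- function(result, pressures, radius,
                                         wall_thickness) {
  stopifnot(inherits(result, "modulus_result"),
            inherits(pressures, "pressure_pair"))
  stop_if(radius <= 0 || wall_thickness <= 0, "geometry must be positive")
  window <- mmhg_to_mpa(c(pressures$diastolic, pressures$systolic)) *
    radius / wall_thickness
  sel <- result$stress >= window[1] & result$stress <= window[2]
  stop_if(!any(sel),
          paste0("no stress samples inside the physiological window ",
                 "[%.4g, %.4g] MPa; curve spans [%.4g, %.4g] MPa - extend ",
                 "the record or check the geometry"),
          window[1], window[2], min(result$stress), max(result$stress))
  list(E_phys = mean(result$modulus[sel], na.rm = TRUE), window = window)
}

#' Convert mmHg to MPa
#' @param p pressure in mmHg.
#' @return Pressure in MPa (1 mmHg = 1.33322e-4 MPa).
#' @export
mmhg_to_mpa <- function(p) p * 1.33322e-4

#' Trim preconditioning cycles from a raw record
#'
#' Tensile protocols precede the measurement ramp with repeated
#' low-amplitude preconditioning cycles. This helper keeps only the final
#' monotone loading ramp: it finds the last sample where the force returns
#' to (near) zero and discards everything before it.
#'
#' @param record a [tensile_record()] that may include preconditioning.
#' @param zero_tol force threshold counting as "returned to zero", N.
#' @return A trimmed [tensile_record()] whose displacement is re-zeroed.
#' @export
trim_preconditioning <- function(record, zero_tol = 0.02) {
  stopifnot(inherits(record, "tensile_record"))
  near0 <- which(record$force <= zero_tol)
  start <- if (length(near0)) max(near0) else 1L
  idx <- start:length(record$force)
  tensile_record(record$displacement[idx] - record$displacement[start],
                 record$force[idx], record$l0, record$thickness, record$axis)
}

# ---- I/O -------------------------------------------------------------------

#' Write a tensile record as CSV with YAML metadata
#' @param record a [tensile_record()]; @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_tensile_record <- function(record, path) {
  utils::write.csv(data.frame(displacement_mm = record$displacement,
                              force_N = record$force),
                   path, row.names = FALSE)
  yaml::write_yaml(list(l0_mm = record$l0, thickness_mm = record$thickness,
                        axis = record$axis), paste0(path, ".yaml"))
  invisible(path)
}

#' Read a tensile record written by [write_tensile_record()]
#' @param path CSV path with a `<path>.yaml` metadata sidecar.
#' @return A [tensile_record()].
#' @export
read_tensile_record <- function(path) {
  df <- utils::read.csv(path)
  stop_if(!all(c("displacement_mm", "force_N") %in% names(df)),
          "expected columns displacement_mm, force_N in %s", path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  tensile_record(df$displacement_mm, df$force_N, meta$l0_mm,
                 meta$thickness_mm, meta$axis %||% "unknown")
}
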