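#' Cine sequence container
#'
#' A cine sequence is a time-ordered stack of 2D intensity frames acquired
#' at a fixed slice position across the cardiac cycle, together with the
#' physical pixel spacing and frame acquisition times.
#'
#' @param frames numeric array of dimension `T x H x W` (frame, row, column).
#' @param pixel_spacing length-2 numeric, (row, column) spacing in mm/pixel.
#'   A single value is recycled to both axes.
#' @param frame_times numeric vector of length `T`, acquisition time of each
#'   frame in ms. Defaults to uniform spacing starting at 0.
#' @param exam_id character identifier of the exam the sequence belongs to.
#' @return An object of class `cine_sequence`.
#' @export
cine_sequence <- function(frames, pixel_spacing, frame_times = NULL,
                          exam_id = "exam") {
  if (length(dim(frames)) == 2L) frames <- array(frames, c(1L, dim(frames)))
  stop_if(length(dim(frames)) != 3L, "frames must be a T x H x W array")
  stop_if(!all(is.finite(frames)), "frames contain non-finite intensities")
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  stop_if(any(pixel_spacing <= 0), "pixel_spacing must be positive")
  nt <- dim(frames)[1]
  if (is.null(frame_times)) frame_times <- seq(0, by = 33, length.out = nt)
  stop_if(length(frame_times) != nt, "frame_times length must equal frame count")
  structure(list(frames = frames, pixel_spacing = pixel_spacing,
                 frame_times = as.numeric(frame_times),
                 exam_id = as.character(exam_id)),
            class = "cine_sequence")
}

#' Binary mask sequence aligned with a cine sequence
#'
#' @param frames array of dimension `T x H x W` with values in \{0, 1\}.
#' @inheritParams cine_sequence
#' @return An object of class `mask_sequence`.
#' @export
mask_sequence <- function(frames, pixel_spacing, exam_id = "exam") {
  if (length(dim(frames)) == 2L) frames <- array(frames, c(1L, dim(frames)))
  stop_if(length(dim(frames)) != 3L, "frames must be a T x H x W array")
  stop_if(!all(frames %in% c(0, 1)), "mask values must be 0 or 1")
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  stop_if(any(pixel_spacing <= 0), "pixel_spacing must be positive")
  structure(list(frames = frames, pixel_spacing = pixel_spacing,
                 exam_id = as.character(exam_id)),
            class = "mask_sequence")
}

#' @export
print.cine_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_sequence '%s': %d frames of %dx%d, %.3gx%.3g mm/px>\n",
              x$exam_id, d[1], d[2], d[3],
              x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}

#' @export
print.mask_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<mask_sequence '%s': %d frames of %dx%d>\n",
              x$exam_id, d[1], d[2], d[3]))
  invisible(x)
}

#' Systolic/diastolic pressure pair
#'
#' Blood pressures recorded during the exam, used as the pulse-pressure
#' denominator of the compliance computation.
#'
#' @param systolic,diastolic pressures in mmHg; `systolic > diastolic > 0`.
#' @return An object of class `pressure_pair`.
#' @export
pressure_pair <- function(systolic, diastolic) {
  stop_if(!is_scalar_num(systolic) || !is_scalar_num(diastolic),
          "pressures must be single numbers")
  stop_if(!(systolic > diastolic && diastolic > 0),
          "require systolic > diastolic > 0 (got %s/%s)", systolic, diastolic)
  structure(list(systolic = systolic, diastolic = diastolic),
            class = "pressure_pair")
}

# ---- I/O -------------------------------------------------------------------

#' Write a cine or mask sequence to disk
#'
#' The frame stack is stored as one 3D NIfTI volume with axes T, H, W and the
#' pixel spacing in the header (`pixdim` entries 2 and 3 carry the row/column
#' spacing in mm; entry 1 carries the frame interval in ms). A YAML sidecar
#' `<path>.yaml` duplicates the metadata, including pressures when supplied.
#'
#' @param x a `cine_sequence` or `mask_sequence`.
#' @param path output path; `.nii.gz` appended when no NIfTI extension given.
#' @param pressures optional [pressure_pair()] stored in the sidecar.
#' @param png_dir optional directory: additionally export every frame as an
#'   8-bit grayscale PNG (requires the `png` package).
#' @return The NIfTI path, invisibly.
#' @export
write_sequence <- function(x, path, pressures = NULL, png_dir = NULL) {
  stopifnot(inherits(x, "cine_sequence") || inherits(x, "mask_sequence"))
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  dt <- if (!is.null(x$frame_times) && length(x$frame_times) > 1)
    diff(x$frame_times)[1] else 33
  img <- RNifti::asNifti(x$frames)
  RNifti::pixdim(img) <- c(dt, x$pixel_spacing[1], x$pixel_spacing[2])
  RNifti::writeNifti(img, path)
  meta <- list(exam_id = x$exam_id,
               pixel_spacing_mm = as.numeric(x$pixel_spacing),
               frame_times_ms = as.numeric(x$frame_times %||% numeric()))
  if (!is.null(pressures)) {
    meta$systolic_mmHg <- pressures$systolic
    meta$diastolic_mmHg <- pressures$diastolic
  }
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  if (!is.null(png_dir)) {
    stop_if(!requireNamespace("png", quietly = TRUE),
            "the 'png' package is required for png_dir export")
    dir.create(png_dir, recursive = TRUE, showWarnings = FALSE)
    rng <- range(x$frames)
    for (t in seq_len(dim(x$frames)[1])) {
      fr <- x$frames[t, , ]
      if (diff(rng) > 0) fr <- (fr - rng[1]) / diff(rng)
      png::writePNG(fr, file.path(png_dir, sprintf("frame_%03d.png", t)))
    }
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a cine sequence from disk
#'
#' Accepts either a 3D NIfTI volume written by [write_sequence()] (axes
#' T, H, W) or a directory of ordered per-frame 2D NIfTI/PNG files. Pixel
#' spacing is taken from the NIfTI header or the YAML sidecar; an error is
#' raised, rather than a guessed value used, when neither provides it.
#'
#' @param path NIfTI file or frame directory.
#' @param as_mask logical: construct a [mask_sequence()] (values checked
#'   binary) instead of a [cine_sequence()].
#' @return A `cine_sequence` (or `mask_sequence`).
#' @export
load_sequence <- function(path, as_mask = FALSE) {
  meta <- NULL
  side <- paste0(path, ".yaml")
  if (file.exists(side)) meta <- yaml::read_yaml(side)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(nii(\\.gz)?|png)$",
                             full.names = TRUE))
    stop_if(length(files) == 0, "no frame files found in %s", path)
    frames_list <- lapply(files, function(f) {
      if (grepl("\\.png$", f)) {
        stop_if(!requireNamespace("png", quietly = TRUE),
                "the 'png' package is required to read PNG frames")
        m <- png::readPNG(f)
        if (length(dim(m)) == 3L) m <- m[, , 1]
        m
      } else as.matrix(RNifti::readNifti(f)[, ])
    })
    shp <- vapply(frames_list, function(m) paste(dim(m), collapse = "x"), "")
    bad <- which(shp != shp[1])
    stop_if(length(bad) > 0, "frame '%s' has shape %s, expected %s",
            basename(files[bad[1]]), shp[bad[1]], shp[1])
    side2 <- file.path(path, "sequence.yaml")
    if (is.null(meta) && file.exists(side2)) meta <- yaml::read_yaml(side2)
    stop_if(is.null(meta$pixel_spacing_mm),
            "pixel spacing not found for %s: provide a YAML sidecar", path)
    frames <- aperm(simplify2array(frames_list), c(3, 1, 2))
    spacing <- meta$pixel_spacing_mm
  } else {
    stop_if(!file.exists(path), "no such file: %s", path)
    img <- RNifti::readNifti(path)
    stop_if(length(dim(img)) != 3L, "expected a 3D NIfTI volume in %s", path)
    frames <- array(as.numeric(img), dim(img))
    pd <- RNifti::pixdim(img)
    spacing <- meta$pixel_spacing_mm %||%
      if (all(pd[2:3] > 0)) pd[2:3] else NULL
    stop_if(is.null(spacing),
            "pixel spacing absent from header and sidecar of %s", path)
  }
  exam_id <- meta$exam_id %||% sub("\\.nii(\\.gz)?$", "", basename(path))
  times <- meta$frame_times_ms
  if (!is.null(times) && length(times) != dim(frames)[1]) times <- NULL
  if (as_mask) {
    mask_sequence(round(frames), spacing, exam_id = exam_id)
  } else {
    cine_sequence(frames, spacing, frame_times = times, exam_id = exam_id)
  }
}

#' Read pressures from a sequence sidecar
#' @param path path given to [write_sequence()].
#' @return A [pressure_pair()] or `NULL` when absent.
#' @export
load_pressures <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) return(NULL)
  meta <- yaml::read_yaml(side)
  if (is.null(meta$systolic_mmHg)) return(NULL)
  pressure_pair(meta$systolic_mmHg, meta$diastolic_mmHg)
}

# ---- Preprocessing ---------------------------------------------------------

#' Min-max intensity normalization
#'
#' Rescales a frame to `[0, 1]` by `(x - min) / (max - min)`. A constant
#' frame maps to all zeros (the range contract is kept without dividing
#' by zero).
#'
#' @param frame 2D numeric matrix with finite values.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(frame) {
  stop_if(!all(is.finite(frame)), "frame contains non-finite values")
  r <- range(frame)
  if (r[1] == r[2]) return(array(0, dim(frame)))
  (frame - r[1]) / (r[2] - r[1])
}

#' Percentile-based histogram stretching
#'
#' Linearly maps the `[P_low, P_high]` intensity percentiles to `[0, 1]`,
#' clipping values outside the window. Enhances contrast in low-contrast
#' frames while staying robust to bright flow-artifact outliers. When the
#' two percentiles coincide the function falls back to [minmax_normalize()].
#'
#' @param frame 2D numeric matrix.
#' @param low_pct,high_pct percentile bounds in `[0, 100]`, `low < high`.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
histogram_stretch <- function(frame, low_pct = 1, high_pct = 99) {
  stop_if(!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100),
          "require 0 <= low_pct < high_pct <= 100")
  q <- stats::quantile(frame, c(low_pct, high_pct) / 100, names = FALSE,
                       type = 7)
  if (q[1] == q[2]) return(minmax_normalize(frame))
  pmin(pmax((frame - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Center crop or zero-pad a frame to a square target size
#'
#' Dimensions larger than `target` are center-cropped; smaller ones are
#' zero-padded symmetrically. Odd size differences place the extra pixel on
#' the trailing (bottom/right) side, so the image center is preserved.
#'
#' @param frame 2D matrix.
#' @param target side length in pixels of the output.
#' @return A `target x target` matrix.
#' @export
center_crop_pad <- function(frame, target = 256L) {
  stop_if(target < 1, "target must be >= 1")
  fit_axis <- function(n) {
    if (n >= target) {
      lead <- (n - target) %/% 2L
      list(src = (lead + 1L):(lead + target), dst = 1:target)
    } else {
      lead <- (target - n) %/% 2L
      list(src = 1:n, dst = (lead + 1L):(lead + n))
    }
  }
  ri <- fit_axis(nrow(frame)); ci <- fit_axis(ncol(frame))
  out <- matrix(0, target, target)
  out[ri$dst, ci$dst] <- frame[ri$src, ci$src]
  out
}

#' Random geometric augmentation of a frame/mask pair
#'
#' Draws a random rotation, horizontal/vertical flips, and an affine
#' scale/translation, and applies the identical transform to both the
#' intensity frame (bilinear interpolation) and the mask (nearest neighbor,
#' so binarity is preserved). All ranges default to the values used for
#' training; setting every range to zero and disabling flips yields the
#' identity.
#'
#' @param frame 2D numeric matrix.
#' @param mask 2D binary matrix of the same shape.
#' @param params list with elements `rotation_deg` (max |angle|, default 15),
#'   `flip_h`, `flip_v` (logical, each applied with probability 0.5 when
#'   enabled), `scale_range` (default `c(0.9, 1.1)`), `translate_frac`
#'   (max |shift| as a fraction of the image size, default 0.05).
#' @param seed integer seed for the random draws (optional).
#' @return `list(frame = , mask = )` with the transformed pair.
#' @export
augment_pair <- function(frame, mask, params = list(), seed = NULL) {
  stop_if(!identical(dim(frame), dim(mask)), "frame and mask shapes differ")
  p <- utils::modifyList(list(rotation_deg = 15, flip_h = TRUE, flip_v = TRUE,
                              scale_range = c(0.9, 1.1),
                              translate_frac = 0.05), params)
  draw <- with_seed(seed, {
    list(theta = stats::runif(1, -p$rotation_deg, p$rotation_deg) * pi / 180,
         fh = isTRUE(p$flip_h) && stats::runif(1) < 0.5,
         fv = isTRUE(p$flip_v) && stats::runif(1) < 0.5,
         s = stats::runif(1, p$scale_range[1], p$scale_range[2]),
         tr = stats::runif(1, -p$translate_frac, p$translate_frac) * nrow(frame),
         tc = stats::runif(1, -p$translate_frac, p$translate_frac) * ncol(frame))
  })
  # Forward map: p' = M (p - ctr) + ctr + t with M = R(theta) S(s) F.
  # Output pixels are filled by the inverse map with interpolation.
  M <- matrix(c(cos(draw$theta), sin(draw$theta),
                -sin(draw$theta), cos(draw$theta)), 2, 2) * draw$s
  M <- M %*% diag(c(if (draw$fv) -1 else 1, if (draw$fh) -1 else 1))
  Minv <- solve(M)
  ctr <- (dim(frame) + 1) / 2
  H <- nrow(frame); W <- ncol(frame)
  rr <- rep(seq_len(H), times = W) - ctr[1] - draw$tr
  cc <- rep(seq_len(W), each = H) - ctr[2] - draw$tc
  sr <- Minv[1, 1] * rr + Minv[1, 2] * cc + ctr[1]
  sc <- Minv[2, 1] * rr + Minv[2, 2] * cc + ctr[2]
  list(frame = matrix(bilinear_sample(frame, sr, sc), H, W),
       mask = matrix(nearest_sample(mask, sr, sc), H, W))
}

# Bilinear interpolation at fractional (row, col) positions; outside -> 0.
bilinear_sample <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- numeric(length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
}

nearest_sample <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  ri <- round(r); ci <- round(c)
  ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  v <- numeric(length(ri))
  v[ok] <- img[cbind(ri[ok], ci[ok])]
  v
}

#' Standard preprocessing applied to every frame before segmentation
#'
#' Histogram stretching followed by min-max normalization and center
#' crop/padding to the model's input size. Operates frame-by-frame; the
#' frame count and spacing metadata are never altered.
#'
#' @param x a `cine_sequence`.
#' @param target model input side length in pixels.
#' @param stretch logical, apply [histogram_stretch()] first.
#' @param low_pct,high_pct stretch percentiles.
#' @return A preprocessed `cine_sequence` with `target x target` frames.
#' @export
preprocess_sequence <- function(x, target = 256L, stretch = TRUE,
                                low_pct = 1, high_pct = 99) {
  stopifnot(inherits(x, "cine_sequence"))
  nt <- dim(x$frames)[1]
  out <- array(0, c(nt, target, target))
  for (t in seq_len(nt)) {
    fr <- x$frames[t, , ]
    if (stretch) fr <- histogram_stretch(fr, low_pct, high_pct)
    out[t, , ] <- center_crop_pad(minmax_normalize(fr), target)
  }
  cine_sequence(out, x$pixel_spacing, frame_times = x$frame_times,
                exam_id = x$exam_id)
}

#' Center crop/pad a mask sequence to match preprocessed frames
#' @param m a `mask_sequence`; @param target side length in pixels.
#' @return A `mask_sequence` with `target x target` frames.
#' @export
preprocess_masks <- function(m, target = 256L) {
  stopifnot(inherits(m, "mask_sequence"))
  nt <- dim(m$frames)[1]
  out <- array(0, c(nt, target, target))
  for (t in seq_len(nt)) out[t, , ] <- center_crop_pad(m$frames[t, , ], target)
  mask_sequence(out, m$pixel_spacing, exam_id = m$exam_id)
}
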