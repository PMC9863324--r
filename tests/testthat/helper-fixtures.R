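# Shared fixtures, built in code.

# Rasterized disk/ellipse mask: pixel centers inside the analytic boundary.
raster_ellipse <- function(n, a_px, b_px = a_px, center = (n + 1) / 2) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  matrix(as.integer(((rows - center[1]) / b_px)^2 +
                      ((cols - center[length(center)]) / a_px)^2 <= 1), n, n)
}

# Random blob-free binary mask with given density (seeded by caller).
random_mask <- function(n, p = 0.3) {
  matrix(rbinom(n * n, 1, p), n, n)
}

# Small training exam: a pulsating bright ellipse with noise, built
# directly so it works at any network input size (the full phantom
# generator enforces a 64 px minimum grid).
small_exam <- function(input = 64L, n_frames = 3L, seed = 1L) {
  set.seed(seed)
  a0 <- input / 4 + runif(1, -2, 2)
  cr <- input / 2 + runif(1, -3, 3)
  cc <- input / 2 + runif(1, -3, 3)
  cine <- array(0, c(n_frames, input, input))
  masks <- array(0L, c(n_frames, input, input))
  for (t in seq_len(n_frames)) {
    s <- 1 + 0.08 * (t - 1) / max(1, n_frames - 1)
    m <- raster_ellipse(input, a0 * s, 0.9 * a0 * s, center = c(cr, cc))
    masks[t, , ] <- m
    cine[t, , ] <- 0.25 + 0.65 * m + matrix(rnorm(input^2, 0, 0.05),
                                            input, input)
  }
  list(cine = cine_sequence(cine, 1.17, exam_id = sprintf("small%03d", seed)),
       masks = mask_sequence(masks, 1.17,
                             exam_id = sprintf("small%03d", seed)))
}

# Brute-force directed/symmetric Hausdorff over all boundary pixel pairs,
# used as the independent oracle for hausdorff_mm.
brute_hausdorff <- function(a, b, spacing) {
  spacing <- rep_len(spacing, 2L)
  bound <- function(m) {
    px <- which(m > 0, arr.ind = TRUE)
    keep <- apply(px, 1, function(q) {
      nb <- rbind(q + c(1, 0), q - c(1, 0), q + c(0, 1), q - c(0, 1))
      any(nb[, 1] < 1 | nb[, 1] > nrow(m) | nb[, 2] < 1 | nb[, 2] > ncol(m) |
            m[pmin(pmax(nb[, 1], 1), nrow(m)) +
                (pmin(pmax(nb[, 2], 1), ncol(m)) - 1) * nrow(m)] == 0)
    })
    px[keep, , drop = FALSE]
  }
  pa <- bound(a); pb <- bound(b)
  pa <- sweep(pa, 2, spacing, `*`); pb <- sweep(pb, 2, spacing, `*`)
  d2 <- outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2
  sqrt(max(min(apply(d2, 1, min), Inf),
           max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}
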