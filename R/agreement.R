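#' Correlation between predicted and reference measurements
#'
#' Sample Pearson correlation (Spearman optionally) with the two-sided
#' p-value from the t transform with n - 2 degrees of freedom, as used to
#' compare automatically computed areas and compliances against expert
#' ground truth.
#'
#' @param x,y numeric vectors of equal length (n >= 3), nonzero variance.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p_value`, `n`, `method`.
#' @export
correlation_stats <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stop_if(length(x) != length(y), "x and y must have equal length")
  stop_if(length(x) < 3, "need at least 3 pairs")
  stop_if(stats::sd(x) == 0 || stats::sd(y) == 0,
          "correlation is undefined for a zero-variance series")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = method)
}

#' Bland-Altman agreement statistics
#'
#' Mean and standard deviation (sample, n - 1 denominator) of the paired
#' differences `x - y`, with the data for the conventional plot: the
#' pairwise means against the differences and the +/- 1.96 SD limits of
#' agreement. The sign convention is predicted minus ground truth, so a
#' positive mean difference reads as an overestimation by the method.
#'
#' @param x predicted values; @param y reference values (equal length >= 2).
#' @return List with `mean_diff`, `sd_diff`, `n`, `limits` (c(lower,
#'   upper)), and `plot_data` (data.frame `mean`, `difference`).
#' @export
bland_altman <- function(x, y) {
  stop_if(length(x) != length(y), "x and y must have equal length")
  stop_if(length(x) < 2, "need at least 2 pairs")
  d <- x - y
  md <- mean(d); sdd <- stats::sd(d)
  list(mean_diff = md, sd_diff = sdd, n = length(d),
       limits = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd),
       plot_data = data.frame(mean = (x + y) / 2, difference = d))
}

#' Per-quadrant cohort summary
#'
#' Mean and standard deviation (n - 1) of a per-subject, per-quadrant
#' metric, with rows in the fixed reporting order medial, anterior,
#' lateral, posterior.
#'
#' @param values a subjects x 4 numeric matrix or data.frame whose columns
#'   are named with the four quadrant labels (any order); every subject
#'   must have all four values.
#' @return data.frame with columns `quadrant`, `mean`, `sd`.
#' @export
quadrant_summary <- function(values) {
  order_out <- c("medial", "anterior", "lateral", "posterior")
  values <- as.matrix(values)
  stop_if(is.null(colnames(values)) ||
            !setequal(colnames(values), order_out),
          "columns must be named with the four quadrant labels")
  stop_if(anyNA(values), "every subject needs all four quadrant values")
  values <- values[, order_out, drop = FALSE]
  data.frame(quadrant = order_out,
             mean = apply(values, 2, mean),
             sd = apply(values, 2, stats::sd),
             row.names = NULL)
}

#' Agreement table between predicted and reference series
#'
#' Convenience wrapper producing one row per metric with the correlation,
#' p-value and Bland-Altman mean difference +/- SD, mirroring the layout
#' used to compare predicted and ground-truth minimum/maximum areas and
#' compliance.
#'
#' @param predicted,reference data.frames with identical column names; one
#'   row per subject.
#' @param method correlation method, see [correlation_stats()].
#' @return data.frame with columns `metric`, `r`, `p_value`, `mean_diff`,
#'   `sd_diff`, `n`.
#' @export
agreement_table <- function(predicted, reference,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stop_if(!identical(sort(names(predicted)), sort(names(reference))),
          "predicted and reference must share column names")
  do.call(rbind, lapply(names(predicted), function(m) {
    cs <- correlation_stats(predicted[[m]], reference[[m]], method)
    ba <- bland_altman(predicted[[m]], reference[[m]])
    data.frame(metric = m, r = cs$r, p_value = cs$p_value,
               mean_diff = ba$mean_diff, sd_diff = ba$sd_diff, n = cs$n)
  }))
}
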