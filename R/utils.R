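#' @useDynLib aortaflex, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif quantile sd cor.test pt
#' @importFrom grDevices contourLines
#' @importFrom utils head read.csv write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. NULL seed = use current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
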