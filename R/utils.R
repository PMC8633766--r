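#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rexp rnorm rpois runif rbeta sd cor ks.test qt
#' @importFrom utils head read.csv write.csv
NULL

# clamp to [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-seed derivation; keeps results below .Machine$integer.max
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 97L + as.numeric(k) * 7919) %% 2147483647
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# euclidean distance between point and matrix of points
euclid <- function(x, y, xs, ys) sqrt((xs - x)^2 + (ys - y)^2)
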