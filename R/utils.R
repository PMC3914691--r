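# shared helpers

#' Round half away from zero
#'
#' Commercial rounding used for printed percentages: 0.5 always rounds away
#' from zero (base `round()` rounds half to even).
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return rounded numeric vector
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a root seed and a label
#'
#' Each simulated lineage draws from its own stream; the child seed is a
#' deterministic hash of the root seed and the lineage name, kept below 2^31.
#'
#' @param seed integer root seed
#' @param label character scalar (e.g. lineage name)
#' @return integer seed
#' @export
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- as.double(seed %% 2147483647)
  for (k in codes) h <- (h * 131 + k) %% 2147483629
  as.integer(h %% 2147483647L)
}

stop_user <- function(...) stop(..., call. = FALSE)

# interval containment: midpoint in [start, end) (0-based half-open)
.mid_in <- function(mid, start, end) mid >= start & mid < end
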