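#' @keywords internal
#' @useDynLib holterscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Per-patient sub-seed: deterministic counter scheme keeping values < 2^31.
sub_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1000003 + i) %% 2147483629)
}

#' Round half away from zero
#'
#' Commercial rounding used for all reported percentages: halves round away
#' from zero (so 79.165 -> 79.17), unlike [round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by one ulp so values stored as ..4999999 due to binary representation
  # still round up, without disturbing genuine below-half cases
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}
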