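#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a temporary RNG state so that seeded helpers do not
## disturb the caller's random stream.  `seed = NULL` leaves the stream alone.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Round half away from zero
#'
#' Display rounding used for the reported metrics: ties round up in absolute
#' value (0.69565 -> 0.6957 at 4 decimals), unlike [round()]'s banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  ## nudge by one ulp so values that are exactly .xxxx5 in decimal but stored
  ## a hair below in binary still round up
  trunc(x * p + sign(x) * (0.5 + 1e-9)) / p
}

## shared key for unordered pairs (lexicographic canonical form)
pair_key <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  paste(lo, hi, sep = "\r")
}

stop_if_not <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
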