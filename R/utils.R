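#' @importFrom rlang %||% abort warn inform .data
#' @importFrom stats pt var sd cor dist hclust cutree as.dist rnorm runif
#'   rlnorm qnorm pnorm dhyper r2dtable chisq.test p.adjust smooth.spline
#'   predict uniroot rbinom quantile setNames
#' @importFrom utils head read.delim
NULL

# Named substreams derived from one master seed so partial re-runs of a
# pipeline stage reproduce exactly. Kept below 2^31 (R integers are 32-bit).
substream_seed <- function(master_seed, name) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  codes <- utf8ToInt(name)
  h <- (sum(as.numeric(codes) * seq_along(codes)) * 2654435) %% 1000003
  as.integer((abs(master_seed) + h) %% .Machine$integer.max)
}

# Stochastic rounding: floor(x) + 1 with probability frac(x). Expectation x.
stochastic_round <- function(x) {
  lo <- floor(x)
  as.integer(lo + (runif(length(x)) < (x - lo)))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

outcome_levels <- c("lethal", "indolent", "excluded")
gleason_levels <- c("G4_6", "G7", "G8_10", "unknown")
erg_levels <- c("rearranged", "negative", "unknown")
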