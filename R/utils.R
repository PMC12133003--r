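# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Report-style rounding: exact halves round up (0.0005 -> 0.001), unlike
#' base R's round-half-even. Used wherever summary tables are printed to a
#' fixed number of decimals.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.46875, 2) # 0.47
round_half_up <- function(x, digits = 3) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-12) / scale
}

# Deterministic per-stage seed fan-out: one user seed, independent streams
# per pipeline stage. Stays below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Modal value of an integer vector ignoring NA; returns c(mode, count, n_obs).
modal_count <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(c(NA_integer_, 0L, 0L))
  tab <- tabulate(x + 1L, nbins = 3L)
  m <- which.max(tab) - 1L
  c(m, tab[m + 1L], length(x))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
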