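#' Landis-Koch interpretation band of an agreement coefficient
#'
#' Maps a coefficient to the conventional verbal agreement categories.
#' The printed bands (0.81-1.00 almost perfect, 0.61-0.80 substantial,
#' 0.41-0.60 moderate, 0.21-0.40 fair, < 0.20 slight/poor) leave gaps
#' between 0.20/0.21 etc.; they are implemented as contiguous half-open
#' intervals: `<= 0.20` slight_poor, `(0.20, 0.40]` fair, `(0.40, 0.60]`
#' moderate, `(0.60, 0.80]` substantial, `> 0.80` almost_perfect. The
#' function is total on the reals: coefficients above 1 (a CI bound, say)
#' map to almost_perfect and negative ones to slight_poor.
#'
#' @param coefficient Numeric vector of agreement coefficients.
#' @return Character vector of band labels.
#' @examples
#' interpret_band(c(0.94, 0.62, 0.47, 0.15, -0.2))
#' @export
interpret_band <- function(coefficient) {
  stopifnot(is.numeric(coefficient))
  labs <- c("slight_poor", "fair", "moderate", "substantial", "almost_perfect")
  out <- labs[findInterval(coefficient, c(0.20, 0.40, 0.60, 0.80),
                           left.open = TRUE) + 1L]
  out[is.na(coefficient)] <- NA_character_
  out
}
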