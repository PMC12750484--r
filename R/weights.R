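#' Agreement weight matrices for ordinal categories
#'
#' Builds the q x q weight matrix used by the weighted agreement
#' coefficients. With `d = |k - l|` the distance between category ranks:
#' \describe{
#'   \item{identity}{`w = 1` on the diagonal, 0 off it (unweighted; turns
#'     AC2 into AC1).}
#'   \item{linear}{`w = 1 - d / (q - 1)`.}
#'   \item{quadratic}{`w = 1 - d^2 / (q - 1)^2`.}
#'   \item{ordinal}{`w = 1 - d (d + 1) / (q (q - 1))`, i.e. one minus the
#'     ratio of category pairs spanned; the default for ordinal clinical
#'     scales.}
#' }
#'
#' @param kind Weight family.
#' @param q Number of categories (>= 2).
#' @return Object of class `"agreement_weights"`: list with `q`, `kind` and
#'   the matrix `w` (symmetric, unit diagonal, entries in `[0, 1]`).
#' @examples
#' make_weights("ordinal", 4)$w
#' @export
make_weights <- function(kind = c("ordinal", "identity", "linear", "quadratic"), q) {
  kind <- match.arg(kind)
  q <- as.integer(q)
  if (length(q) != 1L || is.na(q) || q < 2L)
    stop("agreement weights need q >= 2 categories", call. = FALSE)
  d <- abs(outer(seq_len(q), seq_len(q), "-"))
  w <- switch(kind,
    identity  = (d == 0) + 0,
    linear    = 1 - d / (q - 1),
    quadratic = 1 - d^2 / (q - 1)^2,
    ordinal   = 1 - d * (d + 1) / (q * (q - 1)))
  structure(list(q = q, kind = kind, w = w), class = "agreement_weights")
}

#' @export
print.agreement_weights <- function(x, ...) {
  cat(sprintf("<agreement_weights> %s, q = %d\n", x$kind, x$q))
  print(round(x$w, 4))
  invisible(x)
}

as_agreement_weights <- function(weights, q) {
  if (inherits(weights, "agreement_weights")) {
    if (weights$q != q)
      stop(sprintf("weight matrix is for q = %d categories but data has q = %d",
                   weights$q, q), call. = FALSE)
    return(weights)
  }
  if (is.character(weights) && length(weights) == 1L) return(make_weights(weights, q))
  if (is.matrix(weights)) {
    if (!all(dim(weights) == c(q, q)))
      stop("custom weight matrix must be q x q", call. = FALSE)
    return(structure(list(q = q, kind = "custom", w = weights),
                     class = "agreement_weights"))
  }
  stop("'weights' must be a family name, an agreement_weights object or a q x q matrix",
       call. = FALSE)
}
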