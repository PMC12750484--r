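#' Pairwise agreement between all rater pairs
#'
#' Computes [gwet_agreement()] restricted to each unordered pair of raters,
#' on the subjects the pair co-rated. With four raters this yields the six
#' pairwise coefficients (student vs each expert, and the expert pairs).
#'
#' @param ratings Subjects x raters matrix of category values (`NA` for
#'   missing ratings); column names identify the raters.
#' @param weights Weight family name, [make_weights()] object, or matrix.
#' @param categories Full category set (see [subject_category_counts()]).
#' @param conflev Confidence level, default 0.95.
#' @return Data frame with one row per unordered rater pair: `rater_a`,
#'   `rater_b`, the [as.data.frame.agreement_estimate()] columns, and
#'   `absent`/`reason` flags for pairs with no co-rated subjects (their
#'   estimate columns are `NA`, never zero).
#' @export
pairwise_agreement <- function(ratings, weights = "ordinal", categories,
                               conflev = 0.95) {
  ratings <- as.matrix(ratings)
  R <- ncol(ratings)
  if (R < 2L) stop("pairwise agreement needs at least two raters", call. = FALSE)
  if (is.null(colnames(ratings))) colnames(ratings) <- paste0("R", seq_len(R))
  pairs <- utils::combn(R, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    sub <- ratings[, c(a, b), drop = FALSE]
    co <- rowSums(!is.na(sub)) == 2L
    base <- data.frame(rater_a = colnames(ratings)[a],
                       rater_b = colnames(ratings)[b],
                       stringsAsFactors = FALSE)
    if (!any(co)) {
      est <- data.frame(method = NA_character_, weights_kind = NA_character_,
                        coefficient = NA_real_, p_a = NA_real_, p_e = NA_real_,
                        se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        n_subjects = 0L, band = NA_character_,
                        stringsAsFactors = FALSE)
      cbind(base, est, absent = TRUE,
            reason = "no co-rated subjects", stringsAsFactors = FALSE)
    } else {
      est <- as.data.frame(gwet_agreement(sub[co, , drop = FALSE],
                                          weights = weights,
                                          categories = categories,
                                          conflev = conflev))
      cbind(base, est, absent = FALSE, reason = NA_character_,
            stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape a composite table to a subjects x raters matrix for one feature
#'
#' @param composites Output of [compose_all()].
#' @param feature_id Feature to extract.
#' @param subjects Optional subject subset (and ordering); default all
#'   subjects, sorted.
#' @return Subjects x raters integer matrix of composite scores, `NA` where
#'   a rater did not score a subject.
#' @export
ratings_matrix <- function(composites, feature_id, subjects = NULL) {
  sub <- composites[composites$feature_id == feature_id, , drop = FALSE]
  if (!nrow(sub)) stop("no composites for feature ", feature_id, call. = FALSE)
  if (is.null(subjects)) subjects <- sort(unique(sub$subject_id))
  raters <- sort(unique(sub$rater_id))
  m <- matrix(NA_integer_, length(subjects), length(raters),
              dimnames = list(subjects, raters))
  si <- match(sub$subject_id, subjects)
  ri <- match(sub$rater_id, raters)
  keep <- !is.na(si) & !is.na(ri)
  m[cbind(si[keep], ri[keep])] <- sub$composite[keep]
  m
}
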