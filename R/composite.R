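#' Threshold-based composite score from per-lobe ratings
#'
#' Aggregates one feature's per-lobe ordinal scores (0 to `per_lobe_max`)
#' into a single per-recording composite, reflecting both the severity and
#' the extent of the finding across lobes. The composite is 0 when every
#' lobe is rated 0. Otherwise, for every severity level `v` reached by at
#' least one lobe, the level contributes `v + 1` if more than
#' `majority_fraction` of the scored lobes reach at least `v` (with five
#' lobes and the default 50 percent cutoff: three or more lobes), and `v`
#' otherwise; the composite is the maximum contribution over levels.
#'
#' For a 0-2 per-lobe scale this reproduces the enumerated clinical rules:
#' composite 1 = some lobe rated 1 but fewer than three lobes; 2 = three or
#' more lobes rated >= 1, or a minority of lobes rated 2; 3 = three or more
#' lobes rated 2. Counting lobes rated *at least* `v` (rather than exactly
#' `v`) makes the rule total and monotone on mixed vectors and generalizes
#' to any ordinal scale.
#'
#' @param scores Integer vector of per-lobe scores (one per scored lobe).
#' @param per_lobe_max Integer >= 1; the feature's per-lobe scale maximum.
#' @param majority_fraction Fraction of lobes that must reach a level for
#'   the majority bonus; strict inequality, default 0.5.
#' @return Integer composite in `0:(per_lobe_max + 1)`.
#' @examples
#' composite_threshold(c(0, 0, 0, 0, 0), 2)  # 0
#' composite_threshold(c(1, 1, 1, 0, 0), 2)  # 2: majority at level 1
#' composite_threshold(c(2, 2, 2, 0, 0), 2)  # 3: majority at level 2
#' composite_threshold(c(2, 1, 1, 1, 1), 2)  # 2
#' @seealso [composite_maximum()], [compose_all()]
#' @export
composite_threshold <- function(scores, per_lobe_max, majority_fraction = 0.5) {
  check_lobe_scores(scores, per_lobe_max)
  n_lobes <- length(scores)
  best <- 0L
  for (v in seq_len(per_lobe_max)) {
    n_ge <- sum(scores >= v)
    if (n_ge >= 1L) {
      cand <- if (n_ge > majority_fraction * n_lobes) v + 1L else v
      if (cand > best) best <- cand
    }
  }
  as.integer(best)
}

#' Maximum-across-lobes composite score
#'
#' Aggregation rule for secretion color (Murray sputum chart, 0 watery to
#' 8 purulent): the composite is the highest per-lobe score.
#'
#' @inheritParams composite_threshold
#' @return Integer composite in `0:per_lobe_max`.
#' @examples
#' composite_maximum(c(3, 0, 5, 2, 0), 8)  # 5
#' @export
composite_maximum <- function(scores, per_lobe_max) {
  check_lobe_scores(scores, per_lobe_max)
  as.integer(max(scores))
}

check_lobe_scores <- function(scores, per_lobe_max) {
  if (length(scores) == 0L) stop("no lobes: at least one per-lobe score is required",
                                 call. = FALSE)
  if (anyNA(scores) || any(scores != as.integer(scores)))
    stop("per-lobe scores must be integers", call. = FALSE)
  if (any(scores < 0L) || any(scores > per_lobe_max))
    stop(sprintf("per-lobe scores must lie in [0, %d]", per_lobe_max), call. = FALSE)
  invisible(TRUE)
}

# Vectorized threshold composite over a groups x lobes matrix; NA lobes are
# ignored (the majority cutoff is taken over observed lobes per row).
composite_threshold_matrix <- function(mat, per_lobe_max, majority_fraction = 0.5) {
  n_lobes <- rowSums(!is.na(mat))
  best <- integer(nrow(mat))
  for (v in seq_len(per_lobe_max)) {
    n_ge <- rowSums(mat >= v, na.rm = TRUE)
    cand <- ifelse(n_ge >= 1L, ifelse(n_ge > majority_fraction * n_lobes, v + 1L, v), 0L)
    best <- pmax(best, cand)
  }
  as.integer(best)
}

composite_maximum_matrix <- function(mat, per_lobe_max) {
  out <- suppressWarnings(apply(mat, 1L, max, na.rm = TRUE))
  as.integer(out)
}

#' Compute all composite scores of a rating study
#'
#' Applies each feature's aggregation rule to every (subject, rater) cell of
#' a long-format ratings table, producing one composite score per
#' (subject, rater, feature).
#'
#' @param ratings Long-format data frame with columns `subject_id`, `group`,
#'   `rater_id`, `feature_id`, `lobe`, `score` (the ratings CSV dialect; see
#'   [read_ratings()]).
#' @param registry A `"feature_registry"`; default [default_feature_registry()].
#' @param lobes Lobe codes expected per (subject, rater, feature); default
#'   the five canonical lobes.
#' @param missing_lobes `"strict"` (default) errors if any expected lobe is
#'   unscored; `"lenient"` computes the composite over the observed lobes,
#'   rescaling the majority cutoff to the observed lobe count.
#' @param majority_fraction Passed to [composite_threshold()].
#' @return Data frame with columns `subject_id`, `group`, `rater_id`,
#'   `feature_id`, `composite`, one row per (subject, rater, feature),
#'   ordered by feature, subject, rater.
#' @examples
#' reg <- default_feature_registry()
#' r <- simulate_ratings(simulation_config(n_subjects = 4, seed = 1))
#' head(compose_all(r, reg))
#' @export
compose_all <- function(ratings, registry = default_feature_registry(),
                        lobes = canonical_lobes(),
                        missing_lobes = c("strict", "lenient"),
                        majority_fraction = 0.5) {
  missing_lobes <- match.arg(missing_lobes)
  registry <- as_feature_registry(registry)
  validate_ratings(ratings, registry, lobes = lobes)

  out <- lapply(unique(as.character(ratings$feature_id)), function(fid) {
    fdef <- registry[[fid]]
    sub <- ratings[ratings$feature_id == fid, , drop = FALSE]
    cell <- paste(sub$subject_id, sub$rater_id, sep = "\r")
    cells <- unique(cell)
    ci <- match(cell, cells)
    li <- match(as.character(sub$lobe), lobes)
    mat <- matrix(NA_integer_, nrow = length(cells), ncol = length(lobes))
    mat[cbind(ci, li)] <- sub$score
    if (missing_lobes == "strict" && anyNA(mat)) {
      bad <- which(rowSums(is.na(mat)) > 0L)
      parts <- strsplit(cells[bad], "\r", fixed = TRUE)
      stop(sprintf(
        "incomplete lobe set for feature '%s' in: %s", fid,
        paste(vapply(parts, function(p)
          sprintf("(subject %s, rater %s)", p[1], p[2]), ""), collapse = ", ")),
        call. = FALSE)
    }
    comp <- switch(fdef$aggregation,
      threshold = composite_threshold_matrix(mat, fdef$per_lobe_max, majority_fraction),
      maximum   = composite_maximum_matrix(mat, fdef$per_lobe_max))
    # unique() preserves first-appearance order, so rows of `sub` at the first
    # occurrence of each cell line up with `cells`
    first <- sub[!duplicated(ci), , drop = FALSE]
    data.frame(subject_id = cells_part(cells, 1L),
               group = as.character(first$group),
               rater_id = cells_part(cells, 2L),
               feature_id = fid,
               composite = comp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$feature_id, out$subject_id, out$rater_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

cells_part <- function(cells, i) {
  vapply(strsplit(cells, "\r", fixed = TRUE), `[[`, "", i)
}

# Shared structural validation of a long ratings table against a registry.
validate_ratings <- function(ratings, registry, lobes = canonical_lobes()) {
  need <- c("subject_id", "group", "rater_id", "feature_id", "lobe", "score")
  miss <- setdiff(need, names(ratings))
  if (length(miss))
    stop("ratings table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  unknown_f <- setdiff(unique(as.character(ratings$feature_id)), names(registry))
  if (length(unknown_f))
    stop("unknown feature_id(s): ", paste(unknown_f, collapse = ", "), call. = FALSE)
  bad_lobe <- !(as.character(ratings$lobe) %in% lobes)
  if (any(bad_lobe))
    stop("unknown lobe code(s) at row(s) ",
         paste(utils::head(which(bad_lobe), 5L), collapse = ", "),
         ": expected one of ", paste(lobes, collapse = "/"), call. = FALSE)
  if (anyNA(ratings$score) || any(ratings$score != as.integer(ratings$score)))
    stop("scores must be integers", call. = FALSE)
  lmax <- vapply(registry, `[[`, 0L, "per_lobe_max")[as.character(ratings$feature_id)]
  bad <- which(ratings$score < 0L | ratings$score > lmax)
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf(
      "score out of range at row %d: subject %s, feature %s, lobe %s has score %d (allowed 0-%d)",
      b, ratings$subject_id[b], ratings$feature_id[b], ratings$lobe[b],
      ratings$score[b], lmax[b]), call. = FALSE)
  }
  key <- paste(ratings$subject_id, ratings$rater_id, ratings$feature_id, ratings$lobe)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("duplicate rating at row %d: subject %s, rater %s, feature %s, lobe %s",
                 d, ratings$subject_id[d], ratings$rater_id[d],
                 ratings$feature_id[d], ratings$lobe[d]), call. = FALSE)
  }
  grp <- tapply(as.character(ratings$group), ratings$subject_id,
                function(g) length(unique(g)))
  if (any(grp > 1L))
    stop("group label is not constant within subject(s): ",
         paste(names(grp)[grp > 1L], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
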