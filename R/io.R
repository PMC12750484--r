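#' Read a long-format ratings CSV
#'
#' The dialect is a UTF-8 comma-separated file with header
#' `subject_id,group,rater_id,feature_id,lobe,score`: one row per
#' (subject, rater, feature, lobe) with an integer score. Extra columns are
#' preserved on read but ignored by the analysis. The table is validated
#' against the registry: known features, canonical lobe codes, integer
#' scores within each feature's 0..`per_lobe_max` range, no duplicate keys,
#' and a constant group label per subject; violations are reported with the
#' offending row.
#'
#' @param path CSV path.
#' @param registry Feature registry used for validation; default
#'   [default_feature_registry()].
#' @return Validated ratings data frame.
#' @seealso [write_ratings()], [compose_all()]
#' @export
read_ratings <- function(path, registry = default_feature_registry()) {
  if (!file.exists(path)) stop("ratings file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("subject_id", "group", "rater_id", "feature_id", "lobe", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sc <- suppressWarnings(as.integer(tab$score))
  bad <- which(is.na(sc) | sc != suppressWarnings(as.numeric(tab$score)))
  if (length(bad))
    stop(sprintf("%s: non-integer score '%s' at data row %d",
                 path, tab$score[bad[1]], bad[1]), call. = FALSE)
  tab$score <- sc
  validate_ratings(tab, as_feature_registry(registry))
  tab
}

#' Write a ratings table in the canonical CSV dialect
#'
#' Row order is preserved; output is UTF-8, comma-separated, unquoted, with
#' the canonical six-column header first (extra columns follow). Reading a
#' canonical file and writing it back is byte-identical.
#'
#' @param ratings Ratings data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ratings <- function(ratings, path) {
  need <- c("subject_id", "group", "rater_id", "feature_id", "lobe", "score")
  ratings <- ratings[, c(need, setdiff(names(ratings), need)), drop = FALSE]
  utils::write.csv(ratings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a composite-score table as CSV
#'
#' Columns: `subject_id,group,rater_id,feature_id,composite`.
#'
#' @param composites Output of [compose_all()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_composites <- function(composites, path) {
  utils::write.csv(composites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' Recognized fields mirror [study_config()]: `weights_kind`,
#' `unit_of_analysis`, `strata`, `conflev`, `majority_fraction`, and
#' `reference_values` (path to a CSV with `feature_id,reference`, resolved
#' relative to the YAML file).
#'
#' @param path YAML path.
#' @return A `"study_config"`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  ref <- NULL
  if (!is.null(y$reference_values)) {
    rp <- y$reference_values
    if (!file.exists(rp)) rp <- file.path(dirname(path), y$reference_values)
    ref <- utils::read.csv(rp, stringsAsFactors = FALSE)
  }
  study_config(
    weights_kind = y$weights_kind %||% "ordinal",
    unit_of_analysis = y$unit_of_analysis %||% "composite",
    strata = if (is.null(y$strata)) c("CF", "nonCF") else unlist(y$strata),
    reference_values = ref,
    conflev = y$conflev %||% 0.95,
    majority_fraction = y$majority_fraction %||% 0.5)
}

#' Literature reference coefficients for the original pediatric score
#'
#' Loads the packaged table of weighted-kappa agreement coefficients
#' reported for the six overlapping features of the original pediatric
#' bronchoscopy score (literature values, not recomputed by this package),
#' for use as `reference_values` in [study_config()].
#'
#' @return Data frame `feature_id`, `reference`.
#' @export
thomas_reference_values <- function() {
  utils::read.csv(system.file("extdata", "thomas_reference_kappa.csv",
                              package = "bronchoscore"),
                  stringsAsFactors = FALSE)
}
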