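#' Configuration of a reliability study analysis
#'
#' @param weights_kind Weight family for AC2 (default `"ordinal"`; see
#'   [make_weights()]).
#' @param unit_of_analysis `"composite"` (default: one composite score per
#'   recording is the rated unit) or `"per_lobe"` (every subject-lobe pair
#'   is a unit, on the per-lobe 0..L scale).
#' @param strata Group labels to analyze separately (default CF / non-CF);
#'   `NULL` disables stratification.
#' @param reference_values Optional data frame `feature_id`, `reference`
#'   with external literature coefficients to place next to this study's
#'   (e.g. the weighted kappas of the original pediatric score); adds a
#'   comparison section to the report.
#' @param conflev Confidence level for all intervals, default 0.95.
#' @param majority_fraction Majority cutoff for the threshold composite,
#'   default 0.5.
#' @return Object of class `"study_config"`.
#' @export
study_config <- function(weights_kind = "ordinal",
                         unit_of_analysis = c("composite", "per_lobe"),
                         strata = c("CF", "nonCF"),
                         reference_values = NULL,
                         conflev = 0.95,
                         majority_fraction = 0.5) {
  unit_of_analysis <- match.arg(unit_of_analysis)
  if (!is.null(reference_values))
    stopifnot(all(c("feature_id", "reference") %in% names(reference_values)))
  structure(list(weights_kind = weights_kind,
                 unit_of_analysis = unit_of_analysis,
                 strata = strata,
                 reference_values = reference_values,
                 conflev = conflev,
                 majority_fraction = majority_fraction),
            class = "study_config")
}

#' Run the full inter-rater reliability analysis of a rating study
#'
#' End-to-end orchestration: per-lobe ratings are aggregated to composite
#' scores (unless analyzing per lobe), then for every feature the weighted
#' Gwet AC2 coefficient with CI and Landis-Koch band is computed overall,
#' within each stratum (CF / non-CF), and for every rater pair; optionally
#' a comparison table against external reference coefficients is added.
#'
#' @param ratings Long-format ratings table ([read_ratings()] /
#'   [simulate_ratings()] dialect).
#' @param registry Feature registry; default [default_feature_registry()].
#' @param config A [study_config()].
#' @return Object of class `"study_report"`: list with data frames
#'   `overall`, `by_stratum`, `pairwise`, optionally `comparison`, plus
#'   `meta` (unit, weights, subject counts per stratum). Interpretation
#'   bands are always derived from the coefficients at build time, never
#'   stored independently.
#' @examples
#' r <- simulate_ratings(simulation_config(n_subjects = 12, seed = 7))
#' rep <- analyze_study(r, config = study_config(strata = NULL))
#' rep$overall[, c("feature_id", "coefficient", "band")]
#' @export
analyze_study <- function(ratings, registry = default_feature_registry(),
                          config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  registry <- as_feature_registry(registry)
  validate_ratings(ratings, registry)
  if (length(unique(ratings$rater_id)) < 2L)
    stop("the analysis needs at least two raters", call. = FALSE)

  feature_ids <- names(registry)[names(registry) %in% unique(as.character(ratings$feature_id))]
  present <- vapply(feature_ids, function(fid) {
    length(unique(ratings$rater_id[ratings$feature_id == fid]))
  }, 0L)
  if (any(present < length(unique(ratings$rater_id))))
    stop("feature(s) missing for some raters: ",
         paste(feature_ids[present < length(unique(ratings$rater_id))],
               collapse = ", "), call. = FALSE)

  if (config$unit_of_analysis == "composite") {
    units <- compose_all(ratings, registry,
                         majority_fraction = config$majority_fraction)
    unit_col <- "composite"
    cat_range <- function(fdef) composite_range(fdef)
    unit_id <- units$subject_id
  } else {
    units <- ratings
    names(units)[names(units) == "score"] <- "composite"
    unit_col <- "composite"
    cat_range <- function(fdef) 0:fdef$per_lobe_max
    unit_id <- paste(units$subject_id, units$lobe, sep = ":")
    units$subject_id <- unit_id
  }

  subj_group <- tapply(as.character(units$group), units$subject_id,
                       function(g) g[1])

  estimate_one <- function(fid, subjects = NULL) {
    fdef <- registry[[fid]]
    m <- ratings_matrix(units, fid, subjects = subjects)
    gwet_agreement(m, weights = config$weights_kind,
                   categories = cat_range(fdef), conflev = config$conflev)
  }

  overall <- do.call(rbind, lapply(feature_ids, function(fid)
    cbind(feature_id = fid, as.data.frame(estimate_one(fid)),
          stringsAsFactors = FALSE)))

  by_stratum <- NULL
  strata_n <- NULL
  if (!is.null(config$strata)) {
    missing_strata <- setdiff(config$strata, unique(as.character(units$group)))
    if (length(missing_strata))
      stop("stratum label(s) not present in the ratings: ",
           paste(missing_strata, collapse = ", "), call. = FALSE)
    rows <- list()
    strata_n <- integer(0)
    for (s in config$strata) {
      subjects <- sort(names(subj_group)[subj_group == s])
      strata_n[s] <- length(subjects)
      for (fid in feature_ids) {
        if (length(subjects) < 2L) {
          est <- data.frame(method = NA_character_, weights_kind = NA_character_,
                            coefficient = NA_real_, p_a = NA_real_, p_e = NA_real_,
                            se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                            n_subjects = length(subjects), band = NA_character_,
                            stringsAsFactors = FALSE)
          rows[[length(rows) + 1L]] <-
            cbind(stratum = s, feature_id = fid, est, absent = TRUE,
                  reason = "fewer than two subjects in stratum",
                  stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <-
            cbind(stratum = s, feature_id = fid,
                  as.data.frame(estimate_one(fid, subjects = subjects)),
                  absent = FALSE, reason = NA_character_,
                  stringsAsFactors = FALSE)
        }
      }
    }
    by_stratum <- do.call(rbind, rows)
    rownames(by_stratum) <- NULL
  }

  pairwise <- do.call(rbind, lapply(feature_ids, function(fid) {
    fdef <- registry[[fid]]
    m <- ratings_matrix(units, fid)
    cbind(feature_id = fid,
          pairwise_agreement(m, weights = config$weights_kind,
                             categories = cat_range(fdef),
                             conflev = config$conflev),
          stringsAsFactors = FALSE)
  }))
  rownames(pairwise) <- NULL

  comparison <- NULL
  if (!is.null(config$reference_values)) {
    ref <- config$reference_values
    idx <- match(overall$feature_id, ref$feature_id)
    comparison <- data.frame(
      feature_id = overall$feature_id,
      reference = ref$reference[idx],
      reference_band = interpret_band(ref$reference[idx]),
      this_study = overall$coefficient,
      this_study_band = interpret_band(overall$coefficient),
      stringsAsFactors = FALSE)
  }

  structure(list(
    overall = overall, by_stratum = by_stratum, pairwise = pairwise,
    comparison = comparison,
    meta = list(unit_of_analysis = config$unit_of_analysis,
                weights_kind = config$weights_kind,
                conflev = config$conflev,
                n_subjects = length(unique(unit_id)),
                n_raters = length(unique(ratings$rater_id)),
                strata_n = strata_n)),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d features, %d raters, %d units (%s), weights = %s\n",
              nrow(x$overall), x$meta$n_raters, x$meta$n_subjects,
              x$meta$unit_of_analysis, x$meta$weights_kind))
  print(x$overall[, c("feature_id", "coefficient", "ci_low", "ci_high", "band")],
        digits = 3)
  invisible(x)
}

#' Write a study report to CSV, JSON and a text forest plot
#'
#' Emits `overall.csv`, `by_stratum.csv`, `pairwise.csv` (each section only
#' when non-empty), `comparison.csv` when reference values were supplied,
#' the whole report as `report.json`, and `forest.txt`, a text forest plot
#' of the overall coefficients with their CIs around the 0.6 reference line
#' separating moderate from substantial agreement. File content is a
#' deterministic function of the report.
#'
#' @param report A `"study_report"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wr <- function(df, name) {
    if (is.null(df) || !nrow(df)) return()
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    written <<- c(written, p)
  }
  wr(report$overall, "overall.csv")
  wr(report$by_stratum, "by_stratum.csv")
  wr(report$pairwise, "pairwise.csv")
  wr(report$comparison, "comparison.csv")

  jp <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(meta = report$meta, overall = report$overall,
         by_stratum = report$by_stratum, pairwise = report$pairwise,
         comparison = report$comparison),
    jp, dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null",
    pretty = TRUE)
  written <- c(written, jp)

  fp <- file.path(dir, "forest.txt")
  writeLines(forest_text(report$overall, report$meta$conflev), fp)
  written <- c(written, fp)
  invisible(written)
}

# ASCII forest plot of coefficients and CIs on [min(0, lo), max(1, hi)],
# with a '|' reference line at 0.6.
forest_text <- function(overall, conflev = 0.95, width = 60L) {
  lo <- min(0, overall$ci_low, na.rm = TRUE)
  hi <- max(1, overall$ci_high, na.rm = TRUE)
  pos <- function(x) 1L + as.integer(round((x - lo) / (hi - lo) * (width - 1L)))
  ref <- pos(0.6)
  hdr <- sprintf("%-18s %8s  [%d%% CI]            %s", "feature", "coef",
                 round(100 * conflev), "0.6 reference line marked '|'")
  lines <- vapply(seq_len(nrow(overall)), function(i) {
    row <- rep(" ", width)
    row[ref] <- "|"
    a <- pos(overall$ci_low[i]); b <- pos(overall$ci_high[i])
    row[seq(max(1L, a), min(width, b))] <- "-"
    row[pos(overall$coefficient[i])] <- "*"
    sprintf("%-18s %8.3f (%.3f, %.3f) %s", overall$feature_id[i],
            overall$coefficient[i], overall$ci_low[i], overall$ci_high[i],
            paste(row, collapse = ""))
  }, "")
  c(hdr, lines)
}
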