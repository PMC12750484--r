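#' Define a scored bronchoscopic feature
#'
#' A feature definition fixes the per-lobe ordinal scale (0 to `per_lobe_max`)
#' and the rule used to aggregate the five lobe scores into a per-recording
#' composite: `"threshold"` applies the majority-cutoff algorithm (see
#' [composite_threshold()]), `"maximum"` takes the highest lobe score (used
#' for secretion color on the 0-8 Murray sputum chart).
#'
#' @param feature_id Short identifier, e.g. `"mucosal_edema"`.
#' @param display_name Human-readable name.
#' @param per_lobe_max Integer >= 1; maximum per-lobe ordinal score.
#' @param aggregation `"threshold"` or `"maximum"`.
#' @param level_labels Optional character vector of `per_lobe_max + 1` ordered
#'   level labels (score 0 first).
#' @return An object of class `"feature_definition"`.
#' @seealso [default_feature_registry()], [composite_range()]
#' @export
feature_definition <- function(feature_id, display_name, per_lobe_max,
                               aggregation = c("threshold", "maximum"),
                               level_labels = NULL) {
  aggregation <- match.arg(aggregation)
  if (!is.character(feature_id) || length(feature_id) != 1L || !nzchar(feature_id))
    stop("'feature_id' must be a single non-empty string", call. = FALSE)
  per_lobe_max <- as.integer(per_lobe_max)
  if (length(per_lobe_max) != 1L || is.na(per_lobe_max) || per_lobe_max < 1L)
    stop("'per_lobe_max' must be a single integer >= 1", call. = FALSE)
  if (!is.null(level_labels)) {
    if (length(level_labels) != per_lobe_max + 1L)
      stop(sprintf("feature '%s': 'level_labels' must have %d entries (one per level 0..%d)",
                   feature_id, per_lobe_max + 1L, per_lobe_max), call. = FALSE)
    level_labels <- as.character(level_labels)
  }
  structure(
    list(feature_id = feature_id, display_name = display_name,
         per_lobe_max = per_lobe_max, aggregation = aggregation,
         level_labels = level_labels),
    class = "feature_definition")
}

#' @export
print.feature_definition <- function(x, ...) {
  cat(sprintf("<feature> %s (%s): per-lobe scale 0-%d, aggregation = %s\n",
              x$feature_id, x$display_name, x$per_lobe_max, x$aggregation))
  invisible(x)
}

#' The canonical five bronchial lobes
#'
#' Right upper, right middle, right lower, left upper and left lower lobe;
#' each feature is scored once per lobe.
#' @return Character vector of the five lobe codes.
#' @export
canonical_lobes <- function() c("RUL", "RML", "RLL", "LUL", "LLL")

#' The ten-feature bronchoscopy scoring registry
#'
#' The modified scoring tool assesses ten visual features per lobe: six from
#' the earlier pediatric bronchitis score (secretion amount and color,
#' mucosal edema, ridging, erythema, pallor) and four additions targeting
#' cystic fibrosis airway pathology (secretion viscosity, bleeding, vascular
#' drawing, mucus plugging). All features use the threshold composite rule
#' except secretion color, which takes the maximum across lobes.
#'
#' Mucus plugging is rated binary per lobe (0 absent / 1 present). By default
#' its composite follows the general threshold rule at scale maximum 1,
#' giving composite values 0 (no plugging), 1 (present in a minority of
#' lobes) and 2 (present in three or more lobes). With
#' `mucus_plugging_binary = TRUE` the composite stays binary: 1 if any lobe
#' is plugged (an any-lobe OR, i.e. the maximum rule at scale 1).
#'
#' @param mucus_plugging_binary Keep the mucus-plugging composite binary
#'   (default `FALSE`: use the graded threshold composite).
#' @return A named list of [feature_definition()] objects, class
#'   `"feature_registry"`.
#' @examples
#' reg <- default_feature_registry()
#' names(reg)
#' reg$secretion_color
#' @export
default_feature_registry <- function(mucus_plugging_binary = FALSE) {
  severity3 <- c("normal", "mild", "moderate-severe")
  defs <- list(
    feature_definition("secretion_color", "Secretion color (Murray chart)", 8L, "maximum"),
    feature_definition("secretion_amount", "Secretion amount", 3L, "threshold",
                       c("no secretion", "< 1/3 of lumen", "1/3-2/3 of lumen",
                         "filling > 2/3 of the lumen")),
    feature_definition("mucosal_edema", "Mucosal edema", 2L, "threshold", severity3),
    feature_definition("mucosal_ridging", "Mucosal ridging", 2L, "threshold", severity3),
    feature_definition("erythema", "Erythema", 2L, "threshold", severity3),
    feature_definition("mucosal_pallor", "Mucosal pallor", 2L, "threshold", severity3),
    feature_definition("viscosity", "Viscosity of secretion", 2L, "threshold",
                       c("normal (watery)", "loose (moves with suction)",
                         "viscous (thick, tenacious mucus)")),
    feature_definition("bleeding", "Bleeding", 2L, "threshold",
                       c("none", "after manipulation", "spontaneous")),
    feature_definition("vascular_drawing", "Vascular drawing", 2L, "threshold",
                       c("normal (faint submucosal vessels)",
                         "light (prominent submucosal vessels)",
                         "severe (engorged vascular pattern)")),
    feature_definition("mucus_plugging", "Mucus plugging", 1L,
                       if (isTRUE(mucus_plugging_binary)) "maximum" else "threshold",
                       c("no plugging", "present (obstruction)"))
  )
  names(defs) <- vapply(defs, `[[`, "", "feature_id")
  structure(defs, class = "feature_registry")
}

#' @export
print.feature_registry <- function(x, ...) {
  cat(sprintf("<feature_registry> %d features\n", length(x)))
  for (f in x)
    cat(sprintf("  %-18s 0-%d  %s\n", f$feature_id, f$per_lobe_max, f$aggregation))
  invisible(x)
}

as_feature_registry <- function(registry) {
  if (inherits(registry, "feature_registry")) return(registry)
  if (inherits(registry, "feature_definition")) registry <- list(registry)
  stopifnot(is.list(registry), all(vapply(registry, inherits, TRUE, "feature_definition")))
  names(registry) <- vapply(registry, `[[`, "", "feature_id")
  structure(registry, class = "feature_registry")
}

#' Composite score range of a feature
#'
#' The threshold rule can exceed the per-lobe maximum by one (the majority
#' bonus), so threshold features span `0:(per_lobe_max + 1)`; maximum-rule
#' features span `0:per_lobe_max`. This full instrument-defined range is the
#' category space used by the agreement engine, whether or not every value
#' is observed in a sample.
#'
#' @param feature A [feature_definition()].
#' @return Integer vector of attainable composite values.
#' @export
composite_range <- function(feature) {
  stopifnot(inherits(feature, "feature_definition"))
  top <- feature$per_lobe_max + if (feature$aggregation == "threshold") 1L else 0L
  0:top
}

#' Read a feature registry from a YAML or JSON file
#'
#' The file holds a list of feature entries with fields `feature_id`,
#' `display_name`, `per_lobe_max`, `aggregation` and optional `level_labels`,
#' mirroring [feature_definition()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"feature_registry"`.
#' @export
read_feature_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  defs <- lapply(raw, function(e) {
    feature_definition(e$feature_id,
                       e$display_name %||% e$feature_id,
                       e$per_lobe_max,
                       e$aggregation %||% "threshold",
                       e$level_labels)
  })
  as_feature_registry(defs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
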