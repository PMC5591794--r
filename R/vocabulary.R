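## Controlled vocabulary of the uDISE model and of the four foreign
## DISE classification systems the package can convert to and from.

.STRUCTURES <- data.frame(
  code  = c("N", "V", "Ts", "O", "Tb", "E", "L"),
  label = c("nose", "velum", "tonsils",
            "lateral pharyngeal wall/oropharynx", "tongue base",
            "epiglottis", "larynx"),
  canonical_order = 1:7,
  stringsAsFactors = FALSE
)

.DEGREES <- data.frame(
  value = 0:2,
  label = c("none", "partial", "complete"),
  band  = c("<50%", "50-75%", ">75%"),
  stringsAsFactors = FALSE
)

.CONFIGURATIONS <- data.frame(
  code  = c("AP", "L", "C"),
  label = c("anteroposterior", "lateral", "concentric"),
  stringsAsFactors = FALSE
)

## Fixed site -> admissible configuration table. Nose and larynx carry no
## configuration; tonsils collapse laterally only; the epiglottis folds
## anteroposteriorly or laterally.
.ALLOWED_CONFIGS <- list(
  N  = character(0),
  V  = c("AP", "L", "C"),
  Ts = "L",
  O  = c("AP", "L", "C"),
  Tb = c("AP", "L", "C"),
  E  = c("AP", "L"),
  L  = character(0)
)

#' uDISE anatomical structures
#'
#' The seven upper-airway sites of the uDISE model in canonical order:
#' nose (N), velum (V), tonsils (Ts), lateral pharyngeal wall/oropharynx (O),
#' tongue base (Tb), epiglottis (E) and larynx (L).
#'
#' @return A data frame with columns `code`, `label` and `canonical_order`.
#' @examples
#' udiseStructures()
#' @export
udiseStructures <- function() .STRUCTURES

#' uDISE obstruction degrees
#'
#' Degree 0 is no obstruction (no vibration, airway narrowing below 50%),
#' degree 1 partial obstruction (vibration, 50-75%), degree 2 complete
#' obstruction (collapse, above 75%). The percent bands are descriptive
#' labels only; no numeric narrowing is computed.
#'
#' @return A data frame with columns `value`, `label` and `band`.
#' @export
udiseDegrees <- function() .DEGREES

#' uDISE obstruction configurations
#'
#' Anteroposterior (AP), lateral (L) and concentric (C) collapse patterns.
#'
#' @return A data frame with columns `code` and `label`.
#' @export
udiseConfigurations <- function() .CONFIGURATIONS

#' Configurations admissible at a site
#'
#' Returns the fixed set of collapse configurations the uDISE model admits
#' for an anatomical structure. The nose and larynx carry none (obstruction
#' there is static or not configuration-typed), the tonsils collapse only
#' laterally, the epiglottis anteroposteriorly or laterally, and the velum,
#' oropharynx and tongue base in all three patterns.
#'
#' @param structure A single structure code (see [udiseStructures()]).
#' @return Character vector of configuration codes (possibly empty).
#' @examples
#' allowedConfigurations("V")
#' allowedConfigurations("Ts")
#' @export
allowedConfigurations <- function(structure) {
  if (!is.character(structure) || length(structure) != 1L ||
      !structure %in% .STRUCTURES$code) {
    stop("unknown structure code: ", deparse(structure), call. = FALSE)
  }
  .ALLOWED_CONFIGS[[structure]]
}

## ---- foreign systems -------------------------------------------------------

## Per-system site vocabulary: grade ranges, admissible configurations and
## whether a configuration must accompany a graded finding. NOHL larynx is
## scored negative/positive ("N"/"P") rather than graded.
.SYSTEMS <- list(
  PRINGLE = list(
    label = "Pringle and Croft grading",
    sites = NULL,                       # whole-exam grade, no site
    grades = 1:5
  ),
  VOTE = list(
    label = "VOTE (velum, oropharynx, tongue base, epiglottis)",
    sites = list(
      V = list(grades = 0:2, configurations = c("AP", "L", "C")),
      O = list(grades = 0:2, configurations = "L"),
      T = list(grades = 0:2, configurations = "AP"),
      E = list(grades = 0:2, configurations = c("AP", "L"))
    )
  ),
  NOHL = list(
    label = "NOHL (nose, oropharynx, hypopharynx, larynx)",
    sites = list(
      N  = list(grades = 1:4, configurations = character(0)),
      O  = list(grades = 1:4, configurations = c("AP", "t", "C")),
      H  = list(grades = 1:4, configurations = c("AP", "L", "C")),
      Ts = list(grades = 1:4, configurations = character(0)),
      L  = list(flags = c("N", "P"), configurations = character(0))
    )
  ),
  PTLTBE = list(
    label = "P-T-L-Tb-E (palate, tonsils, lateral wall, tongue base, epiglottis)",
    sites = list(
      P  = list(grades = 1:3, configurations = character(0)),
      T  = list(grades = 1:3, configurations = character(0)),
      L  = list(grades = 1:3, configurations = character(0)),
      Tb = list(grades = 1:3, configurations = character(0)),
      E  = list(grades = 1:2, configurations = character(0))
    )
  )
)

#' Foreign classification systems known to the crosswalk
#'
#' @return Character vector of system identifiers.
#' @export
foreignSystems <- function() names(.SYSTEMS)

.systemSpec <- function(system) {
  if (!is.character(system) || length(system) != 1L ||
      !system %in% names(.SYSTEMS)) {
    stop("unknown classification system: ", deparse(system), call. = FALSE)
  }
  .SYSTEMS[[system]]
}

#' Export the model vocabulary as JSON
#'
#' Writes the uDISE vocabulary (structures, degrees, configurations, the
#' per-site admissible-configuration table and the foreign-system site
#' grammars) to a machine-readable JSON document, so external rule files and
#' schemas can reference a single source of truth. The same document ships
#' with the package under `extdata/udise-vocabulary.json`.
#'
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
exportVocabulary <- function(path) {
  doc <- list(
    structures = .STRUCTURES,
    degrees = .DEGREES,
    configurations = .CONFIGURATIONS,
    allowed_configurations = .ALLOWED_CONFIGS,
    systems = lapply(.SYSTEMS, function(s) {
      list(label = s$label,
           sites = if (is.null(s$sites)) NULL else
             lapply(s$sites, function(x) x[!vapply(x, is.null, logical(1))]),
           grades = s$grades)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
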