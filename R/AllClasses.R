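## S4 classes for uDISE findings, profiles, foreign tokens, the crosswalk
## rule base and conversion results.

#' @import methods
#' @include vocabulary.R
NULL

## Violations for a (structure, degree, configuration) triple; configuration
## is NA_character_ when absent. Returns character(0) when valid.
.findingViolations <- function(structure, degree, configuration) {
  v <- character(0)
  if (!is.character(structure) || length(structure) != 1L ||
      !structure %in% .STRUCTURES$code) {
    return(paste0("unknown structure code: ", deparse(structure)))
  }
  if (!is.numeric(degree) && !is.integer(degree)) {
    return(paste0(structure, ": degree must be an integer in 0..2"))
  }
  if (length(degree) != 1L || is.na(degree) || degree != as.integer(degree) ||
      !as.integer(degree) %in% 0:2) {
    return(paste0(structure, ": degree ", deparse(degree),
                  " outside 0..2"))
  }
  allowed <- .ALLOWED_CONFIGS[[structure]]
  cfg <- configuration
  hasCfg <- length(cfg) == 1L && !is.na(cfg)
  if (length(cfg) != 1L) {
    return(paste0(structure, ": configuration must be a single code or NA"))
  }
  if (hasCfg && !cfg %in% .CONFIGURATIONS$code) {
    return(paste0(structure, ": unknown configuration code ", deparse(cfg)))
  }
  if (hasCfg && length(allowed) == 0L) {
    v <- c(v, paste0(structure, ": site carries no configuration, got ", cfg))
  } else if (hasCfg && !cfg %in% allowed) {
    v <- c(v, paste0(structure, ": configuration ", cfg,
                     " not allowed (admissible: ",
                     paste(allowed, collapse = ", "), ")"))
  }
  if (!hasCfg && degree >= 1 && length(allowed) > 0L) {
    v <- c(v, paste0(structure, ": configuration required at degree >= 1 ",
                     "(admissible: ", paste(allowed, collapse = ", "), ")"))
  }
  v
}

#' SiteFinding: one uDISE finding at one anatomical site
#'
#' A validated triple of structure, obstruction degree (0-2) and, where the
#' site admits one, a collapse configuration. Configuration is mandatory at
#' degree >= 1 for sites with a nonempty admissible set, optional at degree 0
#' (canonical notation omits it there, but the crosswalk can carry it), and
#' forbidden at the nose and larynx.
#'
#' @slot structure Structure code (see [udiseStructures()]).
#' @slot degree Integer obstruction degree, 0, 1 or 2.
#' @slot configuration Configuration code or `NA_character_`.
#' @seealso [siteFinding()], [validateFinding()]
#' @export
setClass("SiteFinding",
  representation(structure = "character", degree = "integer",
                 configuration = "character"),
  prototype(structure = "N", degree = 0L, configuration = NA_character_),
  validity = function(object) {
    v <- .findingViolations(object@structure, object@degree,
                            object@configuration)
    if (length(v)) v else TRUE
  }
)

#' UdiseProfile: a complete uDISE examination record
#'
#' Exactly one valid [SiteFinding-class] per anatomical structure, stored in
#' canonical site order (N, V, Ts, O, Tb, E, L). The severity index of a
#' profile is the sum of its seven degrees, hence always in 0..14.
#'
#' @slot findings List of seven `SiteFinding` objects in canonical order.
#' @seealso [udiseProfile()], [severityIndex()]
#' @export
setClass("UdiseProfile",
  representation(findings = "list"),
  validity = function(object) {
    f <- object@findings
    if (length(f) != 7L) {
      return(sprintf("profile must hold 7 findings, got %d", length(f)))
    }
    if (!all(vapply(f, is, logical(1), "SiteFinding"))) {
      return("all findings must be SiteFinding objects")
    }
    codes <- vapply(f, function(x) x@structure, character(1))
    if (!identical(codes, .STRUCTURES$code)) {
      return(paste0("findings must follow canonical site order ",
                    paste(.STRUCTURES$code, collapse = ","), "; got ",
                    paste(codes, collapse = ",")))
    }
    msgs <- unlist(lapply(f, function(x)
      .findingViolations(x@structure, x@degree, x@configuration)))
    if (length(msgs)) msgs else TRUE
  }
)

#' ForeignToken: a finding in a foreign classification system
#'
#' A validated finding expressed in one of the four mapped systems. Pringle
#' grades are whole-exam tokens (no site); the NOHL larynx is scored by a
#' negative/positive flag instead of a grade; VOTE configurations are
#' mandatory at grade >= 1 and optional at grade 0.
#'
#' @slot system System id, one of `foreignSystems()`.
#' @slot site Site code within the system, or `NA` (Pringle).
#' @slot grade Integer grade, or `NA` (NOHL larynx).
#' @slot flag `"N"` or `"P"` for the NOHL larynx, else `NA`.
#' @slot configuration System-specific configuration code or `NA`.
#' @seealso [foreignToken()], [parseForeign()]
#' @export
setClass("ForeignToken",
  representation(system = "character", site = "character", grade = "integer",
                 flag = "character", configuration = "character"),
  prototype(system = "PRINGLE", site = NA_character_, grade = 1L,
            flag = NA_character_, configuration = NA_character_),
  validity = function(object) {
    v <- .tokenViolations(object)
    if (length(v)) v else TRUE
  }
)

.tokenViolations <- function(tok) {
  sys <- tok@system
  if (length(sys) != 1L || !sys %in% names(.SYSTEMS)) {
    return(paste0("unknown system: ", deparse(sys)))
  }
  spec <- .SYSTEMS[[sys]]
  site <- tok@site; grade <- tok@grade
  flag <- tok@flag; cfg <- tok@configuration
  if (sys == "PRINGLE") {
    v <- character(0)
    if (!is.na(site)) v <- c(v, "PRINGLE grades carry no site")
    if (!is.na(cfg)) v <- c(v, "PRINGLE grades carry no configuration")
    if (is.na(grade) || !grade %in% spec$grades) {
      v <- c(v, paste0("PRINGLE grade must be 1..5, got ", deparse(grade)))
    }
    return(v)
  }
  if (is.na(site) || !site %in% names(spec$sites)) {
    return(paste0(sys, ": unknown site ", deparse(site), " (sites: ",
                  paste(names(spec$sites), collapse = ", "), ")"))
  }
  ss <- spec$sites[[site]]
  v <- character(0)
  if (!is.null(ss$flags)) {              # NOHL larynx
    if (is.na(flag) || !flag %in% ss$flags) {
      v <- c(v, paste0(sys, " ", site, ": flag must be one of ",
                       paste(ss$flags, collapse = "/")))
    }
    if (!is.na(grade)) v <- c(v, paste0(sys, " ", site, ": carries no grade"))
  } else {
    if (is.na(grade) || !grade %in% ss$grades) {
      v <- c(v, paste0(sys, " ", site, ": grade ", deparse(grade),
                       " outside ", min(ss$grades), "..", max(ss$grades)))
    }
    if (!is.na(flag)) v <- c(v, paste0(sys, " ", site, ": carries no flag"))
  }
  if (!is.na(cfg)) {
    if (!length(ss$configurations) || !cfg %in% ss$configurations) {
      v <- c(v, paste0(sys, " ", site, ": configuration ", cfg,
                       " not defined for this site"))
    }
  } else if (length(ss$configurations) && sys == "VOTE" &&
             !is.na(grade) && grade >= 1) {
    v <- c(v, paste0("VOTE ", site, ": configuration required at grade >= 1"))
  } else if (length(ss$configurations) && sys == "NOHL") {
    v <- c(v, paste0("NOHL ", site, ": configuration required"))
  }
  v
}

#' RuleBase: the loaded crosswalk rule set
#'
#' Holds the fully expanded, validated mapping rules of the shipped (or a
#' user-supplied) rule file, together with the coverage map derived from the
#' udise-to-foreign rules: for every uDISE cell and every system, whether the
#' cell is covered, the site is not considered anatomically (marker `X`), or
#' the site is considered but this degree/configuration has no counterpart
#' (marker `-`).
#'
#' @slot rules List of rule records (see [loadRuleBase()] for the schema).
#' @slot systems Character vector of system ids present.
#' @slot version Rule-file format version string.
#' @slot source Path the rule base was loaded from.
#' @slot coverage Data frame: structure, degree, configuration, system,
#'   status (`covered`/`site_excluded`/`config_excluded`) and rendered entry.
#' @seealso [loadRuleBase()], [rulesFor()]
#' @export
setClass("RuleBase",
  representation(rules = "list", systems = "character", version = "character",
                 source = "character", coverage = "data.frame")
)

#' ConversionResult: outcome of a crosswalk conversion
#'
#' Set-valued result of converting findings between uDISE and a foreign
#' system. Candidate sets are per-site; a flag records whether each touched
#' site resolved exactly (one candidate), ambiguously (several), or — in the
#' udise-to-foreign direction — was excluded because the target system does
#' not consider the site (`site_excluded`, grid marker `X`) or not this
#' degree/configuration (`config_excluded`, marker `-`). Foreign tokens whose
#' grade has no printed mapping are flagged `unmapped_grade`. Disjunction
#' groups record one-finding-at-either-site alternatives (the VOTE
#' oropharynx rule), which [severityRange()] honours.
#'
#' @slot direction `"foreign_to_udise"` or `"udise_to_foreign"`.
#' @slot system Foreign system id.
#' @slot source List of source findings/tokens as supplied.
#' @slot candidates Named list, structure code -> data frame
#'   (`degree`, `configuration`) of uDISE candidates.
#' @slot disjunctions List of disjunction groups (`id`, `rule`, `sites`,
#'   per-site candidate data frames).
#' @slot foreignCandidates Named list, structure code -> character vector of
#'   rendered candidate tokens (udise-to-foreign only).
#' @slot unconstrained Structure codes no rule touched.
#' @slot flags Named character vector of per-site flags.
#' @slot provenance Character vector of rule ids fired.
#' @export
setClass("ConversionResult",
  representation(direction = "character", system = "character",
                 source = "list", candidates = "list", disjunctions = "list",
                 foreignCandidates = "list", unconstrained = "character",
                 flags = "character", provenance = "character")
)
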