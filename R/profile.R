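#' @include AllClasses.R AllGenerics.R finding.R
NULL

#' Assemble a uDISE profile from per-site findings
#'
#' Builds a complete examination record from a collection of
#' [SiteFinding-class] objects. Exactly one finding per anatomical structure
#' must be supplied (in any order); the profile stores them in canonical
#' site order N, V, Ts, O, Tb, E, L.
#'
#' @param findings A list of `SiteFinding` objects, or several findings
#'   passed as separate arguments.
#' @return A validated [UdiseProfile-class].
#' @examples
#' udiseProfile(lapply(udiseStructures()$code, siteFinding, degree = 0))
#' @export
udiseProfile <- function(findings, ...) {
  if (is(findings, "SiteFinding")) findings <- c(list(findings), list(...))
  if (!is.list(findings) ||
      !all(vapply(findings, is, logical(1), "SiteFinding"))) {
    stop("findings must be SiteFinding objects", call. = FALSE)
  }
  codes <- vapply(findings, function(x) x@structure, character(1))
  dup <- unique(codes[duplicated(codes)])
  if (length(dup)) {
    stop("duplicate: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(.STRUCTURES$code, codes)
  if (length(missing)) {
    stop("missing: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- unlist(lapply(findings, function(x)
    .findingViolations(x@structure, x@degree, x@configuration)))
  if (length(bad)) {
    stop("invalid finding(s): ", paste(bad, collapse = "; "), call. = FALSE)
  }
  new("UdiseProfile", findings = findings[match(.STRUCTURES$code, codes)])
}

#' @rdname udiseProfile
#' @param ... Further `SiteFinding` objects when `findings` is one.
#' @export
makeProfile <- udiseProfile

#' Build a profile from named degrees and configurations
#'
#' Convenience constructor: unlisted sites default to degree 0 with no
#' configuration.
#'
#' @param degrees Named integer vector, names are structure codes.
#' @param configurations Named character vector of configuration codes.
#' @return A [UdiseProfile-class].
#' @examples
#' profileFromDegrees(c(Ts = 2, Tb = 2), c(Ts = "L", Tb = "AP"))
#' @export
profileFromDegrees <- function(degrees = integer(0),
                               configurations = character(0)) {
  udiseProfile(lapply(.STRUCTURES$code, function(code) {
    d <- if (code %in% names(degrees)) as.integer(degrees[[code]]) else 0L
    cfg <- if (code %in% names(configurations))
      configurations[[code]] else NA_character_
    siteFinding(code, d, cfg)
  }))
}

#' Extract per-site findings from a profile
#'
#' @param profile A [UdiseProfile-class].
#' @param structure Optional structure code; when given, the single
#'   [SiteFinding-class] for that site is returned.
#' @return A list of seven findings in canonical order, or one finding.
#' @export
profileFindings <- function(profile, structure = NULL) {
  stopifnot(is(profile, "UdiseProfile"))
  if (is.null(structure)) return(profile@findings)
  i <- match(structure, .STRUCTURES$code)
  if (is.na(i)) stop("unknown structure code: ", structure, call. = FALSE)
  profile@findings[[i]]
}

#' @rdname finding-accessors
setMethod("obstructionDegree", "UdiseProfile", function(x) {
  stats::setNames(vapply(x@findings, function(f) f@degree, integer(1)),
                  .STRUCTURES$code)
})

#' @rdname finding-accessors
setMethod("obstructionConfiguration", "UdiseProfile", function(x) {
  stats::setNames(vapply(x@findings, function(f) f@configuration,
                         character(1)),
                  .STRUCTURES$code)
})

#' @rdname finding-accessors
setMethod("structureCode", "UdiseProfile", function(x) .STRUCTURES$code)

#' @rdname severityIndex
setMethod("severityIndex", "UdiseProfile", function(x) {
  sum(obstructionDegree(x))
})

setMethod("show", "UdiseProfile", function(object) {
  cat("UdiseProfile:", formatUdise(object),
      sprintf("(severity index %d)\n", severityIndex(object)))
})
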