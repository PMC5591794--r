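#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a single-site uDISE finding
#'
#' @param structure Structure code (`N`, `V`, `Ts`, `O`, `Tb`, `E`, `L`).
#' @param degree Obstruction degree 0, 1 or 2.
#' @param configuration Configuration code (`AP`, `L`, `C`) or `NA`. Required
#'   at degree >= 1 for sites that admit configurations, optional at degree
#'   0, forbidden at the nose and larynx.
#' @return A [SiteFinding-class] object. Invalid combinations raise an error;
#'   use [validateFinding()] for a non-throwing verdict.
#' @examples
#' siteFinding("Ts", 2, "L")
#' siteFinding("N", 1)
#' @export
siteFinding <- function(structure, degree, configuration = NA_character_) {
  new("SiteFinding", structure = as.character(structure),
      degree = as.integer(degree),
      configuration = as.character(configuration))
}

#' Validate a finding without raising
#'
#' Checks a site/degree/configuration combination against the uDISE model's
#' per-site rules and returns a verdict rather than signalling an error.
#'
#' @param finding A [SiteFinding-class], or a structure code when `degree`
#'   is also given.
#' @param degree,configuration Used when `finding` is a bare structure code.
#' @return A list with elements `ok` (logical) and `violations` (character
#'   vector, empty when valid; each entry names the broken rule and field).
#' @examples
#' validateFinding("Ts", 2, "AP")$violations
#' @export
validateFinding <- function(finding, degree = NULL,
                            configuration = NA_character_) {
  if (is(finding, "SiteFinding")) {
    v <- .findingViolations(finding@structure, finding@degree,
                            finding@configuration)
  } else {
    v <- .findingViolations(as.character(finding), degree,
                            as.character(configuration))
  }
  list(ok = length(v) == 0L, violations = v)
}

#' @rdname finding-accessors
setMethod("structureCode", "SiteFinding", function(x) x@structure)

#' @rdname finding-accessors
setMethod("obstructionDegree", "SiteFinding", function(x) x@degree)

#' @rdname finding-accessors
setMethod("obstructionConfiguration", "SiteFinding",
          function(x) x@configuration)

setMethod("show", "SiteFinding", function(object) {
  cfg <- if (is.na(object@configuration)) "" else
    paste0(", ", object@configuration)
  cat(sprintf("SiteFinding %s: degree %d%s\n",
              object@structure, object@degree, cfg))
})
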