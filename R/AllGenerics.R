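#' @include AllClasses.R
NULL

#' Severity index of a uDISE profile
#'
#' The severity index is the sum of the seven per-site obstruction degrees
#' (each 0-2), so it ranges from 0 (patent airway) to 14 (complete collapse
#' at every site). It is invariant under configuration changes at fixed
#' degrees, and raising one site's degree by `d` raises the index by `d`.
#'
#' @param x A [UdiseProfile-class].
#' @return Integer in 0..14.
#' @examples
#' severityIndex(parseUdise("N0V0Ts2LO0Tb2APE0L0"))  # 4
#' @export
setGeneric("severityIndex", function(x) standardGeneric("severityIndex"))

#' Attainable severity range of a conversion result
#'
#' Minimum and maximum severity index over all uDISE profiles consistent
#' with a foreign-to-udise conversion's candidate sets. Unconstrained sites
#' contribute the full 0..2 degree range; disjunction groups (the VOTE
#' oropharynx rule, "oropharynx or tonsils") require at least one of their
#' alternative sites to take a candidate value, leaving the others free.
#'
#' @param x A [ConversionResult-class] in the foreign-to-udise direction.
#' @return Named integer vector `c(min = , max = )`, both in 0..14.
#' @examples
#' rb <- defaultRuleBase()
#' res <- toUdise(foreignToken("NOHL", site = "O", grade = 4,
#'                             configuration = "t"), rb)
#' severityRange(res)
#' @export
setGeneric("severityRange", function(x) standardGeneric("severityRange"))

#' Accessors for findings and profiles
#'
#' `structureCode()`, `obstructionDegree()` and `obstructionConfiguration()`
#' read the components of a [SiteFinding-class]; applied to a
#' [UdiseProfile-class] they return the per-site vector named by structure
#' code in canonical site order. Configurations are `NA` where absent.
#'
#' @param x A `SiteFinding` or `UdiseProfile`.
#' @return A scalar for findings; a named vector for profiles.
#' @examples
#' obstructionDegree(parseUdise("N0V1APTs0O0Tb0E0L0"))
#' @name finding-accessors
NULL

#' @rdname finding-accessors
#' @export
setGeneric("structureCode", function(x) standardGeneric("structureCode"))

#' @rdname finding-accessors
#' @export
setGeneric("obstructionDegree",
           function(x) standardGeneric("obstructionDegree"))

#' @rdname finding-accessors
#' @export
setGeneric("obstructionConfiguration",
           function(x) standardGeneric("obstructionConfiguration"))
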