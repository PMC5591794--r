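#' @include rules.R
NULL

.cellKey <- function(df) {
  paste(df$degree, ifelse(is.na(df$configuration), "", df$configuration))
}

.intersectCells <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  a[.cellKey(a) %in% .cellKey(b), , drop = FALSE]
}

.uniqueCells <- function(df) {
  df <- df[!duplicated(.cellKey(df)), , drop = FALSE]
  rownames(df) <- NULL
  df[order(df$degree, match(df$configuration, .CONFIGURATIONS$code),
           na.last = FALSE), , drop = FALSE]
}

## foreign->udise rules matching one token (degree-0 widening: a VOTE token
## with grade 0 and no configuration matches all configuration variants).
.matchF2U <- function(ruleBase, token) {
  Filter(function(r) {
    if (r$direction != "foreign_to_udise" ||
        r$system != token@system) return(FALSE)
    src <- r$source
    if (token@system != "PRINGLE") {
      if (is.null(src$site) || src$site != token@site) return(FALSE)
    }
    if (!is.null(src$flags)) {
      if (is.na(token@flag) || !token@flag %in% unlist(src$flags)) {
        return(FALSE)
      }
    } else if (is.na(token@grade) ||
               !token@grade %in% unlist(src$grades)) {
      return(FALSE)
    }
    if (!is.null(src$configurations)) {
      if (is.na(token@configuration)) {
        return(token@grade == 0L)              # degree-0 widening
      }
      return(token@configuration %in% unlist(src$configurations))
    }
    TRUE
  }, ruleBase@rules)
}

#' Convert foreign-system findings to uDISE
#'
#' Applies every matching foreign-to-udise rule to the supplied tokens.
#' Constraints from different tokens touching the same uDISE site are
#' intersected (one exam yields one finding per site); alternative
#' interpretations of a single token are unioned. The VOTE oropharynx rule
#' ("oropharynx or tonsils") becomes a disjunction group rather than a
#' conjunction. Sites no rule touches are unconstrained; tokens whose grade
#' has no published mapping (e.g. NOHL tonsil grades 1-2) are flagged
#' `unmapped_grade` and constrain nothing.
#'
#' @param tokens A [ForeignToken-class] or list of them, all one system.
#' @param ruleBase A [RuleBase-class].
#' @return A [ConversionResult-class]. An empty per-site intersection
#'   (contradictory tokens) raises an error of class `udiseContradiction`
#'   naming the site and the rules involved.
#' @examples
#' rb <- defaultRuleBase()
#' toUdise(parseForeign("NOHL", "Ot4"), rb)
#' toUdise(parseForeign("VOTE", "Ok2L"), rb)
#' @export
toUdise <- function(tokens, ruleBase) {
  stopifnot(is(ruleBase, "RuleBase"))
  if (is(tokens, "ForeignToken")) tokens <- list(tokens)
  if (!length(tokens) ||
      !all(vapply(tokens, is, logical(1), "ForeignToken"))) {
    stop("tokens must be ForeignToken objects", call. = FALSE)
  }
  systems <- unique(vapply(tokens, function(t) t@system, character(1)))
  if (length(systems) != 1L) {
    stop("mixed systems in one conversion: ",
         paste(systems, collapse = ", "), call. = FALSE)
  }
  for (tk in tokens) validObject(tk)

  hard <- list()          # structure -> candidate cells (intersected)
  hardRules <- list()     # structure -> rule ids (for error reporting)
  groups <- list()
  flags <- character(0)
  provenance <- character(0)

  for (tk in tokens) {
    matched <- .matchF2U(ruleBase, tk)
    if (!length(matched)) {
      flags[[formatForeignToken(tk)]] <- "unmapped_grade"
      next
    }
    provenance <- c(provenance, vapply(matched, `[[`, character(1), "id"))
    ## union alternative interpretations of this token, per structure
    tokenCells <- list()
    for (r in matched) {
      if (r$disjunction) {
        groups[[length(groups) + 1L]] <- list(
          id = r$id,
          sites = vapply(r$cells, `[[`, character(1), "structure"),
          candidates = stats::setNames(
            lapply(r$cells, `[[`, "cells"),
            vapply(r$cells, `[[`, character(1), "structure")))
        next
      }
      for (con in r$cells) {
        st <- con$structure
        tokenCells[[st]] <- if (is.null(tokenCells[[st]])) con$cells
          else .uniqueCells(rbind(tokenCells[[st]], con$cells))
      }
    }
    for (st in names(tokenCells)) {
      merged <- .intersectCells(hard[[st]], .uniqueCells(tokenCells[[st]]))
      hardRules[[st]] <- c(hardRules[[st]],
                           vapply(matched, `[[`, character(1), "id"))
      if (!nrow(merged)) {
        cond <- structure(
          class = c("udiseContradiction", "error", "condition"),
          list(message = sprintf(
                 "contradictory constraints at site %s (rules: %s)",
                 st, paste(unique(hardRules[[st]]), collapse = ", ")),
               call = NULL, site = st, rules = unique(hardRules[[st]])))
        stop(cond)
      }
      hard[[st]] <- merged
    }
  }

  for (st in names(hard)) {
    flags[[st]] <- if (nrow(hard[[st]]) == 1L) "exact" else "ambiguous"
  }
  for (g in groups) {
    for (st in g$sites) if (is.null(hard[[st]])) flags[[st]] <- "ambiguous"
  }
  constrained <- union(names(hard),
                       unlist(lapply(groups, `[[`, "sites")))
  new("ConversionResult",
      direction = "foreign_to_udise", system = systems,
      source = tokens, candidates = hard, disjunctions = groups,
      foreignCandidates = list(),
      unconstrained = setdiff(.STRUCTURES$code, constrained),
      flags = flags, provenance = unique(provenance))
}

#' Convert a uDISE profile to a foreign system
#'
#' For each of the seven sites, fires the matching udise-to-foreign rules
#' and collects the candidate foreign tokens. A degree-0 finding without a
#' configuration matches every configuration variant of the relevant rules
#' (widened candidate set). Sites the target system does not consider
#' anatomically are flagged `site_excluded` (reference-grid marker `X`);
#' sites it considers, but not at this degree/configuration, are flagged
#' `config_excluded` (marker `-`).
#'
#' @param profile A [UdiseProfile-class].
#' @param system One of `foreignSystems()`.
#' @param ruleBase A [RuleBase-class].
#' @return A [ConversionResult-class] with per-site foreign candidates.
#' @examples
#' rb <- defaultRuleBase()
#' fromUdise(parseUdise("N0V1APTs0O0Tb0E0L0"), "NOHL", rb)
#' @export
fromUdise <- function(profile, system, ruleBase) {
  stopifnot(is(profile, "UdiseProfile"), is(ruleBase, "RuleBase"))
  .systemSpec(system)
  u2f <- rulesFor(ruleBase, system, "udise_to_foreign")
  touched <- unique(vapply(u2f, function(r) r$source$structure,
                           character(1)))
  cand <- list(); flags <- character(0); provenance <- character(0)
  for (f in profile@findings) {
    st <- f@structure
    if (!st %in% touched) { flags[[st]] <- "site_excluded"; next }
    matched <- .matchU2F(ruleBase, system, st, f@degree, f@configuration)
    if (!length(matched)) { flags[[st]] <- "config_excluded"; next }
    toks <- unique(unlist(lapply(matched, function(r)
      vapply(r$tokens, formatForeignToken, character(1)))))
    cand[[st]] <- sort(toks)
    flags[[st]] <- if (length(toks) == 1L) "exact" else "ambiguous"
    provenance <- c(provenance, vapply(matched, `[[`, character(1), "id"))
  }
  new("ConversionResult",
      direction = "udise_to_foreign", system = system,
      source = profile@findings, candidates = list(), disjunctions = list(),
      foreignCandidates = cand,
      unconstrained = character(0),
      flags = flags, provenance = unique(provenance))
}

## ---- accessors -------------------------------------------------------------

#' Candidate sets and flags of a conversion result
#'
#' `candidates()` returns the uDISE candidate cells for one site (hard
#' constraints plus, when `includeDisjunctions`, candidates the site may
#' take as part of a disjunction group) or the full per-site list.
#' `foreignCandidates()` returns the rendered candidate tokens of a
#' udise-to-foreign result. `conversionFlags()`, `unconstrainedSites()` and
#' `provenance()` expose the per-site flags, untouched sites and rule ids.
#'
#' @param result A [ConversionResult-class].
#' @param structure Optional structure code.
#' @param includeDisjunctions Include disjunction-group candidates.
#' @return A data frame (`degree`, `configuration`), list, character vector.
#' @name conversion-accessors
NULL

#' @rdname conversion-accessors
#' @export
candidates <- function(result, structure = NULL,
                       includeDisjunctions = TRUE) {
  stopifnot(is(result, "ConversionResult"))
  get1 <- function(st) {
    cells <- result@candidates[[st]]
    if (includeDisjunctions) {
      for (g in result@disjunctions) {
        if (st %in% g$sites) {
          cells <- if (is.null(cells)) g$candidates[[st]]
            else .uniqueCells(rbind(cells, g$candidates[[st]]))
        }
      }
    }
    if (is.null(cells)) {
      data.frame(degree = integer(0), configuration = character(0))
    } else cells
  }
  if (!is.null(structure)) return(get1(structure))
  constrained <- setdiff(.STRUCTURES$code, result@unconstrained)
  stats::setNames(lapply(constrained, get1), constrained)
}

#' @rdname conversion-accessors
#' @export
foreignCandidates <- function(result, structure = NULL) {
  stopifnot(is(result, "ConversionResult"))
  if (is.null(structure)) return(result@foreignCandidates)
  fc <- result@foreignCandidates[[structure]]
  if (is.null(fc)) character(0) else fc
}

#' @rdname conversion-accessors
#' @export
conversionFlags <- function(result) result@flags

#' @rdname conversion-accessors
#' @export
unconstrainedSites <- function(result) result@unconstrained

#' @rdname conversion-accessors
#' @export
provenance <- function(result) result@provenance

#' Serialize a conversion result to JSON-ready fields
#'
#' @param result A [ConversionResult-class].
#' @return A list with stable field names (`direction`, `system`, `source`,
#'   `candidates`, `disjunctions`, `foreign_candidates`, `unconstrained`,
#'   `flags`, `provenance`), suitable for `jsonlite::toJSON()`.
#' @export
conversionToList <- function(result) {
  stopifnot(is(result, "ConversionResult"))
  srcTxt <- if (result@direction == "foreign_to_udise") {
    vapply(result@source, formatForeignToken, character(1))
  } else {
    formatUdise(new("UdiseProfile", findings = result@source))
  }
  list(
    direction = result@direction,
    system = result@system,
    source = srcTxt,
    candidates = lapply(result@candidates, function(df)
      data.frame(degree = df$degree, configuration = df$configuration)),
    disjunctions = lapply(result@disjunctions, function(g)
      list(id = g$id, sites = g$sites, candidates = g$candidates)),
    foreign_candidates = result@foreignCandidates,
    unconstrained = result@unconstrained,
    flags = as.list(result@flags),
    provenance = result@provenance
  )
}

## ---- severity range --------------------------------------------------------

#' @rdname severityRange
setMethod("severityRange", "ConversionResult", function(x) {
  if (x@direction != "foreign_to_udise") {
    stop("severityRange applies to foreign->udise results", call. = FALSE)
  }
  hard <- x@candidates
  baseMin <- baseMax <- stats::setNames(integer(7), .STRUCTURES$code)
  for (st in .STRUCTURES$code) {
    if (!is.null(hard[[st]])) {
      baseMin[[st]] <- min(hard[[st]]$degree)
      baseMax[[st]] <- max(hard[[st]]$degree)
    } else {
      baseMin[[st]] <- 0L; baseMax[[st]] <- 2L
    }
  }
  groups <- x@disjunctions
  if (!length(groups)) {
    return(c(min = sum(baseMin), max = sum(baseMax)))
  }
  ## enumerate which alternative satisfies each group; sites not selected
  ## keep their base range
  choices <- expand.grid(lapply(groups, function(g) seq_along(g$sites)),
                         KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (i in seq_len(nrow(choices))) {
    lo <- baseMin; hi <- baseMax; feasible <- TRUE
    for (j in seq_along(groups)) {
      g <- groups[[j]]
      st <- g$sites[[choices[i, j]]]
      cells <- .intersectCells(hard[[st]], g$candidates[[st]])
      if (!nrow(cells)) { feasible <- FALSE; break }
      lo[[st]] <- max(lo[[st]], min(cells$degree))
      hi[[st]] <- min(hi[[st]], max(cells$degree))
      if (lo[[st]] > hi[[st]]) { feasible <- FALSE; break }
    }
    if (!feasible) next
    rng <- c(min = sum(lo), max = sum(hi))
    best <- if (is.null(best)) rng
      else c(min = min(best[["min"]], rng[["min"]]),
             max = max(best[["max"]], rng[["max"]]))
  }
  if (is.null(best)) {
    stop("no admissible site assignment for this result", call. = FALSE)
  }
  best
})

## ---- round-trip containment ------------------------------------------------

.cellContained <- function(degree, configuration, cells) {
  if (!nrow(cells)) return(FALSE)
  hit <- cells$degree == degree
  if (degree == 0L) {
    ## configuration is informational at degree 0: widened matching
    any(hit)
  } else {
    any(hit & !is.na(cells$configuration) &
          cells$configuration == configuration |
        hit & is.na(cells$configuration) & is.na(configuration))
  }
}

#' Check round-trip containment of a profile through a foreign system
#'
#' Converts a profile to `system` and each resulting candidate token back to
#' uDISE, then checks, for every site the system covers at the profile's
#' degree/configuration, that the original finding lies inside the union of
#' the returned candidate sets. A site whose forward conversion has no
#' matching reverse rule (the documented NOHL velum asymmetry: uDISE velum
#' maps to the NOHL oropharynx at palatal level, but NOHL oropharynx AP has
#' no published uDISE mapping) is reported as not contained.
#'
#' @param profile A [UdiseProfile-class].
#' @param system One of `foreignSystems()`.
#' @param ruleBase A [RuleBase-class].
#' @return A list: `contained` (logical over all covered sites), `perSite`
#'   (named logical for covered sites), `skipped` (sites flagged
#'   `site_excluded`/`config_excluded` on the way out).
#' @examples
#' rb <- defaultRuleBase()
#' roundTripContainment(parseUdise("N0V1APTs0O0Tb0E0L0"), "VOTE", rb)
#' @export
roundTripContainment <- function(profile, system, ruleBase) {
  fwd <- fromUdise(profile, system, ruleBase)
  perSite <- logical(0)
  skipped <- names(fwd@flags)[fwd@flags %in%
                                c("site_excluded", "config_excluded")]
  for (st in names(fwd@foreignCandidates)) {
    f <- profileFindings(profile, st)
    ok <- FALSE
    for (tokTxt in fwd@foreignCandidates[[st]]) {
      tok <- parseForeign(system, tokTxt)[[1]]
      back <- tryCatch(toUdise(tok, ruleBase), error = function(e) NULL)
      if (is.null(back)) next
      cells <- candidates(back, st, includeDisjunctions = TRUE)
      if (.cellContained(f@degree, f@configuration, cells)) {
        ok <- TRUE; break
      }
    }
    perSite[[st]] <- ok
  }
  list(contained = all(perSite), perSite = perSite, skipped = skipped)
}

setMethod("show", "ConversionResult", function(object) {
  cat(sprintf("ConversionResult %s [%s]\n", object@system,
              object@direction))
  if (object@direction == "foreign_to_udise") {
    for (st in names(object@candidates)) {
      df <- object@candidates[[st]]
      cat(sprintf("  %s: {%s} [%s]\n", st,
                  paste(paste0(df$degree,
                               ifelse(is.na(df$configuration), "",
                                      df$configuration)), collapse = ", "),
                  object@flags[[st]]))
    }
    for (g in object@disjunctions) {
      cat(sprintf("  disjunction (%s): %s\n", g$id,
                  paste(g$sites, collapse = " | ")))
    }
    if (length(object@unconstrained)) {
      cat("  unconstrained:", paste(object@unconstrained, collapse = ", "),
          "\n")
    }
    rng <- severityRange(object)
    cat(sprintf("  severity range: %d..%d\n", rng[["min"]], rng[["max"]]))
  } else {
    for (st in names(object@flags)) {
      val <- if (st %in% names(object@foreignCandidates)) {
        paste(object@foreignCandidates[[st]], collapse = ", ")
      } else if (object@flags[[st]] == "site_excluded") "X" else "-"
      cat(sprintf("  %s -> %s [%s]\n", st, val, object@flags[[st]]))
    }
  }
  if (length(object@provenance)) {
    cat("  rules:", paste(object@provenance, collapse = ", "), "\n")
  }
})
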