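#' @include AllClasses.R notation.R
NULL

## Expand a constraint record {structure, degrees, configurations?} into a
## data frame of (degree, configuration) cells. Sites without configurations
## get NA; degree-0 cells keep their configuration explicitly (the crosswalk
## needs them), which .findingViolations permits.
.expandConstraint <- function(con) {
  cfgs <- if (is.null(con$configurations)) NA_character_
          else unlist(con$configurations)
  cells <- expand.grid(degree = as.integer(unlist(con$degrees)),
                       configuration = cfgs, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  cells[order(cells$degree, match(cells$configuration,
                                  .CONFIGURATIONS$code)), , drop = FALSE]
}

.checkConstraint <- function(con, ruleId) {
  err <- function(...) stop("rule ", ruleId, ": ", ..., call. = FALSE)
  if (is.null(con$structure) || !con$structure %in% .STRUCTURES$code) {
    err("unknown structure code ", deparse(con$structure))
  }
  degrees <- unlist(con$degrees)
  if (!length(degrees) || !all(degrees %in% 0:2)) {
    err("degrees outside 0..2 for structure ", con$structure)
  }
  allowed <- .ALLOWED_CONFIGS[[con$structure]]
  cfgs <- unlist(con$configurations)
  if (length(cfgs)) {
    if (!length(allowed)) err("structure ", con$structure,
                              " carries no configuration")
    if (!all(cfgs %in% allowed)) {
      err("configuration(s) ", paste(setdiff(cfgs, allowed), collapse = ","),
          " not allowed for ", con$structure)
    }
  } else if (length(allowed)) {
    err("structure ", con$structure, " requires configurations in a rule")
  }
  invisible(TRUE)
}

.checkForeignSide <- function(side, system, ruleId, tokens = FALSE) {
  err <- function(...) stop("rule ", ruleId, ": ", ..., call. = FALSE)
  spec <- .SYSTEMS[[system]]
  checkOne <- function(site, grades, flags, cfgs) {
    if (system == "PRINGLE") {
      if (!is.null(site)) err("PRINGLE rules carry no site")
      if (!all(unlist(grades) %in% spec$grades)) {
        err("PRINGLE grade outside 1..5")
      }
      return(invisible(TRUE))
    }
    if (is.null(site) || !site %in% names(spec$sites)) {
      err("unknown ", system, " site ", deparse(site))
    }
    ss <- spec$sites[[site]]
    if (!is.null(ss$flags)) {
      if (!length(unlist(flags)) || !all(unlist(flags) %in% ss$flags)) {
        err(system, " ", site, " takes flags ",
            paste(ss$flags, collapse = "/"))
      }
    } else if (!length(unlist(grades)) ||
               !all(unlist(grades) %in% ss$grades)) {
      err(system, " ", site, " grade outside ",
          min(ss$grades), "..", max(ss$grades))
    }
    if (length(unlist(cfgs)) &&
        !all(unlist(cfgs) %in% ss$configurations)) {
      err("configuration not defined for ", system, " ", site)
    }
    invisible(TRUE)
  }
  if (tokens) {
    for (tk in side$tokens) {
      checkOne(tk$site, list(tk$grade), list(tk$flag), list(tk$configuration))
    }
  } else {
    checkOne(side$site, side$grades, side$flags, side$configurations)
  }
  invisible(TRUE)
}

.normaliseRule <- function(rule) {
  rule$lossy <- isTRUE(rule$lossy)
  rule$disjunction <- isTRUE(rule$disjunction)
  if (rule$direction == "foreign_to_udise") {
    rule$cells <- lapply(rule$target$constraints, function(con) {
      list(structure = con$structure, cells = .expandConstraint(con))
    })
  } else {
    rule$sourceCells <- .expandConstraint(rule$source)
    rule$tokens <- lapply(rule$target$tokens, function(tk) {
      foreignToken(rule$system,
                   site = if (is.null(tk$site)) NA_character_ else tk$site,
                   grade = if (is.null(tk$grade)) NA_integer_ else tk$grade,
                   flag = if (is.null(tk$flag)) NA_character_ else tk$flag,
                   configuration = if (is.null(tk$configuration))
                     NA_character_ else tk$configuration)
    })
  }
  rule
}

#' Path of the shipped crosswalk rule file
#'
#' @return Absolute path of `extdata/crosswalk-rules.json`.
#' @export
defaultRuleFile <- function() {
  system.file("extdata", "crosswalk-rules.json", package = "udise",
              mustWork = TRUE)
}

#' Load and validate a crosswalk rule base
#'
#' Reads a JSON rule file (by default the one shipped with the package),
#' validates every rule against the model vocabulary and the foreign-system
#' grammars, expands degree/configuration ranges into explicit cell sets and
#' derives the coverage map. Loading fails loudly on unknown codes, grades
#' out of range, duplicate rule ids or malformed records.
#'
#' Rule records carry: `id`, `system`, `direction` (`foreign_to_udise` or
#' `udise_to_foreign`), `source` (a foreign site/grade/configuration pattern
#' or a uDISE structure/degrees/configurations pattern), `target` (uDISE
#' `constraints` or foreign candidate `tokens`), `lossy`, an optional
#' `disjunction` marker (constraints are alternatives, not a conjunction),
#' the mapping equation as `notation`, and an optional free-text `note`.
#'
#' @param path Path to a rule file; defaults to the shipped base.
#' @return A [RuleBase-class].
#' @examples
#' rb <- defaultRuleBase()
#' rb
#' @export
loadRuleBase <- function(path = defaultRuleFile()) {
  if (!file.exists(path)) stop("rule file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path)
  if (is.null(doc$rules) || !length(doc$rules)) {
    stop("rule file has no rules: ", path, call. = FALSE)
  }
  ids <- vapply(doc$rules, function(r)
    if (is.null(r$id)) NA_character_ else r$id, character(1))
  if (anyNA(ids)) stop("rule without id in ", path, call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate rule id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  rules <- lapply(doc$rules, function(rule) {
    if (is.null(rule$system) || !rule$system %in% names(.SYSTEMS)) {
      stop("rule ", rule$id, ": unknown system ", deparse(rule$system),
           call. = FALSE)
    }
    if (is.null(rule$direction) ||
        !rule$direction %in% c("foreign_to_udise", "udise_to_foreign")) {
      stop("rule ", rule$id, ": bad direction", call. = FALSE)
    }
    if (rule$direction == "foreign_to_udise") {
      .checkForeignSide(rule$source, rule$system, rule$id)
      if (is.null(rule$target$constraints) ||
          !length(rule$target$constraints)) {
        stop("rule ", rule$id, ": empty target", call. = FALSE)
      }
      for (con in rule$target$constraints) .checkConstraint(con, rule$id)
    } else {
      .checkConstraint(rule$source, rule$id)
      if (is.null(rule$target$tokens) || !length(rule$target$tokens)) {
        stop("rule ", rule$id, ": empty token set", call. = FALSE)
      }
      .checkForeignSide(rule$target, rule$system, rule$id, tokens = TRUE)
    }
    .normaliseRule(rule)
  })
  names(rules) <- ids
  rb <- new("RuleBase", rules = rules,
            systems = sort(unique(vapply(rules, `[[`, character(1),
                                         "system"))),
            version = if (is.null(doc$format_version)) "unknown"
                      else doc$format_version,
            source = normalizePath(path), coverage = data.frame())
  rb@coverage <- .deriveCoverage(rb)
  rb
}

#' @rdname loadRuleBase
#' @export
defaultRuleBase <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- loadRuleBase(defaultRuleFile())
    cache
  }
})

#' Select rules by system and direction
#'
#' @param ruleBase A [RuleBase-class].
#' @param system One of `foreignSystems()`, or `NULL` for all.
#' @param direction `"foreign_to_udise"`, `"udise_to_foreign"` or `NULL`.
#' @return Named list of rule records in stable (file) order.
#' @examples
#' names(rulesFor(defaultRuleBase(), "PRINGLE", "foreign_to_udise"))
#' @export
rulesFor <- function(ruleBase, system = NULL, direction = NULL) {
  stopifnot(is(ruleBase, "RuleBase"))
  rules <- ruleBase@rules
  if (!is.null(system)) {
    .systemSpec(system)
    rules <- Filter(function(r) r$system == system, rules)
  }
  if (!is.null(direction)) {
    if (!direction %in% c("foreign_to_udise", "udise_to_foreign")) {
      stop("bad direction: ", direction, call. = FALSE)
    }
    rules <- Filter(function(r) r$direction == direction, rules)
  }
  rules
}

#' @rdname loadRuleBase
#' @param ruleBase A [RuleBase-class].
#' @export
ruleIds <- function(ruleBase) names(ruleBase@rules)

## The uDISE cell grid in reference-grid order: site (canonical), then
## configuration (AP, L, C restricted to the admissible set), then degree.
.cellGrid <- function() {
  rows <- do.call(rbind, lapply(.STRUCTURES$code, function(code) {
    allowed <- .ALLOWED_CONFIGS[[code]]
    if (!length(allowed)) {
      data.frame(structure = code, configuration = NA_character_,
                 degree = 0:2, stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(allowed, function(cfg)
        data.frame(structure = code, configuration = cfg, degree = 0:2,
                   stringsAsFactors = FALSE)))
    }
  }))
  rows[, c("structure", "degree", "configuration")]
}

## udise->foreign rules matching one uDISE cell. widen: a degree-0 finding
## without configuration matches every configuration variant.
.matchU2F <- function(ruleBase, system, structure, degree, configuration) {
  Filter(function(r) {
    if (r$direction != "udise_to_foreign" || r$system != system) return(FALSE)
    if (r$source$structure != structure) return(FALSE)
    sc <- r$sourceCells
    if (is.na(configuration) && degree == 0L) {
      any(sc$degree == 0L)                       # degree-0 widening
    } else {
      any(sc$degree == degree &
            (is.na(configuration) & is.na(sc$configuration) |
               !is.na(configuration) & !is.na(sc$configuration) &
               sc$configuration == configuration))
    }
  }, ruleBase@rules)
}

## Coverage of every uDISE cell by every system, derived from the
## udise->foreign rules alone: "covered" when a rule matches the cell
## exactly (no widening); "site_excluded" (grid marker X) when the system
## has no rule touching the structure at all; "config_excluded" (marker -)
## when the structure is touched but this degree/configuration is not.
.deriveCoverage <- function(ruleBase) {
  grid <- .cellGrid()
  out <- do.call(rbind, lapply(names(.SYSTEMS), function(sys) {
    u2f <- Filter(function(r) r$direction == "udise_to_foreign" &&
                    r$system == sys, ruleBase@rules)
    touched <- unique(vapply(u2f, function(r) r$source$structure,
                             character(1)))
    res <- grid
    res$system <- sys
    res$status <- NA_character_
    res$entry <- NA_character_
    for (i in seq_len(nrow(grid))) {
      st <- grid$structure[i]
      if (!st %in% touched) {
        res$status[i] <- "site_excluded"; res$entry[i] <- "X"
        next
      }
      matched <- .matchU2F(ruleBase, sys, st, grid$degree[i],
                           grid$configuration[i])
      if (!length(matched)) {
        res$status[i] <- "config_excluded"; res$entry[i] <- "-"
      } else {
        toks <- unique(unlist(lapply(matched, function(r)
          vapply(r$tokens, formatForeignToken, character(1)))))
        res$status[i] <- "covered"
        res$entry[i] <- paste(sort(toks), collapse = ",")
      }
    }
    res
  }))
  rownames(out) <- NULL
  out
}

#' Coverage map of a rule base
#'
#' One row per uDISE cell and foreign system, with `status` one of
#' `covered`, `site_excluded` (the system does not consider the site
#' anatomically; grid marker `X`) or `config_excluded` (the site is
#' considered but not this degree/configuration; marker `-`), and the
#' rendered foreign entry for covered cells.
#'
#' @param ruleBase A [RuleBase-class].
#' @return A data frame with columns `structure`, `degree`, `configuration`,
#'   `system`, `status`, `entry`.
#' @export
coverageMap <- function(ruleBase) {
  stopifnot(is(ruleBase, "RuleBase"))
  ruleBase@coverage
}

setMethod("show", "RuleBase", function(object) {
  byDir <- table(vapply(object@rules, `[[`, character(1), "direction"))
  cat(sprintf(paste0("RuleBase (format %s): %d rules across %d systems ",
                     "(%s)\n  foreign->udise: %d, udise->foreign: %d\n"),
              object@version, length(object@rules), length(object@systems),
              paste(object@systems, collapse = ", "),
              byDir[["foreign_to_udise"]], byDir[["udise_to_foreign"]]))
})
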