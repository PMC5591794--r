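#' @include engine.R
NULL

#' Regenerate the reference crosswalk grid
#'
#' Derives, purely from the rule base, the reference table relating every
#' uDISE cell (site, degree, configuration) to its counterpart in each of
#' the four foreign systems: the rendered candidate token(s), the marker
#' `X` where the system does not consider the site anatomically, or the
#' marker `-` where it considers the site but not this
#' degree/configuration. Rows follow the grid's enumeration order: site in
#' canonical order, then configuration (AP, L, C), then degree. The output
#' is a pure function of the rule base and is byte-identical across runs.
#'
#' @param ruleBase A [RuleBase-class].
#' @return A data frame with columns `structure`, `degree`,
#'   `configuration` and one column per system.
#' @examples
#' head(generateReferenceTable(defaultRuleBase()))
#' @export
generateReferenceTable <- function(ruleBase) {
  stopifnot(is(ruleBase, "RuleBase"))
  cov <- ruleBase@coverage
  grid <- .cellGrid()
  systems <- names(.SYSTEMS)
  for (sys in systems) {
    sub <- cov[cov$system == sys, ]
    key <- function(df) paste(df$structure, df$degree,
                              ifelse(is.na(df$configuration), "",
                                     df$configuration))
    grid[[sys]] <- sub$entry[match(key(grid), key(sub))]
  }
  rownames(grid) <- NULL
  grid
}

#' Write the reference grid to disk
#'
#' @param table A data frame from [generateReferenceTable()].
#' @param path Output file path.
#' @param format `"csv"` or `"text"` (aligned plain text).
#' @return `path`, invisibly.
#' @export
writeReferenceTable <- function(table, path, format = c("csv", "text")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(table, path, row.names = FALSE, quote = TRUE,
                     na = "")
  } else {
    tab <- table
    tab$configuration[is.na(tab$configuration)] <- ""
    widths <- vapply(names(tab), function(nm)
      max(nchar(c(nm, as.character(tab[[nm]]))), na.rm = TRUE), numeric(1))
    fmtRow <- function(vals) paste(mapply(formatC, as.character(vals),
                                          width = widths, flag = "-"),
                                   collapse = "  ")
    writeLines(c(fmtRow(names(tab)),
                 apply(tab, 1L, fmtRow)), path)
  }
  invisible(path)
}

#' Summarise a cohort of uDISE profiles
#'
#' @param profiles Nonempty list of [UdiseProfile-class] objects.
#' @return A list: `n`; `degreeCounts` (7 x 3 matrix, sites by degree);
#'   `severity` with `min`, `max`, `mean` and `histogram` (named counts over
#'   the observed severity indices); `multilevelCount`, the number of
#'   profiles with obstruction (degree >= 1) at two or more sites.
#' @examples
#' cohortSummary(list(parseUdise("N0V0Ts2LO0Tb2APE0L0")))
#' @export
cohortSummary <- function(profiles) {
  if (!is.list(profiles) || !length(profiles) ||
      !all(vapply(profiles, is, logical(1), "UdiseProfile"))) {
    stop("profiles must be a nonempty list of UdiseProfile objects",
         call. = FALSE)
  }
  degMat <- t(vapply(profiles, obstructionDegree, integer(7)))
  counts <- vapply(0:2, function(d) colSums(degMat == d), numeric(7))
  dimnames(counts) <- list(.STRUCTURES$code, as.character(0:2))
  sev <- rowSums(degMat)
  hist <- table(factor(sev, levels = 0:14))
  hist <- hist[hist > 0]
  list(
    n = length(profiles),
    degreeCounts = counts,
    severity = list(min = min(sev), max = max(sev), mean = mean(sev),
                    histogram = stats::setNames(as.integer(hist),
                                                names(hist))),
    multilevelCount = sum(rowSums(degMat >= 1L) >= 2L)
  )
}
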