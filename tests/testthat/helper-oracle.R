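# Shared helpers: the canonical valid-cell space, an exhaustive
# brute-force severity oracle independent of severityRange()'s analytic
# computation, and enumerators for profiles and foreign tokens.

# Canonical cells of one site: degree 0 without configuration; degrees 1-2
# with each admissible configuration (bare degrees at the nose and larynx).
canonicalCells <- function(code) {
  allowed <- allowedConfigurations(code)
  if (!length(allowed)) {
    return(data.frame(degree = 0:2, configuration = NA_character_,
                      stringsAsFactors = FALSE))
  }
  rbind(
    data.frame(degree = 0L, configuration = NA_character_),
    expand.grid(degree = 1:2, configuration = allowed,
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  )
}

# Full assignment space over all seven sites (46305 canonical profiles),
# built once per test run.
.assignmentSpace <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sts <- udiseStructures()$code
    cells <- lapply(sts, canonicalCells)
    names(cells) <- sts
    idx <- expand.grid(lapply(cells, function(df) seq_len(nrow(df))),
                       KEEP.OUT.ATTRS = FALSE)
    names(idx) <- sts
    degs <- vapply(sts, function(st) cells[[st]]$degree[idx[[st]]],
                   integer(nrow(idx)))
    cache <<- list(cells = cells, idx = idx, degrees = degs)
    cache
  }
})

# Which canonical cells of a site are consistent with a candidate set?
# Degree-0 widening applies: a bare degree-0 cell matches any degree-0
# candidate regardless of its configuration.
.cellsConsistent <- function(cells, cand) {
  vapply(seq_len(nrow(cells)), function(i) {
    d <- cells$degree[i]; cfg <- cells$configuration[i]
    any(cand$degree == d &
          (d == 0L |
             (!is.na(cand$configuration) & !is.na(cfg) &
                cand$configuration == cfg) |
             (is.na(cand$configuration) & is.na(cfg))))
  }, logical(1))
}

# Brute-force severity range: enumerate every canonical profile consistent
# with the result's constraints (hard candidate sets intersected per site;
# disjunction groups satisfied at one of their sites at least) and take the
# attained min/max of the severity index.
oracleSeverityRange <- function(result) {
  sp <- .assignmentSpace()
  sts <- udiseStructures()$code
  ok <- rep(TRUE, nrow(sp$idx))
  for (st in names(result@candidates)) {
    mask <- .cellsConsistent(sp$cells[[st]], result@candidates[[st]])
    ok <- ok & mask[sp$idx[[st]]]
  }
  for (g in result@disjunctions) {
    groupOk <- rep(FALSE, nrow(sp$idx))
    for (st in g$sites) {
      mask <- .cellsConsistent(sp$cells[[st]], g$candidates[[st]])
      groupOk <- groupOk | mask[sp$idx[[st]]]
    }
    ok <- ok & groupOk
  }
  sev <- rowSums(sp$degrees[ok, , drop = FALSE])
  c(min = as.integer(min(sev)), max = as.integer(max(sev)))
}

# Every fully specified token of a foreign system (the enumerable token
# space used by the property sweeps).
allForeignTokens <- function(system) {
  toks <- list()
  push <- function(t) toks[[length(toks) + 1L]] <<- t
  if (system == "PRINGLE") {
    for (g in 1:5) push(foreignToken("PRINGLE", grade = g))
  } else if (system == "VOTE") {
    for (site in c("V", "O", "T", "E")) {
      cfgs <- switch(site, V = c("AP", "L", "C"), O = "L", T = "AP",
                     E = c("AP", "L"))
      for (g in 0:2) for (cf in cfgs)
        push(foreignToken("VOTE", site = site, grade = g,
                          configuration = cf))
    }
  } else if (system == "NOHL") {
    for (g in 1:4) push(foreignToken("NOHL", site = "N", grade = g))
    for (cf in c("AP", "t", "C")) for (g in 1:4)
      push(foreignToken("NOHL", site = "O", grade = g, configuration = cf))
    for (cf in c("AP", "L", "C")) for (g in 1:4)
      push(foreignToken("NOHL", site = "H", grade = g, configuration = cf))
    for (g in 1:4) push(foreignToken("NOHL", site = "Ts", grade = g))
    for (f in c("N", "P")) push(foreignToken("NOHL", site = "L", flag = f))
  } else if (system == "PTLTBE") {
    for (site in c("P", "T", "L", "Tb")) for (g in 1:3)
      push(foreignToken("PTLTBE", site = site, grade = g))
    for (g in 1:2) push(foreignToken("PTLTBE", site = "E", grade = g))
  }
  toks
}

# Random valid profile under a fixed RNG state (caller seeds).
randomProfile <- function() {
  udiseProfile(lapply(udiseStructures()$code, function(code) {
    cells <- canonicalCells(code)
    i <- sample.int(nrow(cells), 1L)
    siteFinding(code, cells$degree[i], cells$configuration[i])
  }))
}

zeroProfile <- function() {
  udiseProfile(lapply(udiseStructures()$code, siteFinding, degree = 0))
}
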