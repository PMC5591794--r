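#!/usr/bin/env Rscript
## Regenerates inst/extdata/crosswalk-rules.json, the shipped crosswalk rule
## base: every published mapping equation between uDISE and the four foreign
## systems, as direction-specific declarative rules. Run from the package
## root: Rscript data-raw/make-crosswalk-rules.R

rules <- list()
add <- function(id, system, direction, source, target, lossy = FALSE,
                disjunction = FALSE, notation = NULL, note = NULL) {
  r <- list(id = id, system = system, direction = direction, source = source,
            target = target, lossy = lossy)
  if (disjunction) r$disjunction <- TRUE
  if (!is.null(notation)) r$notation <- notation
  if (!is.null(note)) r$note <- note
  rules[[length(rules) + 1L]] <<- r
}
cons <- function(structure, degrees, configurations = NULL) {
  x <- list(structure = structure, degrees = as.integer(degrees))
  if (!is.null(configurations)) x$configurations <- as.list(configurations)
  x
}
tok <- function(site = NULL, grade = NULL, flag = NULL,
                configuration = NULL) {
  x <- list()
  if (!is.null(site)) x$site <- site
  if (!is.null(configuration)) x$configuration <- configuration
  if (!is.null(grade)) x$grade <- as.integer(grade)
  if (!is.null(flag)) x$flag <- flag
  x
}
F2U <- "foreign_to_udise"; U2F <- "udise_to_foreign"
ALLC <- c("AP", "L", "C")

## ======================= foreign -> uDISE ==================================

## Pringle/Croft whole-exam grades. G1/G2 constrain velum AND tonsils; G3/G4
## constrain the oropharynx (the velum requirement is dropped by the
## oro-hypopharyngeal constraint); G5 constrains tongue base AND epiglottis.
add("PRINGLE.G1", "PRINGLE", F2U, list(grades = list(1L)),
    list(constraints = list(cons("V", 0:1, ALLC), cons("Ts", 0:1, "L"))),
    lossy = TRUE, notation = "G1 -> {V 0-1, AP/L/C} u {Ts 0-1, L}")
add("PRINGLE.G2", "PRINGLE", F2U, list(grades = list(2L)),
    list(constraints = list(cons("V", 2, ALLC), cons("Ts", 2, "L"))),
    lossy = TRUE, notation = "G2 -> {V 2, AP/L/C} u {Ts 2, L}")
add("PRINGLE.G3", "PRINGLE", F2U, list(grades = list(3L)),
    list(constraints = list(cons("O", 2, ALLC))),
    lossy = TRUE, notation = "G3 -> {O 2, AP/L/C}",
    note = "inspiration-phase distinction of G3 vs G4 not modelled")
add("PRINGLE.G4", "PRINGLE", F2U, list(grades = list(4L)),
    list(constraints = list(cons("O", 2, ALLC))),
    lossy = TRUE, notation = "G4 -> {O 2, AP/L/C}",
    note = "expiration-phase distinction of G3 vs G4 not modelled")
add("PRINGLE.G5", "PRINGLE", F2U, list(grades = list(5L)),
    list(constraints = list(cons("Tb", 0:2, ALLC), cons("E", 0:2,
                                                        c("AP", "L")))),
    lossy = TRUE, notation = "G5 -> {Tb 0-2, AP/L/C : E 0-2, AP/L}")

## VOTE: velum, tongue base and epiglottis map one-to-one on
## (degree, configuration); the oropharynx maps disjunctively to uDISE
## oropharynx OR tonsils (both lateral).
for (c in ALLC) for (d in 0:2) {
  add(sprintf("VOTE.V.%s.%d", c, d), "VOTE", F2U,
      list(site = "V", grades = list(d), configurations = list(c)),
      list(constraints = list(cons("V", d, c))),
      notation = sprintf("Vk %d %s -> {V %d, %s}", d, c, d, c))
}
for (d in 0:2) {
  add(sprintf("VOTE.O.%d", d), "VOTE", F2U,
      list(site = "O", grades = list(d), configurations = list("L")),
      list(constraints = list(cons("O", d, "L"), cons("Ts", d, "L"))),
      disjunction = TRUE, lossy = TRUE,
      notation = sprintf("Ok %d L -> {O %d, L} u {Ts %d, L}", d, d, d))
  add(sprintf("VOTE.T.%d", d), "VOTE", F2U,
      list(site = "T", grades = list(d), configurations = list("AP")),
      list(constraints = list(cons("Tb", d, "AP"))),
      notation = sprintf("Tk %d AP -> {Tb %d, AP}", d, d))
}
for (c in c("AP", "L")) for (d in 0:2) {
  add(sprintf("VOTE.E.%s.%d", c, d), "VOTE", F2U,
      list(site = "E", grades = list(d), configurations = list(c)),
      list(constraints = list(cons("E", d, c))),
      notation = sprintf("Ek %d %s -> {E %d, %s}", d, c, d, c))
}

## NOHL: quartile grades bucket onto uDISE degrees (1-2 -> 0, 3 -> 1,
## 4 -> 2) at the nose, oropharynx (transversal/concentric) and hypopharynx;
## tonsil hypertrophy grades 3-4 map to complete lateral tonsillar
## obstruction (grades 1-2 have no published mapping); the larynx flag maps
## to epiglottis constraints.
bucket <- list(list(g = c(1L, 2L), d = 0L), list(g = 3L, d = 1L),
               list(g = 4L, d = 2L))
for (b in bucket) {
  gl <- paste(b$g, collapse = "")
  add(sprintf("NOHL.N.%s", gl), "NOHL", F2U,
      list(site = "N", grades = as.list(b$g)),
      list(constraints = list(cons("N", b$d))),
      lossy = length(b$g) > 1L,
      notation = sprintf("Nv %s -> {N %d}", paste(b$g, collapse = "-"), b$d))
  add(sprintf("NOHL.Ot.%s", gl), "NOHL", F2U,
      list(site = "O", grades = as.list(b$g), configurations = list("t")),
      list(constraints = list(cons("O", b$d, "L"))),
      lossy = length(b$g) > 1L,
      notation = sprintf("Ov t %s -> {O %d, L}",
                         paste(b$g, collapse = "-"), b$d))
  add(sprintf("NOHL.Oc.%s", gl), "NOHL", F2U,
      list(site = "O", grades = as.list(b$g), configurations = list("C")),
      list(constraints = list(cons("O", b$d, "C"))),
      lossy = length(b$g) > 1L,
      notation = sprintf("Ov C %s -> {O %d, C}",
                         paste(b$g, collapse = "-"), b$d))
  add(sprintf("NOHL.Hap.%s", gl), "NOHL", F2U,
      list(site = "H", grades = as.list(b$g), configurations = list("AP")),
      list(constraints = list(cons("Tb", b$d, "AP"))),
      lossy = length(b$g) > 1L,
      notation = sprintf("Hv AP %s -> {Tb %d, AP}",
                         paste(b$g, collapse = "-"), b$d))
  add(sprintf("NOHL.Hl.%s", gl), "NOHL", F2U,
      list(site = "H", grades = as.list(b$g), configurations = list("L")),
      list(constraints = list(cons("Tb", b$d, "L"))),
      lossy = length(b$g) > 1L,
      notation = sprintf("Hv L %s -> {Tb %d, L}",
                         paste(b$g, collapse = "-"), b$d))
  add(sprintf("NOHL.Hc.%s", gl), "NOHL", F2U,
      list(site = "H", grades = as.list(b$g), configurations = list("C")),
      list(constraints = list(cons("Tb", b$d, "L"))),
      lossy = TRUE,
      notation = sprintf("Hv C %s -> {Tb %d, L}",
                         paste(b$g, collapse = "-"), b$d),
      note = paste("concentric hypopharynx maps to LATERAL tongue base,",
                   "as published; implemented verbatim"))
}
add("NOHL.Ts.34", "NOHL", F2U,
    list(site = "Ts", grades = list(3L, 4L)),
    list(constraints = list(cons("Ts", 2, "L"))), lossy = TRUE,
    notation = "Tsv 3-4 -> {Ts 2, L}",
    note = "tonsil grades 1-2 have no published mapping (unmapped_grade)")
add("NOHL.LN", "NOHL", F2U, list(site = "L", flags = list("N")),
    list(constraints = list(cons("E", 0, c("AP", "L")))), lossy = TRUE,
    notation = "Lv N -> {E 0, AP} / {E 0, L}")
add("NOHL.LP", "NOHL", F2U, list(site = "L", flags = list("P")),
    list(constraints = list(cons("E", 1:2, c("AP", "L")))), lossy = TRUE,
    notation = "Lv P -> {E 1-2, AP} / {E 1-2, L}")

## P-T-L-Tb-E: palate grades split over AP/concentric velum; tonsils,
## lateral wall and tongue base shift grade g to degree g-1; epiglottis
## grade 2 is ambiguous over degrees 1-2.
add("PTLTBE.P.1", "PTLTBE", F2U, list(site = "P", grades = list(1L)),
    list(constraints = list(cons("V", 0, c("AP", "C")))), lossy = TRUE,
    notation = "Pv 1 -> {V 0, AP/C}")
add("PTLTBE.P.2", "PTLTBE", F2U, list(site = "P", grades = list(2L)),
    list(constraints = list(cons("V", 1:2, "AP"))), lossy = TRUE,
    notation = "Pv 2 -> {V 1-2, AP}")
add("PTLTBE.P.3", "PTLTBE", F2U, list(site = "P", grades = list(3L)),
    list(constraints = list(cons("V", 1:2, "C"))), lossy = TRUE,
    notation = "Pv 3 -> {V 1-2, C}")
for (g in 1:3) {
  add(sprintf("PTLTBE.T.%d", g), "PTLTBE", F2U,
      list(site = "T", grades = list(g)),
      list(constraints = list(cons("Ts", g - 1L, "L"))),
      notation = sprintf("Tv %d -> {Ts %d, L}", g, g - 1L))
  add(sprintf("PTLTBE.L.%d", g), "PTLTBE", F2U,
      list(site = "L", grades = list(g)),
      list(constraints = list(cons("O", g - 1L, "L"))),
      notation = sprintf("Lv %d -> {O %d, L}", g, g - 1L))
  add(sprintf("PTLTBE.Tb.%d", g), "PTLTBE", F2U,
      list(site = "Tb", grades = list(g)),
      list(constraints = list(cons("Tb", g - 1L, "AP"))),
      notation = sprintf("Tbv %d -> {Tb %d, AP}", g, g - 1L))
}
add("PTLTBE.E.1", "PTLTBE", F2U, list(site = "E", grades = list(1L)),
    list(constraints = list(cons("E", 0, "AP"))),
    notation = "Ev 1 -> {E 0, AP}")
add("PTLTBE.E.2", "PTLTBE", F2U, list(site = "E", grades = list(2L)),
    list(constraints = list(cons("E", 1:2, "AP"))), lossy = TRUE,
    notation = "Ev 2 -> {E 1-2, AP}")

## ======================= uDISE -> foreign ==================================

usrc <- function(structure, degrees, configurations = NULL)
  cons(structure, degrees, configurations)
toks <- function(...) list(tokens = list(...))

## --- uDISE -> PRINGLE
add("U2.PRINGLE.V.01", "PRINGLE", U2F, usrc("V", 0:1, ALLC),
    toks(tok(grade = 1)), lossy = TRUE,
    notation = "{V 0-1, AP/L/C} -> G1")
add("U2.PRINGLE.V.2", "PRINGLE", U2F, usrc("V", 2, ALLC),
    toks(tok(grade = 2)), lossy = TRUE, notation = "{V 2, AP/L/C} -> G2")
add("U2.PRINGLE.Ts.01", "PRINGLE", U2F, usrc("Ts", 0:1, "L"),
    toks(tok(grade = 1)), lossy = TRUE, notation = "{Ts 0-1, L} -> G1")
add("U2.PRINGLE.Ts.2", "PRINGLE", U2F, usrc("Ts", 2, "L"),
    toks(tok(grade = 2)), lossy = TRUE, notation = "{Ts 2, L} -> G2")
add("U2.PRINGLE.O.2", "PRINGLE", U2F, usrc("O", 2, ALLC),
    toks(tok(grade = 3), tok(grade = 4)), lossy = TRUE,
    notation = "{O 2, AP/L/C} -> G3 | G4",
    note = "G3/G4 differ only by respiratory phase, which uDISE drops")
add("U2.PRINGLE.Tb", "PRINGLE", U2F, usrc("Tb", 0:2, ALLC),
    toks(tok(grade = 5)), lossy = TRUE, notation = "{Tb 0-2, AP/L/C} -> G5")
add("U2.PRINGLE.E", "PRINGLE", U2F, usrc("E", 0:2, c("AP", "L")),
    toks(tok(grade = 5)), lossy = TRUE, notation = "{E 0-2, AP/L} -> G5")

## --- uDISE -> VOTE (identity on covered cells; Ts folds onto Ok)
for (c in ALLC) for (d in 0:2) {
  add(sprintf("U2.VOTE.V.%s.%d", c, d), "VOTE", U2F, usrc("V", d, c),
      toks(tok(site = "V", grade = d, configuration = c)),
      notation = sprintf("{V %d, %s} -> Vk %d %s", d, c, d, c))
}
for (d in 0:2) {
  add(sprintf("U2.VOTE.Ts.%d", d), "VOTE", U2F, usrc("Ts", d, "L"),
      toks(tok(site = "O", grade = d, configuration = "L")), lossy = TRUE,
      notation = sprintf("{Ts %d, L} -> Ok %d L", d, d),
      note = "tonsils and lateral wall are one VOTE level")
  add(sprintf("U2.VOTE.O.%d", d), "VOTE", U2F, usrc("O", d, "L"),
      toks(tok(site = "O", grade = d, configuration = "L")), lossy = TRUE,
      notation = sprintf("{O %d, L} -> Ok %d L", d, d))
  add(sprintf("U2.VOTE.Tb.%d", d), "VOTE", U2F, usrc("Tb", d, "AP"),
      toks(tok(site = "T", grade = d, configuration = "AP")),
      notation = sprintf("{Tb %d, AP} -> Tk %d AP", d, d))
}
for (c in c("AP", "L")) for (d in 0:2) {
  add(sprintf("U2.VOTE.E.%s.%d", c, d), "VOTE", U2F, usrc("E", d, c),
      toks(tok(site = "E", grade = d, configuration = c)),
      notation = sprintf("{E %d, %s} -> Ek %d %s", d, c, d, c))
}

## --- uDISE -> NOHL
## Degrees expand back to quartile-grade buckets; the uDISE velum maps to
## the NOHL oropharynx (palatal level) in the matching configuration
## (lateral velum -> transversal); tongue base maps to the hypopharynx
## (concentric included, mirroring the reference grid, although the reverse
## direction folds concentric onto lateral); epiglottis and larynx both map
## to the larynx negative/positive flag.
nohlGrades <- function(d) if (d == 0L) list(1L, 2L) else list(d + 2L)
gradeToks <- function(site, cfg, d) {
  do.call(toks, lapply(nohlGrades(d), function(g)
    tok(site = site, grade = g,
        configuration = if (is.null(cfg)) NULL else cfg)))
}
for (d in 0:2) {
  add(sprintf("U2.NOHL.N.%d", d), "NOHL", U2F, usrc("N", d),
      gradeToks("N", NULL, d), lossy = d == 0L,
      notation = sprintf("{N %d} -> Nv %s", d,
                         paste(unlist(nohlGrades(d)), collapse = "-")))
}
vmap <- c(AP = "AP", L = "t", C = "C")
for (c in ALLC) for (d in 0:2) {
  add(sprintf("U2.NOHL.V.%s.%d", c, d), "NOHL", U2F, usrc("V", d, c),
      gradeToks("O", vmap[[c]], d), lossy = d == 0L,
      notation = sprintf("{V %d, %s} -> Ov %s %s", d, c, vmap[[c]],
                         paste(unlist(nohlGrades(d)), collapse = "-")))
}
add("U2.NOHL.Ts.2", "NOHL", U2F, usrc("Ts", 2, "L"),
    toks(tok(site = "Ts", grade = 3), tok(site = "Ts", grade = 4)),
    lossy = TRUE, notation = "{Ts 2, L} -> Tsv 3 | Tsv 4",
    note = "tonsil degrees 0-1 have no NOHL counterpart")
omap <- c(L = "t", C = "C")
for (c in c("L", "C")) for (d in 0:2) {
  add(sprintf("U2.NOHL.O.%s.%d", c, d), "NOHL", U2F, usrc("O", d, c),
      gradeToks("O", omap[[c]], d), lossy = d == 0L,
      notation = sprintf("{O %d, %s} -> Ov %s %s", d, c, omap[[c]],
                         paste(unlist(nohlGrades(d)), collapse = "-")))
}
for (c in ALLC) for (d in 0:2) {
  add(sprintf("U2.NOHL.Tb.%s.%d", c, d), "NOHL", U2F, usrc("Tb", d, c),
      gradeToks("H", c, d), lossy = d == 0L,
      notation = sprintf("{Tb %d, %s} -> Hv %s %s", d, c, c,
                         paste(unlist(nohlGrades(d)), collapse = "-")))
}
for (c in c("AP", "L")) for (d in 0:2) {
  add(sprintf("U2.NOHL.E.%s.%d", c, d), "NOHL", U2F, usrc("E", d, c),
      toks(tok(site = "L", flag = if (d == 0L) "N" else "P")), lossy = TRUE,
      notation = sprintf("{E %d, %s} -> Lv %s", d, c,
                         if (d == 0L) "N" else "P"))
}
for (d in 0:2) {
  add(sprintf("U2.NOHL.L.%d", d), "NOHL", U2F, usrc("L", d),
      toks(tok(site = "L", flag = if (d == 0L) "N" else "P")), lossy = TRUE,
      notation = sprintf("{L %d} -> Lv %s", d, if (d == 0L) "N" else "P"))
}

## --- uDISE -> P-T-L-Tb-E
pmap <- list(AP = c(1L, 2L, 2L), C = c(1L, 3L, 3L))
for (c in c("AP", "C")) for (d in 0:2) {
  add(sprintf("U2.PTLTBE.V.%s.%d", c, d), "PTLTBE", U2F, usrc("V", d, c),
      toks(tok(site = "P", grade = pmap[[c]][d + 1L])), lossy = d > 0L,
      notation = sprintf("{V %d, %s} -> Pv %d", d, c, pmap[[c]][d + 1L]))
}
for (d in 0:2) {
  add(sprintf("U2.PTLTBE.Ts.%d", d), "PTLTBE", U2F, usrc("Ts", d, "L"),
      toks(tok(site = "T", grade = d + 1L)),
      notation = sprintf("{Ts %d, L} -> Tv %d", d, d + 1L))
  add(sprintf("U2.PTLTBE.O.%d", d), "PTLTBE", U2F, usrc("O", d, "L"),
      toks(tok(site = "L", grade = d + 1L)),
      notation = sprintf("{O %d, L} -> Lv %d", d, d + 1L))
  add(sprintf("U2.PTLTBE.Tb.%d", d), "PTLTBE", U2F, usrc("Tb", d, "AP"),
      toks(tok(site = "Tb", grade = d + 1L)),
      notation = sprintf("{Tb %d, AP} -> Tbv %d", d, d + 1L))
  add(sprintf("U2.PTLTBE.E.%d", d), "PTLTBE", U2F, usrc("E", d, "AP"),
      toks(tok(site = "E", grade = if (d == 0L) 1L else 2L)),
      lossy = d > 0L,
      notation = sprintf("{E %d, AP} -> Ev %d", d, if (d == 0L) 1L else 2L))
}

doc <- list(
  format_version = "1.0",
  description = paste("Crosswalk rule base between the uDISE model and the",
                      "Pringle/Croft, VOTE, NOHL and P-T-L-Tb-E DISE",
                      "classification systems."),
  systems = c("PRINGLE", "VOTE", "NOHL", "PTLTBE"),
  rules = rules
)
out <- "inst/extdata/crosswalk-rules.json"
jsonlite::write_json(doc, out, auto_unbox = TRUE, digits = NA)
cat("wrote", out, "with", length(rules), "rules\n")
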