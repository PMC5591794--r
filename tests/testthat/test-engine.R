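rb <- defaultRuleBase()

test_that("foreign findings convert to the published uDISE candidates", {
  # VOTE oropharynx: disjunctively oropharynx OR tonsils, both lateral
  res <- toUdise(foreignToken("VOTE", site = "O", grade = 2,
                              configuration = "L"), rb)
  expect_identical(conversionFlags(res)[["O"]], "ambiguous")
  expect_identical(conversionFlags(res)[["Ts"]], "ambiguous")
  expect_identical(candidates(res, "O"),
                   data.frame(degree = 2L, configuration = "L"),
                   ignore_attr = TRUE)
  expect_identical(candidates(res, "Ts")$degree, 2L)
  expect_length(res@disjunctions, 1)

  # NOHL transversal oropharynx grade 4 -> complete lateral oropharynx
  res <- toUdise(parseForeign("NOHL", "Ot4"), rb)
  expect_identical(conversionFlags(res)[["O"]], "exact")
  expect_identical(candidates(res, "O")$degree, 2L)
  expect_identical(candidates(res, "O")$configuration, "L")

  # NOHL nose grade 3 -> partial nasal obstruction
  res <- toUdise(parseForeign("NOHL", "N3"), rb)
  expect_identical(conversionFlags(res)[["N"]], "exact")
  expect_identical(candidates(res, "N")$degree, 1L)

  # Pringle G5 constrains tongue base and epiglottis, ambiguous
  res <- toUdise(parseForeign("PRINGLE", "G5"), rb)
  expect_identical(nrow(candidates(res, "Tb")), 9L)   # 0-2 x AP/L/C
  expect_identical(nrow(candidates(res, "E")), 6L)    # 0-2 x AP/L
  expect_identical(conversionFlags(res)[["Tb"]], "ambiguous")
  expect_setequal(unconstrainedSites(res), c("N", "V", "Ts", "O", "L"))

  # PTLTBE epiglottis grade 2 is ambiguous over degrees 1-2
  res <- toUdise(parseForeign("PTLTBE", "E2"), rb)
  expect_identical(candidates(res, "E")$degree, 1:2)
  expect_identical(unique(candidates(res, "E")$configuration), "AP")
})

test_that("every single-token conversion yields model-valid candidates", {
  for (sys in foreignSystems()) {
    for (tok in allForeignTokens(sys)) {
      res <- toUdise(tok, rb)
      cand <- candidates(res)
      for (st in names(cand)) {
        df <- cand[[st]]
        for (i in seq_len(nrow(df))) {
          verdict <- validateFinding(st, df$degree[i], df$configuration[i])
          expect_true(verdict$ok,
                      info = sprintf("%s %s -> %s (%d,%s)", sys,
                                     formatForeignToken(tok), st,
                                     df$degree[i], df$configuration[i]))
        }
      }
    }
  }
})

test_that("unmapped grades are flagged and constrain nothing", {
  res <- toUdise(parseForeign("NOHL", "Ts1"), rb)
  expect_identical(unname(conversionFlags(res)["Ts1"]), "unmapped_grade")
  expect_identical(unconstrainedSites(res), udiseStructures()$code)
  # NOHL oropharynx AP has no published forward mapping either
  res <- toUdise(parseForeign("NOHL", "OAP3"), rb)
  expect_identical(unname(conversionFlags(res)["OAP3"]), "unmapped_grade")
})

test_that("multi-token conversion intersects per site and reports
           contradictions", {
  # degree-0 widening: a bare VOTE Vk0 matches all configuration variants
  res <- toUdise(parseForeign("VOTE", "Vk0"), rb)
  expect_identical(nrow(candidates(res, "V")), 3L)
  expect_identical(unique(candidates(res, "V")$degree), 0L)

  # consistent tokens: full VOTE exam
  res <- toUdise(parseForeign("VOTE", "Vk2AP Ok1L Tk2AP Ek0"), rb)
  expect_identical(candidates(res, "V")$degree, 2L)
  expect_identical(candidates(res, "Tb")$degree, 2L)
  expect_identical(nrow(candidates(res, "E")), 2L)    # Ek0 widened

  # contradictory tokens at one site
  expect_error(
    toUdise(parseForeign("VOTE", "Vk1AP Vk2AP"), rb),
    class = "udiseContradiction")
  err <- tryCatch(toUdise(parseForeign("VOTE", "Vk1AP Vk2AP"), rb),
                  error = identity)
  expect_match(conditionMessage(err), "site V")
  expect_true(all(c("VOTE.V.AP.1", "VOTE.V.AP.2") %in% err$rules))

  expect_error(
    toUdise(list(foreignToken("VOTE", site = "V", grade = 1,
                              configuration = "AP"),
                 foreignToken("PRINGLE", grade = 1)), rb),
    "mixed systems")
})

test_that("uDISE profiles convert to published foreign candidates", {
  p <- function(d, cfg = character(0)) profileFromDegrees(d, cfg)

  res <- fromUdise(p(c(V = 1), c(V = "AP")), "VOTE", rb)
  expect_identical(foreignCandidates(res, "V"), "Vk1AP")
  expect_identical(conversionFlags(res)[["V"]], "exact")

  res <- fromUdise(p(c(O = 2), c(O = "L")), "PRINGLE", rb)
  expect_setequal(foreignCandidates(res, "O"), c("G3", "G4"))
  expect_identical(conversionFlags(res)[["O"]], "ambiguous")

  res <- fromUdise(p(c(V = 1), c(V = "AP")), "NOHL", rb)
  expect_identical(foreignCandidates(res, "V"), "OAP3")

  res <- fromUdise(p(c(N = 1)), "PRINGLE", rb)
  expect_identical(conversionFlags(res)[["N"]], "site_excluded")

  res <- fromUdise(p(c(Tb = 2), c(Tb = "L")), "PTLTBE", rb)
  expect_identical(conversionFlags(res)[["Tb"]], "config_excluded")

  # degree-0 widening on the way out
  res <- fromUdise(zeroProfile(), "NOHL", rb)
  expect_setequal(foreignCandidates(res, "V"),
                  c("OAP1", "OAP2", "Ot1", "Ot2", "OC1", "OC2"))
})

test_that("severity ranges follow the candidate structure", {
  # exact single site, rest unconstrained
  res <- toUdise(parseForeign("NOHL", "Ot4"), rb)
  expect_identical(severityRange(res), c(min = 2L, max = 14L))
  # full NOHL exam pinning every site
  res <- toUdise(parseForeign("NOHL", "N1 Ot4 HAP4 Ts3 LP"), rb)
  rng <- severityRange(res)
  # N=0, Ts=O=Tb=2, E in 1..2, velum and larynx free in 0..2
  expect_identical(unname(rng), c(7L, 12L))
  expect_identical(unname(rng), unname(oracleSeverityRange(res)))
})

test_that("severity ranges agree with brute-force enumeration", {
  # spot-check here; the exhaustive sweep lives in the acceptance suite
  toks <- list(parseForeign("PRINGLE", "G5")[[1]],
               parseForeign("VOTE", "Ok2L")[[1]],
               parseForeign("NOHL", "LP")[[1]],
               parseForeign("PTLTBE", "P2")[[1]])
  for (tok in toks) {
    res <- toUdise(tok, rb)
    expect_identical(unname(severityRange(res)),
                     unname(oracleSeverityRange(res)),
                     info = formatForeignToken(tok))
  }
  # Pringle G5 leaves the full 0..14 range attainable
  expect_identical(
    unname(severityRange(toUdise(parseForeign("PRINGLE", "G5"), rb))),
    c(0L, 14L))
})

test_that("round trips are contained for VOTE and P-T-L-Tb-E but the NOHL
           velum asymmetry is not", {
  p <- profileFromDegrees(c(V = 1), c(V = "AP"))
  expect_true(roundTripContainment(p, "VOTE", rb)$contained)
  expect_true(roundTripContainment(p, "PTLTBE", rb)$contained)
  nohl <- roundTripContainment(p, "NOHL", rb)
  expect_false(nohl$perSite[["V"]])
  expect_true(roundTripContainment(zeroProfile(), "PTLTBE", rb)$contained)
})

test_that("conversion results serialize with stable field names", {
  res <- toUdise(parseForeign("VOTE", "Ok2L"), rb)
  lst <- conversionToList(res)
  expect_setequal(names(lst),
                  c("direction", "system", "source", "candidates",
                    "disjunctions", "foreign_candidates", "unconstrained",
                    "flags", "provenance"))
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE)
  expect_true(jsonlite::validate(js))
})
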