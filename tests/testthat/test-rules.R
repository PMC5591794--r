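rb <- defaultRuleBase()

test_that("the shipped rule base loads, expanded and validated", {
  expect_s4_class(rb, "RuleBase")
  expect_setequal(rb@systems, c("PRINGLE", "VOTE", "NOHL", "PTLTBE"))
  expect_false(anyDuplicated(ruleIds(rb)) > 0)
  # ranges are expanded to explicit cells at load time
  g1 <- rulesFor(rb, "PRINGLE", "foreign_to_udise")[["PRINGLE.G1"]]
  vCells <- g1$cells[[1]]$cells
  expect_identical(nrow(vCells), 6L)          # degrees 0-1 x AP/L/C
  expect_setequal(unique(vCells$degree), 0:1)
})

test_that("rule selection is direction- and system-specific", {
  voteF2U <- rulesFor(rb, "VOTE", "foreign_to_udise")
  expect_true("VOTE.O.2" %in% names(voteF2U))
  # the oropharynx rule constrains O and Ts disjunctively
  expect_true(voteF2U[["VOTE.O.2"]]$disjunction)
  expect_setequal(
    vapply(voteF2U[["VOTE.O.2"]]$cells, `[[`, character(1), "structure"),
    c("O", "Ts"))

  nohlU2F <- rulesFor(rb, "NOHL", "udise_to_foreign")
  r <- nohlU2F[["U2.NOHL.V.AP.1"]]
  expect_identical(r$source$structure, "V")
  expect_identical(formatForeignToken(r$tokens[[1]]), "OAP3")

  ptF2U <- rulesFor(rb, "PTLTBE", "foreign_to_udise")
  p3 <- ptF2U[["PTLTBE.P.3"]]
  expect_identical(p3$cells[[1]]$structure, "V")
  expect_setequal(p3$cells[[1]]$cells$degree, 1:2)
  expect_identical(unique(p3$cells[[1]]$cells$configuration), "C")

  expect_error(rulesFor(rb, "OTHER"), "unknown classification system")
})

test_that("malformed rule files fail loudly at load", {
  writeBase <- function(rules) {
    path <- tempfile(fileext = ".json")
    jsonlite::write_json(list(format_version = "1.0", rules = rules),
                         path, auto_unbox = TRUE)
    path
  }
  okRule <- list(id = "X.1", system = "VOTE",
                 direction = "foreign_to_udise",
                 source = list(site = "V", grades = list(1),
                               configurations = list("AP")),
                 target = list(constraints = list(
                   list(structure = "V", degrees = list(1),
                        configurations = list("AP")))))
  expect_s4_class(loadRuleBase(writeBase(list(okRule))), "RuleBase")

  badGrade <- okRule; badGrade$source$grades <- list(5)
  expect_error(loadRuleBase(writeBase(list(badGrade))), "grade outside")

  badStructure <- okRule
  badStructure$target$constraints[[1]]$structure <- "Q"
  expect_error(loadRuleBase(writeBase(list(badStructure))),
               "unknown structure")

  badConfig <- okRule
  badConfig$target$constraints[[1]]$configurations <- list("AP", "C")
  badConfig$target$constraints[[1]]$structure <- "Ts"
  expect_error(loadRuleBase(writeBase(list(badConfig))), "not allowed")

  expect_error(loadRuleBase(writeBase(list(okRule, okRule))),
               "duplicate rule id")
  expect_error(loadRuleBase(writeBase(list())), "no rules")
  expect_error(loadRuleBase("/nonexistent/rules.json"), "not found")
})

test_that("VOTE velum/tongue-base/epiglottis rules are one-to-one;
           only the oropharynx is one-to-many", {
  for (r in rulesFor(rb, "VOTE", "foreign_to_udise")) {
    if (r$disjunction) {
      expect_identical(r$source$site, "O")
      next
    }
    cellCount <- sum(vapply(r$cells, function(con) nrow(con$cells),
                            integer(1)))
    expect_identical(cellCount, 1L)
  }
})

test_that("NOHL grade bucketing is monotone at fixed site/configuration", {
  combos <- list(list(site = "N", cfg = NA), list(site = "O", cfg = "t"),
                 list(site = "O", cfg = "C"), list(site = "H", cfg = "AP"),
                 list(site = "H", cfg = "L"), list(site = "H", cfg = "C"),
                 list(site = "Ts", cfg = NA))
  for (cb in combos) {
    prevMin <- prevMax <- -1L
    for (g in 1:4) {
      tok <- foreignToken("NOHL", site = cb$site, grade = g,
                          configuration = if (is.na(cb$cfg)) NA else cb$cfg)
      res <- toUdise(tok, rb)
      cand <- candidates(res, if (cb$site == "N") "N"
                              else if (cb$site == "O") "O"
                              else if (cb$site == "H") "Tb" else "Ts")
      if (!nrow(cand)) next                    # unmapped grade (Ts 1-2)
      expect_gte(min(cand$degree), prevMin)
      expect_gte(max(cand$degree), prevMax)
      prevMin <- min(cand$degree); prevMax <- max(cand$degree)
    }
  }
})

test_that("coverage map statuses partition the cell grid per system", {
  cov <- coverageMap(rb)
  expect_identical(nrow(cov), 42L * 4L)
  expect_setequal(unique(cov$status),
                  c("covered", "site_excluded", "config_excluded"))
  # nose and larynx: only NOHL considers them
  for (sys in c("PRINGLE", "VOTE", "PTLTBE")) {
    sub <- cov[cov$system == sys & cov$structure %in% c("N", "L"), ]
    expect_true(all(sub$status == "site_excluded"))
  }
  nohlNose <- cov[cov$system == "NOHL" & cov$structure == "N", ]
  expect_true(all(nohlNose$status == "covered"))
})
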