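test_that("simulation configs validate their probabilities", {
  expect_s3_class(simulationConfig(10), "SimulationConfig")
  expect_error(simulationConfig(0), "positive integer")
  expect_error(simulationConfig(10, degreeProbs = list(V = c(0.5, 0.5))),
               "triple")
  expect_error(simulationConfig(10, degreeProbs = list(V = c(0.5, 0.4, 0.2))),
               "summing to 1")
  expect_error(
    simulationConfig(10, configProbs = list(Ts = c(AP = 1))),
    "cover exactly")
})

test_that("degenerate configurations pin the severity index", {
  allZero <- simulateCohort(
    simulationConfig(20, seed = 3,
                     degreeProbs = stats::setNames(
                       rep(list(c(1, 0, 0)), 7), udiseStructures()$code)))
  expect_true(all(vapply(allZero, severityIndex, integer(1)) == 0L))

  allTwo <- simulateCohort(
    simulationConfig(20, seed = 3,
                     degreeProbs = stats::setNames(
                       rep(list(c(0, 0, 1)), 7), udiseStructures()$code)))
  expect_true(all(vapply(allTwo, severityIndex, integer(1)) == 14L))
})

test_that("simulated profiles are valid and seed-deterministic", {
  cfg <- simulationConfig(50, seed = 11)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(vapply(a, formatUdise, character(1)),
                   vapply(b, formatUdise, character(1)))
  c2 <- simulateCohort(simulationConfig(50, seed = 12))
  expect_false(identical(vapply(a, formatUdise, character(1)),
                         vapply(c2, formatUdise, character(1))))
  for (p in a) {
    for (f in profileFindings(p)) {
      expect_true(validateFinding(f)$ok)
      if (obstructionDegree(f) == 0L) {
        expect_true(is.na(obstructionConfiguration(f)))
      }
    }
  }
})

test_that("mean severity tracks the closed-form expectation", {
  # E[severity] = 7 * (p1 + 2 p2) with the default (0.5, 0.3, 0.2)
  cohort <- simulateCohort(simulationConfig(2000, seed = 5))
  sev <- vapply(cohort, severityIndex, integer(1))
  expected <- 7 * (0.3 + 2 * 0.2)
  siteVar <- (0.3 + 4 * 0.2) - (0.3 + 2 * 0.2)^2
  se <- sqrt(7 * siteVar / 2000)
  expect_lt(abs(mean(sev) - expected), 3 * se)
})

test_that("worked examples parse to their recorded severities", {
  ex <- workedExamples()
  for (i in seq_len(nrow(ex))) {
    expect_identical(severityIndex(parseUdise(ex$score[i])),
                     ex$severity[i], info = ex$name[i])
  }
})
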