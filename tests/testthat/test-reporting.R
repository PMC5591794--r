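rb <- defaultRuleBase()

test_that("the regenerated grid matches the hand-encoded fixture cell by
           cell", {
  gen <- generateReferenceTable(rb)
  fix <- referenceGridFixture()
  expect_identical(dim(gen), dim(fix))
  expect_identical(names(gen), names(fix))
  for (sys in foreignSystems()) {
    for (i in seq_len(nrow(gen))) {
      expect_identical(
        gen[[sys]][i], fix[[sys]][i],
        info = sprintf("cell (%s, %d, %s) x %s", gen$structure[i],
                       gen$degree[i],
                       ifelse(is.na(gen$configuration[i]), "-",
                              gen$configuration[i]), sys))
    }
  }
})

test_that("specific grid rows carry the published entries and markers", {
  gen <- generateReferenceTable(rb)
  row <- function(st, d, cfg) {
    hit <- gen$structure == st & gen$degree == d &
      (is.na(gen$configuration) & is.na(cfg) |
         !is.na(gen$configuration) & !is.na(cfg) & gen$configuration == cfg)
    gen[hit, ]
  }
  r <- row("V", 2, "C")
  expect_identical(r$PRINGLE, "G2")
  expect_identical(r$VOTE, "Vk2C")
  expect_identical(r$NOHL, "OC4")
  expect_identical(r$PTLTBE, "P3")

  r <- row("N", 2, NA)
  expect_identical(r$PRINGLE, "X")
  expect_identical(r$VOTE, "X")
  expect_identical(r$NOHL, "N4")
  expect_identical(r$PTLTBE, "X")

  r <- row("Tb", 1, "L")
  expect_identical(r$PRINGLE, "G5")
  expect_identical(r$VOTE, "-")
  expect_identical(r$NOHL, "HL3")
  expect_identical(r$PTLTBE, "-")
})

test_that("grid generation is deterministic", {
  t1 <- generateReferenceTable(rb)
  t2 <- generateReferenceTable(loadRuleBase(defaultRuleFile()))
  expect_identical(t1, t2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeReferenceTable(t1, f1); writeReferenceTable(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("cohort summaries count degrees, severities and multilevel
           obstruction", {
  s <- cohortSummary(list(zeroProfile()))
  expect_identical(s$severity$histogram, c(`0` = 1L))
  expect_identical(s$multilevelCount, 0L)

  p <- parseUdise("N0V0Ts2LO0Tb2APE0L0")
  s <- cohortSummary(list(p))
  expect_identical(s$multilevelCount, 1L)
  expect_identical(s$severity$mean, 4)
  expect_identical(s$degreeCounts["Ts", "2"], 1)

  cohort <- simulateCohort(simulationConfig(100, seed = 7))
  s <- cohortSummary(cohort)
  expect_identical(sum(s$severity$histogram), 100L)
  expect_identical(unname(rowSums(s$degreeCounts)), rep(100, 7))

  expect_error(cohortSummary(list()), "nonempty")
})
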