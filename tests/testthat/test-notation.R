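test_that("worked score strings parse to the expected findings", {
  p <- parseUdise("N0V0Ts2LO0Tb2APE0L0")
  expect_identical(obstructionDegree(p)[["Ts"]], 2L)
  expect_identical(obstructionConfiguration(p)[["Ts"]], "L")
  expect_identical(obstructionDegree(p)[["Tb"]], 2L)
  expect_identical(obstructionConfiguration(p)[["Tb"]], "AP")
  expect_identical(sum(obstructionDegree(p)), 4L)

  p2 <- parseUdise("N0V1APTs0O0Tb0E0L0")
  expect_identical(obstructionDegree(p2)[["V"]], 1L)
  expect_identical(obstructionConfiguration(p2)[["V"]], "AP")

  p3 <- parseUdise("N0V0Ts1LO0Tb0E0L0")
  expect_identical(obstructionDegree(p3)[["Ts"]], 1L)
})

test_that("separated typography parses identically to the compact form", {
  compact <- "N0V0Ts2LO0Tb2APE0L0"
  for (txt in c("N_0_V_0_Ts_2L_O_0_Tb_2AP_E_0_L_0_",
                "N0 V0 Ts2L O0 Tb2AP E0 L0",
                "N0-V0-Ts2L-O0-Tb2AP-E0-L0")) {
    expect_identical(formatUdise(parseUdise(txt)),
                     formatUdise(parseUdise(compact)))
  }
})

test_that("the epiglottis/larynx 'L' ambiguity resolves by lookahead", {
  # E2 followed by larynx: the trailing L is the larynx site, not a config
  p <- parseUdise("N0V0Ts0O0Tb0E2APL0")
  expect_identical(obstructionConfiguration(p)[["E"]], "AP")
  # lateral epiglottic fold then larynx: E2L + L0
  p2 <- parseUdise("N0V0Ts0O0Tb0E2LL1")
  expect_identical(obstructionConfiguration(p2)[["E"]], "L")
  expect_identical(obstructionDegree(p2)[["L"]], 1L)
})

test_that("canonical serialization drops degree-0 configurations", {
  expect_identical(formatUdise(zeroProfile()), "N0V0Ts0O0Tb0E0L0")
  p <- profileFromDegrees(c(E = 2), c(E = "AP"))
  expect_identical(formatUdise(p), "N0V0Ts0O0Tb0E2APL0")
  withCfg <- profileFromDegrees(integer(0), c(V = "AP"))
  expect_identical(formatUdise(withCfg), "N0V0Ts0O0Tb0E0L0")
})

test_that("parse/format round-trips on random valid profiles", {
  set.seed(20260920)
  for (i in 1:200) {
    p <- randomProfile()
    txt <- formatUdise(p)
    back <- parseUdise(txt)
    expect_identical(formatUdise(back), txt)
    expect_identical(obstructionDegree(back), obstructionDegree(p))
  }
})

test_that("parse errors cite the character offset and the broken rule", {
  expect_error(parseUdise("N0V0Ts0O0Tb0E0"), "expected site 'L'")
  expect_error(parseUdise("N0Ts0V0O0Tb0E0L0"), "expected site 'V'")
  expect_error(parseUdise("N0V5Ts0O0Tb0E0L0"), "expected degree")
  expect_error(parseUdise("N0V1Ts0O0Tb0E0L0"), "required at degree")
  expect_error(parseUdise("N0V0Ts2APO0Tb0E0L0"), "admissible: L")
  expect_error(parseUdise("N0V0Ts0O0Tb0E0L0X"), "trailing input")
  err <- tryCatch(parseUdise("N0V0Ts0O0Tb0E0"), error = identity)
  expect_match(conditionMessage(err), "character 15")
})

test_that("foreign token strings parse per system grammar", {
  v <- parseForeign("VOTE", "Vk2AP Ok1L Tk2AP Ek0")
  expect_length(v, 4)
  expect_identical(vapply(v, formatForeignToken, character(1)),
                   c("Vk2AP", "Ok1L", "Tk2AP", "Ek0"))

  g <- parseForeign("PRINGLE", "G3")[[1]]
  expect_identical(g@grade, 3L)

  n <- parseForeign("NOHL", "N3 Ot4 HAP3 LP")
  expect_identical(n[[1]]@grade, 3L)
  expect_identical(n[[2]]@configuration, "t")
  expect_identical(n[[3]]@site, "H")
  expect_identical(n[[4]]@flag, "P")

  p <- parseForeign("PTLTBE", "P3 Tb2 E1")
  expect_identical(vapply(p, function(t) t@site, character(1)),
                   c("P", "Tb", "E"))
})

test_that("foreign grammar rejects out-of-vocabulary tokens", {
  expect_error(parseForeign("VOTE", "Vk4AP"), "outside 0..2")
  expect_error(parseForeign("VOTE", "Nk1"), "cannot parse")
  expect_error(parseForeign("PRINGLE", "G6"), "1..5")
  expect_error(parseForeign("NOHL", "O5t"), "cannot parse")
  expect_error(parseForeign("NOHL", "Ot5"), "outside 1..4")
  expect_error(parseForeign("PTLTBE", "E3"), "outside 1..2")
  expect_error(parseForeign("VOTE", "Vk1"), "required at grade")
})

test_that("token rendering round-trips through the grammar", {
  for (sys in foreignSystems()) {
    for (tok in allForeignTokens(sys)) {
      txt <- formatForeignToken(tok)
      back <- parseForeign(sys, txt)[[1]]
      expect_identical(formatForeignToken(back), txt)
    }
  }
})
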