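test_that("composition algebra is element-wise and guards non-negativity", {
  a <- comp(C = 16, H = 32, O = 2)
  b <- comp(C = 2, H = 4, N = 1)
  ab <- comp_add(a, b)
  expect_equal(unclass(ab)[c("C", "H", "N", "O")],
               c(C = 18L, H = 36L, N = 1L, O = 2L))
  expect_equal(comp_subtract(ab, b), a)
  expect_error(comp_subtract(a, comp(N = 1)), "negative")
  expect_error(comp(C = -1), "non-negative")
  expect_equal(comp_scale(b, 3), comp(C = 6, H = 12, N = 3))
})

test_that("formulas render in Hill order and parse back", {
  expect_identical(formula_of(comp(C = 16, H = 32, O = 2)), "C16H32O2")
  expect_identical(formula_of(comp()), "")
  expect_identical(formula_of(comp(C = 42, H = 82, N = 1, O = 8, P = 1)),
                   "C42H82NO8P")
  # no carbon: plain alphabetical
  expect_identical(formula_of(comp(O = 1, H = 2)), "H2O")
  for (f in c("C16H32O2", "C42H82NO8P", "H2O", "C44H80NO7P"))
    expect_identical(formula_of(parse_formula(f)), f)
  expect_error(parse_formula("C16xH32"), "malformed")
})

test_that("monoisotopic masses match the atomic-mass oracle", {
  # frozen sums of IUPAC monoisotopic masses
  expect_equal(monoisotopic_mass(comp(H = 2, O = 1)), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(comp()), 0.0)
  expect_equal(monoisotopic_mass(comp(C = 16, H = 32, O = 2)), 256.240230,
               tolerance = 1e-6)
  expect_error(monoisotopic_mass(c(Xx = 1)), "Xx")
  expect_gt(average_mass(comp(C = 16, H = 32, O = 2)),
            monoisotopic_mass(comp(C = 16, H = 32, O = 2)))
})

test_that("mass and formula are additive over composition sums", {
  set.seed(11)
  for (i in 1:20) {
    a <- comp(C = sample(0:30, 1), H = sample(0:60, 1), O = sample(0:8, 1),
              N = sample(0:2, 1))
    b <- comp(C = sample(0:30, 1), H = sample(0:60, 1), P = sample(0:2, 1))
    ab <- comp_add(a, b)
    expect_equal(monoisotopic_mass(ab),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-9)
    for (el in union(names(a), names(b))) {
      ca <- if (el %in% names(a)) unclass(a)[[el]] else 0L
      cb <- if (el %in% names(b)) unclass(b)[[el]] else 0L
      cab <- if (el %in% names(ab)) unclass(ab)[[el]] else 0L
      expect_identical(cab, ca + cb)
    }
    # adding CH2 advances the monoisotopic mass by one methylene unit
    expect_equal(monoisotopic_mass(comp_add(a, comp(C = 1, H = 2))),
                 monoisotopic_mass(a) + 14.015650, tolerance = 1e-6)
  }
})

test_that("the adduct registry holds exactly the nine supported adducts", {
  reg <- adduct_registry()
  expect_setequal(reg$label,
                  c("[M.]+", "[M+H]+", "[M+K]+", "[M+Na]+", "[M+Li]+",
                    "[M+NH4]+", "[M-H]-", "[M+Cl]-", "[M+OAc]-"))
  expect_true(all(reg$polarity[reg$charge > 0] == "positive"))
  # deltas derive from the atomic mass table with electron correction
  expect_equal(reg$mass_delta[reg$label == "[M+H]+"], 1.007276, tolerance = 1e-6)
  expect_equal(reg$mass_delta[reg$label == "[M.]+"], -0.000548580,
               tolerance = 1e-5)
  expect_equal(reg$mass_delta[reg$label == "[M-H]-"], -1.007276, tolerance = 1e-6)
  # registry round-trips through its config-file representation
  cfg <- system.file("extdata", "adducts.tsv", package = "lipidgen")
  reg2 <- load_adduct_registry(cfg)
  expect_equal(reg2$mass_delta, reg$mass_delta, tolerance = 1e-9)
})

test_that("adduct m/z applies signed deltas with electron-mass correction", {
  M <- 759.577954
  expect_equal(adduct_mz(M, "[M+H]+"), 760.585230, tolerance = 1e-6)
  expect_equal(adduct_mz(M, "[M.]+"), 759.577405, tolerance = 1e-6)
  expect_equal(adduct_mz(M, "[M-H]-"), 758.570678, tolerance = 1e-6)
  # typographic minus accepted
  expect_equal(adduct_mz(M, "[M−H]−"), 758.570678, tolerance = 1e-6)
  # positive-mode ordering for any fixed M follows the delta table
  mzs <- adduct_mz(M, c("[M+K]+", "[M+Na]+", "[M+NH4]+", "[M+Li]+",
                        "[M+H]+", "[M.]+"))
  expect_true(all(diff(mzs) < 0))
  err <- expect_error(adduct_mz(M, "[M+Xy]+"), "unknown adduct")
  expect_match(conditionMessage(err), "[M+OAc]-", fixed = TRUE)
  expect_error(adduct_mz(-1, "[M+H]+"), "positive")
})
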