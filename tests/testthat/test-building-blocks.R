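test_that("free chain compositions follow CnH(2n-2d)O2 / CnH(2n+2-2d)O", {
  acid <- function(n, d) list(kind = "fatty-acid", carbons = n, double_bonds = d)
  alc <- function(n, d) list(kind = "fatty-alcohol", carbons = n, double_bonds = d)
  expect_identical(formula_of(chain_composition(acid(16, 0))), "C16H32O2")
  expect_identical(formula_of(chain_composition(alc(16, 0))), "C16H34O")
  expect_identical(formula_of(chain_composition(acid(20, 4))), "C20H32O2")
})

test_that("systematic residue names are assembled from stems and locants", {
  expect_identical(acyl_name(16, 0), "hexadecanoyl")
  expect_identical(acyl_name(20, 4, "5Z,8Z,11Z,14Z"),
                   "5Z,8Z,11Z,14Z-eicosatetraenoyl")
  expect_identical(acyl_name(18, 1, "9Z"), "9Z-octadecenoyl")
  expect_identical(alkyl_name(16, 0), "hexadecyl")
  expect_identical(alkenyl_name(16, 0), "1Z-hexadecenyl")
  expect_identical(alkenyl_name(18, 1, "9Z"), "1Z,9Z-octadecadienyl")
})

test_that("chain libraries load from TSV with row-level diagnostics", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("kind\tcarbons\tdouble_bonds\tpositions\ttrivial_name",
               "fatty-acid\t16\t0\t\tpalmitic acid",
               "fatty-acid\t18\t1\t9Z\toleic acid",
               "fatty-acid\t20\t4\t5Z;8Z;11Z;14Z\tarachidonic acid"), tf)
  out <- load_chain_library(tf)
  expect_equal(nrow(out$chains), 3)
  expect_equal(nrow(out$diagnostics), 0)
  expect_identical(out$chains$residue_name[3], "5Z,8Z,11Z,14Z-eicosatetraenoyl")

  # positions count mismatching the double-bond count rejects the row
  writeLines(c("kind\tcarbons\tdouble_bonds\tpositions\ttrivial_name",
               "fatty-acid\t16\t0\t\tok",
               "fatty-acid\t18\t2\t9Z\tbad"), tf)
  out <- load_chain_library(tf)
  expect_equal(nrow(out$chains), 1)
  expect_equal(out$diagnostics$row, 2)
  expect_match(out$diagnostics$message, "positions count")

  # duplicates collapse with a warning
  writeLines(c("kind\tcarbons\tdouble_bonds\tpositions\ttrivial_name",
               "fatty-acid\t16\t0\t\ta",
               "fatty-acid\t16\t0\t\tb"), tf)
  expect_warning(out <- load_chain_library(tf), "duplicate")
  expect_equal(nrow(out$chains), 1)

  writeLines("kind\tcarbons\tdouble_bonds\tpositions\ttrivial_name", tf)
  expect_error(load_chain_library(tf), "empty")
  expect_error(load_chain_library(tempfile()), "cannot read")
})

test_that("invalid chain descriptors are rejected with the offending field", {
  bad <- data.frame(kind = "fatty-acid", carbons = 18, double_bonds = 1,
                    positions = "18Z", trivial_name = "x")
  expect_error(chain_library(bad), "positions")
  bad$positions <- "9Z,8Z"
  expect_error(chain_library(bad), "positions|double_bonds")
  bad2 <- data.frame(kind = "sterol", carbons = 18, double_bonds = 0,
                     positions = "", trivial_name = "x")
  expect_error(chain_library(bad2), "kind")
})

test_that("the built-in pool satisfies parity and unsaturation identities", {
  pool <- chain_pool()
  expect_equal(sum(pool$kind == "fatty-acid"), 80)
  expect_equal(sum(pool$kind == "fatty-alcohol"), 18)
  for (i in seq_len(nrow(pool))) {
    cc <- chain_composition(pool[i, ])
    n <- unclass(cc)[["C"]]; h <- unclass(cc)[["H"]]
    expect_true(h %% 2 == 0)
    # rings + double bonds from the formula: (2C + 2 - H) / 2
    dou <- (2 * n + 2 - h) / 2
    expected <- pool$double_bonds[i] + if (pool$kind[i] == "fatty-acid") 1 else 0
    expect_equal(dou, expected)
  }
})

test_that("fixture libraries are deterministic and bounded by the pool", {
  a <- fixture_library(4, 2, seed = 7)
  b <- fixture_library(4, 2, seed = 7)
  expect_identical(a$chains, b$chains)
  expect_equal(sum(a$chains$kind == "fatty-acid"), 4)
  expect_equal(sum(a$chains$kind == "fatty-alcohol"), 2)
  expect_setequal(names(a$templates), c("PC", "PC-O", "TG"))
  expect_false(identical(a$chains, fixture_library(4, 2, seed = 8)$chains))
  one <- fixture_library(1, 0, seed = 0)
  expect_equal(nrow(one$chains), 1)
  expect_error(fixture_library(500, 0), "pool size")
  expect_error(fixture_library(0, 0), "n_acids")
})
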