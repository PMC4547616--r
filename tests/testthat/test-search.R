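make_small_library <- function() {
  fx <- fixture_library(6, 2, seed = 21)
  isos <- enumerate_all(fx$templates, fx$chains, structures = FALSE)
  build_hierarchy(isos, fx$templates)
}

test_that("m/z search finds known adduct peaks with ~0 ppm error", {
  ch <- po_chains()
  h <- build_hierarchy(enumerate_isomeric(builtin_templates()$PC, ch))
  M <- 759.577805  # PC(16:0/18:1), oracle mass
  hits <- mz_search(h, adduct_mz(M, "[M+H]+"), 5, "ppm", "positive")
  expect_true(any(hits$label == "PC(34:1)" & hits$adduct == "[M+H]+"))
  expect_lt(min(abs(hits$mz_error_ppm)), 0.01)
  # positive-mode query never returns negative-mode adducts
  expect_true(all(hits$adduct %in%
                    adduct_registry()$label[adduct_registry()$charge > 0]))
  # degenerate Da tolerance keeps only exact stored values
  exact <- mz_search(h, adduct_mz(M, "[M+H]+"), 1e-6, "Da", "positive")
  expect_true(all(abs(exact$mz_theoretical - adduct_mz(M, "[M+H]+")) <= 1e-6))
  expect_gt(nrow(exact), 0)
  # far out of library mass range
  expect_equal(nrow(mz_search(h, 100.0, 5, "ppm")), 0)
  expect_error(mz_search(h, 760, -1, "ppm"), "tolerance")
  # adduct filter
  only_na <- mz_search(h, adduct_mz(M, "[M+Na]+"), 5, "ppm",
                       adducts = "[M+Na]+")
  expect_true(all(only_na$adduct == "[M+Na]+"))
})

test_that("binary-search hits equal a brute-force linear scan", {
  h <- make_small_library()
  idx <- mz_index(h)
  set.seed(33)
  # queries centred on real peaks (with jitter) and uniform decoys
  centres <- sample(idx$mz, 120, replace = TRUE) *
    (1 + stats::runif(120, -8e-6, 8e-6))
  decoys <- stats::runif(60, min(idx$mz) - 5, max(idx$mz) + 5)
  for (q in c(centres, decoys)) {
    got <- mz_search(idx, q, 5, "ppm")
    half <- q * 5e-6
    want <- idx[abs(idx$mz - q) <= half, ]
    expect_setequal(paste(got$id, got$adduct), paste(want$id, want$adduct))
  }
})

test_that("a ppm tolerance equals the equivalent Da tolerance", {
  h <- make_small_library()
  idx <- mz_index(h)
  set.seed(7)
  for (q in sample(idx$mz, 25) * (1 + stats::runif(25, -4e-6, 4e-6))) {
    a <- mz_search(idx, q, 5, "ppm")
    b <- mz_search(idx, q, q * 5e-6, "Da")
    expect_identical(paste(a$id, a$adduct), paste(b$id, b$adduct))
  }
})

test_that("identifier mapping matches exact keys and counts ambiguity", {
  a <- data.frame(id = c("A1", "A2", "A3"),
                  inchikey = c("AAAAAAAAAAAAAA-BBBBBBBBBB-N",
                               "CCCCCCCCCCCCCC-DDDDDDDDDD-N",
                               "EEEEEEEEEEEEEE-FFFFFFFFFF-N"))
  b <- data.frame(id = c("B1", "B2", "B3"),
                  inchikey = c("AAAAAAAAAAAAAA-BBBBBBBBBB-N",
                               "AAAAAAAAAAAAAA-ZZZZZZZZZZ-N",
                               "CCCCCCCCCCCCCC-DDDDDDDDDD-N"))
  m <- map_identifiers(a, b, "inchikey")
  expect_equal(nrow(m$rows), 2)
  expect_true(all(m$rows$ambiguity_count == 1))
  expect_identical(m$unmatched, "A3")
  # first-block matching is a documented relaxation
  m2 <- map_identifiers(a, b, "inchikey", first_block = TRUE)
  expect_equal(sum(m2$rows$source_id == "A1"), 2)
  expect_equal(unique(m2$rows$ambiguity_count[m2$rows$source_id == "A1"]), 2)
  # symmetry: a->b transposes to b->a
  m3 <- map_identifiers(b, a, "inchikey")
  expect_setequal(paste(m$rows$source_id, m$rows$target_id),
                  paste(m3$rows$target_id, m3$rows$source_id))
  expect_error(map_identifiers(a, data.frame(id = "X"), "inchikey"), "key")

  # mapping a node set to itself on abbreviation is the identity
  h <- make_small_library()
  sp <- h$nodes[h$nodes$level == "Species", c("id", "label")]
  m4 <- map_identifiers(sp, sp, "abbreviation")
  expect_equal(nrow(m4$rows), nrow(sp))
  expect_identical(m4$rows$source_id, m4$rows$target_id)
  expect_length(m4$unmatched, 0)
})
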