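tpl <- builtin_templates()

test_that("rollup operators are functional and idempotent", {
  expect_identical(parent_structural("PC(P-16:0/20:4(5Z,8Z,11Z,14Z))"),
                   "PC(P-16:0/20:4)")
  expect_identical(parent_structural("PC(16:0/18:0)"), "PC(16:0/18:0)")
  expect_identical(parent_structural("PC(16:0/18:1(9Z))"), "PC(16:0/18:1)")
  expect_identical(parent_structural(parent_structural("PC(16:0/18:1(9Z))")),
                   parent_structural("PC(16:0/18:1(9Z))"))
  expect_identical(parent_molecular("PC(18:1/16:0)"), "PC(16:0_18:1)")
  # the plasmalogen and the alkyl ether collapse onto one molecular parent
  expect_identical(parent_molecular("PC(O-16:1/20:4)"),
                   parent_molecular("PC(P-16:0/20:4)"))
  expect_identical(parent_species("PC(16:0_18:1)"), "PC(34:1)")
  expect_identical(parent_species("LPC(16:0_0:0)"), "LPC(16:0)")
  expect_error(parent_molecular("PC(O-36:5)"), "structural")
  expect_error(parent_species("PC(16:0/18:1)"), "molecular")
})

test_that("the printed worked example builds its full seven-level chain", {
  alkenyl_pc <- class_template(
    "PC-P", "Glycerophospholipid", "Glycerophosphocholine",
    "Monoalkylmonoacylglycerophosphocholine", "PC",
    tpl$PC$backbone, tpl$PC$backbone_name,
    data.frame(sn = 1:2, linkages = I(list("alkenyl", "ester")),
               may_be_empty = FALSE))
  iso <- enumerate_isomeric(alkenyl_pc, table1_chains())
  h <- build_hierarchy(iso, chains = table1_chains())
  expect_equal(level_counts(h)$n, rep(1, 7))
  want <- c(Category = "Glycerophospholipid",
            Class = "Glycerophosphocholine",
            Subclass = "Monoalkylmonoacylglycerophosphocholine",
            Species = "PC(O-36:5)",
            `Molecular subspecies` = "PC(O-16:1_20:4)",
            `Structural subspecies` = "PC(P-16:0/20:4)",
            `Isomeric subspecies` = "PC(P-16:0/20:4(5Z,8Z,11Z,14Z))")
  got <- setNames(h$nodes$label, h$nodes$level)[names(want)]
  expect_identical(got, want)
  # every edge spans exactly one level downward
  lv <- match(h$edges$child_level, hierarchy_levels())
  expect_true(all(lv - match(h$edges$parent_level, hierarchy_levels()) == 1))
})

test_that("empty input gives an empty hierarchy", {
  h <- build_hierarchy(data.frame())
  expect_equal(nrow(h$nodes), 0)
  expect_equal(nrow(h$edges), 0)
  expect_true(all(level_counts(h)$n == 0))
})

test_that("hierarchy counts match the brute-force oracle on fixtures", {
  three <- chain_library(data.frame(
    kind = "fatty-acid", carbons = c(16, 18, 18),
    double_bonds = c(0, 1, 2), positions = c("", "9Z", "9Z,12Z"),
    trivial_name = c("a", "b", "c")))
  iso <- enumerate_isomeric(tpl$PC, three)
  h <- build_hierarchy(iso)
  lc <- setNames(level_counts(h)$n, level_counts(h)$level)
  o <- oracle_counts(tpl$PC, three)
  expect_equal(unname(lc["Isomeric subspecies"]), o$iso)   # 9
  expect_equal(unname(lc["Structural subspecies"]), o$str) # 9
  expect_equal(unname(lc["Molecular subspecies"]), o$mol)  # 6
  expect_equal(unname(lc["Species"]), o$spc)
  expect_equal(o$iso, 9)
  expect_equal(o$mol, 6)

  for (seed in c(2, 9)) {
    fx <- fixture_library(6, 4, seed = seed)
    isos <- enumerate_all(fx$templates, fx$chains, structures = FALSE)
    h <- build_hierarchy(isos, fx$templates)
    lc <- setNames(level_counts(h)$n, level_counts(h)$level)
    oc <- lapply(fx$templates, oracle_counts, chains = fx$chains)
    # per-level union over templates; keys never collide across classes
    # except deliberately identical abbreviations (none among PC/PC-O/TG)
    expect_equal(unname(lc["Isomeric subspecies"]),
                 sum(vapply(oc, `[[`, 0L, "iso")))
    expect_equal(unname(lc["Structural subspecies"]),
                 sum(vapply(oc, `[[`, 0L, "str")))
    expect_equal(unname(lc["Molecular subspecies"]),
                 sum(vapply(oc, `[[`, 0L, "mol")))
  }
})

test_that("counts are monotone and compositions consistent within species", {
  fx <- fixture_library(7, 4, seed = 13)
  isos <- enumerate_all(fx$templates, fx$chains, structures = FALSE)
  h <- build_hierarchy(isos, fx$templates)
  lc <- setNames(level_counts(h)$n, level_counts(h)$level)
  expect_true(lc["Isomeric subspecies"] >= lc["Structural subspecies"])
  expect_true(lc["Structural subspecies"] >= lc["Molecular subspecies"])
  expect_true(lc["Molecular subspecies"] >= lc["Species"])
  # all isomeric descendants of one species share one formula
  iso_nodes <- h$nodes[h$nodes$level == "Isomeric subspecies", ]
  up <- function(ids, lv) {
    e <- h$edges[h$edges$child_level == lv, ]
    e$parent_id[match(ids, e$child_id)]
  }
  sp <- up(up(up(iso_nodes$id, "Isomeric subspecies"),
              "Structural subspecies"), "Molecular subspecies")
  expect_true(all(tapply(iso_nodes$formula, sp,
                         function(f) length(unique(f))) == 1))
  # species carbon/double-bond sums commute with the direct chain sums
  for (r in seq_len(min(20, nrow(isos)))) {
    tplr <- fx$templates[[isos$template_key[r]]]
    sns <- tplr$slots$sn
    sum_c <- sum(vapply(sns, function(sn) isos[[paste0("sn", sn, "_c")]][r], 0L))
    sum_db <- sum(vapply(sns, function(sn) isos[[paste0("sn", sn, "_dbsum")]][r], 0L))
    spc <- parent_species(parent_molecular(parent_structural(isos$abbreviation[r])))
    ab <- parse_abbreviation(spc)
    expect_equal(ab$terms$c, sum_c)
    expect_equal(ab$terms$db, sum_db)
  }
})

test_that("node ids are stable, distinct and order-independent", {
  expect_identical(assign_ids("Species", "PC(34:1)"),
                   assign_ids("Species", "PC(34:1)"))
  expect_false(assign_ids("Species", "PC(34:1)") ==
                 assign_ids("Species", "PC(34:2)"))
  labs <- c("PC(34:1)", "PC(34:2)", "PC(36:1)")
  ids1 <- assign_ids("Species", labs)
  ids2 <- assign_ids("Species", rev(labs))
  expect_identical(ids1, rev(ids2))
})
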