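pc <- builtin_templates()$PC
pco <- builtin_templates()[["PC-O"]]

test_that("lipid composition follows condensation arithmetic", {
  ch <- po_chains()
  asn <- list(list(chain = ch[1, ], linkage = "ester"),
              list(chain = ch[2, ], linkage = "ester"))
  cc <- lipid_composition(pc, asn)
  expect_identical(formula_of(cc), "C42H82NO8P")
  # oracle: GPC backbone C8H20NO6P + C16H32O2 + C18H34O2 - 2 H2O
  expect_equal(monoisotopic_mass(cc), 759.577805, tolerance = 1e-4)

  t1 <- table1_chains()
  asn2 <- list(list(chain = t1[1, ], linkage = "alkenyl"),
               list(chain = t1[2, ], linkage = "ester"))
  expect_identical(formula_of(lipid_composition(pco, asn2)), "C44H80NO7P")

  # the zero-chain case: all slots empty leaves the backbone untouched
  mg <- builtin_templates()$MG
  asn3 <- list(list(chain = po_chains()[1, ], linkage = "ester"), NULL, NULL)
  expect_identical(
    formula_of(lipid_composition(pc, list(NULL, NULL))),
    formula_of(pc$backbone_composition))
  expect_identical(formula_of(lipid_composition(mg, asn3)), "C19H38O4")
})

test_that("invalid assignments name the offending slot", {
  ch <- po_chains()
  expect_error(
    lipid_composition(pc, list(list(chain = ch[1, ], linkage = "alkyl"),
                               list(chain = ch[2, ], linkage = "ester"))),
    "not allowed at slot sn-1")
  t1 <- table1_chains()
  expect_error(
    lipid_composition(pc, list(list(chain = t1[1, ], linkage = "ester"),
                               list(chain = t1[2, ], linkage = "ester"))),
    "requires a fatty-acid")
})

test_that("assembled structure strings agree with compositional arithmetic", {
  ch <- po_chains()
  asn <- list(list(chain = ch[1, ], linkage = "ester"),
              list(chain = ch[2, ], linkage = "ester"))
  s <- assemble_structure(pc, asn)
  expect_false(grepl("\\{", s))
  expect_identical(formula_of(smiles_composition(s)), "C42H82NO8P")
  # and with an independent engine
  expect_identical(unname(ob_formula(s)), "C42H82NO8P")

  # empty sn-2 renders a free hydroxyl on the glycerol carbon
  lpc <- builtin_templates()$LPC
  s2 <- assemble_structure(lpc, list(list(chain = ch[1, ], linkage = "ester"),
                                     NULL))
  expect_match(s2, "[C@@H](O)", fixed = TRUE)

  # alkenyl linkage writes the 1Z ene-ether motif next to the glycerol oxygen
  t1 <- table1_chains()
  s3 <- assemble_structure(pco, list(list(chain = t1[1, ], linkage = "alkenyl"),
                                     list(chain = t1[2, ], linkage = "ester")))
  expect_match(s3, "O/C=C\\", fixed = TRUE)
  expect_identical(formula_of(smiles_composition(s3)), "C44H80NO7P")
})

test_that("enumeration is the exact slot-wise Cartesian product", {
  ch <- po_chains()
  iso <- enumerate_isomeric(pc, ch)
  expect_equal(nrow(iso), 4)
  # sn-positional isomers are distinct structures at this level
  expect_true(all(c("PC(16:0/18:1(9Z))", "PC(18:1(9Z)/16:0)") %in%
                    iso$abbreviation))
  # identical chains in both slots give exactly one structure
  expect_equal(sum(iso$abbreviation == "PC(16:0/16:0)"), 1)

  # an alkenyl-only sn-1 slot with one alcohol and one acid: one structure
  alkenyl_pc <- class_template(
    "PC-P", "Glycerophospholipid", "Glycerophosphocholine",
    "Monoalkylmonoacylglycerophosphocholine", "PC",
    pc$backbone, pc$backbone_name,
    data.frame(sn = 1:2, linkages = I(list("alkenyl", "ester")),
               may_be_empty = FALSE))
  iso2 <- enumerate_isomeric(alkenyl_pc, table1_chains())
  expect_equal(nrow(iso2), 1)
  expect_identical(iso2$abbreviation, "PC(P-16:0/20:4(5Z,8Z,11Z,14Z))")

  # a mandatory slot with no eligible chain yields an empty set + warning
  acids_only <- po_chains()
  expect_warning(iso3 <- enumerate_isomeric(pco, acids_only), "no eligible")
  expect_equal(nrow(iso3), 0)
})

test_that("enumeration counts equal the brute-force oracle across fixtures", {
  for (seed in c(1, 7)) {
    fx <- fixture_library(5, 3, seed = seed)
    for (tpl in fx$templates) {
      got <- suppressWarnings(enumerate_isomeric(tpl, fx$chains,
                                                 structures = FALSE))
      expect_equal(nrow(got), oracle_counts(tpl, fx$chains)$iso,
                   info = paste(tpl$key, "seed", seed))
      expect_false(anyDuplicated(got$abbreviation) > 0)
    }
  }
  # templates with optional slots obey the (+1 for may-be-empty) count law
  dg <- builtin_templates()$DG
  lpc <- builtin_templates()$LPC
  ch <- po_chains()
  expect_equal(nrow(enumerate_isomeric(dg, ch)), 4)   # 2 x 2 x (empty only)
  expect_equal(nrow(enumerate_isomeric(lpc, ch)), 2)  # 2 x (empty only)
})

test_that("composition is conserved slot-wise and under P/O exchange", {
  fx <- fixture_library(4, 2, seed = 3)
  for (tpl in fx$templates) {
    iso <- suppressWarnings(enumerate_isomeric(tpl, fx$chains))
    if (nrow(iso) == 0) next
    water <- 18.010565
    for (r in sample(nrow(iso), min(10, nrow(iso)))) {
      filled <- 0; chain_mass <- 0
      for (sn in tpl$slots$sn) {
        lk <- iso[[paste0("sn", sn, "_linkage")]][r]
        ci <- iso[[paste0("sn", sn, "_chain")]][r]
        if (is.na(ci) || lk == "empty") next
        filled <- filled + 1
        m <- monoisotopic_mass(chain_composition(fx$chains[ci, ]))
        if (lk == "alkenyl")
          m <- m - monoisotopic_mass(comp(H = 2))
        chain_mass <- chain_mass + m
      }
      expect_equal(iso$monoisotopic_mass[r],
                   monoisotopic_mass(tpl$backbone_composition) + chain_mass -
                     filled * water,
                   tolerance = 1e-6)
    }
  }
  # alkenyl n:d in a lipid weighs exactly as alkyl n:(d+1)
  alcohols <- chain_library(data.frame(
    kind = "fatty-alcohol", carbons = c(16, 16), double_bonds = c(0, 1),
    positions = c("", "9Z"), trivial_name = c("a", "b")))
  acid <- table1_chains()[2, ]
  m_p <- lipid_composition(pco, list(list(chain = alcohols[1, ], linkage = "alkenyl"),
                                     list(chain = acid, linkage = "ester")))
  m_o <- lipid_composition(pco, list(list(chain = alcohols[2, ], linkage = "alkyl"),
                                     list(chain = acid, linkage = "ester")))
  expect_identical(m_p, m_o)
})
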