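# lipidgen

Combinatorial generation and hierarchical classification of glycerolipid
and glycerophospholipid structures for mass-spectrometry lipidomics.

MS-based lipidomics identifies lipids at varying depths of certainty: a
precursor mass constrains only the sum composition, MS/MS may reveal
per-chain compositions, and only targeted work pins down sn positions or
double-bond geometry. `lipidgen` builds the explicit candidate space that
such data maps onto. Starting from curated building blocks — fatty
acids/alcohols with known double-bond positions, and lipid-class templates
(an sn-glycerol backbone fragment with typed attachment slots for ester,
alkyl-ether and 1Z-alkenyl/vinyl-ether linkages) — it:

* enumerates every feasible **isomeric subspecies** (exact Cartesian
  product over slots; no hypothetical chains or positions),
* assembles each structure string by fragment substitution and derives its
  formula, monoisotopic/average mass and m/z for nine adducts
  (`[M.]+`, `[M+H]+`, `[M+K]+`, `[M+Na]+`, `[M+Li]+`, `[M+NH4]+`,
  `[M-H]-`, `[M+Cl]-`, `[M+OAc]-`),
* generates and parses shorthand abbreviations and systematic names at
  every level, and
* rolls everything up into the deduplicated seven-level hierarchy
  (Category > Class > Subclass > Species > Molecular > Structural >
  Isomeric subspecies), with m/z search and identifier mapping on top,
  plus an evidence-linked annotation store (GO/Uberon occurrence, ECO
  codes, enzyme-reaction links) with per-lipid information flags.

The rollup rules are the standard shorthand semantics: structural parents
drop double-bond positions; molecular parents drop sn assignment and
rewrite `P-n:d` as `O-n:(d+1)` (so a plasmalogen and its alkyl-ether
isomer share one parent — and exactly the same mass); species parents sum
carbons and double bonds under an `O-` flag.

## Worked example

```r
library(lipidgen)

t1 <- chain_library(data.frame(
  kind = c("fatty-alcohol", "fatty-acid"),
  carbons = c(16, 20), double_bonds = c(0, 4),
  positions = c("", "5Z,8Z,11Z,14Z"),
  trivial_name = c("hexadecanol", "arachidonic acid")))

iso <- enumerate_isomeric(builtin_templates()[["PC-O"]], t1)
iso[, c("abbreviation", "formula", "monoisotopic_mass")]
#>                     abbreviation    formula monoisotopic_mass
#> 1 PC(O-16:0/20:4(5Z,8Z,11Z,14Z)) C44H82NO7P          767.5829
#> 2 PC(P-16:0/20:4(5Z,8Z,11Z,14Z)) C44H80NO7P          765.5672

systematic_name(iso, t1)[2]
#> [1] "1-O-(1Z-hexadecenyl)-2-(5Z,8Z,11Z,14Z-eicosatetraenoyl)-sn-glycero-3-phosphocholine"

parent_structural("PC(P-16:0/20:4(5Z,8Z,11Z,14Z))")  # "PC(P-16:0/20:4)"
parent_molecular("PC(P-16:0/20:4)")                  # "PC(O-16:1_20:4)"
parent_species("PC(O-16:1_20:4)")                    # "PC(O-36:5)"

h <- build_hierarchy(iso, chains = t1)
mz_search(h, 766.574517, 5, "ppm", "positive")[1, c("label", "adduct", "mz_error_ppm")]
#>             label adduct mz_error_ppm
#> 1 PC(P-16:0/20:4) [M+H]+  -0.03781728
```

The two enumerated structures differ by one H2 — the vinyl-ether double
bond — and collapse onto the same species `PC(O-36:5)`.

The full pipeline (`generate_library()`) reads a chain TSV and a template
YAML (examples under `inst/extdata/`), writes deterministic `nodes.tsv` /
`edges.tsv` / `counts.tsv` tables and SDF structure exports, and is also
exposed as a command-line tool at `inst/cli/lipidgen`
(`generate`, `counts`, `search`, `map`, `annotations`).

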