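---
title: "Combinatorial generation of glycerolipid libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial generation of glycerolipid libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidgen)
```

## The problem

Mass-spectrometry lipidomics reports signals whose interpretation is
intrinsically ambiguous: a single precursor m/z is compatible with many
glycerolipid and glycerophospholipid structures, and successive analytical
refinements (sum composition, per-chain composition, sn positions,
double-bond positions and geometry) narrow the candidate set step by step.
`lipidgen` makes that candidate space explicit.  From a curated set of
*building blocks* — fatty acids and fatty alcohols with known double-bond
positions, and lipid-class *templates* describing an sn-glycerol backbone
with typed attachment slots — it enumerates every chemically feasible
structure, annotates each with nomenclature, formula, masses and adduct
m/z, and organizes all of them in the seven-level hierarchy used to map MS
outputs to structures:

Category > Class > Subclass > Species > Molecular subspecies >
Structural subspecies > Isomeric subspecies.

Only listed building blocks are combined.  The engine never invents
hypothetical double-bond positions or chain lengths; the feasible-structure
space is exactly the Cartesian product of the curated inputs, which keeps
every generated structure interpretable in terms of known chemistry.

## The generation model

A class template carries a backbone fragment written in SMILES with
numbered slot placeholders — for phosphatidylcholine,

```
C({1})[C@@H]({2})COP(=O)([O-])OCC[N+](C)(C)C
```

— plus, per slot, the set of allowed linkages: `ester` (fatty acid, no
prefix), `alkyl` (fatty alcohol, `O-` prefix) or `alkenyl` (fatty alcohol
attached as a 1Z vinyl ether, `P-` prefix).  Assembly replaces each
placeholder with the chain's residue fragment (`OC(=O)...`, `O...` or
`O/C=C\...`); an empty slot becomes a free hydroxyl, which is how lyso
classes arise.  The stereo descriptor fixes the natural sn-glycerol
configuration, and double-bond geometry is written with directional bonds.
Zwitterionic headgroups are written in charge-separated form, matching
common lipid-database practice.

Composition follows condensation arithmetic rather than atom counting:
backbone composition plus the free-molecule composition of each chain
(acid n:d = CnH(2n−2d)O2, alcohol n:d = CnH(2n+2−2d)O), minus one water
per filled slot.  An alkenyl chain contributes its alcohol's composition
minus H2 — the vinyl-ether double bond.  The package also counts atoms in
every assembled structure string with its own valence-model SMILES reader;
the two routes must agree, and the test suite additionally checks the atom
counts against Open Babel's InChI output as an independent engine.

Masses use a pinned table of IUPAC monoisotopic masses (and abridged
standard atomic weights for the average mass), hard-coded for
reproducibility without network access.  Adduct m/z values are computed for
nine single-molecule adducts — `[M.]+`, `[M+H]+`, `[M+K]+`, `[M+Na]+`,
`[M+Li]+`, `[M+NH4]+`, `[M-H]-`, `[M+Cl]-`, `[M+OAc]-` — each delta derived
from the same atomic-mass table with the electron mass of the charge
carried included.  `[M.]+` is interpreted as the radical cation, M minus
one electron; the alternative reading (M unchanged) differs by 0.55 mDa and
is not used.  m/z values are reported to six decimal places.

## Nomenclature and the hierarchy

The shorthand grammar mirrors accepted lipidomics notation.  At isomeric
level chains are printed in sn order with positions,
`PC(P-16:0/20:4(5Z,8Z,11Z,14Z))`; the structural parent drops positions;
the molecular parent drops sn assignment, rewrites every `P-n:d` as
`O-n:(d+1)` (at that level the vinyl-ether double bond is indistinguishable
from a chain double bond, so a plasmalogen and the corresponding alkyl
ether share one parent) and sorts terms canonically — ether chains first,
then by (carbons, double bonds) ascending, empty `0:0` terms last; the
species parent sums carbons and double bonds and keeps an `O-` flag iff any
chain is ether-linked.  Empty sn positions are printed `0:0` at the
molecular level and below so that a single-chain molecular record remains
distinguishable from its species parent; at species level the sum term
stands alone.  `parse_abbreviation()` inverts all of this, inferring the
level from the separators (`_` molecular, `/` structural, positions
isomeric) and rejecting non-canonical text with a character offset; the
package guarantees `format_abbreviation(parse_abbreviation(x)) == x` over
everything it generates.

Hierarchy nodes are identified by (level, canonical abbreviation); two
structures are the same node iff that key coincides, which deduplicates
the rollup.  Stable identifiers are a 64-bit FNV-1a hash of the key
(prefix `LPD`), so rebuilding the same inputs in any order reproduces the
same ids without a registry; a hash collision aborts the build rather than
silently merging nodes.  Two class tiers are modeled (e.g.
*Glycerophosphocholine* above *Monoalkylmonoacylglycerophosphocholine*)
because subclasses named by linkage pattern sit under a shared headgroup
class; the ether subclass template accepts both alkyl and alkenyl chains at
sn-1, which is why an `O-` species can have both `O-` and `P-` descendants.
Ether linkages are allowed only where a template grants them
(conventionally sn-1, matching plasmalogen chemistry); templates are
user-editable YAML, so classes with other conventions can be added without
code changes.

## Tunable parameters

* **Chain library** (TSV): kind, carbons, double bonds, positions
  (delta-nomenclature locants from the carboxyl/hydroxyl carbon, e.g.
  `5Z;8Z;11Z;14Z`), trivial name.  Positions must be strictly increasing
  in [2, carbons−1]; the alkenyl 1Z bond is implied by the linkage, never
  stored on the chain.
* **Class templates** (YAML): category/class/subclass names, abbreviation,
  backbone fragment, backbone name, slots with allowed linkages and
  `may_be_empty`.
* **Adduct registry** (TSV): label, atoms added/removed, charge; the nine
  defaults ship built in and the registry is user-extensible.
* **Search tolerance**: ppm or Da, strictly positive, no default — an MS
  workflow should state its tolerance explicitly.

## The fixture generator and the reference set

`fixture_library(n_acids, n_alcohols, seed)` draws from a hard-coded pool
of 80 real fatty acids and 18 real fatty alcohols with literature
double-bond positions, paired with diacyl-PC, ether-PC and triacylglycerol
templates; identical arguments give identical fixtures.
`reference_library()` is the full pool crossed with all sixteen built-in
templates (six phospholipid headgroups in diacyl and ether form, lyso-PC,
MG, DG, TG).  It is a *representative reconstruction*: the curated resource
it emulates restricts which chains each class may use and defines 51
classes, and those curated tables are not redistributed here.
Consequently full-scale counts from `reference_library()` characterize the
generation procedure, not the curated resource — unrestricted
triacylglycerol enumeration alone contributes 80^3 = 512 000 isomeric
structures, so per-class chain restrictions dominate the totals.  Passing
tests on these fixtures demonstrate combinatorial correctness
(enumeration equals exhaustive nested-loop oracles, rollup and
deduplication are exact) and annotation correctness; they do not
demonstrate agreement with any particular curated chain selection, and
real biological lipidomes are far sparser than any enumerated library.

## Numerical and degenerate-input choices

* Masses are deterministic sums; equality of the plasmalogen/alkyl-ether
  isomer pair is exact (identical integer compositions), not a tolerance.
* The m/z index is a sorted array scanned by binary search
  (`findInterval`), with an explicit boundary re-check so ties at the
  tolerance edge are included; hits are ranked by |ppm error|, ties broken
  by neutral mass then id.  Equivalence with a linear scan is asserted in
  the tests for both ppm and Da tolerances.
* Conjugated double bonds (locants two apart) cannot be written in the
  directional-bond scheme the assembler uses; such chains are rejected at
  assembly rather than silently mis-drawn.  The built-in pool contains
  only methylene-interrupted chains.
* Enumeration of a template with no eligible chain for a mandatory slot
  returns an empty set with a warning; an empty input hierarchy is valid
  and empty.
* Tables are written with fixed six-decimal formatting and sorted rows, so
  two runs on identical inputs are byte-identical.

## Problem sizes used by the tests

The suite checks oracle equivalence on fixtures of up to 10 chains and 3
templates, round-trip parsing on a ~140 000-record library (triacylglycerol
over 40 acids plus the PC classes over the full pool), 1000 m/z queries
against a >10^5-record index, and one full-scale `reference_library()`
build (574 240 isomeric subspecies).  These sizes were chosen to exercise
the engine at realistic library scale while keeping a complete test run in
a few minutes on one CPU.

## Known limitations

* Sphingolipids, sterols, hydroxylated/branched/cyclic chains and sphingoid
  bases are out of scope; the template model targets glycerolipids and
  glycerophospholipids.
* InChI/InChIKey computation is delegated: keys are accepted as input for
  identifier mapping (full 27-character equality by default, first-block
  matching as an explicit relaxation) but never computed internally.
* Isotope envelopes, multiply-charged and dimer adducts, and MS/MS
  fragmentation are not modeled.
* Ontology term validity (GO/Uberon/ECO, UniProtKB/Rhea identifiers) is
  syntactic only; no ontology files are consulted.
* Annotations attach at the level they were curated; aggregation over
  descendants is an explicit query option, never automatic.

## A worked example

```{r example}
t1 <- chain_library(data.frame(
  kind = c("fatty-alcohol", "fatty-acid"),
  carbons = c(16, 20), double_bonds = c(0, 4),
  positions = c("", "5Z,8Z,11Z,14Z"),
  trivial_name = c("hexadecanol", "arachidonic acid")))
iso <- enumerate_isomeric(builtin_templates()[["PC-O"]], t1)
iso[, c("abbreviation", "formula", "monoisotopic_mass")]
systematic_name(iso, t1)
h <- build_hierarchy(iso, chains = t1)
level_counts(h)
mz_search(h, 766.574517, 5, "ppm", "positive")[1:3, ]
```
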