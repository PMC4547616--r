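# Full-scale representative library: the complete built-in chain pool
# (80 fatty acids, 18 fatty alcohols) crossed with every built-in class
# template.  This is a synthetic reconstruction: the exact chain sets and
# the 51 curated class definitions of the original resource are not
# redistributed here, so per-class counts are representative of the
# generation procedure, not a transcription of the curated inputs.

#' Full-scale representative building-block set
#'
#' The entire built-in pool of 80 fatty acids and 18 fatty alcohols
#' paired with all built-in class templates (glycerophospholipids of six
#' headgroups in diacyl and ether form, lyso-PC, and the glycerolipids
#' MG, DG, TG).  Intended for full-scale generation runs; desk-scale
#' work should use [fixture_library()].
#'
#' @return A list with `chains` (a `chain_library`) and `templates`
#'   (named list of class templates).
#' @export
#' @examples
#' ref <- reference_library()
#' nrow(ref$chains); length(ref$templates)
reference_library <- function() {
  list(chains = chain_pool(), templates = builtin_templates())
}

#' Species subtree sizes
#'
#' Number of molecular, structural and isomeric descendants of one
#' species-level node, as shown on library browse listings.
#'
#' @param h A `lipid_hierarchy`.
#' @param species_label Species abbreviation, e.g. `"PC(O-36:5)"`.
#' @return Named integer vector with elements `molecular`, `structural`,
#'   `isomeric`.
#' @export
species_subtree <- function(h, species_label) {
  stopifnot(inherits(h, "lipid_hierarchy"))
  sp <- h$nodes$id[h$nodes$level == "Species" & h$nodes$label == species_label]
  if (length(sp) != 1) stop("species not found: ", species_label)
  mol <- h$edges$child_id[h$edges$parent_id %in% sp &
                            h$edges$child_level == "Molecular subspecies"]
  str <- h$edges$child_id[h$edges$parent_id %in% mol]
  iso <- h$edges$child_id[h$edges$parent_id %in% str]
  c(molecular = length(mol), structural = length(str), isomeric = length(iso))
}
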