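# Rollup from isomeric subspecies to structural/molecular subspecies and
# species, and construction of the deduplicated seven-level DAG.
# Node identity is (level, canonical label); stable identifiers are a
# deterministic hash of that key, so rebuilding from the same inputs
# reproduces the same ids without any registry.

#' Deterministic stable identifiers for hierarchy nodes
#'
#' `id = "LPD" + 16 hex digits` of a 64-bit FNV-1a hash of
#' `"<level>|<label>"`.  Identical keys always give identical ids, so
#' rebuilding from the same inputs (in any order) reproduces them; a
#' hash collision between distinct keys aborts.
#'
#' @param level,label Character vectors (recycled together).
#' @return Character vector of ids.
#' @export
#' @examples
#' assign_ids("Species", "PC(34:1)")
assign_ids <- function(level, label) {
  key <- paste0(level, "|", enc2utf8(label))
  id <- paste0("LPD", fnv1a64_hex(key))
  dup <- duplicated(id) & !duplicated(key)
  if (any(dup))
    stop("id hash collision for key(s): ", paste(key[dup], collapse = ", "))
  id
}

#' Structural parent of an isomeric abbreviation
#'
#' Drops double-bond positions and geometry, keeping linkage prefixes
#' and the sn assignment.  A structural abbreviation (nothing to drop)
#' is its own fixed point.
#'
#' @param x Abbreviation string(s) at isomeric or structural level.
#' @return Structural-level abbreviation string(s).
#' @export
#' @examples
#' parent_structural("PC(P-16:0/20:4(5Z,8Z,11Z,14Z))")
parent_structural <- function(x) {
  vapply(x, function(s) {
    ab <- parse_abbreviation(s)
    if (!ab$level %in% c("Isomeric subspecies", "Structural subspecies"))
      stop("parent_structural expects an isomeric or structural abbreviation, got ",
           ab$level, ": ", s)
    ab$terms$pos <- ""
    ab$level <- "Structural subspecies"
    format_abbreviation(ab)
  }, character(1), USE.NAMES = FALSE)
}

#' Molecular parent of a structural abbreviation
#'
#' Discards sn positions (terms are re-sorted canonically: ether chains
#' first, then by carbons and double bonds ascending, empty `0:0` terms
#' last) and rewrites every `P-n:d` term as `O-n:(d+1)`: at molecular
#' level the vinyl-ether double bond is indistinguishable from a chain
#' double bond, so a plasmalogen and the corresponding alkyl ether share
#' one molecular parent.
#'
#' @param x Structural-level abbreviation string(s).
#' @return Molecular-level abbreviation string(s).
#' @export
#' @examples
#' parent_molecular("PC(P-16:0/20:4)")
parent_molecular <- function(x) {
  vapply(x, function(s) {
    ab <- parse_abbreviation(s)
    if (ab$level != "Structural subspecies")
      stop("parent_molecular expects a structural abbreviation, got ",
           ab$level, ": ", s)
    t <- ab$terms
    alk <- t$prefix == "P-"
    t$db[alk] <- t$db[alk] + 1L
    t$prefix[alk] <- "O-"
    term <- .term_string(t$prefix, t$c, t$db, "", FALSE)
    t <- t[order(t$c == 0L, t$prefix != "O-", t$c, t$db, term), , drop = FALSE]
    ab$terms <- t
    ab$level <- "Molecular subspecies"
    format_abbreviation(ab)
  }, character(1), USE.NAMES = FALSE)
}

#' Species parent of a molecular abbreviation
#'
#' Sums carbons and double bonds across chains and keeps an `O-` flag
#' iff any chain is ether-linked.
#'
#' @param x Molecular-level abbreviation string(s).
#' @return Species-level abbreviation string(s).
#' @export
#' @examples
#' parent_species("PC(O-16:1_20:4)")
parent_species <- function(x) {
  vapply(x, function(s) {
    ab <- parse_abbreviation(s)
    if (ab$level != "Molecular subspecies")
      stop("parent_species expects a molecular abbreviation, got ",
           ab$level, ": ", s)
    t <- ab$terms
    terms <- data.frame(prefix = if (any(t$prefix == "O-")) "O-" else "",
                        c = sum(t$c), db = sum(t$db), pos = "",
                        stringsAsFactors = FALSE)
    format_abbreviation(lipid_abbreviation(ab$class_abbrev, "Species", terms))
  }, character(1), USE.NAMES = FALSE)
}

.mz_colnames <- function(registry = adduct_registry())
  paste0("mz:", registry$label)

#' Build the seven-level hierarchy from enumerated isomeric subspecies
#'
#' Rolls every isomeric subspecies up to its structural, molecular and
#' species parents, deduplicates nodes at every level, attaches the
#' subclass/class/category nodes from each template's metadata, and
#' annotates species-and-below nodes with formula, monoisotopic and
#' average mass and the m/z of the nine default adducts.  Isomeric nodes
#' additionally carry the structure string and systematic name.
#'
#' @param isos An `isomeric_set` (or a plain data frame row-binding
#'   several sets, with a `template_key` column).
#' @param templates Named list of the [class_template()]s referenced by
#'   `template_key`; defaults to the single `template` attribute.
#' @param chains The [chain_library()] used for enumeration (needed for
#'   systematic names; optional).
#' @param registry Adduct registry for m/z annotation.
#' @return A `lipid_hierarchy`: list with `nodes` and `edges` data
#'   frames.  Nodes have `id`, `level`, `label`, plus annotation
#'   columns; edges have `child_id`, `parent_id`, `child_level`,
#'   `parent_level`.
#' @export
build_hierarchy <- function(isos, templates = NULL, chains = NULL,
                            registry = adduct_registry()) {
  if (is.null(templates)) {
    tpl <- attr(isos, "template")
    templates <- if (is.null(tpl)) list() else stats::setNames(list(tpl), tpl$key)
  }
  if (nrow(isos) == 0) {
    nodes <- data.frame(id = character(0), level = character(0),
                        label = character(0), stringsAsFactors = FALSE)
    edges <- data.frame(child_id = character(0), parent_id = character(0),
                        child_level = character(0), parent_level = character(0))
    return(structure(list(nodes = nodes, edges = edges),
                     class = "lipid_hierarchy"))
  }
  isos <- as.data.frame(isos)
  # per-template vectorized rollup
  isos$structural <- NA_character_
  isos$molecular <- NA_character_
  isos$species <- NA_character_
  isos$name <- NA_character_
  for (key in unique(isos$template_key)) {
    tpl <- templates[[key]]
    if (is.null(tpl)) stop("no template supplied for key: ", key)
    sel <- which(isos$template_key == key)
    sub <- isos[sel, , drop = FALSE]
    sns <- tpl$slots$sn
    isos$structural[sel] <- .abbrev_structural_vec(tpl$abbreviation, sub, sns)
    isos$molecular[sel] <- .abbrev_molecular_vec(tpl$abbreviation, sub, sns)
    isos$species[sel] <- .abbrev_species_vec(tpl$abbreviation, sub, sns)
    if (!is.null(chains))
      isos$name[sel] <- systematic_name(sub, chains, tpl)
  }
  # mass consistency: all isomeric descendants of one species node share
  # one elemental composition
  rep_formula <- isos$formula[match(isos$species, isos$species)]
  if (!all(isos$formula == rep_formula))
    stop("species node with inconsistent descendant compositions")

  lower_node <- function(level, label, formula, mono, avg, smiles = NA,
                         name = NA) {
    keep <- !duplicated(label)
    data.frame(id = assign_ids(level, label[keep]), level = level,
               label = label[keep], name = name[keep],
               formula = formula[keep], monoisotopic_mass = mono[keep],
               average_mass = avg[keep],
               smiles = smiles[keep], stringsAsFactors = FALSE,
               check.names = FALSE)
  }
  n_iso <- lower_node("Isomeric subspecies", isos$abbreviation, isos$formula,
                      isos$monoisotopic_mass, isos$average_mass, isos$smiles,
                      isos$name)
  n_str <- lower_node("Structural subspecies", isos$structural, isos$formula,
                      isos$monoisotopic_mass, isos$average_mass,
                      rep(NA_character_, nrow(isos)))
  n_mol <- lower_node("Molecular subspecies", isos$molecular, isos$formula,
                      isos$monoisotopic_mass, isos$average_mass,
                      rep(NA_character_, nrow(isos)))
  n_spc <- lower_node("Species", isos$species, isos$formula,
                      isos$monoisotopic_mass, isos$average_mass,
                      rep(NA_character_, nrow(isos)))
  lower <- rbind(n_iso, n_str, n_mol, n_spc)
  for (j in seq_len(nrow(registry)))
    lower[[paste0("mz:", registry$label[j])]] <-
      adduct_mz(lower$monoisotopic_mass, registry$label[j], registry)

  # class-tier nodes from template metadata
  tpl_used <- templates[unique(isos$template_key)]
  tier <- function(level, labels) {
    labels <- unique(labels)
    data.frame(id = assign_ids(level, labels), level = level, label = labels,
               name = labels, formula = NA_character_,
               monoisotopic_mass = NA_real_, average_mass = NA_real_,
               smiles = NA_character_, stringsAsFactors = FALSE)
  }
  n_sub <- tier("Subclass", vapply(tpl_used, `[[`, "", "subclass_name"))
  n_cls <- tier("Class", vapply(tpl_used, `[[`, "", "class_name"))
  n_cat <- tier("Category", vapply(tpl_used, `[[`, "", "category"))
  upper <- rbind(n_sub, n_cls, n_cat)
  for (j in seq_len(nrow(registry)))
    upper[[paste0("mz:", registry$label[j])]] <- NA_real_
  nodes <- rbind(upper, lower)
  rownames(nodes) <- NULL
  if (anyDuplicated(nodes$id))
    stop("id hash collision across hierarchy nodes")

  edge <- function(child_level, child_label, parent_level, parent_label) {
    key <- paste0(child_label, "\r", parent_label)
    keep <- !duplicated(key)
    data.frame(child_id = assign_ids(child_level, child_label[keep]),
               parent_id = assign_ids(parent_level, parent_label[keep]),
               child_level = child_level, parent_level = parent_level,
               stringsAsFactors = FALSE)
  }
  tpl_species <- lapply(tpl_used, function(tpl)
    unique(isos$species[isos$template_key == tpl$key]))
  e_list <- list(
    edge("Isomeric subspecies", isos$abbreviation,
         "Structural subspecies", isos$structural),
    edge("Structural subspecies", isos$structural,
         "Molecular subspecies", isos$molecular),
    edge("Molecular subspecies", isos$molecular, "Species", isos$species))
  for (tpl in tpl_used) {
    spc <- tpl_species[[tpl$key]]
    e_list[[length(e_list) + 1]] <-
      edge("Species", spc, "Subclass", rep(tpl$subclass_name, length(spc)))
    e_list[[length(e_list) + 1]] <-
      edge("Subclass", tpl$subclass_name, "Class", tpl$class_name)
    e_list[[length(e_list) + 1]] <-
      edge("Class", tpl$class_name, "Category", tpl$category)
  }
  edges <- do.call(rbind, e_list)
  edges <- edges[!duplicated(paste0(edges$child_id, "\r", edges$parent_id)), ]
  rownames(edges) <- NULL
  # unique upward parent within the subspecies tiers
  for (lv in c("Isomeric subspecies", "Structural subspecies",
               "Molecular subspecies")) {
    ee <- edges[edges$child_level == lv, ]
    if (anyDuplicated(ee$child_id))
      stop("non-unique parent for a ", lv, " node")
  }
  structure(list(nodes = nodes, edges = edges), class = "lipid_hierarchy")
}

#' @export
print.lipid_hierarchy <- function(x, ...) {
  cat("<lipid_hierarchy> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  lc <- level_counts(x)
  for (i in seq_len(nrow(lc)))
    cat(sprintf("  %-22s %d\n", lc$level[i], lc$n[i]))
  invisible(x)
}

#' Node counts per hierarchy level
#'
#' @param h A `lipid_hierarchy`.
#' @return Data frame with columns `level` and `n`, one row per level in
#'   hierarchy order.
#' @export
level_counts <- function(h) {
  stopifnot(inherits(h, "lipid_hierarchy"))
  n <- vapply(.LEVELS, function(lv) sum(h$nodes$level == lv), integer(1))
  data.frame(level = .LEVELS, n = unname(n), stringsAsFactors = FALSE)
}
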