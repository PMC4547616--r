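# Lipid class templates: an sn-glycerol backbone fragment with typed
# attachment slots, plus category/class/subclass naming.  Templates drive
# both enumeration (which chains and linkages may occupy each slot) and
# hierarchy construction (class-tier node names).

.linkage_table <- data.frame(
  label = c("ester", "alkyl", "alkenyl"),
  prefix = c("", "O-", "P-"),
  chain_kind = c("fatty-acid", "fatty-alcohol", "fatty-alcohol"),
  # the obligatory 1Z vinyl-ether double bond of an alkenyl chain is not
  # printed in the chain's own d but counts in species/molecular sums
  db_increment = c(0L, 0L, 1L),
  stringsAsFactors = FALSE
)

#' Linkage registry
#'
#' The three glycerolipid chain linkages: `ester` (no abbreviation
#' prefix, requires a fatty acid), `alkyl` (`O-` prefix, fatty alcohol)
#' and `alkenyl` (`P-` prefix, fatty alcohol attached as a 1Z vinyl
#' ether, contributing one extra double bond to sum compositions).
#'
#' @return Data frame with columns `label`, `prefix`, `chain_kind`,
#'   `db_increment`.
#' @export
linkages <- function() .linkage_table

#' Construct a lipid class template
#'
#' A template is one lipid (sub)class: a backbone SMILES fragment with
#' numbered slot placeholders `{1}`, `{2}`, `{3}` (one per sn position),
#' the set of linkages each slot accepts, and the class-tier names used
#' in the hierarchy.  The free-backbone composition (all slots replaced
#' by hydroxyls) is derived from the fragment itself.
#'
#' @param key Unique template key (e.g. `"PC-O"`).
#' @param category Lipid category name (e.g. `"Glycerophospholipid"`).
#' @param class_name Class name (e.g. `"Glycerophosphocholine"`).
#' @param subclass_name Subclass name (e.g.
#'   `"Monoalkylmonoacylglycerophosphocholine"`).
#' @param abbreviation Class abbreviation used in shorthand names
#'   (e.g. `"PC"`).
#' @param backbone SMILES fragment with `{sn}` placeholders; must declare
#'   the sn-glycerol stereocenter.
#' @param backbone_name Systematic backbone/headgroup name used in
#'   systematic names (e.g. `"sn-glycero-3-phosphocholine"`).
#' @param slots Data frame with columns `sn` (integer), `linkages`
#'   (list column of character vectors; may be empty for an
#'   always-hydroxyl slot) and `may_be_empty` (logical).
#' @return A list of class `class_template`.
#' @export
class_template <- function(key, category, class_name, subclass_name,
                           abbreviation, backbone, backbone_name, slots) {
  stopifnot(is.character(abbreviation), nzchar(abbreviation))
  if (!grepl("@", backbone))
    stop("backbone must declare the sn-glycerol stereocenter: ", key)
  ph <- regmatches(backbone, gregexpr("\\{\\d+\\}", backbone))[[1]]
  ph_sn <- sort(as.integer(gsub("\\D", "", ph)))
  if (!identical(ph_sn, sort(as.integer(slots$sn))))
    stop("template ", key, ": placeholders ", paste(ph, collapse = ","),
         " do not match slots sn=", paste(slots$sn, collapse = ","))
  if (anyDuplicated(slots$sn)) stop("duplicate sn positions in template ", key)
  for (lk in unlist(slots$linkages))
    if (!lk %in% .linkage_table$label) stop("unknown linkage: ", lk)
  free <- backbone
  for (sn in slots$sn) free <- sub(paste0("{", sn, "}"), "O", free, fixed = TRUE)
  backbone_composition <- smiles_composition(free)
  structure(list(
    key = key, category = category, class_name = class_name,
    subclass_name = subclass_name, abbreviation = abbreviation,
    backbone = backbone, backbone_name = backbone_name,
    backbone_composition = backbone_composition,
    slots = slots), class = "class_template")
}

#' @export
print.class_template <- function(x, ...) {
  cat("<class_template> ", x$key, ": ", x$subclass_name,
      " [", x$abbreviation, "], ", nrow(x$slots), " slots, backbone ",
      formula_of(x$backbone_composition), "\n", sep = "")
  invisible(x)
}

.slots_df <- function(...) {
  # .slots_df(list(sn=1, linkages=c("ester"), may_be_empty=FALSE), ...)
  ll <- list(...)
  data.frame(
    sn = vapply(ll, function(s) as.integer(s$sn), integer(1)),
    linkages = I(lapply(ll, function(s) as.character(s$linkages))),
    may_be_empty = vapply(ll, function(s) isTRUE(s$may_be_empty), logical(1))
  )
}

# glycerophospholipid backbones share the sn-3 phospho-headgroup arm;
# stereo descriptor fixed so that the assembled structures match the
# natural (R)-sn-glycero-3-phospholipid configuration
.gp_backbone <- function(head) paste0("C({1})[C@@H]({2})COP(=O)", head)

#' Built-in class templates
#'
#' A set of curated glycerophospholipid and glycerolipid class templates:
#' diacyl and alkyl/alkenyl-acyl (ether) glycerophospholipids for the
#' common headgroups (PC, PE, PA, PG, PI, PS), lyso-PC, and the
#' glycerolipids MG, DG and TG.  Zwitterionic headgroups are written in
#' charge-separated form.
#'
#' @return A named list of [class_template()] objects.
#' @export
#' @examples
#' names(builtin_templates())
builtin_templates <- function() {
  acyl2 <- .slots_df(list(sn = 1, linkages = "ester"),
                     list(sn = 2, linkages = "ester"))
  ether_acyl <- .slots_df(list(sn = 1, linkages = c("alkyl", "alkenyl")),
                          list(sn = 2, linkages = "ester"))
  gp <- function(key, abbrev, class_name, sub_diacyl, sub_ether, head, hname) {
    list(
      class_template(key, "Glycerophospholipid", class_name, sub_diacyl,
                     abbrev, .gp_backbone(head), hname, acyl2),
      class_template(paste0(key, "-O"), "Glycerophospholipid", class_name,
                     sub_ether, abbrev, .gp_backbone(head), hname, ether_acyl)
    )
  }
  tt <- c(
    gp("PC", "PC", "Glycerophosphocholine",
       "Diacylglycerophosphocholine", "Monoalkylmonoacylglycerophosphocholine",
       "([O-])OCC[N+](C)(C)C", "sn-glycero-3-phosphocholine"),
    gp("PE", "PE", "Glycerophosphoethanolamine",
       "Diacylglycerophosphoethanolamine",
       "Monoalkylmonoacylglycerophosphoethanolamine",
       "([O-])OCC[NH3+]", "sn-glycero-3-phosphoethanolamine"),
    gp("PA", "PA", "Glycerophosphate",
       "Diacylglycerophosphate", "Monoalkylmonoacylglycerophosphate",
       "(O)O", "sn-glycero-3-phosphate"),
    gp("PG", "PG", "Glycerophosphoglycerol",
       "Diacylglycerophosphoglycerol", "Monoalkylmonoacylglycerophosphoglycerol",
       "(O)OC[C@@H](O)CO", "sn-glycero-3-phospho-(1'-sn-glycerol)"),
    gp("PI", "PI", "Glycerophosphoinositol",
       "Diacylglycerophosphoinositol", "Monoalkylmonoacylglycerophosphoinositol",
       "(O)OC1C(O)C(O)C(O)C(O)C1O", "sn-glycero-3-phospho-(1'-myo-inositol)"),
    gp("PS", "PS", "Glycerophosphoserine",
       "Diacylglycerophosphoserine", "Monoalkylmonoacylglycerophosphoserine",
       "([O-])OC[C@@H]([NH3+])C(O)=O", "sn-glycero-3-phosphoserine"),
    list(
      class_template("LPC", "Glycerophospholipid", "Glycerophosphocholine",
                     "Monoacylglycerophosphocholine", "LPC",
                     .gp_backbone("([O-])OCC[N+](C)(C)C"),
                     "sn-glycero-3-phosphocholine",
                     .slots_df(list(sn = 1, linkages = "ester"),
                               list(sn = 2, linkages = character(0),
                                    may_be_empty = TRUE))),
      class_template("MG", "Glycerolipid", "Monoradylglycerol",
                     "Monoacylglycerol", "MG",
                     "C({1})[C@@H]({2})C({3})", "sn-glycerol",
                     .slots_df(list(sn = 1, linkages = "ester"),
                               list(sn = 2, linkages = character(0),
                                    may_be_empty = TRUE),
                               list(sn = 3, linkages = character(0),
                                    may_be_empty = TRUE))),
      class_template("DG", "Glycerolipid", "Diradylglycerol",
                     "Diacylglycerol", "DG",
                     "C({1})[C@@H]({2})C({3})", "sn-glycerol",
                     .slots_df(list(sn = 1, linkages = "ester"),
                               list(sn = 2, linkages = "ester"),
                               list(sn = 3, linkages = character(0),
                                    may_be_empty = TRUE))),
      class_template("TG", "Glycerolipid", "Triradylglycerol",
                     "Triacylglycerol", "TG",
                     "C({1})[C@@H]({2})C({3})", "sn-glycerol",
                     .slots_df(list(sn = 1, linkages = "ester"),
                               list(sn = 2, linkages = "ester"),
                               list(sn = 3, linkages = "ester")))
    )
  )
  stats::setNames(tt, vapply(tt, function(t) t$key, character(1)))
}

#' Load class templates from a YAML config file
#'
#' The file holds a list of template entries with fields `key`,
#' `category`, `class_name`, `subclass_name`, `abbreviation`,
#' `backbone`, `backbone_name` and `slots` (each slot: `sn`, `linkages`,
#' `may_be_empty`).
#'
#' @param path Path to the YAML file.
#' @return Named list of [class_template()] objects.
#' @export
load_templates <- function(path) {
  if (!file.exists(path)) stop("cannot read template file: ", path)
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) stop("empty template file: ", path)
  tt <- lapply(raw, function(r) {
    slots <- do.call(.slots_df, lapply(r$slots, function(s)
      list(sn = s$sn, linkages = unlist(s$linkages) %||% character(0),
           may_be_empty = isTRUE(s$may_be_empty))))
    class_template(r$key, r$category, r$class_name, r$subclass_name,
                   r$abbreviation, r$backbone, r$backbone_name, slots)
  })
  stats::setNames(tt, vapply(tt, function(t) t$key, character(1)))
}

#' Write class templates to a YAML config file
#'
#' @param templates Named list of `class_template` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_templates <- function(templates, path) {
  out <- lapply(templates, function(t) {
    list(key = t$key, category = t$category, class_name = t$class_name,
         subclass_name = t$subclass_name, abbreviation = t$abbreviation,
         backbone = t$backbone, backbone_name = t$backbone_name,
         slots = lapply(seq_len(nrow(t$slots)), function(i)
           list(sn = t$slots$sn[i],
                linkages = as.list(t$slots$linkages[[i]]),
                may_be_empty = t$slots$may_be_empty[i])))
  })
  yaml::write_yaml(unname(out), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
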