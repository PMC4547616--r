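# Evidence-linked annotation store: lipid occurrence in tissues/taxa
# (GO/Uberon terms) and enzyme-reaction links, each backed by a mandatory
# Evidence Codes Ontology (ECO) code, plus the per-lipid information
# flags shown on entry listings.

.re_eco <- "^ECO:[0-9]{7}$"
.re_term <- "^(GO|UBERON):[0-9]{7}$"
.re_rhea <- "^RHEA:[0-9]+$"
# UniProtKB accession syntax (6- and 10-character forms)
.re_uniprot <- paste0(
  "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$")

.occurrence_cols <- c("lipid_id", "term_id", "taxon_id", "eco", "pmid",
                      "source_text")
.enzyme_cols <- c("protein_acc", "reaction_id", "eco", "pmid", "lipid_id")

.check_pmid <- function(pmid) {
  is.na(pmid) | (!is.na(suppressWarnings(as.integer(pmid))) &
                   suppressWarnings(as.integer(pmid)) > 0)
}

#' Load and validate occurrence and enzyme-reaction annotations
#'
#' Occurrence rows link a lipid id to a GO or Uberon term and an NCBI
#' taxon; enzyme rows link a UniProtKB protein accession to a Rhea
#' reaction id (optionally naming a participating lipid).  Every row
#' must carry a syntactically valid ECO evidence code; a PubMed id and
#' source text are optional.  Invalid rows are rejected with reasons;
#' ontology and accession validity is syntactic only (no ontology files
#' are consulted).
#'
#' @param occurrence_path TSV with columns `lipid_id`, `term_id`,
#'   `taxon_id`, `eco`, `pmid`, `source_text` (or `NULL` to skip).
#' @param enzyme_path TSV with columns `protein_acc`, `reaction_id`,
#'   `eco`, `pmid` and optionally `lipid_id` (or `NULL` to skip).
#' @param node_ids Optional character vector of known lipid ids; rows
#'   referencing other ids are rejected.
#' @return A list of class `annotation_store`: `occurrence`, `enzymes`
#'   (validated data frames) and `diagnostics` (`file`, `row`,
#'   `message`).
#' @export
load_annotations <- function(occurrence_path = NULL, enzyme_path = NULL,
                             node_ids = NULL) {
  diags <- list()
  note <- function(file, row, msg)
    diags[[length(diags) + 1]] <<- data.frame(file = file, row = row,
                                              message = msg,
                                              stringsAsFactors = FALSE)
  occurrence <- data.frame(matrix(character(0), 0, 6,
                                  dimnames = list(NULL, .occurrence_cols)),
                           stringsAsFactors = FALSE)
  if (!is.null(occurrence_path)) {
    if (!file.exists(occurrence_path))
      stop("cannot read occurrence file: ", occurrence_path)
    raw <- utils::read.delim(occurrence_path, comment.char = "#",
                             colClasses = "character",
                             stringsAsFactors = FALSE)
    for (cc in .occurrence_cols) if (is.null(raw[[cc]])) raw[[cc]] <- ""
    keep <- logical(nrow(raw))
    for (i in seq_len(nrow(raw))) {
      msg <- NULL
      if (!grepl(.re_eco, raw$eco[i]))
        msg <- paste0("missing or malformed ECO code: '", raw$eco[i], "'")
      else if (!grepl(.re_term, raw$term_id[i]))
        msg <- paste0("term_id must be GO:nnnnnnn or UBERON:nnnnnnn: '",
                      raw$term_id[i], "'")
      else if (is.na(suppressWarnings(as.integer(raw$taxon_id[i]))) ||
                 as.integer(raw$taxon_id[i]) <= 0)
        msg <- "taxon_id must be a positive integer"
      else if (nzchar(raw$pmid[i]) && !.check_pmid(raw$pmid[i]))
        msg <- "pmid must be a positive integer when present"
      else if (!is.null(node_ids) && !raw$lipid_id[i] %in% node_ids)
        msg <- paste0("unknown lipid id: ", raw$lipid_id[i])
      if (is.null(msg)) keep[i] <- TRUE else note("occurrence", i, msg)
    }
    occurrence <- raw[keep, .occurrence_cols, drop = FALSE]
    rownames(occurrence) <- NULL
  }
  enzymes <- data.frame(matrix(character(0), 0, 5,
                               dimnames = list(NULL, .enzyme_cols)),
                        stringsAsFactors = FALSE)
  if (!is.null(enzyme_path)) {
    if (!file.exists(enzyme_path))
      stop("cannot read enzyme file: ", enzyme_path)
    raw <- utils::read.delim(enzyme_path, comment.char = "#",
                             colClasses = "character",
                             stringsAsFactors = FALSE)
    for (cc in .enzyme_cols) if (is.null(raw[[cc]])) raw[[cc]] <- ""
    keep <- logical(nrow(raw))
    for (i in seq_len(nrow(raw))) {
      msg <- NULL
      if (!grepl(.re_eco, raw$eco[i]))
        msg <- paste0("missing or malformed ECO code: '", raw$eco[i], "'")
      else if (!grepl(.re_uniprot, raw$protein_acc[i]))
        msg <- paste0("malformed UniProtKB accession: '", raw$protein_acc[i], "'")
      else if (!grepl(.re_rhea, raw$reaction_id[i]))
        msg <- paste0("malformed Rhea identifier: '", raw$reaction_id[i], "'")
      else if (nzchar(raw$pmid[i]) && !.check_pmid(raw$pmid[i]))
        msg <- "pmid must be a positive integer when present"
      else if (!is.null(node_ids) && nzchar(raw$lipid_id[i]) &&
                 !raw$lipid_id[i] %in% node_ids)
        msg <- paste0("unknown lipid id: ", raw$lipid_id[i])
      if (is.null(msg)) keep[i] <- TRUE else note("enzymes", i, msg)
    }
    enzymes <- raw[keep, .enzyme_cols, drop = FALSE]
    rownames(enzymes) <- NULL
  }
  diagnostics <- if (length(diags)) do.call(rbind, diags)
                 else data.frame(file = character(0), row = integer(0),
                                 message = character(0))
  structure(list(occurrence = occurrence, enzymes = enzymes,
                 diagnostics = diagnostics), class = "annotation_store")
}

.descendants <- function(h, id) {
  out <- character(0)
  frontier <- id
  repeat {
    nxt <- h$edges$child_id[h$edges$parent_id %in% frontier]
    nxt <- setdiff(nxt, out)
    if (length(nxt) == 0) break
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Information flags for a lipid entry
#'
#' Every generated lipid has cheminformatic descriptors (`ch`) and is
#' classified in the hierarchy (`cl`).  `lo` is set when an occurrence
#' annotation (tissue/taxon) attaches to the lipid; `me` when the lipid
#' participates in a loaded enzyme-reaction link.  Annotations attach at
#' the level they were curated and are not propagated automatically;
#' `with_descendants = TRUE` opts into aggregating flags from the
#' lipid's descendant subtree.
#'
#' @param lipid_id A node id of `hierarchy`.
#' @param store An [load_annotations()] store.
#' @param hierarchy A `lipid_hierarchy`.
#' @param with_descendants Aggregate annotations from descendants.
#' @return Character vector: subset of `c("ch", "cl", "lo", "me")`.
#' @export
info_flags <- function(lipid_id, store, hierarchy, with_descendants = FALSE) {
  stopifnot(inherits(store, "annotation_store"),
            inherits(hierarchy, "lipid_hierarchy"))
  if (!lipid_id %in% hierarchy$nodes$id)
    stop("unknown lipid id: ", lipid_id)
  ids <- lipid_id
  if (with_descendants) ids <- c(ids, .descendants(hierarchy, lipid_id))
  flags <- c("ch", "cl")
  if (any(store$occurrence$lipid_id %in% ids)) flags <- c(flags, "lo")
  if (any(store$enzymes$lipid_id %in% ids)) flags <- c(flags, "me")
  flags
}
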