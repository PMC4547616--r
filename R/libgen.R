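# End-to-end library generation: load building blocks, enumerate every
# template, build and annotate the hierarchy, export flat TSV tables and
# SDF structures.  Outputs are deterministic: two runs on identical inputs
# produce byte-identical node and edge tables.

.rbind_fill <- function(dfs) {
  dfs <- dfs[vapply(dfs, nrow, integer(1)) > 0]
  if (length(dfs) == 0) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d)))
      d[[cc]] <- if (grepl("_(chain|c|db|dbsum)$", cc)) NA_integer_
                 else NA_character_
    d[cols]
  }))
}

#' Enumerate every template of a set over one chain library
#'
#' Convenience wrapper around [enumerate_isomeric()] that row-binds the
#' per-template sets (templates with fewer slots get `NA` slot columns).
#'
#' @param templates Named list of [class_template()]s.
#' @param chains A [chain_library()].
#' @param structures Assemble SMILES strings (default `TRUE`).
#' @return A data frame with one row per isomeric subspecies across all
#'   templates, with a `template_key` column.
#' @export
enumerate_all <- function(templates, chains, structures = TRUE) {
  sets <- lapply(templates, enumerate_isomeric, chains = chains,
                 structures = structures)
  out <- .rbind_fill(lapply(sets, as.data.frame))
  if (is.null(out)) stop("no structures enumerated")
  rownames(out) <- NULL
  out
}

.fmt_num <- function(x, digits = 6) {
  out <- ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
  out
}

#' Generate, annotate and export a lipid library
#'
#' The full pipeline: load the chain library and class templates,
#' enumerate every isomeric subspecies, build the seven-level hierarchy
#' with names, formulas, masses and adduct m/z values, and write
#' `nodes.tsv`, `edges.tsv`, `counts.tsv` and a `diagnostics.tsv`
#' sidecar to `out_dir`.  Masses and m/z values are written to six
#' decimal places; rows are sorted so identical inputs give
#' byte-identical outputs.
#'
#' @param chains A [chain_library()] or path to a chain TSV.
#' @param templates Named list of [class_template()]s or path to a
#'   template YAML file.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing and just returns the summary.
#' @param registry Adduct registry (default: the built-in nine).
#' @param structures,names Assemble SMILES strings / systematic names
#'   for isomeric nodes.
#' @return Invisibly, a summary list with the `lipid_hierarchy`, the
#'   per-level counts, per-class isomeric counts and any load
#'   diagnostics.
#' @export
generate_library <- function(chains, templates, out_dir = NULL,
                             registry = adduct_registry(),
                             structures = TRUE, names = TRUE) {
  diagnostics <- data.frame(row = integer(0), message = character(0))
  if (is.character(chains)) {
    loaded <- load_chain_library(chains)
    chains <- loaded$chains
    diagnostics <- loaded$diagnostics
  }
  if (is.character(templates)) templates <- load_templates(templates)
  if (length(templates) == 0) stop("no class templates supplied")
  isos <- enumerate_all(templates, chains, structures = structures)
  h <- build_hierarchy(isos, templates,
                       chains = if (names) chains else NULL,
                       registry = registry)
  counts <- level_counts(h)
  per_class <- stats::aggregate(list(isomeric = isos$abbreviation),
                                by = list(template = isos$template_key),
                                FUN = length)
  per_class <- per_class[order(per_class$template), ]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hierarchy(h, out_dir)
    utils::write.table(counts, file.path(out_dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(diagnostics, file.path(out_dir, "diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(structure(list(hierarchy = h, counts = counts,
                           per_class = per_class,
                           diagnostics = diagnostics),
                      class = "library_summary"))
}

#' @export
print.library_summary <- function(x, ...) {
  cat("lipid library summary\n")
  for (i in seq_len(nrow(x$counts)))
    cat(sprintf("  %-22s %d\n", x$counts$level[i], x$counts$n[i]))
  cat("isomeric subspecies per class template:\n")
  for (i in seq_len(nrow(x$per_class)))
    cat(sprintf("  %-22s %d\n", x$per_class$template[i], x$per_class$isomeric[i]))
  if (nrow(x$diagnostics))
    cat("rejected input rows:", nrow(x$diagnostics), "\n")
  invisible(x)
}

#' Write / read the hierarchy as flat TSV tables
#'
#' `nodes.tsv` holds one row per node (id, level, label, name, formula,
#' masses, adduct m/z, structure string); `edges.tsv` one row per
#' parent-child link.  `read_hierarchy()` restores a `lipid_hierarchy`
#' from a directory written by `write_hierarchy()`.
#'
#' @param h A `lipid_hierarchy`.
#' @param dir Directory for the two files.
#' @return `write_hierarchy()`: `dir`, invisibly; `read_hierarchy()`:
#'   a `lipid_hierarchy`.
#' @export
write_hierarchy <- function(h, dir) {
  stopifnot(inherits(h, "lipid_hierarchy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- h$nodes
  ord <- order(match(nodes$level, .LEVELS), nodes$label)
  nodes <- nodes[ord, , drop = FALSE]
  for (cc in names(nodes))
    if (is.numeric(nodes[[cc]])) nodes[[cc]] <- .fmt_num(nodes[[cc]])
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  edges <- h$edges
  edges <- edges[order(match(edges$child_level, .LEVELS), edges$child_id,
                       edges$parent_id), , drop = FALSE]
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(dir) {
  nodes <- utils::read.delim(file.path(dir, "nodes.tsv"), check.names = FALSE,
                             stringsAsFactors = FALSE, na.strings = "")
  for (cc in c("monoisotopic_mass", "average_mass",
               grep("^mz:", names(nodes), value = TRUE)))
    nodes[[cc]] <- as.numeric(nodes[[cc]])
  edges <- utils::read.delim(file.path(dir, "edges.tsv"),
                             stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "lipid_hierarchy")
}

#' Export isomeric-level records as an SDF file
#'
#' One molecule block per record (converted from the structure string by
#' Open Babel via the ChemmineOB package) followed by named data fields:
#' id, abbreviation, systematic name, formula, monoisotopic mass and the
#' adduct m/z values present in the input.  Records without a structure
#' string are skipped with a warning.  The Open Babel header timestamp
#' is normalized so outputs are reproducible.
#'
#' @param records Data frame with at least `smiles`; recognised
#'   annotation columns: `id`, `label`/`abbreviation`, `name`,
#'   `formula`, `monoisotopic_mass` and `mz:*` columns.
#' @param path Output SDF path.
#' @return `path`, invisibly.
#' @export
export_sdf <- function(records, path) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("export_sdf requires the ChemmineOB package")
  records <- as.data.frame(records)
  if (is.null(records$smiles)) records$smiles <- NA_character_
  skip <- is.na(records$smiles) | !nzchar(records$smiles)
  if (any(skip))
    warning("skipping ", sum(skip), " record(s) without a structure string")
  records <- records[!skip, , drop = FALSE]
  if (nrow(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ids <- if (!is.null(records$id)) records$id else sprintf("MOL%05d", seq_len(nrow(records)))
  smi <- paste0(paste(records$smiles, ids), "\n", collapse = "")
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", smi)
  blocks <- strsplit(sdf, "\\$\\$\\$\\$\n")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  if (length(blocks) != nrow(records))
    stop("structure conversion returned ", length(blocks), " molecules for ",
         nrow(records), " records")
  label_col <- if (!is.null(records$abbreviation)) "abbreviation" else "label"
  field_of <- function(i) {
    f <- c()
    add <- function(tag, value) {
      if (!is.null(value) && !is.na(value) && nzchar(as.character(value)))
        f <<- c(f, paste0(">  <", tag, ">"), as.character(value), "")
      invisible(NULL)
    }
    add("id", ids[i])
    add("abbreviation", records[[label_col]][i])
    add("name", records$name[i])
    add("formula", records$formula[i])
    if (!is.null(records$monoisotopic_mass))
      add("monoisotopic_mass", .fmt_num(records$monoisotopic_mass[i]))
    for (cc in grep("^mz:", names(records), value = TRUE))
      add(cc, .fmt_num(records[[cc]][i]))
    f
  }
  out <- character(0)
  for (i in seq_along(blocks)) {
    lines <- strsplit(blocks[i], "\n")[[1]]
    lines[2] <- " lipidgen          2D"   # drop the Open Babel timestamp
    out <- c(out, lines, field_of(i), "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}
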