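# Fragment substitution and combinatorial enumeration of isomeric
# subspecies: each template slot is filled with a (chain, linkage) pair,
# the backbone placeholders are replaced by chain residue fragments, and
# the elemental composition follows by condensation arithmetic (one water
# released per filled slot).

.water <- c(H = 2L, O = 1L)

#' SMILES residue fragment for a chain under a given linkage
#'
#' The fragment starts with the linking oxygen so that substituting it
#' into a backbone placeholder forms the ester (`OC(=O)...`), ether
#' (`O...`) or 1Z vinyl ether (`O/C=C\\...`) bond.  Double-bond geometry
#' is written with directional bonds; conjugated double bonds (locants
#' two apart) are not expressible in this scheme and raise an error.
#'
#' @param chain One chain-library row (list or one-row data frame).
#' @param linkage `"ester"`, `"alkyl"` or `"alkenyl"`.
#' @return A SMILES fragment string.
#' @export
#' @examples
#' chain_fragment(list(kind = "fatty-acid", carbons = 16, double_bonds = 0,
#'                     positions = ""), "ester")
chain_fragment <- function(chain, linkage) {
  info <- .linkage_table[.linkage_table$label == linkage, ]
  if (nrow(info) == 0) stop("unknown linkage: ", linkage)
  if (chain$kind != info$chain_kind)
    stop("linkage ", linkage, " requires a ", info$chain_kind,
         ", got ", chain$kind)
  n <- as.integer(chain$carbons)
  pp <- .parse_positions(chain$positions %||% "")
  pos <- pp$pos; geom <- pp$geom
  if (linkage == "alkenyl") {
    pos <- c(1L, pos); geom <- c("Z", geom)
  }
  if (any(diff(pos) < 3))
    stop("conjugated or adjacent double bonds are not supported: ",
         chain$positions)
  # bond[k] = bond written before carbon k (bond k-1 -> k; bond[1] is O -> C1)
  bond <- rep("", n + 1L)
  for (i in seq_along(pos)) {
    p <- pos[i]
    bond[p + 1L] <- "="
    bond[p] <- "/"
    if (p + 2L <= n) bond[p + 2L] <- if (geom[i] == "Z") "\\" else "/"
  }
  first <- if (linkage == "ester") 2L else 1L
  stem <- if (linkage == "ester") "OC(=O)" else "O"
  paste0(stem, paste0(bond[first:n], "C", collapse = ""))
}

.assignment_check <- function(template, assignment) {
  slots <- template$slots
  if (length(assignment) != nrow(slots))
    stop("assignment must have one entry per slot (", nrow(slots), ")")
  for (i in seq_len(nrow(slots))) {
    a <- assignment[[i]]
    sn <- slots$sn[i]
    # an EMPTY slot renders a free hydroxyl; enumeration (not this
    # mechanical check) enforces which slots may be left empty
    if (.is_empty_slot(a)) next
    if (!a$linkage %in% slots$linkages[[i]])
      stop("linkage ", a$linkage, " not allowed at slot sn-", sn,
           " of ", template$key)
    req <- .linkage_table$chain_kind[.linkage_table$label == a$linkage]
    if (a$chain$kind != req)
      stop("slot sn-", sn, ": linkage ", a$linkage, " requires a ", req)
  }
  invisible(TRUE)
}

.is_empty_slot <- function(a) {
  is.null(a) || identical(a$linkage, "empty") || is.null(a$chain)
}

#' Elemental composition of an assembled lipid
#'
#' Backbone composition plus the free-molecule composition of every
#' attached chain, minus one water per filled slot (each ester, ether or
#' vinyl-ether condensation releases one water).  An alkenyl chain
#' contributes the composition of the corresponding alcohol with one
#' additional degree of unsaturation (two hydrogens fewer).
#'
#' @param template A [class_template()].
#' @param assignment List with one entry per slot, each either
#'   `list(chain = <chain row>, linkage = <label>)` or `NULL` /
#'   `list(linkage = "empty")` for an empty slot.
#' @return An `elemental_composition`.
#' @export
lipid_composition <- function(template, assignment) {
  .assignment_check(template, assignment)
  total <- template$backbone_composition
  for (a in assignment) {
    if (.is_empty_slot(a)) next
    contrib <- chain_composition(a$chain)
    if (a$linkage == "alkenyl") contrib <- comp_subtract(contrib, c(H = 2L))
    total <- comp_subtract(comp_add(total, contrib), .water)
  }
  total
}

#' Assemble the structure string for one slot assignment
#'
#' Replaces each numbered placeholder in the template backbone with the
#' residue fragment of the assigned chain (empty slots become free
#' hydroxyls), preserving the sn-glycerol stereocenter and double-bond
#' geometry.
#'
#' @inheritParams lipid_composition
#' @return A SMILES string with no unreplaced placeholders.
#' @export
assemble_structure <- function(template, assignment) {
  .assignment_check(template, assignment)
  s <- template$backbone
  for (i in seq_len(nrow(template$slots))) {
    a <- assignment[[i]]
    frag <- if (.is_empty_slot(a)) "O" else chain_fragment(a$chain, a$linkage)
    s <- sub(paste0("{", template$slots$sn[i], "}"), frag, s, fixed = TRUE)
  }
  if (grepl("\\{\\d+\\}", s)) stop("unreplaced placeholder in: ", s)
  s
}

# per-slot option table: one row per eligible (chain, linkage) pair plus,
# where allowed, the empty option
.slot_options <- function(template, chains, slot_idx) {
  slots <- template$slots
  opts <- list()
  for (lk in slots$linkages[[slot_idx]]) {
    req <- .linkage_table$chain_kind[.linkage_table$label == lk]
    idx <- which(chains$kind == req)
    if (length(idx))
      opts[[length(opts) + 1]] <- data.frame(chain = idx, linkage = lk,
                                             stringsAsFactors = FALSE)
  }
  out <- if (length(opts)) do.call(rbind, opts)
         else data.frame(chain = integer(0), linkage = character(0))
  if (slots$may_be_empty[slot_idx])
    out <- rbind(data.frame(chain = NA_integer_, linkage = "empty"), out)
  info <- .linkage_table[match(out$linkage, .linkage_table$label), ]
  out$prefix <- ifelse(out$linkage == "empty", "", info$prefix)
  out$c <- ifelse(is.na(out$chain), 0L, chains$carbons[out$chain])
  out$db <- ifelse(is.na(out$chain), 0L, chains$double_bonds[out$chain])
  out$pos <- ifelse(is.na(out$chain), "", chains$positions[out$chain])
  # double bonds counted at species/molecular level (alkenyl adds the 1Z)
  out$db_sum <- out$db + ifelse(out$linkage == "alkenyl", 1L, 0L)
  out$fragment <- vapply(seq_len(nrow(out)), function(i) {
    if (out$linkage[i] == "empty") "O"
    else chain_fragment(chains[out$chain[i], ], out$linkage[i])
  }, character(1))
  # composition contribution net of the released water
  delta <- matrix(0, nrow(out), length(.comp_elements),
                  dimnames = list(NULL, .comp_elements))
  for (i in seq_len(nrow(out))) {
    if (out$linkage[i] == "empty") next
    contrib <- chain_composition(chains[out$chain[i], ])
    if (out$linkage[i] == "alkenyl") contrib <- comp_subtract(contrib, c(H = 2L))
    contrib <- comp_subtract(contrib, .water)
    delta[i, names(contrib)] <- delta[i, names(contrib)] + unclass(contrib)
  }
  attr(out, "delta") <- delta
  out
}

.comp_elements <- c("C", "H", "N", "O", "P", "S", "Na", "K", "Li", "Cl")

.comp_to_row <- function(cc) {
  v <- stats::setNames(numeric(length(.comp_elements)), .comp_elements)
  v[names(cc)] <- unclass(cc)
  v
}

.row_to_formula <- function(m) {
  # vectorized Hill-order formulas from a count matrix (carbon-bearing rows)
  ord <- c("C", "H", sort(setdiff(colnames(m), c("C", "H"))))
  slow <- m[, "C"] == 0
  pieces <- lapply(ord, function(el) {
    n <- m[, el]
    ifelse(n == 0, "", paste0(el, ifelse(n == 1, "", n)))
  })
  out <- do.call(paste0, pieces)
  if (any(slow))
    out[slow] <- apply(m[slow, , drop = FALSE], 1, function(r)
      formula_of(do.call(comp, as.list(r[r > 0]))))
  out
}

#' Enumerate all isomeric subspecies of a template over a chain library
#'
#' Forms the exact Cartesian product over slots of the eligible
#' (chain, linkage) pairs (plus the empty option where a slot may be
#' empty), restricted to the listed chains only -- no hypothetical
#' double-bond positions are invented.  Output rows are deterministic:
#' sorted by slot-wise (prefix, carbons, double bonds, positions).
#'
#' @param template A [class_template()].
#' @param chains A [chain_library()].
#' @param structures If `TRUE` (default), assemble the SMILES string of
#'   every structure.
#' @return A data frame of class `isomeric_set`: one row per isomeric
#'   subspecies with the slot assignment (`sn<i>_chain`, `sn<i>_linkage`,
#'   `sn<i>_prefix`, `sn<i>_c`, `sn<i>_db`, `sn<i>_pos`, `sn<i>_dbsum`),
#'   `abbreviation`, `formula`, `monoisotopic_mass`, `average_mass` and
#'   `smiles`.  The template is attached as attribute `template`.
#' @export
#' @examples
#' fx <- fixture_library(2, 0, seed = 1)
#' nrow(enumerate_isomeric(fx$templates$PC, fx$chains))  # 2 x 2 = 4
enumerate_isomeric <- function(template, chains, structures = TRUE) {
  stopifnot(inherits(template, "class_template"))
  if (nrow(chains) == 0) stop("chains must be non-empty")
  nslot <- nrow(template$slots)
  opts <- lapply(seq_len(nslot), .slot_options, template = template,
                 chains = chains)
  n_opts <- vapply(opts, nrow, integer(1))
  if (any(n_opts == 0)) {
    warning("template ", template$key, ": no eligible chain for slot sn-",
            paste(template$slots$sn[n_opts == 0], collapse = ", sn-"))
    return(.empty_isomeric(template))
  }
  grid <- do.call(expand.grid, c(lapply(rev(n_opts), seq_len),
                                 KEEP.OUT.ATTRS = FALSE))
  grid <- grid[, rev(seq_len(nslot)), drop = FALSE]  # slot 1 varies slowest
  names(grid) <- paste0("s", seq_len(nslot))
  out <- data.frame(template_key = rep(template$key, nrow(grid)),
                    stringsAsFactors = FALSE)
  total <- matrix(rep(.comp_to_row(template$backbone_composition),
                      each = nrow(grid)),
                  nrow = nrow(grid), dimnames = list(NULL, .comp_elements))
  smiles_parts <- strsplit(template$backbone, "\\{\\d+\\}")[[1]]
  ph <- regmatches(template$backbone,
                   gregexpr("\\{\\d+\\}", template$backbone))[[1]]
  ph_order <- as.integer(gsub("\\D", "", ph))  # sn of each placeholder
  frag_cols <- vector("list", nslot)
  for (i in seq_len(nslot)) {
    o <- opts[[i]]
    gi <- grid[[i]]
    sn <- template$slots$sn[i]
    out[[paste0("sn", sn, "_chain")]] <- o$chain[gi]
    out[[paste0("sn", sn, "_linkage")]] <- o$linkage[gi]
    out[[paste0("sn", sn, "_prefix")]] <- o$prefix[gi]
    out[[paste0("sn", sn, "_c")]] <- o$c[gi]
    out[[paste0("sn", sn, "_db")]] <- o$db[gi]
    out[[paste0("sn", sn, "_pos")]] <- o$pos[gi]
    out[[paste0("sn", sn, "_dbsum")]] <- o$db_sum[gi]
    total <- total + attr(o, "delta")[gi, , drop = FALSE]
    frag_cols[[i]] <- o$fragment[gi]
  }
  out$formula <- .row_to_formula(total)
  out$monoisotopic_mass <- as.numeric(total %*% .mono_mass_vec[.comp_elements])
  out$average_mass <- as.numeric(total %*% .avg_mass_vec[.comp_elements])
  if (structures) {
    pieces <- list(smiles_parts[1])
    for (j in seq_along(ph_order)) {
      slot_i <- match(ph_order[j], template$slots$sn)
      pieces[[length(pieces) + 1]] <- frag_cols[[slot_i]]
      pieces[[length(pieces) + 1]] <- smiles_parts[j + 1]
    }
    pieces <- pieces[!vapply(pieces, function(p) identical(p, ""), logical(1))]
    out$smiles <- do.call(paste0, pieces)
  } else {
    out$smiles <- NA_character_
  }
  out$abbreviation <- .abbrev_isomeric_vec(template$abbreviation, out, nslot,
                                           template$slots$sn)
  # deterministic order: slot-wise (prefix, C, DB, positions)
  keys <- list()
  for (sn in template$slots$sn) {
    keys[[length(keys) + 1]] <- out[[paste0("sn", sn, "_prefix")]]
    keys[[length(keys) + 1]] <- out[[paste0("sn", sn, "_c")]]
    keys[[length(keys) + 1]] <- out[[paste0("sn", sn, "_db")]]
    keys[[length(keys) + 1]] <- out[[paste0("sn", sn, "_pos")]]
  }
  ord <- do.call(order, c(keys, list(method = "radix")))
  out <- out[ord, , drop = FALSE]
  attr(out, "row.names") <- .set_row_names(nrow(out))
  attr(out, "template") <- template
  class(out) <- c("isomeric_set", "data.frame")
  out
}

.empty_isomeric <- function(template) {
  out <- data.frame(template_key = character(0), abbreviation = character(0),
                    formula = character(0), monoisotopic_mass = numeric(0),
                    average_mass = numeric(0), smiles = character(0),
                    stringsAsFactors = FALSE)
  attr(out, "template") <- template
  class(out) <- c("isomeric_set", "data.frame")
  out
}
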