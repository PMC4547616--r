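# Minimal SMILES reader for the acyclic/small-ring, non-aromatic structure
# strings this package emits: enough to recover an elemental composition
# (with implicit hydrogens) and an atom/bond graph for validation.
# General-purpose cheminformatics (canonicalization, InChI, depiction) is
# deliberately out of scope and delegated to external toolkits.

.organic_subset <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
.default_valence <- list(B = 3, C = 4, N = 3, O = 2, P = c(3, 5),
                         S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

#' Parse a SMILES string into an atom/bond graph
#'
#' Supports the organic subset, bracket atoms with chirality/H-count/charge,
#' single/double/triple and directional bonds, branches and numeric ring
#' closures.  Aromatic (lowercase) atoms are rejected: the structures this
#' package generates are written in Kekulé form and contain none.
#'
#' @param s A SMILES string.
#' @return A list with data frames `atoms` (`element`, `charge`,
#'   `explicit_h`, `bracket`) and `bonds` (`a1`, `a2`, `order`).
#' @export
smiles_graph <- function(s) {
  stopifnot(is.character(s), length(s) == 1, nzchar(s))
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()
  prev <- NA_integer_      # index of atom to bond the next atom to
  pending_order <- NA_real_
  stack <- integer(0)
  rings <- list()          # ring-closure digit -> (atom, order)
  i <- 1
  add_atom <- function(element, charge = 0L, explicit_h = NA_integer_,
                       bracket = FALSE) {
    atoms[[length(atoms) + 1]] <<- list(element = element, charge = charge,
                                        explicit_h = explicit_h,
                                        bracket = bracket)
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- if (is.na(pending_order)) 1 else pending_order
      bonds[[length(bonds) + 1]] <<- c(prev, idx, ord)
    }
    pending_order <<- NA_real_
    prev <<- idx
    idx
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) stop("unclosed bracket atom at position ", i, " in: ", s)
      body <- substr(s, i + 1, j - 1)
      m <- regmatches(body,
        regexec("^(\\d*)([A-Z][a-z]?)(@{0,2})(H(\\d*))?([+-]\\d*|[+]+|[-]+)?$",
                body))[[1]]
      if (length(m) == 0 || !nzchar(m[3]))
        stop("unsupported bracket atom [", body, "] at position ", i)
      hc <- if (nzchar(m[5])) { if (nzchar(m[6])) as.integer(m[6]) else 1L } else 0L
      chg <- 0L
      cs <- m[7]
      if (nzchar(cs)) {
        chg <- if (grepl("^[+-]\\d+$", cs)) {
          as.integer(cs)
        } else {
          as.integer(nchar(cs)) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
        }
      }
      add_atom(m[3], chg, hc, TRUE)
      i <- j + 1
    } else if (ch %in% c("(", ")")) {
      if (ch == "(") {
        stack <- c(stack, prev)
      } else {
        if (length(stack) == 0) stop("unbalanced ')' at position ", i)
        prev <- stack[length(stack)]
        stack <- stack[-length(stack)]
      }
      i <- i + 1
    } else if (ch %in% c("-", "/", "\\")) {
      pending_order <- 1; i <- i + 1
    } else if (ch == "=") {
      pending_order <- 2; i <- i + 1
    } else if (ch == "#") {
      pending_order <- 3; i <- i + 1
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        key <- substr(s, i + 1, i + 2); i <- i + 3
      } else {
        key <- ch; i <- i + 1
      }
      if (is.na(prev)) stop("ring closure before any atom in: ", s)
      if (!is.null(rings[[key]])) {
        op <- rings[[key]]
        ord <- if (!is.na(pending_order)) pending_order else op[2]
        bonds[[length(bonds) + 1]] <- c(op[1], prev, ord)
        rings[[key]] <- NULL
        pending_order <- NA_real_
      } else {
        rings[[key]] <- c(prev, if (is.na(pending_order)) 1 else pending_order)
        pending_order <- NA_real_
      }
    } else if (ch == ".") {
      prev <- NA_integer_; i <- i + 1
    } else {
      two <- substr(s, i, i + 1)
      sym <- if (two %in% c("Cl", "Br")) two else ch
      if (!sym %in% .organic_subset) {
        if (grepl("[a-z]", ch))
          stop("aromatic atoms are not supported (position ", i, "): ", s)
        stop("unexpected character '", ch, "' at position ", i, " in: ", s)
      }
      add_atom(sym)
      i <- i + nchar(sym)
    }
  }
  if (length(rings)) stop("unmatched ring closure(s) in: ", s)
  if (length(stack)) stop("unbalanced '(' in: ", s)
  atoms <- do.call(rbind, lapply(atoms, as.data.frame))
  bonds <- if (length(bonds)) {
    b <- do.call(rbind, bonds)
    data.frame(a1 = b[, 1], a2 = b[, 2], order = b[, 3])
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0))
  }
  list(atoms = atoms, bonds = bonds)
}

.implicit_h <- function(graph) {
  atoms <- graph$atoms
  bonds <- graph$bonds
  bsum <- numeric(nrow(atoms))
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + bonds$order[k]
      bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + bonds$order[k]
    }
  }
  vapply(seq_len(nrow(atoms)), function(i) {
    if (atoms$bracket[i]) return(0L)  # bracket atoms carry explicit H only
    v <- .default_valence[[atoms$element[i]]]
    if (is.null(v)) return(0L)
    v <- v[v >= bsum[i]]
    if (length(v) == 0) return(0L)
    as.integer(v[1] - bsum[i])
  }, integer(1))
}

#' Elemental composition of a SMILES string
#'
#' Counts every atom, including implicit hydrogens assigned by the
#' standard valence model (organic-subset atoms) and explicit hydrogen
#' counts on bracket atoms.
#'
#' @param s A SMILES string (or character vector of them).
#' @return For a single string, an `elemental_composition`; for a vector,
#'   a character vector of Hill formulas.
#' @export
#' @examples
#' formula_of(smiles_composition("CCO"))  # ethanol, C2H6O
smiles_composition <- function(s) {
  one <- function(si) {
    g <- smiles_graph(si)
    h <- sum(.implicit_h(g)) + sum(g$atoms$explicit_h, na.rm = TRUE)
    tab <- table(g$atoms$element)
    cnt <- stats::setNames(as.integer(tab), names(tab))
    if (h > 0) cnt["H"] <- (if (is.na(cnt["H"])) 0L else cnt["H"]) + as.integer(h)
    do.call(comp, as.list(cnt))
  }
  if (length(s) == 1) one(s) else vapply(s, function(si) formula_of(one(si)), character(1))
}

#' Net formal charge of a SMILES string
#'
#' @param s A SMILES string.
#' @return Integer net charge.
#' @export
smiles_net_charge <- function(s) {
  sum(smiles_graph(s)$atoms$charge)
}
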