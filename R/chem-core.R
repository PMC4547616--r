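# Elemental-composition algebra, Hill formulas, monoisotopic/average mass,
# and adduct m/z computation.

# Atomic masses pinned to IUPAC 2021 monoisotopic values (most abundant
# isotope) and CODATA 2018 electron mass, hard-coded for bit-reproducible
# output without network access.  Standard atomic weights (abridged IUPAC
# 2021) drive the average mass.
.element_table <- data.frame(
  element = c("C", "H", "N", "O", "P", "S", "Na", "K", "Li", "Cl"),
  monoisotopic = c(
    12.0,           # 12C (definition)
    1.00782503207,  # 1H
    14.0030740048,  # 14N
    15.9949146196,  # 16O
    30.97376163,    # 31P
    31.97207100,    # 32S
    22.9897692809,  # 23Na
    38.96370668,    # 39K
    7.01600455,     # 7Li
    34.96885268     # 35Cl
  ),
  average = c(12.011, 1.008, 14.007, 15.999, 30.973761998, 32.06,
              22.98976928, 39.0983, 6.94, 35.45),
  stringsAsFactors = FALSE
)

.electron_mass <- 0.00054857990946

#' Atomic mass table
#'
#' The pinned table of monoisotopic masses (mass of the most abundant
#' isotope) and standard atomic weights used throughout the package,
#' plus the electron mass used for charged-species m/z corrections.
#'
#' @return A list with elements `masses` (data frame with columns
#'   `element`, `monoisotopic`, `average`, in Da) and `electron_mass` (Da).
#' @export
#' @examples
#' atomic_masses()$electron_mass
atomic_masses <- function() {
  list(masses = .element_table, electron_mass = .electron_mass)
}

.mono_mass_vec <- stats::setNames(.element_table$monoisotopic, .element_table$element)
.avg_mass_vec <- stats::setNames(.element_table$average, .element_table$element)

#' Build an elemental composition
#'
#' A composition is a named integer vector mapping element symbols to
#' non-negative counts.  Absent elements are equivalent to count zero.
#'
#' @param ... Element counts, e.g. `comp(C = 16, H = 32, O = 2)`.
#' @return A named integer vector of class `elemental_composition`.
#' @export
#' @examples
#' comp(C = 16, H = 32, O = 2)
comp <- function(...) {
  x <- c(...)
  if (is.null(x)) x <- stats::setNames(integer(0), character(0))
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all composition entries must be named by element symbol")
  if (any(x < 0)) stop("element counts must be non-negative")
  if (any(x != round(x))) stop("element counts must be integers")
  x <- x[x != 0]
  # collapse duplicate symbols
  x <- tapply(as.integer(x), names(x), sum)
  out <- stats::setNames(as.integer(x), names(x))
  class(out) <- "elemental_composition"
  out
}

.as_comp <- function(x) {
  if (inherits(x, "elemental_composition")) return(x)
  do.call(comp, as.list(x))
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<composition> ", formula_of(x), "\n", sep = "")
  invisible(x)
}

#' Composition arithmetic
#'
#' Element-wise addition and subtraction of compositions.  Subtraction
#' that would drive any element negative is an error: compositions count
#' atoms and cannot go below zero.
#'
#' @param a,b Compositions (see [comp()]).
#' @return An `elemental_composition`.
#' @export
comp_add <- function(a, b) {
  a <- .as_comp(a); b <- .as_comp(b)
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  do.call(comp, as.list(out))
}

#' @rdname comp_add
#' @export
comp_subtract <- function(a, b) {
  a <- .as_comp(a); b <- .as_comp(b)
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0))
    stop("subtraction would give a negative count for element(s): ",
         paste(els[out < 0], collapse = ", "))
  do.call(comp, as.list(out))
}

#' @rdname comp_add
#' @param k Non-negative integer multiplier.
#' @export
comp_scale <- function(a, k) {
  a <- .as_comp(a)
  if (k < 0 || k != round(k)) stop("k must be a non-negative integer")
  do.call(comp, as.list(unclass(a) * as.integer(k)))
}

#' Render a composition as a Hill-order formula string
#'
#' Carbon first, hydrogen second, remaining elements alphabetically
#' (when carbon is present; otherwise all elements alphabetically).
#' Elements with count zero are omitted and count one is rendered
#' without a digit.  The empty composition renders as the empty string.
#'
#' @param x An `elemental_composition` or named count vector.
#' @return A character scalar, e.g. `"C42H82NO8P"`.
#' @export
#' @examples
#' formula_of(comp(C = 16, H = 32, O = 2))
formula_of <- function(x) {
  x <- .as_comp(x)
  x <- x[x > 0]
  if (length(x) == 0) return("")
  els <- names(x)
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    ord <- c("C", if ("H" %in% els) "H", rest)
  } else {
    ord <- sort(els)
  }
  n <- unclass(x)[ord]
  paste0(ord, ifelse(n == 1, "", n), collapse = "")
}

#' Parse a molecular formula into a composition
#'
#' Accepts plain element-count formulas such as `"C42H82NO8P"`.
#'
#' @param x Character scalar formula.  The empty string gives the empty
#'   composition.
#' @return An `elemental_composition`.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  if (!nzchar(x)) return(comp())
  m <- gregexpr("[A-Z][a-z]?\\d*", x)[[1]]
  toks <- regmatches(x, gregexpr("[A-Z][a-z]?\\d*", x))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x))
    stop("malformed formula: ", x)
  els <- sub("\\d+$", "", toks)
  cnt <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  cnt[is.na(cnt)] <- 1L
  do.call(comp, as.list(stats::setNames(cnt, els)))
}

.mass_of <- function(x, table) {
  x <- .as_comp(x)
  if (length(x) == 0) return(0.0)
  unknown <- setdiff(names(x), names(table))
  if (length(unknown))
    stop("no atomic mass for element(s): ", paste(unknown, collapse = ", "))
  sum(table[names(x)] * unclass(x))
}

#' Monoisotopic and average mass of a composition
#'
#' Monoisotopic mass sums the mass of the most abundant isotope of each
#' element; average mass uses isotope-abundance-weighted standard atomic
#' weights.
#'
#' @param x An `elemental_composition` or named count vector.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(comp(H = 2, O = 1))  # 18.010565
monoisotopic_mass <- function(x) .mass_of(x, .mono_mass_vec)

#' @rdname monoisotopic_mass
#' @export
average_mass <- function(x) .mass_of(x, .avg_mass_vec)

# ---- adducts ---------------------------------------------------------------

.default_adducts <- data.frame(
  label = c("[M.]+", "[M+H]+", "[M+K]+", "[M+Na]+", "[M+Li]+", "[M+NH4]+",
            "[M-H]-", "[M+Cl]-", "[M+OAc]-"),
  atoms_added = c("", "H", "K", "Na", "Li", "NH4", "", "Cl", "C2H3O2"),
  atoms_removed = c("", "", "", "", "", "", "H", "", ""),
  charge = c(1L, 1L, 1L, 1L, 1L, 1L, -1L, -1L, -1L),
  stringsAsFactors = FALSE
)

.registry_finalize <- function(reg) {
  for (col in c("label", "atoms_added", "atoms_removed"))
    reg[[col]] <- as.character(reg[[col]])
  reg$charge <- as.integer(reg$charge)
  if (any(reg$charge == 0)) stop("adduct charge must be non-zero")
  if (anyDuplicated(reg$label)) stop("duplicate adduct labels")
  reg$polarity <- ifelse(reg$charge > 0, "positive", "negative")
  reg$mass_delta <- vapply(seq_len(nrow(reg)), function(i) {
    monoisotopic_mass(parse_formula(reg$atoms_added[i])) -
      monoisotopic_mass(parse_formula(reg$atoms_removed[i])) -
      reg$charge[i] * .electron_mass
  }, numeric(1))
  class(reg) <- c("adduct_registry", "data.frame")
  reg
}

#' The adduct registry
#'
#' The default registry holds the nine single-molecule adducts computed
#' for every lipid at species level and below: `[M.]+`, `[M+H]+`,
#' `[M+K]+`, `[M+Na]+`, `[M+Li]+`, `[M+NH4]+`, `[M-H]-`, `[M+Cl]-` and
#' `[M+OAc]-`.  Each mass delta is derived from the atomic mass table and
#' includes the electron-mass correction for the charge carried (`[M.]+`
#' is the radical cation, M minus one electron).
#'
#' A user-extensible registry can be loaded from a tab-separated config
#' file with columns `label`, `atoms_added`, `atoms_removed`, `charge`
#' (formula strings, possibly empty; signed integer charge).
#'
#' @param path Path to a TSV adduct config file.
#' @return A data frame of class `adduct_registry` with columns `label`,
#'   `atoms_added`, `atoms_removed`, `charge`, `polarity`, `mass_delta`.
#' @export
#' @examples
#' adduct_registry()[, c("label", "mass_delta")]
adduct_registry <- function() .registry_finalize(.default_adducts)

#' @rdname adduct_registry
#' @export
load_adduct_registry <- function(path) {
  reg <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "atoms_added", "atoms_removed", "charge")
  missing <- setdiff(need, names(reg))
  if (length(missing))
    stop("adduct config lacks column(s): ", paste(missing, collapse = ", "))
  reg$atoms_added[is.na(reg$atoms_added)] <- ""
  reg$atoms_removed[is.na(reg$atoms_removed)] <- ""
  .registry_finalize(reg[need])
}

.normalize_adduct_label <- function(label) {
  # tolerate the typographic minus sign in labels
  gsub("−", "-", label)
}

#' Adduct m/z from a neutral monoisotopic mass
#'
#' Computes `(M + mass_delta) / |z|` for single-molecule adducts, where
#' `mass_delta` accounts for the atoms gained or lost and for the
#' electron mass of the charge carried.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da); may be a vector.
#' @param adduct Adduct label (one of the registry labels); may be a
#'   vector (recycled against `neutral_mass`).
#' @param registry An adduct registry; defaults to the built-in nine.
#' @return m/z value(s), numeric.
#' @export
#' @examples
#' adduct_mz(759.577954, "[M+H]+")  # 760.585230
adduct_mz <- function(neutral_mass, adduct, registry = adduct_registry()) {
  if (any(neutral_mass <= 0)) stop("neutral_mass must be positive")
  adduct <- .normalize_adduct_label(adduct)
  idx <- match(adduct, registry$label)
  if (anyNA(idx))
    stop("unknown adduct label(s): ",
         paste(unique(adduct[is.na(idx)]), collapse = ", "),
         "; supported: ", paste(registry$label, collapse = ", "))
  (neutral_mass + registry$mass_delta[idx]) / abs(registry$charge[idx])
}
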