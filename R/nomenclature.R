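# Shorthand abbreviations (species / molecular / structural / isomeric
# subspecies) and systematic names, following the accepted shorthand
# conventions for glycerolipids: "/" separates sn-ordered chains, "_"
# separates unordered chains, "O-" marks an alkyl ether, "P-" a 1Z-alkenyl
# (vinyl) ether, and an empty sn position is written "0:0".

.LEVELS <- c("Category", "Class", "Subclass", "Species",
             "Molecular subspecies", "Structural subspecies",
             "Isomeric subspecies")

#' The seven hierarchy levels
#'
#' In decreasing-ambiguity order: Category, Class, Subclass, Species,
#' Molecular subspecies, Structural subspecies, Isomeric subspecies.
#'
#' @return Character vector of the seven level names, ordered from the
#'   most general to the most specific.
#' @export
hierarchy_levels <- function() .LEVELS

.term_string <- function(prefix, c, db, pos, with_pos) {
  out <- ifelse(c == 0L, "0:0", paste0(prefix, c, ":", db))
  if (with_pos)
    out <- ifelse(c != 0L & nzchar(pos), paste0(out, "(", pos, ")"), out)
  out
}

# ---- vectorized abbreviation builders over enumeration columns -------------

.slot_cols <- function(df, sns, what) lapply(sns, function(sn) df[[paste0("sn", sn, "_", what)]])

.abbrev_join <- function(class_abbrev, terms, sep) {
  paste0(class_abbrev, "(", do.call(paste, c(terms, sep = sep)), ")")
}

.abbrev_isomeric_vec <- function(class_abbrev, df, nslot, sns) {
  terms <- lapply(sns, function(sn)
    .term_string(df[[paste0("sn", sn, "_prefix")]], df[[paste0("sn", sn, "_c")]],
                 df[[paste0("sn", sn, "_db")]], df[[paste0("sn", sn, "_pos")]],
                 with_pos = TRUE))
  .abbrev_join(class_abbrev, terms, "/")
}

.abbrev_structural_vec <- function(class_abbrev, df, sns) {
  terms <- lapply(sns, function(sn)
    .term_string(df[[paste0("sn", sn, "_prefix")]], df[[paste0("sn", sn, "_c")]],
                 df[[paste0("sn", sn, "_db")]], "", with_pos = FALSE))
  .abbrev_join(class_abbrev, terms, "/")
}

# molecular level: sn positions discarded (canonical sort), every P-n:d
# rewritten as O-n:(d+1) -- the vinyl-ether double bond becomes
# indistinguishable from a chain double bond.  The canonical order
# (ether chains first, then (C, DB) ascending, empty 0:0 terms last) is
# applied with a vectorized sorting network over the <= 3 slots.
.abbrev_molecular_vec <- function(class_abbrev, df, sns) {
  k <- length(sns)
  pre <- .slot_cols(df, sns, "prefix"); cc <- .slot_cols(df, sns, "c")
  dbs <- .slot_cols(df, sns, "dbsum")
  pre <- lapply(pre, function(p) ifelse(p == "P-", "O-", p))
  term <- lapply(seq_len(k), function(i)
    .term_string(pre[[i]], cc[[i]], dbs[[i]], "", FALSE))
  # terms are determined by (prefix, c, db), so a numeric key suffices
  key <- lapply(seq_len(k), function(i)
    (cc[[i]] == 0L) * 1e10 + (pre[[i]] != "O-") * 1e9 + cc[[i]] * 1e4 + dbs[[i]])
  swap <- function(i, j) {
    w <- key[[i]] > key[[j]]
    ti <- term[[i]]; ki <- key[[i]]
    term[[i]][w] <<- term[[j]][w]; key[[i]][w] <<- key[[j]][w]
    term[[j]][w] <<- ti[w]; key[[j]][w] <<- ki[w]
  }
  if (k >= 2) swap(1, 2)
  if (k == 3) { swap(2, 3); swap(1, 2) }
  if (k > 3) stop("more than three slots are not supported")
  .abbrev_join(class_abbrev, term, "_")
}

.abbrev_species_vec <- function(class_abbrev, df, sns) {
  cc <- .slot_cols(df, sns, "c"); dbs <- .slot_cols(df, sns, "dbsum")
  pre <- .slot_cols(df, sns, "prefix")
  sum_c <- Reduce(`+`, cc)
  sum_db <- Reduce(`+`, dbs)
  ether <- Reduce(`|`, lapply(pre, function(p) p %in% c("O-", "P-")))
  paste0(class_abbrev, "(", ifelse(ether, "O-", ""), sum_c, ":", sum_db, ")")
}

# ---- abbreviation object, parser and formatter -----------------------------

#' Construct a shorthand-abbreviation object
#'
#' @param class_abbrev Class abbreviation, e.g. `"PC"`.
#' @param level One of `"Species"`, `"Molecular subspecies"`,
#'   `"Structural subspecies"`, `"Isomeric subspecies"`.
#' @param terms Data frame with columns `prefix` (`""`, `"O-"` or
#'   `"P-"`), `c`, `db` (integers) and `pos` (locant string, empty when
#'   unknown); one row per chain term, in printed order.
#' @return A list of class `lipid_abbreviation`.
#' @export
lipid_abbreviation <- function(class_abbrev, level, terms) {
  if (!level %in% .LEVELS[4:7])
    stop("unknown level: ", level, " (expected one of ",
         paste(.LEVELS[4:7], collapse = ", "), ")")
  stopifnot(all(c("prefix", "c", "db", "pos") %in% names(terms)))
  if (level == "Species" && nrow(terms) != 1)
    stop("species level carries exactly one sum term")
  structure(list(class_abbrev = class_abbrev, level = level,
                 terms = terms), class = "lipid_abbreviation")
}

#' @export
print.lipid_abbreviation <- function(x, ...) {
  cat("<abbreviation> ", format_abbreviation(x), " [", x$level, "]\n", sep = "")
  invisible(x)
}

#' Render a `lipid_abbreviation` as text
#'
#' Inverse of [parse_abbreviation()]: species prints its single sum
#' term, molecular terms join with `"_"`, structural/isomeric terms join
#' with `"/"` (positions printed at isomeric level only).
#'
#' @param x A [lipid_abbreviation()].
#' @return Character scalar.
#' @export
format_abbreviation <- function(x) {
  stopifnot(inherits(x, "lipid_abbreviation"))
  t <- x$terms
  with_pos <- x$level == "Isomeric subspecies"
  term <- .term_string(t$prefix, t$c, t$db, t$pos, with_pos)
  sep <- if (x$level == "Molecular subspecies") "_" else "/"
  paste0(x$class_abbrev, "(", paste(term, collapse = sep), ")")
}

.parse_error <- function(text, offset, why) {
  stop(sprintf("cannot parse abbreviation '%s' at character %d: %s",
               text, offset, why), call. = FALSE)
}

#' Parse a shorthand abbreviation
#'
#' Infers the level from the separators and the presence of double-bond
#' positions: a single sum term is a Species, `"_"`-separated terms a
#' Molecular subspecies, `"/"`-separated terms a Structural subspecies,
#' and positions on at least one chain an Isomeric subspecies.  Malformed
#' strings raise an error reporting the character offset.
#'
#' @param text Abbreviation string, e.g. `"PC(O-16:1_20:4)"`.
#' @return A [lipid_abbreviation()].
#' @export
#' @examples
#' parse_abbreviation("PC(O-36:5)")$level
parse_abbreviation <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  m <- regexec("^([A-Za-z][A-Za-z0-9]*)\\(", text)[[1]]
  if (m[1] == -1) .parse_error(text, 1, "expected class abbreviation then '('")
  class_abbrev <- substr(text, m[2], m[2] + attr(m, "match.length")[2] - 1)
  if (substr(text, nchar(text), nchar(text)) != ")")
    .parse_error(text, nchar(text), "expected closing ')'")
  inner_start <- attr(m, "match.length")[1] + 1
  inner <- substr(text, inner_start, nchar(text) - 1)
  if (!nzchar(inner)) .parse_error(text, inner_start, "empty chain list")
  has_us <- grepl("_", inner, fixed = TRUE)
  # "/" only counts as a separator outside position parentheses (none in
  # this grammar contain "/", so a plain scan is enough)
  has_sl <- grepl("/", inner, fixed = TRUE)
  if (has_us && has_sl)
    .parse_error(text, inner_start + regexpr("[_/]", inner) - 1,
                 "mixed '_' and '/' separators")
  sep <- if (has_us) "_" else if (has_sl) "/" else NA
  toks <- if (is.na(sep)) inner else strsplit(inner, sep, fixed = TRUE)[[1]]
  if (!is.na(sep) && grepl(paste0("\\", sep, "$"), inner))
    toks <- c(toks, "")
  term_re <- "^(O-|P-)?([0-9]+):([0-9]+)(\\(([0-9]+[ZE](,[0-9]+[ZE])*)\\))?$"
  mm <- regexec(term_re, toks)
  bad <- vapply(mm, function(m) m[1] == -1, logical(1))
  if (any(bad)) {
    i <- which(bad)[1]
    offset <- inner_start +
      (if (i > 1) sum(nchar(toks[seq_len(i - 1)])) + (i - 1) else 0)
    .parse_error(text, offset, paste0("malformed chain term '", toks[i], "'"))
  }
  gs <- regmatches(toks, mm)
  k <- length(toks)
  terms <- structure(
    list(prefix = vapply(gs, `[`, "", 2),
         c = as.integer(vapply(gs, `[`, "", 3)),
         db = as.integer(vapply(gs, `[`, "", 4)),
         pos = vapply(gs, `[`, "", 6)),
    class = "data.frame", row.names = .set_row_names(k))
  has_pos <- any(nzchar(terms$pos))
  level <- if (identical(sep, "_")) {
    if (has_pos) .parse_error(text, inner_start,
                              "positions are not printed at molecular level")
    "Molecular subspecies"
  } else if (identical(sep, "/")) {
    if (has_pos) "Isomeric subspecies" else "Structural subspecies"
  } else {
    if (has_pos) "Isomeric subspecies" else "Species"
  }
  if (level == "Species" && terms$prefix[1] == "P-")
    .parse_error(text, inner_start, "species-level sum terms use 'O-', not 'P-'")
  ab <- lipid_abbreviation(class_abbrev, level, terms)
  # re-rendering must reproduce the input; catches e.g. non-canonical zeros
  if (format_abbreviation(ab) != text)
    .parse_error(text, inner_start, "not in canonical form")
  ab
}

# ---- systematic names ------------------------------------------------------

.residue_term <- function(chain, linkage) {
  c_ <- chain$carbons; d <- chain$double_bonds; p <- chain$positions
  if (linkage == "ester") {
    nm <- acyl_name(c_, d, p)
    if (nzchar(p)) paste0("(", nm, ")") else nm
  } else if (linkage == "alkyl") {
    nm <- alkyl_name(c_, d, p)
    if (nzchar(p)) paste0("O-(", nm, ")") else paste0("O-", nm)
  } else if (linkage == "alkenyl") {
    paste0("O-(", alkenyl_name(c_, d, p), ")")
  } else stop("unknown linkage: ", linkage)
}

.multiplier <- c("", "di", "tri")

#' Systematic name of an isomeric subspecies
#'
#' Joins sn-position-ordered residue names with the backbone/headgroup
#' name: ethers carry the `O-` locant, alkenyl residues the `1Z-...enyl`
#' form, and runs of identical residues are condensed
#' (`1,2-dihexadecanoyl-`).  Empty sn positions are omitted.
#'
#' @param iso One row of an `isomeric_set` (or a data frame of rows).
#' @param chains The [chain_library()] the set was enumerated from.
#' @param template The [class_template()]; defaults to the `template`
#'   attribute of `iso`.
#' @return Character vector of systematic names.
#' @export
systematic_name <- function(iso, chains, template = attr(iso, "template")) {
  if (is.null(template)) stop("template must be supplied")
  sns <- template$slots$sn
  vapply(seq_len(nrow(iso)), function(r) {
    res <- character(0); posn <- integer(0); link <- character(0)
    for (sn in sns) {
      lk <- iso[[paste0("sn", sn, "_linkage")]][r]
      ci <- iso[[paste0("sn", sn, "_chain")]][r]
      if (is.na(ci) || lk == "empty") next
      res <- c(res, .residue_term(chains[ci, ], lk))
      posn <- c(posn, sn)
      link <- c(link, lk)
    }
    if (length(res) == 0)
      return(template$backbone_name)
    # condense runs of identical residue terms: "1,2-dihexadecanoyl"
    parts <- character(0)
    i <- 1
    while (i <= length(res)) {
      j <- i
      while (j < length(res) && res[j + 1] == res[i] && link[j + 1] == link[i]) j <- j + 1
      k <- j - i + 1
      locs <- paste(posn[i:j], collapse = ",")
      term <- res[i]
      if (k > 1) {
        mult <- .multiplier[k]
        # "O-" locant stays outside the multiplier: 1,2-di-O-hexadecyl
        term <- if (startsWith(term, "O-")) paste0("di-", term)
                else if (grepl("^\\(", term)) paste0(mult, term)
                else paste0(mult, term)
      }
      parts <- c(parts, paste0(locs, "-", term))
      i <- j + 1
    }
    paste(c(parts, template$backbone_name), collapse = "-")
  }, character(1))
}
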