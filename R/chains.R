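# Fatty acyl/alkyl building blocks: descriptors, composition, systematic
# residue names, TSV I/O and the deterministic fixture generator.

# saturated alkane stems, indexed by carbon count (stem includes the "an")
.alkane_stems <- c(
  "2" = "ethan", "3" = "propan", "4" = "butan", "5" = "pentan",
  "6" = "hexan", "7" = "heptan", "8" = "octan", "9" = "nonan",
  "10" = "decan", "11" = "undecan", "12" = "dodecan", "13" = "tridecan",
  "14" = "tetradecan", "15" = "pentadecan", "16" = "hexadecan",
  "17" = "heptadecan", "18" = "octadecan", "19" = "nonadecan",
  "20" = "eicosan", "21" = "heneicosan", "22" = "docosan",
  "23" = "tricosan", "24" = "tetracosan", "25" = "pentacosan",
  "26" = "hexacosan", "27" = "heptacosan", "28" = "octacosan",
  "29" = "nonacosan", "30" = "triacontan", "31" = "hentriacontan",
  "32" = "dotriacontan")

.ene_multiplier <- c("", "di", "tri", "tetra", "penta", "hexa", "hepta", "octa")

.stem_for <- function(n) {
  s <- .alkane_stems[as.character(n)]
  if (any(is.na(s))) stop("no name stem for carbon count ", n)
  unname(s)
}

# "5Z,8Z,11Z,14Z" + suffix building: d double bonds with given locant string
.unsat_name <- function(n, d, locants, suffix_sat, suffix_unsat) {
  stem <- .stem_for(n)
  if (d == 0) return(paste0(stem, suffix_sat))
  base <- sub("an$", "", stem)
  mult <- .ene_multiplier[d]
  if (is.na(mult)) stop("too many double bonds to name: ", d)
  body <- if (d == 1) paste0(base, "en", suffix_unsat)
          else paste0(base, "a", mult, "en", suffix_unsat)
  if (nzchar(locants)) paste0(locants, "-", body) else body
}

#' Systematic residue names for chain building blocks
#'
#' `acyl_name()` renders the fatty-acyl residue (e.g. `"hexadecanoyl"`,
#' `"5Z,8Z,11Z,14Z-eicosatetraenoyl"`), `alkyl_name()` the O-alkyl
#' residue (`"hexadecyl"`), and `alkenyl_name()` the 1Z-alkenyl
#' (plasmalogen) residue (`"1Z-hexadecenyl"`), in which the obligatory
#' 1Z vinyl-ether double bond is added to the chain's own double bonds.
#'
#' @param carbons Carbon count.
#' @param double_bonds Number of double bonds in the chain itself.
#' @param positions Locant string like `"5Z,8Z,11Z,14Z"` (empty when
#'   `double_bonds == 0`).
#' @return Character scalar residue name.
#' @export
#' @examples
#' acyl_name(20, 4, "5Z,8Z,11Z,14Z")
acyl_name <- function(carbons, double_bonds, positions = "") {
  .unsat_name(carbons, double_bonds, positions, "oyl", "oyl")
}

#' @rdname acyl_name
#' @export
alkyl_name <- function(carbons, double_bonds, positions = "") {
  stem <- .stem_for(carbons)
  if (double_bonds == 0) return(paste0(sub("an$", "", stem), "yl"))
  .unsat_name(carbons, double_bonds, positions, "yl", "yl")
}

#' @rdname alkyl_name
#' @export
alkenyl_name <- function(carbons, double_bonds, positions = "") {
  loc <- if (nzchar(positions)) paste0("1Z,", positions) else "1Z"
  .unsat_name(carbons, double_bonds + 1L, loc, "yl", "yl")
}

.parse_positions <- function(positions) {
  # "5Z;8Z" or "5Z,8Z" -> list(pos = int vector, geom = chr vector)
  positions <- gsub(";", ",", positions)
  if (is.na(positions) || !nzchar(positions))
    return(list(pos = integer(0), geom = character(0)))
  toks <- strsplit(positions, ",", fixed = TRUE)[[1]]
  toks <- trimws(toks)
  if (!all(grepl("^\\d+[ZE]$", toks)))
    stop("malformed double-bond positions: ", positions)
  list(pos = as.integer(sub("[ZE]$", "", toks)),
       geom = sub("^\\d+", "", toks))
}

.positions_string <- function(pos, geom) paste0(pos, geom, collapse = ",")

.validate_chain_row <- function(kind, carbons, double_bonds, positions) {
  if (!kind %in% c("fatty-acid", "fatty-alcohol"))
    return("kind must be 'fatty-acid' or 'fatty-alcohol'")
  if (is.na(carbons) || carbons < 2) return("carbons must be >= 2")
  if (is.na(double_bonds) || double_bonds < 0)
    return("double_bonds must be >= 0")
  pp <- tryCatch(.parse_positions(positions), error = function(e) e)
  if (inherits(pp, "error")) return(conditionMessage(pp))
  if (length(pp$pos) != double_bonds)
    return(sprintf("positions count (%d) != double_bonds (%d)",
                   length(pp$pos), double_bonds))
  if (double_bonds > 0) {
    if (any(diff(pp$pos) <= 0)) return("positions must be strictly increasing")
    if (any(pp$pos < 2) || any(pp$pos > carbons - 1))
      return("positions must lie in [2, carbons-1]")
  }
  NULL
}

#' Construct a chain library
#'
#' A chain library is a data frame of fatty-acid and fatty-alcohol
#' building blocks with columns `kind`, `carbons`, `double_bonds`,
#' `positions` (locant string, e.g. `"5Z,8Z,11Z,14Z"`), `trivial_name`
#' and a derived `residue_name` (acyl form for acids, alkyl form for
#' alcohols).  Double-bond positions are delta-nomenclature, 1-based from
#' the carboxyl/hydroxyl carbon.  The alkenyl (P-) form of an alcohol is
#' not a separate record: it is the same building block flagged by the
#' linkage at assembly time.
#'
#' @param df Data frame with at least `kind`, `carbons`, `double_bonds`,
#'   `positions`; `trivial_name` optional.
#' @return A validated `chain_library` data frame.
#' @export
chain_library <- function(df) {
  need <- c("kind", "carbons", "double_bonds", "positions")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("chain table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) stop("empty chain library")
  df$carbons <- as.integer(df$carbons)
  df$double_bonds <- as.integer(df$double_bonds)
  df$positions <- gsub(";", ",", ifelse(is.na(df$positions), "", df$positions))
  if (is.null(df$trivial_name)) df$trivial_name <- ""
  for (i in seq_len(nrow(df))) {
    msg <- .validate_chain_row(df$kind[i], df$carbons[i], df$double_bonds[i],
                               df$positions[i])
    if (!is.null(msg)) stop("chain row ", i, ": ", msg)
  }
  df$residue_name <- vapply(seq_len(nrow(df)), function(i) {
    if (df$kind[i] == "fatty-acid")
      acyl_name(df$carbons[i], df$double_bonds[i], df$positions[i])
    else alkyl_name(df$carbons[i], df$double_bonds[i], df$positions[i])
  }, character(1))
  rownames(df) <- NULL
  class(df) <- c("chain_library", "data.frame")
  df
}

#' Elemental composition of a free chain building block
#'
#' A free fatty acid n:d has composition `CnH(2n-2d)O2`; a free fatty
#' alcohol n:d has `CnH(2n+2-2d)O`.
#'
#' @param chain One row of a [chain_library()] (data frame or list with
#'   fields `kind`, `carbons`, `double_bonds`).
#' @return An `elemental_composition`.
#' @export
#' @examples
#' formula_of(chain_composition(list(kind = "fatty-acid",
#'                                   carbons = 16, double_bonds = 0)))
chain_composition <- function(chain) {
  n <- as.integer(chain$carbons); d <- as.integer(chain$double_bonds)
  if (chain$kind == "fatty-acid") comp(C = n, H = 2L * n - 2L * d, O = 2L)
  else if (chain$kind == "fatty-alcohol") comp(C = n, H = 2L * n + 2L - 2L * d, O = 1L)
  else stop("unknown chain kind: ", chain$kind)
}

#' Load a chain library from a TSV file
#'
#' Expects a UTF-8 tab-separated file with a header row and columns
#' `kind`, `carbons`, `double_bonds`, `positions` (semicolon- or
#' comma-separated locants such as `"5Z;8Z;11Z;14Z"`, empty for
#' saturated chains) and `trivial_name`.  Lines starting with `#` are
#' ignored.  Invalid rows are rejected and reported; duplicate rows
#' (same kind, carbons, double bonds and positions) are collapsed with
#' a warning.
#'
#' @param path Path to the TSV file.
#' @return A list with `chains` (a `chain_library`) and `diagnostics`
#'   (data frame with columns `row`, `message`).
#' @export
load_chain_library <- function(path) {
  if (!file.exists(path)) stop("cannot read chain library: ", path)
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("kind", "carbons", "double_bonds", "positions")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("chain table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0) stop("empty chain library: ", path)
  if (is.null(raw$trivial_name)) raw$trivial_name <- ""
  diagnostics <- list()
  keep <- logical(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    carbons <- suppressWarnings(as.integer(raw$carbons[i]))
    dbs <- suppressWarnings(as.integer(raw$double_bonds[i]))
    msg <- .validate_chain_row(raw$kind[i], carbons, dbs, raw$positions[i])
    if (is.null(msg)) keep[i] <- TRUE
    else diagnostics[[length(diagnostics) + 1]] <- data.frame(
      row = i, message = msg, stringsAsFactors = FALSE)
  }
  ok <- raw[keep, , drop = FALSE]
  if (nrow(ok) == 0) stop("no valid chains in library: ", path)
  key <- paste(ok$kind, ok$carbons, ok$double_bonds,
               gsub(";", ",", ok$positions))
  if (anyDuplicated(key)) {
    warning("collapsed ", sum(duplicated(key)), " duplicate chain row(s)")
    ok <- ok[!duplicated(key), , drop = FALSE]
  }
  chains <- chain_library(data.frame(
    kind = ok$kind, carbons = as.integer(ok$carbons),
    double_bonds = as.integer(ok$double_bonds), positions = ok$positions,
    trivial_name = ok$trivial_name, stringsAsFactors = FALSE))
  diagnostics <- if (length(diagnostics)) do.call(rbind, diagnostics)
                 else data.frame(row = integer(0), message = character(0))
  list(chains = chains, diagnostics = diagnostics)
}

#' Write a chain library to TSV
#'
#' @param chains A `chain_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain_library <- function(chains, path) {
  df <- as.data.frame(chains)[, c("kind", "carbons", "double_bonds",
                                  "positions", "trivial_name")]
  df$positions <- gsub(",", ";", df$positions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- hard-coded pool of real building blocks -------------------------------

.acid <- function(c, d, pos, triv) {
  data.frame(kind = "fatty-acid", carbons = c, double_bonds = d,
             positions = pos, trivial_name = triv, stringsAsFactors = FALSE)
}
.alcohol <- function(c, d, pos, triv) {
  data.frame(kind = "fatty-alcohol", carbons = c, double_bonds = d,
             positions = pos, trivial_name = triv, stringsAsFactors = FALSE)
}

#' The built-in pool of real fatty acids and fatty alcohols
#'
#' Eighty fatty acids and eighteen fatty alcohols with literature
#' double-bond positions and geometries, from which [fixture_library()]
#' and [reference_library()] draw.  The pool covers the saturated series
#' and the common mono- and polyunsaturated chains (n-3, n-6, n-7, n-9
#' families).
#'
#' @return A `chain_library` with 98 rows.
#' @export
chain_pool <- function() {
  acids <- do.call(rbind, list(
    # saturated series
    .acid(4, 0, "", "butyric acid"), .acid(5, 0, "", "valeric acid"),
    .acid(6, 0, "", "caproic acid"), .acid(7, 0, "", "enanthic acid"),
    .acid(8, 0, "", "caprylic acid"), .acid(9, 0, "", "pelargonic acid"),
    .acid(10, 0, "", "capric acid"), .acid(11, 0, "", "undecylic acid"),
    .acid(12, 0, "", "lauric acid"), .acid(13, 0, "", "tridecylic acid"),
    .acid(14, 0, "", "myristic acid"), .acid(15, 0, "", "pentadecylic acid"),
    .acid(16, 0, "", "palmitic acid"), .acid(17, 0, "", "margaric acid"),
    .acid(18, 0, "", "stearic acid"), .acid(19, 0, "", "nonadecylic acid"),
    .acid(20, 0, "", "arachidic acid"), .acid(21, 0, "", "heneicosylic acid"),
    .acid(22, 0, "", "behenic acid"), .acid(23, 0, "", "tricosylic acid"),
    .acid(24, 0, "", "lignoceric acid"), .acid(25, 0, "", "hyenic acid"),
    .acid(26, 0, "", "cerotic acid"), .acid(27, 0, "", "carboceric acid"),
    .acid(28, 0, "", "montanic acid"),
    # monounsaturated
    .acid(12, 1, "11Z", "lauroleic acid"),
    .acid(14, 1, "9Z", "myristoleic acid"),
    .acid(15, 1, "10Z", "10Z-pentadecenoic acid"),
    .acid(16, 1, "9Z", "palmitoleic acid"),
    .acid(16, 1, "9E", "palmitelaidic acid"),
    .acid(16, 1, "6Z", "sapienic acid"),
    .acid(17, 1, "9Z", "9Z-heptadecenoic acid"),
    .acid(18, 1, "9Z", "oleic acid"),
    .acid(18, 1, "9E", "elaidic acid"),
    .acid(18, 1, "11Z", "vaccenic acid"),
    .acid(18, 1, "6Z", "petroselinic acid"),
    .acid(19, 1, "10Z", "10Z-nonadecenoic acid"),
    .acid(20, 1, "11Z", "gondoic acid"),
    .acid(20, 1, "5Z", "5Z-eicosenoic acid"),
    .acid(20, 1, "8Z", "8Z-eicosenoic acid"),
    .acid(22, 1, "13Z", "erucic acid"),
    .acid(22, 1, "11Z", "cetoleic acid"),
    .acid(24, 1, "15Z", "nervonic acid"),
    .acid(26, 1, "17Z", "ximenic acid"),
    # diunsaturated
    .acid(18, 2, "9Z,12Z", "linoleic acid"),
    .acid(18, 2, "9E,12E", "linolelaidic acid"),
    .acid(20, 2, "11Z,14Z", "11Z,14Z-eicosadienoic acid"),
    .acid(22, 2, "13Z,16Z", "13Z,16Z-docosadienoic acid"),
    .acid(16, 2, "9Z,12Z", "9Z,12Z-hexadecadienoic acid"),
    # triunsaturated
    .acid(18, 3, "9Z,12Z,15Z", "alpha-linolenic acid"),
    .acid(18, 3, "6Z,9Z,12Z", "gamma-linolenic acid"),
    .acid(16, 3, "7Z,10Z,13Z", "7Z,10Z,13Z-hexadecatrienoic acid"),
    .acid(20, 3, "8Z,11Z,14Z", "dihomo-gamma-linolenic acid"),
    .acid(20, 3, "11Z,14Z,17Z", "11Z,14Z,17Z-eicosatrienoic acid"),
    .acid(20, 3, "5Z,8Z,11Z", "mead acid"),
    .acid(22, 3, "13Z,16Z,19Z", "13Z,16Z,19Z-docosatrienoic acid"),
    # tetraunsaturated
    .acid(16, 4, "4Z,7Z,10Z,13Z", "4Z,7Z,10Z,13Z-hexadecatetraenoic acid"),
    .acid(18, 4, "6Z,9Z,12Z,15Z", "stearidonic acid"),
    .acid(20, 4, "5Z,8Z,11Z,14Z", "arachidonic acid"),
    .acid(20, 4, "8Z,11Z,14Z,17Z", "8Z,11Z,14Z,17Z-eicosatetraenoic acid"),
    .acid(22, 4, "7Z,10Z,13Z,16Z", "adrenic acid"),
    .acid(24, 4, "9Z,12Z,15Z,18Z", "9Z,12Z,15Z,18Z-tetracosatetraenoic acid"),
    # pentaunsaturated
    .acid(20, 5, "5Z,8Z,11Z,14Z,17Z", "eicosapentaenoic acid"),
    .acid(21, 5, "6Z,9Z,12Z,15Z,18Z", "heneicosapentaenoic acid"),
    .acid(22, 5, "7Z,10Z,13Z,16Z,19Z", "docosapentaenoic acid"),
    .acid(22, 5, "4Z,7Z,10Z,13Z,16Z", "osbond acid"),
    .acid(24, 5, "9Z,12Z,15Z,18Z,21Z", "9Z,12Z,15Z,18Z,21Z-tetracosapentaenoic acid"),
    # hexaunsaturated
    .acid(22, 6, "4Z,7Z,10Z,13Z,16Z,19Z", "docosahexaenoic acid"),
    .acid(24, 6, "6Z,9Z,12Z,15Z,18Z,21Z", "nisinic acid"),
    .acid(28, 6, "10Z,13Z,16Z,19Z,22Z,25Z", "10Z,13Z,16Z,19Z,22Z,25Z-octacosahexaenoic acid"),
    # odd and less common unsaturated, filling out the pool
    .acid(14, 1, "5Z", "physeteric acid"),
    .acid(17, 2, "9Z,12Z", "9Z,12Z-heptadecadienoic acid"),
    .acid(19, 2, "10Z,13Z", "10Z,13Z-nonadecadienoic acid"),
    .acid(29, 0, "", "nonacosylic acid"),
    .acid(18, 1, "13Z", "13Z-octadecenoic acid"),
    .acid(20, 2, "8Z,11Z", "8Z,11Z-eicosadienoic acid"),
    .acid(22, 2, "11Z,14Z", "11Z,14Z-docosadienoic acid"),
    .acid(24, 2, "15Z,18Z", "15Z,18Z-tetracosadienoic acid"),
    .acid(26, 2, "17Z,20Z", "17Z,20Z-hexacosadienoic acid"),
    .acid(30, 0, "", "melissic acid")
  ))
  # drop the duplicate heneicosanoic/heneicosylic entry
  acids <- acids[!duplicated(paste(acids$kind, acids$carbons,
                                   acids$double_bonds, acids$positions)), ]
  alcohols <- do.call(rbind, list(
    .alcohol(10, 0, "", "decanol"), .alcohol(12, 0, "", "dodecanol"),
    .alcohol(14, 0, "", "tetradecanol"), .alcohol(15, 0, "", "pentadecanol"),
    .alcohol(16, 0, "", "hexadecanol"), .alcohol(17, 0, "", "heptadecanol"),
    .alcohol(18, 0, "", "octadecanol"), .alcohol(20, 0, "", "eicosanol"),
    .alcohol(22, 0, "", "docosanol"), .alcohol(24, 0, "", "tetracosanol"),
    .alcohol(26, 0, "", "hexacosanol"), .alcohol(28, 0, "", "octacosanol"),
    .alcohol(30, 0, "", "triacontanol"),
    .alcohol(16, 1, "9Z", "palmitoleyl alcohol"),
    .alcohol(18, 1, "9Z", "oleyl alcohol"),
    .alcohol(18, 2, "9Z,12Z", "linoleyl alcohol"),
    .alcohol(20, 1, "11Z", "gondoyl alcohol"),
    .alcohol(22, 1, "13Z", "erucyl alcohol")
  ))
  chain_library(rbind(acids, alcohols))
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Deterministic desk-scale fixture: chains plus class templates
#'
#' Draws `n_acids` fatty acids and `n_alcohols` fatty alcohols from the
#' hard-coded pool of real building blocks ([chain_pool()]) and pairs
#' them with a small set of built-in class templates (diacyl-PC,
#' alkyl/alkenyl-acyl-PC and triacylglycerol).  Identical arguments give
#' identical output.
#'
#' @param n_acids Number of fatty acids (>= 1).
#' @param n_alcohols Number of fatty alcohols (>= 0).
#' @param seed Integer seed controlling the draw.
#' @return A list with `chains` (a `chain_library`) and `templates`
#'   (named list of class templates).
#' @export
#' @examples
#' fx <- fixture_library(4, 2, seed = 7)
#' nrow(fx$chains)
fixture_library <- function(n_acids, n_alcohols = 0, seed = 1) {
  if (n_acids < 1) stop("n_acids must be >= 1")
  pool <- chain_pool()
  acids <- which(pool$kind == "fatty-acid")
  alcohols <- which(pool$kind == "fatty-alcohol")
  if (n_acids > length(acids))
    stop("n_acids exceeds pool size (", length(acids), ")")
  if (n_alcohols > length(alcohols))
    stop("n_alcohols exceeds pool size (", length(alcohols), ")")
  sel <- .with_seed(seed, {
    c(sample(acids, n_acids),
      if (n_alcohols > 0) sample(alcohols, n_alcohols))
  })
  chains <- pool[sort(sel), , drop = FALSE]
  rownames(chains) <- NULL
  class(chains) <- c("chain_library", "data.frame")
  tset <- builtin_templates()
  list(chains = chains, templates = tset[c("PC", "PC-O", "TG")])
}
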