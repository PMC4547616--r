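# m/z search over a generated library (sorted index + binary search) and
# identifier mapping between compound sets.

#' Build the flat m/z index of a hierarchy
#'
#' One row per (record, adduct) pair for every node at Species level and
#' below, sorted by theoretical m/z.  [mz_search()] builds this lazily;
#' precompute it when issuing many queries.
#'
#' @param h A `lipid_hierarchy` (or its `nodes` data frame).
#' @param registry Adduct registry (for polarity).
#' @return Data frame `id`, `label`, `level`, `adduct`, `polarity`,
#'   `mz`, `monoisotopic_mass`, sorted by `mz`.
#' @export
mz_index <- function(h, registry = adduct_registry()) {
  nodes <- if (inherits(h, "lipid_hierarchy")) h$nodes else h
  nodes <- nodes[nodes$level %in% .LEVELS[4:7] & !is.na(nodes$monoisotopic_mass), ]
  idx <- do.call(rbind, lapply(seq_len(nrow(registry)), function(j) {
    col <- paste0("mz:", registry$label[j])
    mz <- if (!is.null(nodes[[col]])) nodes[[col]]
          else adduct_mz(nodes$monoisotopic_mass, registry$label[j], registry)
    data.frame(id = nodes$id, label = nodes$label, level = nodes$level,
               adduct = registry$label[j], polarity = registry$polarity[j],
               mz = mz, monoisotopic_mass = nodes$monoisotopic_mass,
               stringsAsFactors = FALSE)
  }))
  idx <- idx[order(idx$mz, idx$id, idx$adduct), ]
  rownames(idx) <- NULL
  class(idx) <- c("mz_index", "data.frame")
  idx
}

#' Search a library by observed m/z
#'
#' Returns every (record, adduct) pair whose theoretical m/z lies within
#' the tolerance of the query, restricted by polarity and optionally by
#' adduct, ranked by absolute ppm error (ties: neutral mass ascending,
#' then id).  The index is scanned by binary search on the sorted m/z
#' values.
#'
#' @param h A `lipid_hierarchy`, nodes data frame, or a prebuilt
#'   [mz_index()].
#' @param mz Observed m/z value.
#' @param tolerance Tolerance value (> 0).
#' @param unit `"ppm"` or `"Da"`.
#' @param polarity `"positive"`, `"negative"` or `"both"`.
#' @param adducts Optional subset of adduct labels to consider.
#' @param registry Adduct registry.
#' @return Data frame of hits: `id`, `label`, `level`, `adduct`,
#'   `mz_theoretical`, `mz_error_ppm`, ordered by `abs(mz_error_ppm)`.
#' @export
#' @examples
#' fx <- fixture_library(2, 0, seed = 1)
#' h <- build_hierarchy(enumerate_isomeric(fx$templates$PC, fx$chains))
#' mz_search(h, 760.585230, 5, "ppm", "positive")
mz_search <- function(h, mz, tolerance, unit = c("ppm", "Da"),
                      polarity = c("both", "positive", "negative"),
                      adducts = NULL, registry = adduct_registry()) {
  unit <- match.arg(unit)
  polarity <- match.arg(polarity)
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be > 0")
  idx <- if (inherits(h, "mz_index")) h else mz_index(h, registry)
  half <- if (unit == "ppm") mz * tolerance * 1e-6 else tolerance
  lo <- findInterval(mz - half, idx$mz)          # last value < lower bound
  hi <- findInterval(mz + half, idx$mz)          # last value <= upper bound
  sel <- if (hi > lo) (lo + 1L):hi else integer(0)
  hits <- idx[sel, , drop = FALSE]
  # findInterval(lo) can exclude an exact boundary tie; re-check edges
  hits <- hits[hits$mz >= mz - half & hits$mz <= mz + half, , drop = FALSE]
  if (polarity != "both") hits <- hits[hits$polarity == polarity, , drop = FALSE]
  if (!is.null(adducts)) {
    adducts <- .normalize_adduct_label(adducts)
    hits <- hits[hits$adduct %in% adducts, , drop = FALSE]
  }
  err <- (mz - hits$mz) / hits$mz * 1e6
  out <- data.frame(id = hits$id, label = hits$label, level = hits$level,
                    adduct = hits$adduct, mz_theoretical = hits$mz,
                    mz_error_ppm = err, stringsAsFactors = FALSE)
  out <- out[order(abs(out$mz_error_ppm), hits$monoisotopic_mass, out$id), ]
  rownames(out) <- NULL
  out
}

#' Map identifiers between two compound sets by exact key equality
#'
#' Matches records of `set_a` to records of `set_b` on a shared key:
#' an externally supplied InChIKey, or the canonical abbreviation or
#' formula computed by this package.  One output row per matching
#' (source, target) pair; `ambiguity_count` is the number of targets
#' sharing that source's key.  Sources with no match are reported in
#' the `unmatched` component.
#'
#' @param set_a,set_b Data frames with an `id` column and the key column
#'   (`inchikey`, `abbreviation`/`label`, or `formula`).
#' @param key One of `"inchikey"`, `"abbreviation"`, `"formula"`.
#' @param first_block For InChIKeys only: match on the first
#'   (connectivity) block instead of the full 27-character key.
#' @return List with `rows` (data frame `source_id`, `target_id`,
#'   `match_key`, `key`, `ambiguity_count`) and `unmatched` (character
#'   vector of source ids).
#' @export
map_identifiers <- function(set_a, set_b,
                            key = c("inchikey", "abbreviation", "formula"),
                            first_block = FALSE) {
  key <- match.arg(key)
  get_keys <- function(s, nm) {
    col <- if (key == "abbreviation" && is.null(s[[key]])) "label" else key
    if (is.null(s[[col]]))
      stop("set ", nm, " has no '", key, "' key column")
    k <- as.character(s[[col]])
    if (key == "inchikey" && first_block) k <- sub("-.*$", "", k)
    k
  }
  ka <- get_keys(set_a, "a"); kb <- get_keys(set_b, "b")
  ids_a <- as.character(set_a$id); ids_b <- as.character(set_b$id)
  if (is.null(set_a$id) || is.null(set_b$id)) stop("both sets need an 'id' column")
  rows <- merge(data.frame(source_id = ids_a, key = ka, stringsAsFactors = FALSE),
                data.frame(target_id = ids_b, key = kb, stringsAsFactors = FALSE),
                by = "key")
  if (nrow(rows)) {
    amb <- stats::ave(seq_len(nrow(rows)), rows$source_id, rows$key,
                      FUN = length)
    rows$ambiguity_count <- as.integer(amb)
  } else {
    rows$ambiguity_count <- integer(0)
  }
  rows <- rows[order(rows$source_id, rows$target_id),
               c("source_id", "target_id", "key", "ambiguity_count")]
  rows$match_key <- key
  rownames(rows) <- NULL
  list(rows = rows, unmatched = sort(unique(ids_a[!ka %in% kb])))
}
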