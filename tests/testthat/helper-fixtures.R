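# Shared fixtures and independent oracles.

# chains used by the printed worked example: hexadecanol (attached as a
# 1Z-alkenyl ether) and arachidonic acid
table1_chains <- function() {
  chain_library(data.frame(
    kind = c("fatty-alcohol", "fatty-acid"),
    carbons = c(16, 20), double_bonds = c(0, 4),
    positions = c("", "5Z,8Z,11Z,14Z"),
    trivial_name = c("hexadecanol", "arachidonic acid"),
    stringsAsFactors = FALSE))
}

po_chains <- function() {
  chain_library(data.frame(
    kind = "fatty-acid", carbons = c(16, 18), double_bonds = c(0, 1),
    positions = c("", "9Z"),
    trivial_name = c("palmitic acid", "oleic acid"),
    stringsAsFactors = FALSE))
}

# independent exhaustive nested-loop enumeration with set-based dedup;
# mirrors only the combinatorial *definition*, not the package internals
oracle_counts <- function(template, chains) {
  kind_of <- c(ester = "fatty-acid", alkyl = "fatty-alcohol",
               alkenyl = "fatty-alcohol")
  prefix_of <- c(ester = "", alkyl = "O-", alkenyl = "P-")
  dbinc_of <- c(ester = 0L, alkyl = 0L, alkenyl = 1L)
  slot_opts <- lapply(seq_len(nrow(template$slots)), function(i) {
    opts <- list()
    if (template$slots$may_be_empty[i])
      opts[[length(opts) + 1]] <- list(empty = TRUE)
    for (lk in template$slots$linkages[[i]])
      for (j in which(chains$kind == kind_of[lk]))
        opts[[length(opts) + 1]] <- list(empty = FALSE, chain = j, linkage = lk)
    opts
  })
  iso <- character(0); str <- character(0); mol <- character(0)
  spc <- character(0)
  idx <- rep(1L, length(slot_opts))
  sizes <- vapply(slot_opts, length, integer(1))
  if (any(sizes == 0)) return(list(iso = 0L, str = 0L, mol = 0L, spc = 0L))
  repeat {
    terms_iso <- character(0); terms_str <- character(0)
    terms_mol <- character(0)
    sum_c <- 0L; sum_db <- 0L; ether <- FALSE
    for (k in seq_along(idx)) {
      o <- slot_opts[[k]][[idx[k]]]
      if (o$empty) {
        terms_iso <- c(terms_iso, "0:0"); terms_str <- c(terms_str, "0:0")
        terms_mol <- c(terms_mol, "zz0:0")
        next
      }
      ch <- chains[o$chain, ]
      pf <- prefix_of[o$linkage]
      base <- paste0(pf, ch$carbons, ":", ch$double_bonds)
      terms_iso <- c(terms_iso, if (nzchar(ch$positions))
        paste0(base, "(", ch$positions, ")") else base)
      terms_str <- c(terms_str, base)
      dmol <- ch$double_bonds + dbinc_of[o$linkage]
      pmol <- if (pf == "P-") "O-" else pf
      # sortable molecular term: ethers first, then C, DB
      terms_mol <- c(terms_mol, sprintf("%s%03d:%03d",
                                        if (pmol == "O-") "a" else "m",
                                        ch$carbons, dmol))
      sum_c <- sum_c + ch$carbons; sum_db <- sum_db + dmol
      ether <- ether || pf %in% c("O-", "P-")
    }
    iso <- c(iso, paste(terms_iso, collapse = "/"))
    str <- c(str, paste(terms_str, collapse = "/"))
    mol <- c(mol, paste(sort(terms_mol), collapse = "_"))
    spc <- c(spc, paste0(if (ether) "O-" else "", sum_c, ":", sum_db))
    k <- length(idx)
    while (k > 0) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= sizes[k]) break
      idx[k] <- 1L; k <- k - 1L
    }
    if (k == 0) break
  }
  list(iso = length(unique(iso)), str = length(unique(str)),
       mol = length(unique(mol)), spc = length(unique(spc)))
}

# formula of a SMILES string via Open Babel's InChI, an independent engine
ob_formula <- function(smiles) {
  skip_if_not_installed("ChemmineOB")
  inp <- paste0(paste(smiles, seq_along(smiles)), "\n", collapse = "")
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "INCHI", inp))
  lines <- strsplit(out, "\n")[[1]]
  lines <- lines[startsWith(lines, "InChI=")]
  vapply(strsplit(lines, "/"), `[`, character(1), 2)
}
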