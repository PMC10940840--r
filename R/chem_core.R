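## chem_core: atom-mapped reaction SMILES -> filtered substrate-product pairs.
##
## A substrate-product pair (A, C) is the reaction surrogate used throughout:
## the single substrate A from which most of product C's heavy atoms derive.
## Atom provenance is read off the atom-map numbers written into the reaction
## SMILES by an external atom-to-atom mapper; this module never computes maps.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I",
                    "b", "c", "n", "o", "p", "s")

#' Tokenize the atoms of a SMILES string
#'
#' Light lexical scan extracting, in writing order, every atom with its
#' element symbol, atom-map number (0 when absent) and heavy-atom flag.
#' Bond, ring-closure and branch symbols are skipped; no graph perception is
#' done (canonicalization is delegated to OpenBabel).
#'
#' @param smiles a single SMILES string (one molecule; no "." separators).
#' @return data.frame with columns `symbol`, `map` (integer), `heavy` (logical).
#' @export
smiles_atoms <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  sym <- character(0); map <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", smiles)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(":([0-9]+)$", body))[[1]]
      amap <- if (length(m)) as.integer(m[2]) else 0L
      core <- sub(":[0-9]+$", "", body)
      # element symbol after optional isotope digits
      em <- regmatches(core, regexec("^[0-9]*([A-Z][a-z]?|[a-z]{1,2}|\\*)", core))[[1]]
      if (!length(em)) stop("cannot read bracket atom [", body, "] in: ", smiles)
      sym <- c(sym, em[2]); map <- c(map, amap)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      sym <- c(sym, paste0(ch, chars[i + 1L])); map <- c(map, 0L)
      i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET || ch == "*") {
      sym <- c(sym, ch); map <- c(map, 0L)
      i <- i + 1L
    } else if (ch == "%") {
      i <- i + 3L                     # two-digit ring closure
    } else {
      i <- i + 1L                     # bonds, digits, branches, charges
    }
  }
  if (!length(sym)) stop("no atoms found in SMILES: ", smiles)
  data.frame(symbol = sym, map = map,
             heavy = !(sym %in% c("H", "h")),
             stringsAsFactors = FALSE)
}

#' Strip atom-map numbers from a SMILES string
#' @param smiles SMILES string, possibly atom-mapped.
#' @return The same SMILES with all `:<n>` atom-map suffixes removed.
#' @export
strip_atom_maps <- function(smiles) gsub(":[0-9]+\\]", "]", smiles)

#' Canonicalize a SMILES string
#'
#' Atom maps are stripped and the molecule is round-tripped through
#' OpenBabel's canonical SMILES writer. Stereo descriptors are preserved
#' as written. Results are memoized.
#'
#' @param smiles SMILES string.
#' @return Canonical SMILES string.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  s <- strip_atom_maps(smiles)
  key <- paste0("can:", s)
  hit <- get0(key, envir = .pz_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  out <- trimws(ChemmineOB::convertFormat("SMI", "CAN", s))
  if (!nzchar(out)) stop("SMILES failed to parse: '", smiles, "'")
  assign(key, out, envir = .pz_cache)
  out
}

#' Parse one atom-mapped reaction SMILES line
#'
#' The line must contain a substrate and a product field separated by `>>`
#' (or two `>` with an agent field between them; agents are dropped with a
#' warning, never treated as substrates). Nonzero atom-map numbers must be
#' unique within each side.
#'
#' @param line reaction SMILES, e.g. `"[CH3:1][CH2:2][OH:3]>>[CH3:1][CH:2]=[O:3]"`.
#' @param reaction_id identifier carried through to extracted pairs.
#' @param ec character vector of four-level EC numbers (may be empty).
#' @return An object of class `mapped_reaction` with elements `reaction_id`,
#'   `substrates`, `products` (lists of per-molecule atom tables) and
#'   `ec_numbers`.
#' @examples
#' rxn <- parse_mapped_reaction("[CH3:1][CH2:2][OH:3]>>[CH3:1][CH:2]=[O:3]", "r1")
#' length(rxn$substrates)
#' @export
parse_mapped_reaction <- function(line, reaction_id = "rxn", ec = character(0)) {
  stopifnot(is.character(line), length(line) == 1L)
  parts <- strsplit(line, ">", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop("reaction '", reaction_id, "': expected 'substrates>>products' or ",
         "'substrates>agents>products', got ", length(parts) - 1L, " '>' fields")
  if (nzchar(parts[2]))
    warning("reaction '", reaction_id, "': agent field '", parts[2],
            "' dropped (agents are not substrates)")
  parse_side <- function(side, role) {
    mols <- strsplit(side, ".", fixed = TRUE)[[1]]
    mols <- mols[nzchar(mols)]
    if (!length(mols)) stop("reaction '", reaction_id, "': empty ", role, " side")
    lapply(mols, function(s) {
      atoms <- tryCatch(smiles_atoms(s), error = function(e)
        stop("reaction '", reaction_id, "': malformed ", role, " molecule '",
             s, "': ", conditionMessage(e)))
      # full parse check through the canonicalizer
      tryCatch(canonical_smiles(s), error = function(e)
        stop("reaction '", reaction_id, "': malformed ", role, " molecule '",
             s, "'"))
      list(smiles = s, atoms = atoms, role = role)
    })
  }
  subs <- parse_side(parts[1], "substrate")
  prods <- parse_side(parts[3], "product")
  check_maps <- function(mols, role) {
    maps <- unlist(lapply(mols, function(m) m$atoms$map[m$atoms$map > 0L]))
    dup <- unique(maps[duplicated(maps)])
    if (length(dup))
      stop("reaction '", reaction_id, "': atom-map number(s) ",
           paste(dup, collapse = ", "), " duplicated among ", role, "s")
  }
  check_maps(subs, "substrate")
  check_maps(prods, "product")
  structure(list(reaction_id = reaction_id, substrates = subs,
                 products = prods, ec_numbers = as.character(ec),
                 line = line),
            class = "mapped_reaction")
}

#' @export
print.mapped_reaction <- function(x, ...) {
  cat("<mapped_reaction ", x$reaction_id, "> ",
      length(x$substrates), " substrate(s) >> ",
      length(x$products), " product(s); EC: ",
      if (length(x$ec_numbers)) paste(x$ec_numbers, collapse = ";") else "-",
      "\n", sep = "")
  invisible(x)
}

#' Assign each heavy product atom to its source substrate
#'
#' Each heavy atom of the chosen product is looked up by atom-map number in
#' the substrates; atoms with map 0, or whose map is absent from every
#' substrate, are unmapped (`NA`).
#'
#' @param rxn a `mapped_reaction`.
#' @param product_index 1-based index of the product molecule.
#' @return data.frame with one row per heavy product atom: `symbol`, `map`,
#'   `substrate` (1-based substrate index or `NA` for unmapped atoms).
#' @export
atom_provenance <- function(rxn, product_index) {
  stopifnot(inherits(rxn, "mapped_reaction"),
            product_index >= 1L, product_index <= length(rxn$products))
  prod <- rxn$products[[product_index]]
  heavy <- prod$atoms[prod$atoms$heavy, , drop = FALSE]
  sub_of_map <- integer(0)
  for (i in seq_along(rxn$substrates)) {
    m <- rxn$substrates[[i]]$atoms$map
    m <- m[m > 0L]
    sub_of_map[as.character(m)] <- i
  }
  src <- rep(NA_integer_, nrow(heavy))
  pos <- heavy$map > 0L
  hit <- sub_of_map[as.character(heavy$map[pos])]
  src[pos] <- unname(hit)
  data.frame(symbol = heavy$symbol, map = heavy$map, substrate = src,
             stringsAsFactors = FALSE)
}

#' Extract substrate-product pairs by the majority-provenance rule
#'
#' For every (substrate A, product C) combination the provenance fraction is
#' the number of heavy atoms of C mapped to A divided by the total number of
#' heavy atoms of C (unmapped atoms count in the denominator only). A pair is
#' emitted iff its fraction is strictly greater than `threshold`.
#'
#' @param rxn a `mapped_reaction`.
#' @param threshold strict lower bound on the provenance fraction (default 0.5).
#' @return data.frame of pairs: `reaction_id`, `substrate_smiles`,
#'   `product_smiles` (both canonical, map-free), `provenance_fraction`,
#'   `substrate_index`, `product_index`.
#' @examples
#' rxn <- parse_mapped_reaction("[CH3:1][CH2:2][OH:3]>>[CH3:1][CH:2]=[O:3]", "r1")
#' extract_pairs(rxn)
#' @export
extract_pairs <- function(rxn, threshold = 0.5) {
  stopifnot(inherits(rxn, "mapped_reaction"), threshold >= 0, threshold <= 1)
  out <- list()
  for (pi in seq_along(rxn$products)) {
    prod <- rxn$products[[pi]]
    n_heavy <- sum(prod$atoms$heavy)
    if (n_heavy == 0L) {
      warning("reaction '", rxn$reaction_id, "': product ", pi,
              " ('", prod$smiles, "') has no heavy atoms; skipped")
      next
    }
    prov <- atom_provenance(rxn, pi)
    prod_can <- canonical_smiles(prod$smiles)
    for (si in seq_along(rxn$substrates)) {
      frac <- sum(!is.na(prov$substrate) & prov$substrate == si) / n_heavy
      if (frac > threshold) {
        out[[length(out) + 1L]] <- data.frame(
          reaction_id = rxn$reaction_id,
          substrate_smiles = canonical_smiles(rxn$substrates[[si]]$smiles),
          product_smiles = prod_can,
          provenance_fraction = frac,
          substrate_index = si, product_index = pi,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(reaction_id = character(0), substrate_smiles = character(0),
                      product_smiles = character(0), provenance_fraction = numeric(0),
                      substrate_index = integer(0), product_index = integer(0)))
  do.call(rbind, out)
}

#' Default cofactor exclusion list
#'
#' Canonical SMILES for common cofactors and ubiquitous small co-substrates
#' (ATP, ADP, AMP, NAD(P)(H), CoA, acetyl-CoA, FAD, FADH2, phosphate,
#' diphosphate, CO2, water, O2, H+, ammonia), loaded from the editable file
#' shipped at `inst/extdata/cofactors.smi`.
#'
#' @return Character vector of canonical SMILES.
#' @export
default_cofactors <- function() {
  path <- system.file("extdata", "cofactors.smi", package = "pairzyme")
  read_cofactor_list(path)
}

#' Read a cofactor list file
#'
#' One SMILES per line; blank lines and `#` comments allowed. Entries are
#' canonicalized on load so user-supplied dialects match.
#'
#' @param path file path.
#' @return Character vector of canonical SMILES.
#' @export
read_cofactor_list <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  unique(vapply(lines, canonical_smiles, character(1), USE.NAMES = FALSE))
}

#' Filter out single-atom and cofactor pairs
#'
#' Drops any pair whose substrate or product either has exactly one heavy
#' atom (e.g. water, a proton) or canonically matches an entry of the
#' cofactor set. Survivor order is preserved; applying the filter twice
#' changes nothing.
#'
#' @param pairs data.frame as returned by [extract_pairs()].
#' @param cofactors character vector of canonical SMILES
#'   (default [default_cofactors()]).
#' @return Filtered pairs data.frame.
#' @export
filter_pairs <- function(pairs, cofactors = default_cofactors()) {
  if (!nrow(pairs)) return(pairs)
  heavy_count <- function(s)
    vapply(s, function(x) sum(smiles_atoms(x)$heavy), numeric(1))
  sub_n <- heavy_count(pairs$substrate_smiles)
  prod_n <- heavy_count(pairs$product_smiles)
  bad <- sub_n <= 1L | prod_n <= 1L |
    pairs$substrate_smiles %in% cofactors |
    pairs$product_smiles %in% cofactors
  pairs[!bad, , drop = FALSE]
}

#' Format a pair as reaction SMILES
#'
#' Canonical `"substrate>>product"` string; equal pairs map to identical
#' strings, which is used as the deduplication key and as the input to the
#' reaction-pair embedder.
#'
#' @param substrate_smiles,product_smiles SMILES strings (canonicalized here).
#' @return Reaction SMILES string.
#' @export
pair_to_reaction_smiles <- function(substrate_smiles, product_smiles) {
  paste0(vapply(substrate_smiles, canonical_smiles, character(1), USE.NAMES = FALSE),
         ">>",
         vapply(product_smiles, canonical_smiles, character(1), USE.NAMES = FALSE))
}

#' Read a reactions table
#'
#' TSV with columns `reaction_id`, `mapped_rxn_smiles`, `ec_numbers`
#' (semicolon-separated, may be empty).
#'
#' @param path TSV file path.
#' @return list of `mapped_reaction` objects.
#' @export
read_reactions <- function(path) {
  tab <- data.table::fread(path, sep = "\t", colClasses = "character",
                           data.table = FALSE)
  stopifnot(all(c("reaction_id", "mapped_rxn_smiles") %in% names(tab)))
  ecs <- if ("ec_numbers" %in% names(tab)) tab$ec_numbers else rep("", nrow(tab))
  lapply(seq_len(nrow(tab)), function(i) {
    ec <- strsplit(ecs[i], ";", fixed = TRUE)[[1]]
    ec <- trimws(ec[nzchar(trimws(ec))])
    parse_mapped_reaction(tab$mapped_rxn_smiles[i], tab$reaction_id[i], ec)
  })
}

#' Extract and filter pairs for a list of reactions
#'
#' @param reactions list of `mapped_reaction` objects.
#' @param threshold provenance threshold (strict; default 0.5).
#' @param cofactors cofactor SMILES set.
#' @return Combined pairs data.frame.
#' @export
mine_pairs <- function(reactions, threshold = 0.5,
                       cofactors = default_cofactors()) {
  res <- lapply(reactions, extract_pairs, threshold = threshold)
  pairs <- do.call(rbind, res)
  filter_pairs(pairs, cofactors)
}

#' Write a pairs table
#' @param pairs pairs data.frame.
#' @param path output TSV path.
#' @export
write_pairs <- function(pairs, path) {
  data.table::fwrite(pairs[, c("reaction_id", "substrate_smiles",
                               "product_smiles", "provenance_fraction")],
                     path, sep = "\t")
  invisible(path)
}
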