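## triad_dataset: substrate-product-enzyme triads, EC-mismatch unlabeled
## generation, deduplication, train/test splitting and sequence-identity
## characterization.
##
## Triads are kept as plain data.frames with columns
##   triad_id, reaction_id, substrate_smiles, product_smiles,
##   enzyme_id, label ("positive" | "unlabeled")
## Enzymes live in a separate data.frame keyed by enzyme_id
## (columns enzyme_id, sequence, ec, length).

#' Read an enzyme FASTA file
#'
#' EC numbers are parsed from a header token of the form `EC=a.b.c.d` when
#' present; headers without one yield `NA` EC.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `enzyme_id`, `sequence`, `ec`, `length`.
#' @export
read_enzymes_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  id <- vapply(strsplit(hdr, "\\s+"), `[`, character(1), 1L)
  ec <- rep(NA_character_, length(hdr))
  m <- regmatches(hdr, regexec("EC=([0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+)", hdr))
  hit <- lengths(m) == 2L
  ec[hit] <- vapply(m[hit], `[`, character(1), 2L)
  data.frame(enzyme_id = id, sequence = as.character(aa), ec = ec,
             length = Biostrings::width(aa), stringsAsFactors = FALSE)
}

#' Write enzymes to FASTA
#' @param enzymes enzyme data.frame (`enzyme_id`, `sequence`, optional `ec`).
#' @param path output path.
#' @export
write_enzymes_fasta <- function(enzymes, path) {
  hdr <- enzymes$enzyme_id
  if (!is.null(enzymes$ec)) {
    has <- !is.na(enzymes$ec)
    hdr[has] <- paste0(hdr[has], " EC=", enzymes$ec[has])
  }
  x <- Biostrings::AAStringSet(enzymes$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.empty_triads <- function() {
  data.frame(triad_id = character(0), reaction_id = character(0),
             substrate_smiles = character(0), product_smiles = character(0),
             enzyme_id = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

.triad_ids <- function(df) {
  paste(df$reaction_id, df$substrate_smiles, df$product_smiles,
        df$enzyme_id, df$label, sep = "|")
}

#' Build positive triads from pairs and their source enzymes
#'
#' One positive triad per (pair, enzyme) combination, where the enzymes are
#' those annotated on the pair's source reaction. Enzymes longer than
#' `max_len` amino acids are excluded (strictly greater; a 1000-residue
#' enzyme is kept under the default cap).
#'
#' @param pairs pairs data.frame from [extract_pairs()]/[filter_pairs()].
#' @param enzymes_by_reaction named list: reaction_id -> enzyme data.frame.
#' @param max_len maximum enzyme length (default 1000).
#' @return Triads data.frame (all `label == "positive"`); the number of
#'   over-length enzymes skipped is attached as attribute `n_skipped_long`.
#' @export
build_triads <- function(pairs, enzymes_by_reaction, max_len = 1000L) {
  stopifnot(all(pairs$reaction_id %in% names(enzymes_by_reaction)))
  out <- list(); skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    enz <- enzymes_by_reaction[[pairs$reaction_id[i]]]
    if (is.null(enz) || !nrow(enz)) next
    keep <- enz$length <= max_len
    skipped <- skipped + sum(!keep)
    enz <- enz[keep, , drop = FALSE]
    if (!nrow(enz)) next
    out[[length(out) + 1L]] <- data.frame(
      reaction_id = pairs$reaction_id[i],
      substrate_smiles = pairs$substrate_smiles[i],
      product_smiles = pairs$product_smiles[i],
      enzyme_id = enz$enzyme_id, label = "positive",
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else .empty_triads()
  res$triad_id <- if (nrow(res)) sprintf("t%06d", seq_len(nrow(res))) else character(0)
  res <- res[, c("triad_id", "reaction_id", "substrate_smiles",
                 "product_smiles", "enzyme_id", "label")]
  attr(res, "n_skipped_long") <- skipped
  res
}

#' Generate EC-mismatch unlabeled triads for one reaction
#'
#' Uniformly samples `k` enzymes (without replacement) from the pool whose
#' four-level EC differs from every EC of the reaction, and attaches each
#' sampled enzyme to every substrate-product pair of that reaction as an
#' unlabeled triad. With fewer than `k` eligible enzymes all eligible ones
#' are used and a shortfall warning is raised.
#'
#' @param reaction_pairs pairs data.frame restricted to one reaction.
#' @param reaction_ecs character vector of the reaction's EC numbers (>= 1).
#' @param pool enzyme data.frame with non-missing `ec`.
#' @param k number of unlabeled enzymes to draw (default 20).
#' @param seed integer seed.
#' @param exclude_same_subclass if TRUE, enzymes sharing the first three EC
#'   levels with the reaction are also ineligible (stricter negatives;
#'   default FALSE = full four-level comparison).
#' @return Unlabeled triads data.frame.
#' @export
generate_unlabeled <- function(reaction_pairs, reaction_ecs, pool, k = 20L,
                               seed = 1L, exclude_same_subclass = FALSE) {
  stopifnot(nrow(reaction_pairs) >= 1L, length(reaction_ecs) >= 1L)
  rid <- unique(reaction_pairs$reaction_id)
  stopifnot(length(rid) == 1L)
  pool <- pool[!is.na(pool$ec), , drop = FALSE]
  eligible <- !(pool$ec %in% reaction_ecs)
  if (exclude_same_subclass) {
    ec3 <- function(x) sub("\\.[^.]+$", "", x)
    eligible <- eligible & !(ec3(pool$ec) %in% ec3(reaction_ecs))
  }
  cand <- pool[eligible, , drop = FALSE]
  if (!nrow(cand)) {
    warning("reaction '", rid, "': no EC-mismatched enzymes in pool; ",
            "0 unlabeled triads generated")
    return(.empty_triads())
  }
  n_draw <- min(k, nrow(cand))
  if (n_draw < k)
    warning("reaction '", rid, "': only ", n_draw, " eligible enzymes for ",
            k, " requested unlabeled draws")
  idx <- withr::with_seed(seed, sample.int(nrow(cand), n_draw))
  drawn <- cand[idx, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(reaction_pairs)), function(i) {
    data.frame(reaction_id = rid,
               substrate_smiles = reaction_pairs$substrate_smiles[i],
               product_smiles = reaction_pairs$product_smiles[i],
               enzyme_id = drawn$enzyme_id, label = "unlabeled",
               stringsAsFactors = FALSE)
  }))
  out$triad_id <- sprintf("%s.u%04d", rid, seq_len(nrow(out)))
  out[, c("triad_id", "reaction_id", "substrate_smiles", "product_smiles",
          "enzyme_id", "label")]
}

#' Deduplicate triads
#'
#' One triad survives per (canonical pair string, enzyme) key; the first
#' occurrence wins within a label, and a key present as both positive and
#' unlabeled keeps only the positive (a verified positive cannot serve as a
#' presumed negative).
#'
#' @param triads triads data.frame.
#' @param enzymes enzyme data.frame (sequences define enzyme identity; two
#'   ids with the same sequence collapse). Optional; ids used if missing.
#' @return Deduplicated triads data.frame.
#' @export
deduplicate_triads <- function(triads, enzymes = NULL) {
  if (!nrow(triads)) return(triads)
  enz_key <- triads$enzyme_id
  if (!is.null(enzymes)) {
    seq_of <- stats::setNames(enzymes$sequence, enzymes$enzyme_id)
    hit <- triads$enzyme_id %in% names(seq_of)
    enz_key[hit] <- seq_of[triads$enzyme_id[hit]]
  }
  key <- paste(triads$substrate_smiles, triads$product_smiles, enz_key,
               sep = ">>|")
  # positives first, stable within label, so positive wins any clash
  ord <- order(triads$label != "positive", seq_len(nrow(triads)))
  t2 <- triads[ord, , drop = FALSE]
  k2 <- key[ord]
  res <- t2[!duplicated(k2), , drop = FALSE]
  res[order(match(res$triad_id, triads$triad_id)), , drop = FALSE]
}

#' Split triads into a fixed-size test set and a training remainder
#'
#' Uniformly samples `n_pos` positives and `n_neg` unlabeled triads as the
#' test set; everything else is the training set. Reproducible under `seed`.
#'
#' @param triads deduplicated triads data.frame.
#' @param n_pos,n_neg test-set class sizes.
#' @param seed integer seed.
#' @return list of class `dataset_split`: `train_ids`, `test_ids`, `seed`,
#'   `counts`.
#' @export
split_test <- function(triads, n_pos = 5000L, n_neg = 5000L, seed = 1L) {
  pos <- triads$triad_id[triads$label == "positive"]
  neg <- triads$triad_id[triads$label == "unlabeled"]
  if (length(pos) < n_pos)
    stop("need ", n_pos, " positives but only ", length(pos), " available")
  if (length(neg) < n_neg)
    stop("need ", n_neg, " unlabeled but only ", length(neg), " available")
  test <- withr::with_seed(seed, c(sample(pos, n_pos), sample(neg, n_neg)))
  train <- setdiff(triads$triad_id, test)
  structure(list(train_ids = train, test_ids = test, seed = as.integer(seed),
                 counts = c(test_pos = n_pos, test_neg = n_neg,
                            train = length(train))),
            class = "dataset_split")
}

#' Write a dataset split to disk
#' @param split a `dataset_split`.
#' @param dir output directory (created if absent).
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(split$train_ids, file.path(dir, "train_ids.txt"))
  writeLines(split$test_ids, file.path(dir, "test_ids.txt"))
  jsonlite::write_json(list(seed = split$seed, counts = as.list(split$counts)),
                       file.path(dir, "split_manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Global-alignment percent identity between two protein sequences
#'
#' Needleman-Wunsch global alignment with BLOSUM62, gap opening 10 and gap
#' extension 0.5; identity = matching positions / alignment length (gaps
#' included) x 100.
#'
#' @param a,b amino-acid sequences (20-letter alphabet plus X).
#' @return Percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  ok <- function(s) grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", s)
  if (!ok(a) || !ok(b))
    stop("sequences must use the 20-letter amino-acid alphabet plus X")
  aln <- Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, type = "global")
  as.numeric(Biostrings::pid(aln, type = "PID1"))
}

#' Summarize sequence-identity structure of a sequence set
#'
#' All-vs-all average percent identities (optionally on a capped uniform
#' subsample) plus the fraction of sequences whose average identity to the
#' others is below 30%.
#'
#' @param sequences character vector of sequences.
#' @param sample_cap maximum number of sequences aligned (default 30).
#' @param seed subsample seed.
#' @return list: `mean_identity`, `frac_below_30`, `n_used`, `subsampled`.
#' @export
dataset_identity_summary <- function(sequences, sample_cap = 30L, seed = 1L) {
  sequences <- sequences[nzchar(sequences)]
  n <- length(sequences)
  stopifnot(n >= 2L)
  subsampled <- n > sample_cap
  if (subsampled)
    sequences <- withr::with_seed(seed, sample(sequences, sample_cap))
  m <- length(sequences)
  idm <- matrix(100, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    idm[i, j] <- idm[j, i] <- pairwise_identity(sequences[i], sequences[j])
  }
  avg_to_others <- (rowSums(idm) - 100) / (m - 1L)
  list(mean_identity = mean(idm[upper.tri(idm)]),
       frac_below_30 = mean(avg_to_others < 30),
       n_used = m, subsampled = subsampled)
}

#' Write / read triads TSV
#' @param triads triads data.frame.
#' @param path TSV path.
#' @export
write_triads <- function(triads, path) {
  data.table::fwrite(triads, path, sep = "\t")
  invisible(path)
}

#' @rdname write_triads
#' @export
read_triads <- function(path) {
  data.table::fread(path, sep = "\t", colClasses = "character",
                    data.table = FALSE)
}
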