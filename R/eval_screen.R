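## eval_screen: ROC/PRC metrics and the screening applications
## (single-pair ranking, multi-pair intersection screening, rank reports).

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability with midrank tie correction,
#' which equals the trapezoidal integral of TPR over FPR across all
#' thresholds.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y), !anyNA(scores), !anyNA(y))
  np <- sum(y); nn <- sum(!y)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Area under the step curve traced by sweeping the decision threshold over
#' all distinct scores (average precision with tie grouping).
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1 vector; at least one positive required.
#' @return PR-AUC in \[0, 1\].
#' @export
prc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y))
  P <- sum(y)
  if (P == 0L) stop("at least one positive required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yo <- y[ord]
  grp_last <- which(diff(s) != 0)
  cut <- c(grp_last, length(s))          # last index of each tie group
  tp <- cumsum(yo)[cut]
  n_at <- cut
  recall <- tp / P
  precision <- tp / n_at
  sum(diff(c(0, recall)) * precision)
}

#' Score labeled triads and fill a metric report
#'
#' Deterministic evaluation: all triads are scored, ROC-AUC and PRC-AUC are
#' computed on the scores, and the confusion matrix is taken at the given
#' threshold.
#'
#' @param model a `promiscuity_model`.
#' @param triads labeled triads data.frame.
#' @param enzymes enzyme data.frame.
#' @param threshold positive-call threshold (default 0.5).
#' @return list of class `metric_report`: `roc_auc`, `prc_auc`, `accuracy`,
#'   `tp`, `fp`, `tn`, `fn`, `n`, `scores`.
#' @export
evaluate_triads <- function(model, triads, enzymes, threshold = 0.5) {
  sc <- score_triads(model, triads, enzymes)
  y <- triads$label == "positive"
  call_pos <- sc > threshold
  structure(list(
    roc_auc = roc_auc(sc, y), prc_auc = prc_auc(sc, y),
    accuracy = mean(call_pos == y),
    tp = sum(call_pos & y), fp = sum(call_pos & !y),
    tn = sum(!call_pos & !y), fn = sum(!call_pos & y),
    n = length(sc), scores = sc), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("ROC-AUC %.4f  PRC-AUC %.4f  acc %.4f  (TP %d FP %d TN %d FN %d)\n",
              x$roc_auc, x$prc_auc, x$accuracy, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Screen an enzyme library against one substrate-product pair
#'
#' Scores every library enzyme, sorts descending (ties broken by enzyme_id
#' for determinism) and assigns ranks 1..n and relative ranks rank/n.
#' Over-length sequences are skipped with a warning and reported in the
#' `skipped` attribute.
#'
#' @param model a `promiscuity_model`.
#' @param substrate_smiles,product_smiles the pair.
#' @param library enzyme data.frame (`enzyme_id`, `sequence`).
#' @return data.frame: `enzyme_id`, `score`, `rank`, `relative_rank`.
#' @export
screen_enzymes <- function(model, substrate_smiles, product_smiles, library) {
  stopifnot(nrow(library) >= 1L)
  too_long <- nchar(library$sequence) > model$cfg$max_enzyme_len
  if (any(too_long))
    warning(sum(too_long), " over-length sequence(s) skipped: ",
            paste(utils::head(library$enzyme_id[too_long], 3L), collapse = ", "))
  lib <- library[!too_long, , drop = FALSE]
  sc <- vapply(lib$sequence, function(s)
    score_triad(model, substrate_smiles, product_smiles, s), numeric(1))
  ord <- order(-sc, lib$enzyme_id)
  out <- data.frame(enzyme_id = lib$enzyme_id[ord], score = sc[ord],
                    rank = seq_along(ord),
                    relative_rank = seq_along(ord) / length(ord),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- library$enzyme_id[too_long]
  out
}

#' Two-step (multi-pair) intersection screening
#'
#' Screens the library against each pair in turn; an enzyme survives iff its
#' score exceeds `threshold` for every pair. Survivors are ranked by the
#' minimum of their per-pair scores (the conservative aggregate that
#' reproduces pair-by-pair intersection). The full score matrix is returned
#' for inspection.
#'
#' @param model a `promiscuity_model`.
#' @param pairs data.frame with `substrate_smiles`, `product_smiles` rows.
#' @param library enzyme data.frame.
#' @param threshold per-pair survival threshold (default 0.5).
#' @return list: `shortlist` (data.frame `enzyme_id`, `min_score`, `rank`),
#'   `score_matrix` (enzymes x pairs).
#' @export
multi_pair_screen <- function(model, pairs, library, threshold = 0.5) {
  stopifnot(nrow(pairs) >= 1L)
  keep <- nchar(library$sequence) <= model$cfg$max_enzyme_len
  lib <- library[keep, , drop = FALSE]
  M <- matrix(NA_real_, nrow(lib), nrow(pairs),
              dimnames = list(lib$enzyme_id,
                              paste0("pair", seq_len(nrow(pairs)))))
  for (j in seq_len(nrow(pairs))) {
    M[, j] <- vapply(lib$sequence, function(s)
      score_triad(model, pairs$substrate_smiles[j], pairs$product_smiles[j], s),
      numeric(1))
  }
  min_score <- apply(M, 1L, min)
  surv <- min_score > threshold
  ids <- lib$enzyme_id[surv]
  ms <- min_score[surv]
  ord <- order(-ms, ids)
  shortlist <- data.frame(enzyme_id = ids[ord], min_score = ms[ord],
                          rank = seq_along(ord), stringsAsFactors = FALSE)
  list(shortlist = shortlist, score_matrix = M)
}

#' Rank report for one target enzyme in a screening result
#'
#' @param target_id enzyme id to look up.
#' @param ranked screening output from [screen_enzymes()].
#' @param threshold positive-call threshold for the positive count.
#' @return list: `rank`, `relative_rank`, `positive_count`.
#' @export
rank_of <- function(target_id, ranked, threshold = 0.5) {
  i <- match(target_id, ranked$enzyme_id)
  if (is.na(i)) stop("target '", target_id, "' not present in ranking")
  list(rank = ranked$rank[i], relative_rank = ranked$relative_rank[i],
       positive_count = sum(ranked$score > threshold))
}
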