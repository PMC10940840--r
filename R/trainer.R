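## trainer: positive-unlabeled training with balanced undersampling,
## label-smoothed binary cross-entropy, dynamic purging of confidently
## positive unlabeled examples, and a rectified-Adam optimizer.

#' Training configuration
#'
#' Defaults are the full-scale settings (64 epochs, batch 64, lr 5e-6,
#' weight decay 1e-5, smoothing 0.1, purge trigger AUC 0.9 / score 0.8,
#' 20:1 unlabeled ratio); desk-scale runs override `epochs`, `batch_size`
#' and `lr`.
#'
#' @param epochs,batch_size,lr,weight_decay optimizer schedule.
#' @param label_smoothing smoothing rate epsilon in \[0, 0.5).
#' @param purge_trigger_auc validation ROC-AUC that arms purging.
#' @param purge_score_threshold unlabeled examples scoring above this are
#'   permanently removed once purging is armed.
#' @param neg_ratio unlabeled:positive generation ratio (bookkeeping).
#' @param seed master seed for sampling, dropout and init.
#' @param loss_variant `"standard"` (symmetric smoothed targets) or
#'   `"as_printed"` (literal hybrid form; see [smoothed_bce_loss()]).
#' @param optimizer `"radam"` or `"adam"`.
#' @param grad_clip global gradient-norm clip (0 disables).
#' @param val_frac fraction of training positives carved into the fixed
#'   validation slice that drives the purge trigger.
#' @param early_stop_auc stop once validation ROC-AUC reaches this (NULL =
#'   run all epochs).
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 64L, batch_size = 64L, lr = 5e-6,
                         weight_decay = 1e-5, label_smoothing = 0.1,
                         purge_trigger_auc = 0.9, purge_score_threshold = 0.8,
                         neg_ratio = 20L, seed = 1L,
                         loss_variant = c("standard", "as_printed"),
                         optimizer = c("radam", "adam"), grad_clip = 1.0,
                         val_frac = 0.05, early_stop_auc = NULL) {
  loss_variant <- match.arg(loss_variant)
  optimizer <- match.arg(optimizer)
  stopifnot(label_smoothing >= 0, label_smoothing < 0.5,
            purge_trigger_auc > 0, purge_trigger_auc < 1,
            purge_score_threshold > 0, purge_score_threshold < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay,
                 label_smoothing = label_smoothing,
                 purge_trigger_auc = purge_trigger_auc,
                 purge_score_threshold = purge_score_threshold,
                 neg_ratio = as.integer(neg_ratio), seed = as.integer(seed),
                 loss_variant = loss_variant, optimizer = optimizer,
                 grad_clip = grad_clip, val_frac = val_frac,
                 early_stop_auc = early_stop_auc),
            class = "train_config")
}

#' Label-smoothed binary cross-entropy
#'
#' Two variants of the smoothing/cross-entropy hybrid. `"standard"` softens
#' the targets symmetrically, `y' = y(1 - eps) + eps/2`, and evaluates plain
#' binary cross-entropy against `y'`; it reduces to unsmoothed BCE at
#' `eps = 0` and is minimized at `p = y'`. `"as_printed"` is the literal
#' hybrid form `-mean[(eps y) log p + (1 - (1 - eps) y) log(1 - p)]`, kept
#' for fidelity experiments: for `y = 1` both of its terms carry `eps`, so
#' its positive-class minimum sits at `p = 0.5` rather than near 1, which is
#' why `"standard"` is the default.
#'
#' @param p predicted probabilities (clamped to \[1e-7, 1 - 1e-7\]).
#' @param y labels in \{0, 1\}.
#' @param eps smoothing rate (default 0.1).
#' @param variant `"standard"` or `"as_printed"`.
#' @return Mean loss (non-negative scalar).
#' @export
smoothed_bce_loss <- function(p, y, eps = 0.1,
                              variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  stopifnot(length(p) == length(y), eps >= 0, eps < 0.5)
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  if (variant == "standard") {
    yp <- y * (1 - eps) + eps / 2
    -mean(yp * log(p) + (1 - yp) * log(1 - p))
  } else {
    -mean((eps * y) * log(p) + (1 - (1 - eps) * y) * log(1 - p))
  }
}

## d(mean loss)/dp, elementwise (length of p); clamping region has zero grad
.smoothed_bce_grad <- function(p, y, eps, variant) {
  n <- length(p)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  g <- if (variant == "standard") {
    yp <- y * (1 - eps) + eps / 2
    -(yp / pc - (1 - yp) / (1 - pc)) / n
  } else {
    -((eps * y) / pc - (1 - (1 - eps) * y) / (1 - pc)) / n
  }
  g[p != pc] <- 0
  g
}

#' Draw a balanced epoch negative set from the unlabeled pool
#'
#' Uniformly samples as many unlabeled triads as there are positives,
#' without replacement; a pool smaller than the positive set is used whole
#' with a warning. A fresh draw is taken every epoch.
#'
#' @param positives positive triads data.frame.
#' @param unlabeled_pool unlabeled triads data.frame.
#' @param seed draw seed.
#' @return data.frame of sampled unlabeled triads.
#' @export
sample_epoch_negatives <- function(positives, unlabeled_pool, seed = 1L) {
  if (!nrow(unlabeled_pool)) stop("unlabeled pool is empty")
  n <- nrow(positives)
  if (nrow(unlabeled_pool) < n) {
    warning("unlabeled pool (", nrow(unlabeled_pool),
            ") smaller than positive set (", n, "); using all of it")
    return(unlabeled_pool)
  }
  idx <- withr::with_seed(seed, sample.int(nrow(unlabeled_pool), n))
  unlabeled_pool[idx, , drop = FALSE]
}

#' Purge confidently positive unlabeled examples
#'
#' No-op while the validation ROC-AUC is at or below the trigger. Once the
#' trigger is exceeded, every pool member is scored and those above the
#' score threshold are permanently removed (they are presumed to be
#' unverified positives, not negatives). Positives are never candidates.
#'
#' @param model a `promiscuity_model`.
#' @param unlabeled_pool unlabeled triads data.frame.
#' @param enzymes enzyme data.frame.
#' @param current_val_auc validation ROC-AUC at this checkpoint.
#' @param cfg a `train_config`.
#' @return list: `pool` (surviving triads), `purged_ids`, `triggered`.
#' @export
purge_unlabeled <- function(model, unlabeled_pool, enzymes, current_val_auc,
                            cfg) {
  if (!(current_val_auc > cfg$purge_trigger_auc) || !nrow(unlabeled_pool))
    return(list(pool = unlabeled_pool, purged_ids = character(0),
                triggered = FALSE))
  sc <- score_triads(model, unlabeled_pool, enzymes)
  drop <- sc > cfg$purge_score_threshold
  list(pool = unlabeled_pool[!drop, , drop = FALSE],
       purged_ids = unlabeled_pool$triad_id[drop], triggered = TRUE)
}

## optimizer state ------------------------------------------------------------

.opt_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

## RAdam (rectified Adam) update; falls back to plain Adam when requested.
.opt_step <- function(params, grads, state, cfg) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  t <- state$t
  if (cfg$grad_clip > 0) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
    if (is.finite(gn) && gn > cfg$grad_clip)
      grads <- lapply(grads, function(g) g * (cfg$grad_clip / gn))
  }
  rho_inf <- 2 / (1 - b2) - 1
  rho_t <- rho_inf - 2 * t * b2^t / (1 - b2^t)
  use_rect <- cfg$optimizer == "radam"
  r_t <- if (use_rect && rho_t > 4)
    sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
           ((rho_inf - 4) * (rho_inf - 2) * rho_t)) else NA_real_
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (cfg$weight_decay > 0) g <- g + cfg$weight_decay * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / (1 - b1^t)
    if (!use_rect) {
      vhat <- sqrt(state$v[[nm]] / (1 - b2^t)) + eps
      params[[nm]] <- params[[nm]] - cfg$lr * mhat / vhat
    } else if (rho_t > 4) {
      vhat <- sqrt(state$v[[nm]] / (1 - b2^t)) + eps
      params[[nm]] <- params[[nm]] - cfg$lr * r_t * mhat / vhat
    } else {
      params[[nm]] <- params[[nm]] - cfg$lr * mhat
    }
  }
  list(params = params, state = state)
}

#' Fit the promiscuity model under the positive-unlabeled regime
#'
#' Each epoch draws a fresh balanced set of unlabeled "negatives", trains in
#' mini-batches, evaluates ROC-AUC on a fixed validation slice, and applies
#' the purge rule. The best-validation parameter set is restored at the end.
#' Fully seeded: two runs with the same config and inputs produce identical
#' histories at a fixed BLAS thread count.
#'
#' @param triads training triads data.frame (positives + unlabeled).
#' @param enzymes enzyme data.frame covering every `enzyme_id`.
#' @param model a `promiscuity_model` (modified copy returned).
#' @param cfg a `train_config`.
#' @param verbose print per-epoch progress.
#' @return list: `model` (best-validation parameters), `history`
#'   (per-epoch data.frame: `epoch`, `mean_loss`, `val_auc`, `pool_size`,
#'   `n_purged`), `purge_log`, `val_ids`.
#' @export
fit_promiscuity <- function(triads, enzymes, model, cfg, verbose = FALSE) {
  stopifnot(inherits(model, "promiscuity_model"), inherits(cfg, "train_config"))
  pos <- triads[triads$label == "positive", , drop = FALSE]
  unl <- triads[triads$label == "unlabeled", , drop = FALSE]
  if (!nrow(pos)) stop("no positive triads")
  if (!nrow(unl)) stop("no unlabeled triads")

  n_val <- max(1L, ceiling(cfg$val_frac * nrow(pos)))
  n_val <- min(n_val, nrow(pos) - 1L, nrow(unl) - 1L)
  val_idx <- withr::with_seed(child_seed(cfg$seed, "val"), list(
    pos = sample.int(nrow(pos), n_val),
    unl = sample.int(nrow(unl), n_val)))
  val <- rbind(pos[val_idx$pos, ], unl[val_idx$unl, ])
  pos <- pos[-val_idx$pos, , drop = FALSE]
  pool <- unl[-val_idx$unl, , drop = FALSE]

  seq_of <- stats::setNames(enzymes$sequence, enzymes$enzyme_id)
  miss <- setdiff(unique(triads$enzyme_id), names(seq_of))
  if (length(miss)) stop("enzyme sequence(s) missing for: ",
                         paste(utils::head(miss, 3L), collapse = ", "))

  # feature caches (frozen inputs)
  ecache <- new.env(parent = emptyenv())
  enz_feat <- function(id) {
    hit <- get0(id, envir = ecache, inherits = FALSE)
    if (is.null(hit)) {
      hit <- embed_enzyme(seq_of[[id]], model$embed_table)
      assign(id, hit, envir = ecache)
    }
    hit
  }
  pair_base <- function(sub, prod)
    encode_pair_base(pair_to_reaction_smiles(sub, prod), model$encoder)

  history <- data.frame()
  purge_log <- character(0)
  best <- list(auc = -Inf, params = model$params)
  opt <- .opt_init(model$params)
  armed <- FALSE

  set.seed(child_seed(cfg$seed, "train-stream"))
  for (ep in seq_len(cfg$epochs)) {
    negs <- suppressWarnings(
      sample_epoch_negatives(pos, pool, child_seed(cfg$seed, paste0("ep", ep))))
    epoch_set <- rbind(pos, negs)
    ord <- sample.int(nrow(epoch_set))
    epoch_set <- epoch_set[ord, , drop = FALSE]
    y_all <- as.numeric(epoch_set$label == "positive")
    tot_loss <- 0; n_seen <- 0L

    for (start in seq(1L, nrow(epoch_set), by = cfg$batch_size)) {
      rows <- start:min(start + cfg$batch_size - 1L, nrow(epoch_set))
      gsum <- list()
      ps <- numeric(length(rows))
      caches <- vector("list", length(rows))
      for (j in seq_along(rows)) {
        i <- rows[j]
        B <- pair_base(epoch_set$substrate_smiles[i],
                       epoch_set$product_smiles[i])
        E <- enz_feat(epoch_set$enzyme_id[i])
        fw <- .forward_example(model, B, E, training = TRUE)
        ps[j] <- fw$p
        caches[[j]] <- fw$cache
      }
      yb <- y_all[rows]
      loss <- smoothed_bce_loss(ps, yb, cfg$label_smoothing, cfg$loss_variant)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; reduce the learning rate")
      dps <- .smoothed_bce_grad(ps, yb, cfg$label_smoothing, cfg$loss_variant)
      for (j in seq_along(rows)) {
        g <- .backward_example(model, caches[[j]], dps[j])
        for (nm in names(g)) gsum[[nm]] <- gsum[[nm]] %+0% g[[nm]]
      }
      st <- .opt_step(model$params, gsum, opt, cfg)
      model$params <- st$params
      opt <- st$state
      tot_loss <- tot_loss + loss * length(rows)
      n_seen <- n_seen + length(rows)
    }

    val_scores <- score_triads(model, val, enzymes)
    val_auc <- roc_auc(val_scores, val$label == "positive")
    armed <- armed || val_auc > cfg$purge_trigger_auc
    n_purged <- 0L
    if (armed) {
      pu <- purge_unlabeled(model, pool, enzymes,
                            current_val_auc = max(val_auc,
                                                  cfg$purge_trigger_auc + 1e-9),
                            cfg = cfg)
      n_purged <- length(pu$purged_ids)
      if (n_purged) {
        purge_log <- c(purge_log,
                       paste0("epoch ", ep, ": ", pu$purged_ids))
        pool <- pu$pool
      }
    }
    history <- rbind(history, data.frame(
      epoch = ep, mean_loss = tot_loss / n_seen, val_auc = val_auc,
      pool_size = nrow(pool), n_purged = n_purged))
    # ties prefer the later (more-trained) checkpoint: small validation
    # slices saturate their AUC early and would otherwise pin training
    # to a premature snapshot
    if (val_auc >= best$auc) best <- list(auc = val_auc, params = model$params)
    if (verbose)
      pz_msg(sprintf("epoch %d loss %.4f val_auc %.3f pool %d purged %d",
                     ep, tot_loss / n_seen, val_auc, nrow(pool), n_purged))
    if (!is.null(cfg$early_stop_auc) && val_auc >= cfg$early_stop_auc) break
  }
  model$params <- best$params
  list(model = model, history = history, purge_log = purge_log,
       val_ids = val$triad_id)
}
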