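## embeddings: per-residue enzyme features (CBOW over amino acids) and
## per-token substrate-product-pair features (frozen reaction encoder plus a
## trainable convolutional adapter head).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_VOCAB <- c(AA20, "X")     # 21 tokens: 20 amino acids + catch-all

#' Create an empty CBOW embedding table
#'
#' @param dim embedding dimension N (default 100).
#' @param seed initialization seed.
#' @return list of class `embedding_table`: `vocab` (token -> index),
#'   `W` (V x N input embeddings), `U` (N x V output matrix).
#' @export
cbow_init <- function(dim = 100L, seed = 1L) {
  V <- length(AA_VOCAB)
  withr::with_seed(seed, {
    W <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim,
                dimnames = list(AA_VOCAB, NULL))
    U <- matrix(0, dim, V, dimnames = list(NULL, AA_VOCAB))
  })
  structure(list(vocab = stats::setNames(seq_len(V), AA_VOCAB), W = W, U = U,
                 dim = dim),
            class = "embedding_table")
}

.seq_to_idx <- function(sequence, vocab) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- vocab[chars]
  unk <- is.na(idx)
  if (any(unk)) {
    warning(sum(unk), " unknown residue(s) mapped to X")
    idx[unk] <- vocab[["X"]]
  }
  unname(idx)
}

## All length-3 windows of a corpus: rows (left context, center, right context)
.cbow_windows <- function(sequences, vocab) {
  wins <- lapply(sequences, function(s) {
    idx <- .seq_to_idx(s, vocab)
    L <- length(idx)
    if (L < 3L) return(NULL)
    cbind(idx[1:(L - 2L)], idx[2:(L - 1L)], idx[3:L])
  })
  wins <- wins[!vapply(wins, is.null, logical(1))]
  if (!length(wins)) stop("corpus contains no window of length 3")
  do.call(rbind, wins)
}

#' Train CBOW residue embeddings
#'
#' Continuous bag-of-words over enzyme sequences: every 3-residue window is
#' one training example, predicting the center residue from its two flanking
#' residues via a full-softmax objective (V = 21 makes the full softmax
#' cheap; no negative sampling). The hidden vector is the mean of the context
#' rows of `W`.
#'
#' @param sequences character vector of enzyme sequences (the corpus).
#' @param dim embedding dimension (default 100).
#' @param epochs passes over the window set (default 3).
#' @param lr SGD learning rate (default 0.05).
#' @param batch_size mini-batch size (default 512).
#' @param seed seed for init and shuffling.
#' @param verbose print per-epoch loss.
#' @return A trained `embedding_table`; per-epoch mean losses in
#'   attribute `history`.
#' @export
train_cbow <- function(sequences, dim = 100L, epochs = 3L, lr = 0.05,
                       batch_size = 512L, seed = 1L, verbose = FALSE) {
  tab <- cbow_init(dim = dim, seed = seed)
  win <- .cbow_windows(sequences, tab$vocab)
  n <- nrow(win)
  V <- length(tab$vocab)
  losses <- numeric(epochs)
  withr::with_seed(child_seed(seed, "cbow"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1L, n)]
        B <- length(rows)
        c1 <- win[rows, 1L]; ctr <- win[rows, 2L]; c2 <- win[rows, 3L]
        H <- (tab$W[c1, , drop = FALSE] + tab$W[c2, , drop = FALSE]) / 2
        Y <- H %*% tab$U
        Y <- Y - apply(Y, 1L, max)
        P <- exp(Y); P <- P / rowSums(P)
        tot <- tot - sum(log(pmax(P[cbind(seq_len(B), ctr)], 1e-12)))
        dY <- P
        dY[cbind(seq_len(B), ctr)] <- dY[cbind(seq_len(B), ctr)] - 1
        dY <- dY / B
        dH <- dY %*% t(tab$U)
        tab$U <- tab$U - lr * crossprod(H, dY)
        dW <- rowsum(rbind(dH, dH) / 2, group = c(c1, c2))
        g <- as.integer(rownames(dW))
        tab$W[g, ] <- tab$W[g, ] - lr * dW
      }
      losses[ep] <- tot / n
      if (verbose) pz_msg("cbow epoch ", ep, " loss ", round(losses[ep], 4))
    }
  })
  attr(tab, "history") <- losses
  tab
}

#' CBOW forward pass: probability of each center token given a context
#'
#' The hidden vector is the mean of the context tokens' input-embedding rows;
#' the output is the full softmax over the 21-token vocabulary.
#'
#' @param table an `embedding_table`.
#' @param context character vector of context tokens (unknowns map to X with
#'   a warning).
#' @return Named probability vector over the vocabulary (sums to 1).
#' @export
cbow_forward <- function(table, context) {
  stopifnot(inherits(table, "embedding_table"), length(context) >= 1L)
  idx <- .seq_to_idx(paste(context, collapse = ""), table$vocab)
  h <- colMeans(table$W[idx, , drop = FALSE])
  y <- drop(t(table$U) %*% h)
  y <- y - max(y)
  p <- exp(y); p <- p / sum(p)
  stats::setNames(p, names(table$vocab))
}

#' Embed an enzyme sequence as an L x N feature matrix
#'
#' Row i is the trained input-embedding row of residue i (X for unknowns):
#' a pure per-residue lookup, preserving the residue-level correspondence
#' needed for attention mapping.
#'
#' @param sequence amino-acid sequence.
#' @param table an `embedding_table`.
#' @return L x N numeric matrix.
#' @export
embed_enzyme <- function(sequence, table) {
  stopifnot(inherits(table, "embedding_table"))
  if (!nzchar(sequence)) stop("empty sequence")
  idx <- .seq_to_idx(sequence, table$vocab)
  unname(table$W[idx, , drop = FALSE])
}

#' Save / load an embedding table (JSON vocab + flat matrix text)
#' @param table an `embedding_table`.
#' @param dir directory to hold `vocab.json`, `W.txt`, `U.txt`.
#' @export
save_embedding_table <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(as.list(table$vocab), file.path(dir, "vocab.json"),
                       auto_unbox = TRUE)
  utils::write.table(table$W, file.path(dir, "W.txt"), row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(table$U, file.path(dir, "U.txt"), row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}

#' @rdname save_embedding_table
#' @export
load_embedding_table <- function(dir) {
  vocab <- unlist(jsonlite::read_json(file.path(dir, "vocab.json")))
  W <- as.matrix(utils::read.table(file.path(dir, "W.txt")))
  U <- as.matrix(utils::read.table(file.path(dir, "U.txt")))
  dimnames(W) <- list(names(vocab), NULL); dimnames(U) <- list(NULL, names(vocab))
  structure(list(vocab = vocab, W = W, U = U, dim = ncol(W)),
            class = "embedding_table")
}

## ---------------------------------------------------------------------------
## Frozen reaction encoder (built-in fallback) and adapter head.
## ---------------------------------------------------------------------------

SMILES_CHARS <- c(strsplit("CNOPSFIBclnops", "")[[1]],
                  "r", "=", "#", "(", ")", "[", "]", "+", "-", ".", ">",
                  "@", "/", "\\", ":", "%", as.character(0:9), "H", "*", "?")

#' Built-in frozen reaction encoder
#'
#' A small, deterministic character-level encoder for reaction SMILES:
#' a fixed random character embedding followed by two frozen self-attention
#' mixing layers. Its parameters are generated from a constant seed, are
#' never updated by training, and stand behind the same interface as any
#' pretrained drop-in encoder (a function mapping `"A>>C"` to a T x D
#' matrix).
#'
#' @param dim output dimension D (default 32).
#' @param seed constant parameter seed (default 20240314).
#' @return list of class `reaction_encoder` with `$encode(smiles)`,
#'   `$dim`, `$params`.
#' @export
fallback_reaction_encoder <- function(dim = 32L, seed = 20240314L) {
  V <- length(SMILES_CHARS)
  params <- withr::with_seed(seed %% 2147483647L, list(
    E  = matrix(stats::rnorm(V * dim, 0, 1 / sqrt(dim)), V, dim),
    Wq1 = matrix(stats::rnorm(dim * dim, 0, 1 / sqrt(dim)), dim, dim),
    Wk1 = matrix(stats::rnorm(dim * dim, 0, 1 / sqrt(dim)), dim, dim),
    Wv1 = matrix(stats::rnorm(dim * dim, 0, 1 / sqrt(dim)), dim, dim),
    Wq2 = matrix(stats::rnorm(dim * dim, 0, 1 / sqrt(dim)), dim, dim),
    Wk2 = matrix(stats::rnorm(dim * dim, 0, 1 / sqrt(dim)), dim, dim),
    Wv2 = matrix(stats::rnorm(dim * dim, 0, 1 / sqrt(dim)), dim, dim)))
  id <- sprintf("fallback-%d-%d", dim, seed)
  lookup <- stats::setNames(seq_len(V), SMILES_CHARS)
  encode <- function(smiles) {
    chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
    idx <- lookup[chars]
    idx[is.na(idx)] <- lookup[["?"]]
    X <- params$E[idx, , drop = FALSE]
    for (lyr in 1:2) {
      Wq <- params[[paste0("Wq", lyr)]]; Wk <- params[[paste0("Wk", lyr)]]
      Wv <- params[[paste0("Wv", lyr)]]
      att <- scaled_dot_attention(X %*% Wq, X %*% Wk, X %*% Wv)
      X <- X + att$output
    }
    X
  }
  structure(list(encode = encode, dim = dim, params = params, id = id),
            class = "reaction_encoder")
}

#' Create a trainable adapter head over a frozen reaction encoder
#'
#' Two 1-D convolutions (kernel 3, length-preserving zero padding, GELU
#' between) with channel widths D -> D -> H, followed by a position-wise
#' linear map H -> H. These are the only trainable parameters on the
#' pair-feature path.
#'
#' @param d_in encoder output dimension D.
#' @param d_out model hidden size H.
#' @param seed init seed.
#' @return Named list of parameter matrices.
#' @export
new_adapter_head <- function(d_in, d_out, seed = 1L) {
  withr::with_seed(child_seed(seed, "adapter"), {
    cv <- function(di, do) matrix(stats::rnorm(di * do, 0, 1 / sqrt(3 * di)), di, do)
    list(ad_c1_m = cv(d_in, d_in), ad_c1_0 = cv(d_in, d_in),
         ad_c1_p = cv(d_in, d_in), ad_c1_b = numeric(d_in),
         ad_c2_m = cv(d_in, d_out), ad_c2_0 = cv(d_in, d_out),
         ad_c2_p = cv(d_in, d_out), ad_c2_b = numeric(d_out),
         ad_lin_W = diag(1, d_out), ad_lin_b = numeric(d_out))
  })
}

#' Embed a substrate-product pair as a T x H feature matrix
#'
#' The pair's canonical reaction SMILES passes through the frozen encoder
#' (T x D) and then the adapter head (T x H). Base encodings are cached per
#' pair string.
#'
#' @param substrate_smiles,product_smiles the pair (canonicalized here).
#' @param encoder a `reaction_encoder`.
#' @param head adapter parameters from [new_adapter_head()].
#' @return T x H matrix; the raw T x D base encoding as attribute `base`.
#' @export
embed_pair <- function(substrate_smiles, product_smiles, encoder, head) {
  rs <- pair_to_reaction_smiles(substrate_smiles, product_smiles)
  B <- encode_pair_base(rs, encoder)
  out <- adapter_forward(B, head)$Y
  attr(out, "base") <- B
  out
}

## Frozen base encoding of a canonical reaction SMILES, memoized per encoder.
encode_pair_base <- function(reaction_smiles, encoder) {
  enc_id <- if (!is.null(encoder$id)) encoder$id else paste0("d", encoder$dim)
  key <- paste0("base:", enc_id, ":", reaction_smiles)
  hit <- get0(key, envir = .pz_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  B <- encoder$encode(reaction_smiles)
  assign(key, B, envir = .pz_cache)
  B
}

## broadcast a length-ncol vector across all rows (fast sweep replacement)
.addrow <- function(X, v) X + rep(v, each = nrow(X))

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

## exact GELU with the pnorm factor cached for the backward pass
.gelu_fwd <- function(x) {
  P <- stats::pnorm(x)
  list(Y = x * P, P = P)
}
.gelu_bwd <- function(dY, x, P)
  dY * (P + x * exp(-0.5 * x * x) * 0.3989422804014327)

## kernel-3 1-D convolution along rows: Y[t,] = X[t-1]Wm + X[t]W0 + X[t+1]Wp + b
conv3_forward <- function(X, Wm, W0, Wp, b) {
  T <- nrow(X)
  if (T == 1L) {
    Xm <- matrix(0, 1L, ncol(X)); Xp <- Xm
  } else {
    Xm <- rbind(0, X[-T, , drop = FALSE])
    Xp <- rbind(X[-1L, , drop = FALSE], 0)
  }
  Y <- .addrow(Xm %*% Wm + X %*% W0 + Xp %*% Wp, b)
  list(Y = Y, Xm = Xm, Xp = Xp)
}

conv3_backward <- function(dY, X, Xm, Xp, Wm, W0, Wp) {
  T <- nrow(X)
  dX <- dY %*% t(W0)
  up <- rbind(dY[-1L, , drop = FALSE], 0)     # dY[t+1] contributes via Wm
  dn <- rbind(0, dY[-T, , drop = FALSE])      # dY[t-1] contributes via Wp
  if (T == 1L) { up <- matrix(0, 1L, ncol(dY)); dn <- matrix(0, 1L, ncol(dY)) }
  dX <- dX + up %*% t(Wm) + dn %*% t(Wp)
  list(dX = dX,
       dWm = crossprod(Xm, dY), dW0 = crossprod(X, dY),
       dWp = crossprod(Xp, dY), db = colSums(dY))
}

adapter_forward <- function(B, head, mask = NULL) {
  c1 <- conv3_forward(B, head$ad_c1_m, head$ad_c1_0, head$ad_c1_p, head$ad_c1_b)
  g1 <- .gelu_fwd(c1$Y)
  A1 <- g1$Y
  # masked positions must stay exactly zero between the convolutions, or the
  # kernel-3 window at the last valid position would read bias-injected values
  if (!is.null(mask) && !all(mask)) A1[!mask, ] <- 0
  c2 <- conv3_forward(A1, head$ad_c2_m, head$ad_c2_0, head$ad_c2_p, head$ad_c2_b)
  Y <- .addrow(c2$Y %*% head$ad_lin_W, head$ad_lin_b)
  list(Y = Y, cache = list(B = B, c1 = c1, P1 = g1$P, A1 = A1, c2 = c2,
                           mask = mask))
}

adapter_backward <- function(dY, cache, head) {
  g <- list()
  g$ad_lin_W <- crossprod(cache$c2$Y, dY)
  g$ad_lin_b <- colSums(dY)
  d2 <- dY %*% t(head$ad_lin_W)
  bk2 <- conv3_backward(d2, cache$A1, cache$c2$Xm, cache$c2$Xp,
                        head$ad_c2_m, head$ad_c2_0, head$ad_c2_p)
  g$ad_c2_m <- bk2$dWm; g$ad_c2_0 <- bk2$dW0; g$ad_c2_p <- bk2$dWp
  g$ad_c2_b <- bk2$db
  d1 <- .gelu_bwd(bk2$dX, cache$c1$Y, cache$P1)
  if (!is.null(cache$mask) && !all(cache$mask)) d1[!cache$mask, ] <- 0
  bk1 <- conv3_backward(d1, cache$B, cache$c1$Xm, cache$c1$Xp,
                        head$ad_c1_m, head$ad_c1_0, head$ad_c1_p)
  g$ad_c1_m <- bk1$dWm; g$ad_c1_0 <- bk1$dW0; g$ad_c1_p <- bk1$dWp
  g$ad_c1_b <- bk1$db
  g
}
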