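## model: positional-encoding-free transformer encoder-decoder scoring a
## (substrate-product pair, enzyme) combination.
##
## Encoder blocks self-attend over per-residue enzyme features; decoder
## blocks self-attend over pair tokens and cross-attend to the encoder
## output; position-wise feed-forwards are replaced by two kernel-3 1-D
## convolutions (the convolutions are the only carriers of order
## information -- there is no positional encoding anywhere). Output is a
## mean-pool over decoder positions into a two-way softmax.
##
## Forward and backward passes are written directly against the parameter
## list; gradients are verified by finite differences in the test suite.

LN_EPS <- 1e-5

#' Model configuration
#'
#' Defaults are the full-scale settings (12 layers, 8 heads, hidden and norm
#' shape 64, dropout 0.1, enzyme cap 1000); desk-scale runs shrink
#' `n_layers`, `n_heads` and `hidden`.
#'
#' @param n_layers encoder blocks (the decoder gets the same number).
#' @param n_heads attention heads; must divide `hidden`.
#' @param hidden model width H (also the layer-norm shape).
#' @param dropout drop rate on attention weights and feed-forward outputs.
#' @param max_enzyme_len hard cap on enzyme length.
#' @param d_enzyme per-residue enzyme feature width (CBOW dimension).
#' @param d_pair frozen reaction-encoder output width D.
#' @return list of class `model_config`.
#' @export
model_config <- function(n_layers = 12L, n_heads = 8L, hidden = 64L,
                         dropout = 0.1, max_enzyme_len = 1000L,
                         d_enzyme = 100L, d_pair = 32L) {
  stopifnot(hidden %% n_heads == 0L, n_layers >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 hidden = as.integer(hidden), dropout = dropout,
                 max_enzyme_len = as.integer(max_enzyme_len),
                 d_enzyme = as.integer(d_enzyme), d_pair = as.integer(d_pair)),
            class = "model_config")
}

#' Fixup-style residual-block weight initialization
#'
#' Samples i.i.d. from a zero-mean normal with standard deviation
#' `sigma_l / sqrt(n_l)` where `sigma_l` is `sqrt(2)` for the first layer of
#' a residual block, `sqrt(0.5)` for the last and 1 in between, keeping the
#' block output near unit variance.
#'
#' @param nrow,ncol weight matrix shape.
#' @param l_r 1-based layer position within the residual block.
#' @param n_r number of layers in the block.
#' @param n_l fan-in (number of input units).
#' @param seed optional seed (NULL draws from the current RNG stream).
#' @return nrow x ncol weight matrix.
#' @export
fixup_init <- function(nrow, ncol, l_r, n_r, n_l, seed = NULL) {
  if (l_r < 1L || l_r > n_r) stop("l_r must satisfy 1 <= l_r <= n_r")
  stopifnot(n_l >= 1L)
  sigma <- if (l_r == 1L) sqrt(2) else if (l_r == n_r) sqrt(0.5) else 1
  sd <- sigma / sqrt(n_l)
  draw <- function() matrix(stats::rnorm(nrow * ncol, 0, sd), nrow, ncol)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Scaled dot-product attention
#'
#' `weights = row-softmax(Q K^T / sqrt(d))` with masked key positions
#' receiving exactly zero weight; `output = weights %*% V`. A fully-masked
#' query row yields a zero output row (with a warning).
#'
#' @param Q,K,V query (n_q x d), key (n_k x d), value (n_k x d_v) matrices.
#' @param mask logical vector over key positions (TRUE = attend); NULL = all.
#' @return list with `output` (n_q x d_v) and `weights` (n_q x n_k).
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  d <- ncol(K)
  S <- Q %*% t(K) / sqrt(d)
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(K))
    S[, !mask] <- -Inf
  }
  mx <- apply(S, 1L, max)
  dead <- !is.finite(mx)
  if (any(dead)) {
    warning("fully-masked attention row(s): output set to zero")
    mx[dead] <- 0
  }
  W <- exp(S - mx)
  W[!is.finite(W)] <- 0
  rs <- rowSums(W)
  W <- W / pmax(rs, .Machine$double.eps)
  W[dead, ] <- 0
  list(output = W %*% V, weights = W)
}

#' Multi-head attention
#'
#' Applies per-head query/key/value projections, runs scaled dot-product
#' attention per head, concatenates the head outputs and applies the output
#' projection. `Wq`, `Wk`, `Wv`, `Wo` are H x H with head `i` occupying the
#' i-th block of `H / n_heads` columns.
#'
#' @param Xq query-side input (n_q x H).
#' @param Xkv key/value-side input (n_k x H).
#' @param Wq,Wk,Wv,Wo projection matrices (H x H); `bo` output bias.
#' @param n_heads number of heads.
#' @param mask logical key mask.
#' @return list with `output` (n_q x H) and per-head `weights`.
#' @export
multi_head_attention <- function(Xq, Xkv, Wq, Wk, Wv, Wo, bo, n_heads,
                                 mask = NULL) {
  f <- .mha_forward(Xq, Xkv, Wq, Wk, Wv, Wo, bo, n_heads, mask,
                    dropout = 0, training = FALSE)
  list(output = f$out, weights = f$A)
}

## internal: full multi-head forward with cache for backprop
.mha_forward <- function(Xq, Xkv, Wq, Wk, Wv, Wo, bo, n_heads, mask,
                         dropout, training) {
  H <- ncol(Wq); dk <- H %/% n_heads
  Qc <- Xq %*% Wq; Kc <- Xkv %*% Wk; Vc <- Xkv %*% Wv
  nq <- nrow(Qc)
  masked <- !is.null(mask) && !all(mask)
  O <- matrix(0, nq, H)
  A <- vector("list", n_heads); D <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    S <- tcrossprod(Qc[, cols, drop = FALSE], Kc[, cols, drop = FALSE]) /
      sqrt(dk)
    if (masked) S[, !mask] <- -Inf
    mx <- S[cbind(seq_len(nq), max.col(S, ties.method = "first"))]
    dead <- !is.finite(mx)
    if (any(dead)) mx[dead] <- 0
    W <- exp(S - mx)
    if (masked) W[!is.finite(W)] <- 0
    W <- W / pmax(rowSums(W), .Machine$double.eps)
    if (any(dead)) W[dead, ] <- 0
    A[[h]] <- W
    if (training && dropout > 0) {
      Dm <- matrix((stats::runif(length(W)) >= dropout) / (1 - dropout),
                   nrow(W))
      D[[h]] <- Dm
      W <- W * Dm
    }
    O[, cols] <- W %*% Vc[, cols, drop = FALSE]
  }
  out <- .addrow(O %*% Wo, bo)
  list(out = out, A = A, D = D, Qc = Qc, Kc = Kc, Vc = Vc, O = O,
       Xq = Xq, Xkv = Xkv, mask = mask, n_heads = n_heads, dk = dk)
}

.mha_backward <- function(dOut, cache, Wq, Wk, Wv, Wo) {
  n_heads <- cache$n_heads; dk <- cache$dk
  g <- list(Wo = crossprod(cache$O, dOut), bo = colSums(dOut))
  dO <- dOut %*% t(Wo)
  dQc <- matrix(0, nrow(cache$Qc), ncol(cache$Qc))
  dKc <- matrix(0, nrow(cache$Kc), ncol(cache$Kc))
  dVc <- matrix(0, nrow(cache$Vc), ncol(cache$Vc))
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    Asoft <- cache$A[[h]]
    Adrop <- if (length(cache$D) && !is.null(cache$D[[h]]))
      Asoft * cache$D[[h]] else Asoft
    dOh <- dO[, cols, drop = FALSE]
    dVc[, cols] <- dVc[, cols] + crossprod(Adrop, dOh)
    dAdrop <- tcrossprod(dOh, cache$Vc[, cols, drop = FALSE])
    dAsoft <- if (length(cache$D) && !is.null(cache$D[[h]]))
      dAdrop * cache$D[[h]] else dAdrop
    dS <- Asoft * (dAsoft - rowSums(dAsoft * Asoft))
    dQc[, cols] <- dS %*% cache$Kc[, cols, drop = FALSE] / sqrt(dk)
    dKc[, cols] <- crossprod(dS, cache$Qc[, cols, drop = FALSE]) / sqrt(dk)
  }
  g$Wq <- crossprod(cache$Xq, dQc)
  g$Wk <- crossprod(cache$Xkv, dKc)
  g$Wv <- crossprod(cache$Xkv, dVc)
  g$dXq <- dQc %*% t(Wq)
  g$dXkv <- dKc %*% t(Wk) + dVc %*% t(Wv)
  g
}

.ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  n <- nrow(X)
  Y <- xhat * rep(g, each = n) + rep(b, each = n)
  list(Y = Y, xhat = xhat, inv = inv)
}

.ln_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxh <- dY * rep(g, each = nrow(dY))
  m1 <- rowMeans(dxh)
  m2 <- rowMeans(dxh * xhat)
  dX <- (dxh - m1 - xhat * m2) * cache$inv
  list(dX = dX, dg = dg, db = db)
}

.mask_rows <- function(X, m) { if (!all(m)) X[!m, ] <- 0; X }

#' Construct a promiscuity model
#'
#' Bundles the transformer parameters (fixup-initialized residual blocks,
#' layer norms, input projection, adapter head and softmax head) with the
#' frozen reaction encoder and the trained residue-embedding table, so a
#' model object scores raw (pair, sequence) inputs directly.
#'
#' @param cfg a [model_config()].
#' @param embed_table trained `embedding_table` (residue features).
#' @param encoder a `reaction_encoder` (frozen; default the built-in one
#'   sized to `cfg$d_pair`).
#' @param seed parameter seed.
#' @return list of class `promiscuity_model`.
#' @export
new_promiscuity_model <- function(cfg, embed_table, encoder = NULL,
                                  seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  if (is.null(encoder)) encoder <- fallback_reaction_encoder(cfg$d_pair)
  stopifnot(encoder$dim == cfg$d_pair)
  H <- cfg$hidden
  p <- list()
  withr::with_seed(child_seed(seed, "model-init"), {
    p$enz_proj_W <- matrix(stats::rnorm(cfg$d_enzyme * H, 0,
                                        1 / sqrt(cfg$d_enzyme)),
                           cfg$d_enzyme, H)
    p$enz_proj_b <- numeric(H)
    add_attn <- function(prefix) {
      p[[paste0(prefix, "_Wq")]] <<- fixup_init(H, H, 1L, 2L, H)
      p[[paste0(prefix, "_Wk")]] <<- fixup_init(H, H, 1L, 2L, H)
      p[[paste0(prefix, "_Wv")]] <<- fixup_init(H, H, 1L, 2L, H)
      p[[paste0(prefix, "_Wo")]] <<- fixup_init(H, H, 2L, 2L, H)
      p[[paste0(prefix, "_bo")]] <<- numeric(H)
    }
    add_ln <- function(prefix) {
      p[[paste0(prefix, "_g")]] <<- rep(1, H)
      p[[paste0(prefix, "_b")]] <<- numeric(H)
    }
    add_ff <- function(prefix) {
      p[[paste0(prefix, "1_m")]] <<- fixup_init(H, H, 1L, 2L, 3L * H)
      p[[paste0(prefix, "1_0")]] <<- fixup_init(H, H, 1L, 2L, 3L * H)
      p[[paste0(prefix, "1_p")]] <<- fixup_init(H, H, 1L, 2L, 3L * H)
      p[[paste0(prefix, "1_b")]] <<- numeric(H)
      p[[paste0(prefix, "2_m")]] <<- fixup_init(H, H, 2L, 2L, 3L * H)
      p[[paste0(prefix, "2_0")]] <<- fixup_init(H, H, 2L, 2L, 3L * H)
      p[[paste0(prefix, "2_p")]] <<- fixup_init(H, H, 2L, 2L, 3L * H)
      p[[paste0(prefix, "2_b")]] <<- numeric(H)
    }
    for (b in seq_len(cfg$n_layers)) {
      add_attn(sprintf("enc%d_att", b)); add_ln(sprintf("enc%d_ln1", b))
      add_ff(sprintf("enc%d_ff", b));   add_ln(sprintf("enc%d_ln2", b))
      add_attn(sprintf("dec%d_self", b)); add_ln(sprintf("dec%d_ln1", b))
      add_attn(sprintf("dec%d_cross", b)); add_ln(sprintf("dec%d_ln2", b))
      add_ff(sprintf("dec%d_ff", b));   add_ln(sprintf("dec%d_ln3", b))
    }
    p$head_W <- matrix(stats::rnorm(H * 2L, 0, 1 / sqrt(H)), H, 2L)
    p$head_b <- numeric(2L)
  })
  p <- c(p, new_adapter_head(cfg$d_pair, H, seed = seed))
  structure(list(cfg = cfg, params = p, encoder = encoder,
                 embed_table = embed_table),
            class = "promiscuity_model")
}

#' @export
print.promiscuity_model <- function(x, ...) {
  np <- sum(lengths(x$params))
  cat("<promiscuity_model> ", x$cfg$n_layers, "+", x$cfg$n_layers,
      " blocks, ", x$cfg$n_heads, " heads, H=", x$cfg$hidden,
      ", ", np, " trainable parameters\n", sep = "")
  invisible(x)
}

#' Names of all trainable parameter tensors
#' @param model a `promiscuity_model`.
#' @return Character vector of parameter names.
#' @export
param_names <- function(model) names(model$params)

## ---------------------------------------------------------------------------
## Forward / backward
## ---------------------------------------------------------------------------

## One residual attention sub-block: X + MHA -> LN -> mask
.attn_block_fwd <- function(X, Xkv, p, prefix, ln_name, n_heads, mask_q,
                            mask_kv, dropout, training) {
  f <- .mha_forward(X, Xkv, p[[paste0(prefix, "_Wq")]],
                    p[[paste0(prefix, "_Wk")]], p[[paste0(prefix, "_Wv")]],
                    p[[paste0(prefix, "_Wo")]], p[[paste0(prefix, "_bo")]],
                    n_heads, mask_kv, dropout, training)
  R <- X + f$out
  ln <- .ln_forward(R, p[[paste0(ln_name, "_g")]], p[[paste0(ln_name, "_b")]])
  Y <- .mask_rows(ln$Y, mask_q)
  list(Y = Y, mha = f, ln = ln, ln_name = ln_name, X = X)
}

.attn_block_bwd <- function(dY, cache, p, prefix, mask_q, grads) {
  dY <- .mask_rows(dY, cache$mask_q)
  lb <- .ln_backward(dY, cache$ln, p[[paste0(cache$ln_name, "_g")]])
  grads[[paste0(cache$ln_name, "_g")]] <-
    grads[[paste0(cache$ln_name, "_g")]] %+0% lb$dg
  grads[[paste0(cache$ln_name, "_b")]] <-
    grads[[paste0(cache$ln_name, "_b")]] %+0% lb$db
  mb <- .mha_backward(lb$dX, cache$mha, p[[paste0(prefix, "_Wq")]],
                      p[[paste0(prefix, "_Wk")]], p[[paste0(prefix, "_Wv")]],
                      p[[paste0(prefix, "_Wo")]])
  for (nm in c("Wq", "Wk", "Wv", "Wo", "bo")) {
    key <- paste0(prefix, "_", nm)
    grads[[key]] <- grads[[key]] %+0% mb[[nm]]
  }
  list(dX = lb$dX + mb$dXq, dXkv = mb$dXkv, grads = grads)
}

`%+0%` <- function(a, b) if (is.null(a)) b else a + b

## One residual conv feed-forward sub-block
.ff_block_fwd <- function(X, p, prefix, ln_name, mask_q, dropout, training) {
  c1 <- conv3_forward(X, p[[paste0(prefix, "1_m")]], p[[paste0(prefix, "1_0")]],
                      p[[paste0(prefix, "1_p")]], p[[paste0(prefix, "1_b")]])
  g1 <- .gelu_fwd(c1$Y)
  A1 <- .mask_rows(g1$Y, mask_q)   # keep the conv boundary exactly zero
  c2 <- conv3_forward(A1, p[[paste0(prefix, "2_m")]], p[[paste0(prefix, "2_0")]],
                      p[[paste0(prefix, "2_p")]], p[[paste0(prefix, "2_b")]])
  F2 <- c2$Y
  Dm <- NULL
  if (training && dropout > 0) {
    Dm <- matrix((stats::runif(length(F2)) >= dropout) / (1 - dropout),
                 nrow(F2))
    F2 <- F2 * Dm
  }
  R <- X + F2
  ln <- .ln_forward(R, p[[paste0(ln_name, "_g")]], p[[paste0(ln_name, "_b")]])
  Y <- .mask_rows(ln$Y, mask_q)
  list(Y = Y, c1 = c1, P1 = g1$P, A1 = A1, c2 = c2, Dm = Dm, ln = ln, X = X,
       ln_name = ln_name)
}

.ff_block_bwd <- function(dY, cache, p, prefix, mask_q, grads) {
  dY <- .mask_rows(dY, cache$mask_q)
  lb <- .ln_backward(dY, cache$ln, p[[paste0(cache$ln_name, "_g")]])
  grads[[paste0(cache$ln_name, "_g")]] <-
    grads[[paste0(cache$ln_name, "_g")]] %+0% lb$dg
  grads[[paste0(cache$ln_name, "_b")]] <-
    grads[[paste0(cache$ln_name, "_b")]] %+0% lb$db
  dF2 <- lb$dX
  if (!is.null(cache$Dm)) dF2 <- dF2 * cache$Dm
  b2 <- conv3_backward(dF2, cache$A1, cache$c2$Xm, cache$c2$Xp,
                       p[[paste0(prefix, "2_m")]], p[[paste0(prefix, "2_0")]],
                       p[[paste0(prefix, "2_p")]])
  for (s in c("m", "0", "p")) {
    key <- paste0(prefix, "2_", s)
    grads[[key]] <- grads[[key]] %+0% b2[[paste0("dW", s)]]
  }
  grads[[paste0(prefix, "2_b")]] <- grads[[paste0(prefix, "2_b")]] %+0% b2$db
  d1 <- .mask_rows(.gelu_bwd(b2$dX, cache$c1$Y, cache$P1), cache$mask_q)
  b1 <- conv3_backward(d1, cache$X, cache$c1$Xm, cache$c1$Xp,
                       p[[paste0(prefix, "1_m")]], p[[paste0(prefix, "1_0")]],
                       p[[paste0(prefix, "1_p")]])
  for (s in c("m", "0", "p")) {
    key <- paste0(prefix, "1_", s)
    grads[[key]] <- grads[[key]] %+0% b1[[paste0("dW", s)]]
  }
  grads[[paste0(prefix, "1_b")]] <- grads[[paste0(prefix, "1_b")]] %+0% b1$db
  list(dX = lb$dX + b1$dX, grads = grads)
}

## Full forward pass for one (pair, enzyme) example.
## B: frozen T x D base pair encoding; E: L x d_enzyme residue features.
## enz_len / pair_len: number of valid (non-padding) rows.
.forward_example <- function(model, B, E, enz_len = nrow(E),
                             pair_len = nrow(B), training = FALSE,
                             collect_attn = FALSE) {
  cfg <- model$cfg; p <- model$params
  if (enz_len > cfg$max_enzyme_len)
    stop("enzyme length ", enz_len, " exceeds max_enzyme_len (",
         cfg$max_enzyme_len, "); truncate or raise max_enzyme_len")
  drp <- if (training) cfg$dropout else 0
  mE <- seq_len(nrow(E)) <= enz_len
  mP <- seq_len(nrow(B)) <= pair_len
  E <- .mask_rows(E, mE); B <- .mask_rows(B, mP)

  ad <- adapter_forward(B, p, mask = mP)
  P0 <- .mask_rows(ad$Y, mP)
  X <- .mask_rows(.addrow(E %*% p$enz_proj_W, p$enz_proj_b), mE)

  cache <- list(E = E, B = B, mE = mE, mP = mP, ad = ad, enc = list(),
                dec = list(), training = training)
  attn <- if (collect_attn)
    list(encoder_self = list(), decoder_self = list(), cross = list()) else NULL

  for (b in seq_len(cfg$n_layers)) {
    a <- .attn_block_fwd(X, X, p, sprintf("enc%d_att", b),
                         sprintf("enc%d_ln1", b), cfg$n_heads,
                         mE, mE, drp, training)
    a$mask_q <- mE
    f <- .ff_block_fwd(a$Y, p, sprintf("enc%d_ff", b), sprintf("enc%d_ln2", b),
                       mE, drp, training)
    f$mask_q <- mE
    cache$enc[[b]] <- list(a = a, f = f)
    if (collect_attn) attn$encoder_self[[b]] <- a$mha$A
    X <- f$Y
  }
  Xenc <- X

  Y <- P0
  for (b in seq_len(cfg$n_layers)) {
    s <- .attn_block_fwd(Y, Y, p, sprintf("dec%d_self", b),
                         sprintf("dec%d_ln1", b), cfg$n_heads,
                         mP, mP, drp, training)
    s$mask_q <- mP
    cr <- .attn_block_fwd(s$Y, Xenc, p, sprintf("dec%d_cross", b),
                          sprintf("dec%d_ln2", b), cfg$n_heads,
                          mP, mE, drp, training)
    cr$mask_q <- mP
    f <- .ff_block_fwd(cr$Y, p, sprintf("dec%d_ff", b), sprintf("dec%d_ln3", b),
                       mP, drp, training)
    f$mask_q <- mP
    cache$dec[[b]] <- list(s = s, cr = cr, f = f)
    if (collect_attn) {
      attn$decoder_self[[b]] <- s$mha$A
      attn$cross[[b]] <- cr$mha$A
    }
    Y <- f$Y
  }

  pooled <- colSums(Y[mP, , drop = FALSE]) / sum(mP)
  z <- drop(pooled %*% p$head_W) + p$head_b
  z <- z - max(z)
  pr <- exp(z) / sum(exp(z))
  cache$Xenc <- Xenc; cache$Ydec <- Y; cache$pooled <- pooled; cache$pr <- pr
  list(p = pr[2L], cache = cache, attn = attn)
}

## Backward pass: dp = dLoss/dscore (scalar). Returns named gradient list.
.backward_example <- function(model, cache, dp) {
  cfg <- model$cfg; p <- model$params
  grads <- list()
  pr <- cache$pr
  # score = pr[2]; dz through 2-way softmax
  dz <- c(-pr[1] * pr[2], pr[2] * (1 - pr[2])) * dp
  grads$head_W <- outer(cache$pooled, dz)
  grads$head_b <- dz
  dpooled <- drop(p$head_W %*% dz)
  mP <- cache$mP; mE <- cache$mE
  dY <- matrix(0, length(mP), cfg$hidden)
  dY[mP, ] <- rep(dpooled / sum(mP), each = sum(mP))

  for (b in rev(seq_len(cfg$n_layers))) {
    blk <- cache$dec[[b]]
    fb <- .ff_block_bwd(dY, blk$f, p, sprintf("dec%d_ff", b), mP, grads)
    grads <- fb$grads
    cb <- .attn_block_bwd(fb$dX, blk$cr, p, sprintf("dec%d_cross", b), mP, grads)
    grads <- cb$grads
    grads$dXenc <- grads$dXenc %+0% cb$dXkv
    sb <- .attn_block_bwd(cb$dX, blk$s, p, sprintf("dec%d_self", b), mP, grads)
    grads <- sb$grads
    dY <- sb$dX + sb$dXkv
  }
  dP0 <- .mask_rows(dY, mP)

  dX <- grads$dXenc %+0% matrix(0, length(mE), cfg$hidden)
  grads$dXenc <- NULL
  for (b in rev(seq_len(cfg$n_layers))) {
    blk <- cache$enc[[b]]
    fb <- .ff_block_bwd(dX, blk$f, p, sprintf("enc%d_ff", b), mE, grads)
    grads <- fb$grads
    ab <- .attn_block_bwd(fb$dX, blk$a, p, sprintf("enc%d_att", b), mE, grads)
    grads <- ab$grads
    dX <- ab$dX + ab$dXkv
  }
  dX <- .mask_rows(dX, mE)
  grads$enz_proj_W <- crossprod(cache$E, dX)
  grads$enz_proj_b <- colSums(dX)

  ga <- adapter_backward(dP0, cache$ad$cache, p)
  for (nm in names(ga)) grads[[nm]] <- grads[[nm]] %+0% ga[[nm]]
  grads
}

#' Score one (pair, enzyme) combination
#'
#' Deterministic in evaluation mode (no dropout). Features are computed from
#' the model's own embedding table and frozen reaction encoder.
#'
#' @param model a `promiscuity_model`.
#' @param substrate_smiles,product_smiles the substrate-product pair.
#' @param sequence enzyme amino-acid sequence.
#' @return Probability of catalysis in \[0, 1\].
#' @export
score_triad <- function(model, substrate_smiles, product_smiles, sequence) {
  rs <- pair_to_reaction_smiles(substrate_smiles, product_smiles)
  B <- encode_pair_base(rs, model$encoder)
  E <- embed_enzyme(sequence, model$embed_table)
  .forward_example(model, B, E)$p
}

#' Score many triads (vectorized over rows)
#'
#' @param model a `promiscuity_model`.
#' @param triads triads data.frame.
#' @param enzymes enzyme data.frame (id -> sequence).
#' @return Numeric score vector aligned with `triads` rows.
#' @export
score_triads <- function(model, triads, enzymes) {
  seq_of <- stats::setNames(enzymes$sequence, enzymes$enzyme_id)
  vapply(seq_len(nrow(triads)), function(i) {
    score_triad(model, triads$substrate_smiles[i], triads$product_smiles[i],
                seq_of[[triads$enzyme_id[i]]])
  }, numeric(1))
}

#' Extract attention maps and per-residue importance
#'
#' Runs one deterministic forward pass collecting every attention weight
#' matrix (encoder self, decoder self, cross) for every layer and head, and
#' summarizes cross-attention into a per-residue importance vector: cross
#' weights averaged over layers, heads and pair positions. Padded residues
#' receive exactly zero importance.
#'
#' @param model a `promiscuity_model`.
#' @param substrate_smiles,product_smiles the pair.
#' @param sequence enzyme sequence.
#' @return list: `score`, `encoder_self`, `decoder_self`, `cross`
#'   (layer -> head -> matrix), `residue_importance` (length L).
#' @export
attention_map <- function(model, substrate_smiles, product_smiles, sequence) {
  rs <- pair_to_reaction_smiles(substrate_smiles, product_smiles)
  B <- encode_pair_base(rs, model$encoder)
  E <- embed_enzyme(sequence, model$embed_table)
  f <- .forward_example(model, B, E, collect_attn = TRUE)
  cross <- f$attn$cross
  imp <- Reduce(`+`, lapply(cross, function(heads)
    Reduce(`+`, lapply(heads, colMeans)) / length(heads))) / length(cross)
  list(score = f$p, encoder_self = f$attn$encoder_self,
       decoder_self = f$attn$decoder_self, cross = cross,
       residue_importance = imp)
}

#' Save / load a model checkpoint
#'
#' Versioned checkpoint: binary weights via `saveRDS` plus a JSON config
#' sidecar; reload is deterministic.
#'
#' @param model a `promiscuity_model`.
#' @param dir checkpoint directory.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(c(unclass(model$cfg), list(format_version = 1L)),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) readRDS(file.path(dir, "model.rds"))
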