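# Transformer model: attention oracles, fixup moments, masking, gradients.

test_that("fixup init has the prescribed std in all three positions", {
  n_l <- 64L
  for (case in list(list(l = 1L, sigma = sqrt(2)),
                    list(l = 2L, sigma = 1),
                    list(l = 3L, sigma = sqrt(0.5)))) {
    W <- fixup_init(500L, 200L, case$l, 3L, n_l, seed = 11L)
    expect_equal(stats::sd(W), case$sigma / sqrt(n_l), tolerance = 0.02)
    expect_lt(abs(mean(W)), 0.002)
  }
  # first/last sigma ratio is exactly 2 by algebra
  expect_equal(sqrt(2) / sqrt(0.5), 2)
  expect_identical(fixup_init(4L, 4L, 1L, 2L, 8L, seed = 3L),
                   fixup_init(4L, 4L, 1L, 2L, 8L, seed = 3L))
  expect_error(fixup_init(4L, 4L, 3L, 2L, 8L), "l_r")
})

test_that("scaled dot-product attention matches a loop-based softmax oracle", {
  withr::with_seed(21L, {
    for (rep in 1:5) {
      Q <- matrix(rnorm(12), 3L, 4L)
      K <- matrix(rnorm(20), 5L, 4L)
      V <- matrix(rnorm(10), 5L, 2L)
      got <- scaled_dot_attention(Q, K, V)
      W_oracle <- matrix(0, 3L, 5L)
      for (i in 1:3) {
        e <- numeric(5L)
        for (j in 1:5) e[j] <- exp(sum(Q[i, ] * K[j, ]) / sqrt(4))
        W_oracle[i, ] <- e / sum(e)
      }
      expect_equal(got$weights, W_oracle, tolerance = 1e-6)
      expect_equal(got$output, W_oracle %*% V, tolerance = 1e-6)
    }
  })
})

test_that("attention limits: uniform under equal logits, identity at scale", {
  # all-equal QK^T: uniform 1/n rows
  Q <- matrix(0, 3L, 4L); K <- matrix(0, 6L, 4L); V <- diag(6L)
  got <- scaled_dot_attention(Q, K, V)
  expect_equal(got$weights, matrix(1 / 6, 3L, 6L))
  # Q = K orthonormal at large scale: weights approach identity
  Qs <- diag(4L) * 50
  got2 <- scaled_dot_attention(Qs, Qs, diag(4L))
  expect_equal(got2$weights, diag(4L), tolerance = 1e-6)
  # masked keys receive exactly zero weight
  got3 <- scaled_dot_attention(matrix(rnorm(8), 2L, 4L),
                               matrix(rnorm(16), 4L, 4L),
                               matrix(rnorm(8), 4L, 2L),
                               mask = c(TRUE, TRUE, FALSE, TRUE))
  expect_true(all(got3$weights[, 3L] == 0))
  expect_equal(rowSums(got3$weights), c(1, 1))
  # fully-masked rows yield zero output with a warning
  expect_warning(
    got4 <- scaled_dot_attention(matrix(1, 2L, 2L), matrix(1, 3L, 2L),
                                 matrix(1, 3L, 2L), mask = rep(FALSE, 3L)),
    "fully-masked")
  expect_true(all(got4$output == 0))
})

test_that("multi-head attention reduces to single-head and composes per head", {
  H <- 6L
  X <- matrix(rnorm(4L * H), 4L, H)
  I <- diag(H)
  one <- multi_head_attention(X, X, I, I, I, I, numeric(H), n_heads = 1L)
  ref <- scaled_dot_attention(X, X, X)
  expect_equal(one$output, ref$output, tolerance = 1e-10)
  # 2-head output equals manual concatenation of per-head attention calls
  withr::with_seed(31L, {
    Wq <- matrix(rnorm(H * H), H); Wk <- matrix(rnorm(H * H), H)
    Wv <- matrix(rnorm(H * H), H); Wo <- matrix(rnorm(H * H), H)
  })
  bo <- rnorm(H)
  two <- multi_head_attention(X, X, Wq, Wk, Wv, Wo, bo, n_heads = 2L)
  Qc <- X %*% Wq; Kc <- X %*% Wk; Vc <- X %*% Wv
  manual <- cbind(
    scaled_dot_attention(Qc[, 1:3], Kc[, 1:3], Vc[, 1:3])$output,
    scaled_dot_attention(Qc[, 4:6], Kc[, 4:6], Vc[, 4:6])$output)
  expect_equal(two$output,
               manual %*% Wo + matrix(bo, 4L, H, byrow = TRUE),
               tolerance = 1e-6)
  expect_equal(dim(two$output), c(4L, H))
})

test_that("no parameter tensor is a positional encoding", {
  m <- fixture_tiny_model()
  expect_false(any(grepl("pos", param_names(m), ignore.case = TRUE)))
  # every parameter participates in a documented block
  expect_true(all(grepl("^(enc|dec|head|enz_proj|ad_)", param_names(m))))
})

test_that("scores are probabilities, deterministic in eval mode", {
  m <- fixture_tiny_model()
  p <- score_triad(m, "CCO", "CC=O", "ACDEFGHIKLMNPQRSTVWY")
  expect_gte(p, 0); expect_lte(p, 1)
  expect_identical(p, score_triad(m, "CCO", "CC=O", "ACDEFGHIKLMNPQRSTVWY"))
  expect_error(score_triad(m, "CCO", "CC=O", strrep("A", 61L)),
               "max_enzyme_len")
})

test_that("scores are invariant to trailing padding on either stream", {
  m <- fixture_tiny_model()
  withr::with_seed(5L, {
    B <- matrix(rnorm(7L * 6L), 7L, 6L)
    E <- matrix(rnorm(11L * 10L), 11L, 10L)
    padE <- matrix(rnorm(4L * 10L), 4L, 10L)
    padB <- matrix(rnorm(3L * 6L), 3L, 6L)
  })
  base <- pairzyme:::.forward_example(m, B, E)$p
  pE <- pairzyme:::.forward_example(m, B, rbind(E, padE), enz_len = 11L)$p
  pB <- pairzyme:::.forward_example(m, rbind(B, padB), E, pair_len = 7L)$p
  expect_identical(base, pE)
  expect_identical(base, pB)
  # permuting values in the padded region changes nothing
  pE2 <- pairzyme:::.forward_example(m, B, rbind(E, padE[c(3, 1, 4, 2), ]),
                                     enz_len = 11L)$p
  expect_identical(base, pE2)
})

test_that("analytic gradients match finite differences", {
  m <- fixture_tiny_model()
  withr::with_seed(8L, {
    B <- matrix(rnorm(4L * 6L), 4L, 6L)
    E <- matrix(rnorm(6L * 10L), 6L, 10L)
  })
  y <- 1
  lossfn <- function(mm)
    smoothed_bce_loss(pairzyme:::.forward_example(mm, B, E)$p, y, eps = 0.1)
  fw <- pairzyme:::.forward_example(m, B, E)
  dp <- pairzyme:::.smoothed_bce_grad(fw$p, y, 0.1, "standard")
  g <- pairzyme:::.backward_example(m, fw$cache, dp)
  h <- 1e-5
  withr::with_seed(17L, {
    for (nm in sample(names(m$params), 12L)) {
      ix <- sample(length(m$params[[nm]]), 1L)
      m2 <- m; m2$params[[nm]][ix] <- m2$params[[nm]][ix] + h
      m3 <- m; m3$params[[nm]][ix] <- m3$params[[nm]][ix] - h
      fd <- (lossfn(m2) - lossfn(m3)) / (2 * h)
      expect_equal(g[[nm]][ix], fd, tolerance = 1e-4,
                   info = paste("param", nm, "index", ix))
    }
  })
})

test_that("attention maps are normalized and ignore padded residues", {
  m <- fixture_tiny_model()
  seq <- "ACDEFGHIKLMNPQR"
  am <- attention_map(m, "CCO", "CC=O", seq)
  expect_length(am$residue_importance, nchar(seq))
  for (lyr in am$encoder_self) for (head in lyr)
    expect_equal(rowSums(head), rep(1, nrow(head)), tolerance = 1e-6)
  for (lyr in am$cross) for (head in lyr)
    expect_equal(rowSums(head), rep(1, nrow(head)), tolerance = 1e-6)
  # cross-attention over a padded enzyme gives exactly zero importance there
  E <- embed_enzyme(seq, m$embed_table)
  B <- pairzyme:::encode_pair_base(pair_to_reaction_smiles("CCO", "CC=O"),
                                   m$encoder)
  f <- pairzyme:::.forward_example(m, B, rbind(E, matrix(1, 5L, 10L)),
                                   enz_len = nchar(seq), collect_attn = TRUE)
  cross_pad <- do.call(rbind, lapply(f$attn$cross, function(hh)
    do.call(rbind, lapply(hh, function(W) W[, (nchar(seq) + 1L):(nchar(seq) + 5L)]))))
  expect_true(all(cross_pad == 0))
})

test_that("a small model can overfit one repeated batch", {
  tab <- cbow_init(dim = 20L, seed = 6L)
  cfg <- model_config(n_layers = 2L, n_heads = 2L, hidden = 32L, dropout = 0,
                      d_enzyme = 20L, d_pair = 16L)
  m <- new_promiscuity_model(cfg, tab, fallback_reaction_encoder(16L), seed = 9L)
  withr::with_seed(10L, {
    seqs <- vapply(1:6, function(i) random_aa(25L), character(1))
  })
  tri <- data.frame(
    triad_id = sprintf("t%d", 1:6), reaction_id = "r",
    substrate_smiles = "CCO", product_smiles = "CC=O",
    enzyme_id = sprintf("e%d", 1:6),
    label = rep(c("positive", "unlabeled"), each = 3L),
    stringsAsFactors = FALSE)
  enz <- data.frame(enzyme_id = sprintf("e%d", 1:6), sequence = seqs,
                    stringsAsFactors = FALSE)
  seq_of <- stats::setNames(enz$sequence, enz$enzyme_id)
  y <- as.numeric(tri$label == "positive")
  Bs <- lapply(seq_len(6L), function(i)
    pairzyme:::encode_pair_base("CCO>>CC=O", m$encoder))
  Es <- lapply(seq_len(6L), function(i)
    embed_enzyme(seq_of[[tri$enzyme_id[i]]], m$embed_table))
  opt <- pairzyme:::.opt_init(m$params)
  tcfg <- train_config(lr = 3e-3, label_smoothing = 0, weight_decay = 0,
                       seed = 1L)
  loss <- NA
  for (step in 1:200) {
    ps <- numeric(6L); caches <- vector("list", 6L)
    for (i in 1:6) {
      fw <- pairzyme:::.forward_example(m, Bs[[i]], Es[[i]])
      ps[i] <- fw$p; caches[[i]] <- fw$cache
    }
    loss <- smoothed_bce_loss(ps, y, eps = 0)
    if (loss < 0.05) break
    dps <- pairzyme:::.smoothed_bce_grad(ps, y, 0, "standard")
    gsum <- list()
    for (i in 1:6) {
      g <- pairzyme:::.backward_example(m, caches[[i]], dps[i])
      for (nm in names(g)) gsum[[nm]] <-
          if (is.null(gsum[[nm]])) g[[nm]] else gsum[[nm]] + g[[nm]]
    }
    st <- pairzyme:::.opt_step(m$params, gsum, opt, tcfg)
    m$params <- st$params; opt <- st$state
  }
  expect_lt(loss, 0.1)
})

test_that("checkpoints reload to bit-identical scores", {
  m <- fixture_tiny_model()
  dir <- withr::local_tempdir()
  save_checkpoint(m, dir)
  m2 <- load_checkpoint(dir)
  expect_identical(score_triad(m, "CCO", "CC=O", "ACDEFGHIKL"),
                   score_triad(m2, "CCO", "CC=O", "ACDEFGHIKL"))
  expect_true(file.exists(file.path(dir, "config.json")))
})
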