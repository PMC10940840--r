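# Shared fixtures, memoized per test session. Everything is generated in
# code; heavy artifacts (the trained desk-scale model) are built once and
# reused across the tests that need them.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, builder) {
  hit <- get0(key, envir = .fixture_env, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  val <- builder()
  assign(key, val, envir = .fixture_env)
  val
}

# Small synthetic dataset: fast to generate, used by dataset-level tests.
fixture_dataset <- function() memo_fixture("ds_small", function() {
  suppressWarnings(gen_triad_dataset(synthetic_spec(seed = 101L)))
})

# Tiny model for plumbing tests (shape, masking, maps); not trained.
fixture_tiny_model <- function() memo_fixture("tiny_model", function() {
  cfg <- model_config(n_layers = 1L, n_heads = 2L, hidden = 8L, dropout = 0,
                      max_enzyme_len = 60L, d_enzyme = 10L, d_pair = 6L)
  tab <- cbow_init(dim = 10L, seed = 3L)
  enc <- fallback_reaction_encoder(dim = 6L)
  new_promiscuity_model(cfg, tab, enc, seed = 7L)
})

random_aa <- function(n, seed = NULL) {
  gen <- function() paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                 n, replace = TRUE), collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Independent global-alignment identity oracle (Gotoh affine-gap DP),
# written against the scoring convention gap cost = open + len * extend.
nw_identity_oracle <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -gap_open - gap_ext * i
  for (j in seq_len(m)) Iy[1, j + 1] <- -gap_open - gap_ext * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- S[x[i], y[j]]
    M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                            Ix[i, j + 1] - gap_ext)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                            Iy[i + 1, j] - gap_ext)
  }
  # traceback for identity count and alignment length
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1]))
  matches <- 0L; alen <- 0L
  tol <- 1e-9
  while (i > 0 || j > 0) {
    alen <- alen + 1L
    if (state == 1L) {
      if (x[i] == y[j]) matches <- matches + 1L
      prev <- c(M[i, j], Ix[i, j], Iy[i, j])
      state <- which.max(prev)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      from_m <- abs(Ix[i + 1, j + 1] - (M[i, j + 1] - gap_open - gap_ext)) < tol
      state <- if (from_m) 1L else 2L
      i <- i - 1L
    } else {
      from_m <- abs(Iy[i + 1, j + 1] - (M[i + 1, j] - gap_open - gap_ext)) < tol
      state <- if (from_m) 1L else 3L
      j <- j - 1L
    }
    if (i == 0 && j > 0 && state == 1L) state <- 3L
    if (j == 0 && i > 0 && state == 1L) state <- 2L
  }
  100 * matches / alen
}
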