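# Metrics and screening applications.

test_that("ROC-AUC hits its closed-form limits and the pair-counting oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 10L), rep(c(1, 0), 5L)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  withr::with_seed(41L, {
    for (rep in 1:5) {
      s <- round(runif(20L), 2L)   # rounding forces ties
      y <- rbinom(20L, 1L, 0.4)
      if (sum(y) == 0L || sum(y) == 20L) next
      pos <- s[y == 1]; neg <- s[y == 0]
      wins <- 0
      for (a in pos) for (b in neg)
        wins <- wins + (a > b) + 0.5 * (a == b)
      expect_equal(roc_auc(s, y), wins / (length(pos) * length(neg)),
                   tolerance = 1e-12)
    }
  })
  # invariance under strictly monotone transforms
  withr::with_seed(43L, { s <- runif(30L); y <- rbinom(30L, 1L, 0.5) })
  expect_equal(roc_auc(s, y), roc_auc(qlogis(s), y), tolerance = 1e-12)
  expect_equal(roc_auc(s, y), roc_auc(s^3, y), tolerance = 1e-12)
  # agreement with an independent library implementation
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("PRC-AUC matches a threshold-sweep oracle and known limits", {
  expect_equal(prc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_error(prc_auc(1:3, c(0, 0, 0)), "positive")
  prc_oracle <- function(s, y) {
    ths <- sort(unique(s), decreasing = TRUE)
    rec <- 0; area <- 0
    for (t in ths) {
      tp <- sum(y == 1 & s >= t); fp <- sum(y == 0 & s >= t)
      r <- tp / sum(y == 1); p <- tp / (tp + fp)
      area <- area + (r - rec) * p
      rec <- r
    }
    area
  }
  withr::with_seed(47L, {
    for (rep in 1:6) {
      s <- round(runif(15L), 1L)
      y <- rbinom(15L, 1L, 0.5)
      if (sum(y) == 0L) next
      expect_equal(prc_auc(s, y), prc_oracle(s, y), tolerance = 1e-12)
    }
  })
  # uniform random scores: PRC-AUC concentrates near prevalence
  withr::with_seed(53L, {
    vals <- replicate(30L, {
      s <- runif(400L); y <- rbinom(400L, 1L, 0.25)
      prc_auc(s, y)
    })
  })
  expect_lt(abs(mean(vals) - 0.25), 0.02)
})

test_that("evaluate_triads is internally consistent with the metric functions", {
  ds <- fixture_dataset()
  m <- memo_fixture("purge_model", function() {
    tab <- cbow_init(dim = 12L, seed = 5L)
    cfg <- model_config(n_layers = 1L, n_heads = 2L, hidden = 8L, dropout = 0,
                        d_enzyme = 12L, d_pair = 8L)
    new_promiscuity_model(cfg, tab, fallback_reaction_encoder(8L), seed = 2L)
  })
  tri <- ds$triads[c(which(ds$triads$label == "positive")[1:8],
                     which(ds$triads$label == "unlabeled")[1:8]), ]
  rep <- evaluate_triads(m, tri, ds$enzymes)
  expect_equal(rep$tp + rep$fn, 8L)
  expect_equal(rep$tn + rep$fp, 8L)
  expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, rep$n)
  y <- tri$label == "positive"
  expect_equal(rep$roc_auc, roc_auc(rep$scores, y))
  expect_equal(rep$prc_auc, prc_auc(rep$scores, y))
  expect_equal(rep$accuracy, mean((rep$scores > 0.5) == y))
})

test_that("screening ranks are a deterministic permutation with stable ties", {
  m <- fixture_tiny_model()
  withr::with_seed(61L, {
    lib <- data.frame(enzyme_id = sprintf("z%02d", 1:10),
                      sequence = vapply(1:10, function(i) random_aa(20L),
                                        character(1)),
                      stringsAsFactors = FALSE)
  })
  out <- screen_enzymes(m, "CCO", "CC=O", lib)
  expect_setequal(out$rank, 1:10)
  expect_true(all(diff(out$score) <= 0))
  expect_equal(out$relative_rank, out$rank / 10)
  # duplicated sequence: equal scores, adjacent ranks, id-ordered
  lib2 <- rbind(lib[1:3, ],
                data.frame(enzyme_id = c("dupA", "dupB"),
                           sequence = lib$sequence[1]))
  out2 <- screen_enzymes(m, "CCO", "CC=O", lib2)
  rd <- out2$rank[out2$enzyme_id %in% c("dupA", "dupB")]
  expect_equal(sort(diff(sort(rd))), 1L)
  expect_equal(out2$score[match("dupA", out2$enzyme_id)],
               out2$score[match("dupB", out2$enzyme_id)])
  # over-length enzymes are skipped with a warning
  lib3 <- rbind(lib, data.frame(enzyme_id = "long",
                                sequence = strrep("A", 100L)))
  expect_warning(out3 <- screen_enzymes(m, "CCO", "CC=O", lib3), "over-length")
  expect_false("long" %in% out3$enzyme_id)
  expect_equal(attr(out3, "skipped"), "long")
})

test_that("multi-pair screening is an intersection with min-score ranking", {
  m <- fixture_tiny_model()
  withr::with_seed(67L, {
    lib <- data.frame(enzyme_id = sprintf("z%02d", 1:8),
                      sequence = vapply(1:8, function(i) random_aa(20L),
                                        character(1)),
                      stringsAsFactors = FALSE)
  })
  pairs1 <- data.frame(substrate_smiles = "CCO", product_smiles = "CC=O",
                       stringsAsFactors = FALSE)
  pairs2 <- rbind(pairs1,
                  data.frame(substrate_smiles = "CCCO",
                             product_smiles = "CCC=O"))
  pairs3 <- rbind(pairs2,
                  data.frame(substrate_smiles = "CCCCO",
                             product_smiles = "CCCC=O"))
  th <- 0.45   # untrained scores hover near 0.5: both sides populated
  r1 <- multi_pair_screen(m, pairs1, lib, threshold = th)
  r2 <- multi_pair_screen(m, pairs2, lib, threshold = th)
  r3 <- multi_pair_screen(m, pairs3, lib, threshold = th)
  # single pair reduces to a thresholded screen
  single <- screen_enzymes(m, "CCO", "CC=O", lib)
  expect_setequal(r1$shortlist$enzyme_id,
                  single$enzyme_id[single$score > th])
  # intersection monotonicity: shortlist never grows with more pairs
  expect_true(all(r2$shortlist$enzyme_id %in% r1$shortlist$enzyme_id))
  expect_true(all(r3$shortlist$enzyme_id %in% r2$shortlist$enzyme_id))
  # survivor rule: min score over pairs exceeds the threshold
  expect_true(all(r2$shortlist$min_score > th))
  M <- r2$score_matrix
  excluded <- setdiff(rownames(M), r2$shortlist$enzyme_id)
  expect_true(all(apply(M[excluded, , drop = FALSE], 1L, min) <= th))
  # an enzyme above threshold on one pair but not another is excluded
  if (length(excluded))
    expect_true(any(M[excluded[1], ] > th) || all(M[excluded[1], ] <= th))
})

test_that("rank reports locate the target and count positive calls", {
  ranked <- data.frame(enzyme_id = c("a", "b", "c", "d"),
                       score = c(0.9, 0.7, 0.4, 0.2),
                       rank = 1:4, relative_rank = (1:4) / 4,
                       stringsAsFactors = FALSE)
  r <- rank_of("a", ranked)
  expect_equal(r$rank, 1L)
  expect_equal(r$relative_rank, 0.25)
  expect_equal(r$positive_count, 2L)
  expect_equal(rank_of("d", ranked)$relative_rank, 1)
  expect_error(rank_of("zz", ranked), "not present")
  # all scores below threshold: zero positive calls
  ranked$score <- rep(0.3, 4L)
  expect_equal(rank_of("a", ranked)$positive_count, 0L)
  # recount oracle
  expect_equal(rank_of("b", ranked, threshold = 0.25)$positive_count,
               sum(ranked$score > 0.25))
})
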