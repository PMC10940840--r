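# Atom-mapped reaction parsing, provenance and pair extraction/filtering.

test_that("well-formed mapped reactions round-trip with maps preserved", {
  rxn <- parse_mapped_reaction("[CH3:1][CH2:2][OH:3]>>[CH3:1][CH:2]=[O:3]",
                               "r1", "1.1.1.1")
  expect_length(rxn$substrates, 1L)
  expect_length(rxn$products, 1L)
  expect_equal(rxn$substrates[[1]]$atoms$map, 1:3)
  expect_equal(rxn$products[[1]]$atoms$map, 1:3)
  expect_equal(sum(rxn$substrates[[1]]$atoms$heavy), 3L)
  expect_equal(rxn$ec_numbers, "1.1.1.1")
})

test_that("duplicate map numbers within one side are rejected", {
  expect_error(parse_mapped_reaction("[CH3:1][OH:2].[CH3:1]O>>C", "dup"),
               "duplicated among substrate")
  expect_error(parse_mapped_reaction("CCO>>[CH3:4][CH:4]=O", "dup2"),
               "duplicated among product")
})

test_that("malformed molecules and agent fields are handled", {
  expect_error(parse_mapped_reaction("C1CC>>CC", "bad"), "malformed")
  expect_error(parse_mapped_reaction("CCO>CC=O", "onearrow"), "'>' fields")
  expect_warning(parse_mapped_reaction("[CH3:1][OH:2]>O>[CH3:1][OH:2]", "ag"),
                 "agent")
})

test_that("a 3-substrate, 2-product reaction parses with both sides intact", {
  line <- paste0("[CH3:1][OH:2].[CH3:3][OH:4].[CH3:5][CH2:6][OH:7]>>",
                 "[CH3:1][O:2][CH3:3].[CH3:5][CH2:6][O:7][OH:4]")
  rxn <- parse_mapped_reaction(line, "multi")
  expect_length(rxn$substrates, 3L)
  expect_length(rxn$products, 2L)
  smaps <- sort(unlist(lapply(rxn$substrates, function(m) m$atoms$map)))
  pmaps <- sort(unlist(lapply(rxn$products, function(m) m$atoms$map)))
  expect_equal(smaps[smaps > 0], pmaps[pmaps > 0])
})

test_that("multi-molecule fixture reactions parse with conserved map multisets", {
  rxns <- gen_mapped_reactions(synthetic_spec(seed = 7L))
  expect_gte(length(rxns), 12L)
  for (rxn in rxns) {
    smaps <- sort(unlist(lapply(rxn$substrates, function(m)
      m$atoms$map[m$atoms$map > 0])))
    pmaps <- sort(unlist(lapply(rxn$products, function(m)
      m$atoms$map[m$atoms$map > 0])))
    expect_equal(smaps, pmaps, info = rxn$reaction_id)
  }
})

test_that("atom provenance assigns each heavy product atom to its substrate", {
  rxn <- parse_mapped_reaction(
    "[CH3:1][OH:2].[CH3:3][OH:4]>>[CH3:1][O:2][CH3:3].[OH2:4]", "cond")
  prov <- atom_provenance(rxn, 1L)
  expect_equal(prov$substrate, c(1L, 1L, 2L))
  # product atom with map 0 is unmapped
  rxn0 <- parse_mapped_reaction("[CH3:1][OH:2]>>[CH3:1]O", "m0")
  prov0 <- atom_provenance(rxn0, 1L)
  expect_equal(prov0$substrate, c(1L, NA_integer_))
})

test_that("provenance fractions match a brute-force per-atom lookup oracle", {
  rxns <- gen_mapped_reactions(synthetic_spec(seed = 13L))
  for (rxn in rxns) {
    for (pi in seq_along(rxn$products)) {
      heavy <- rxn$products[[pi]]$atoms
      heavy <- heavy[heavy$heavy, , drop = FALSE]
      if (!nrow(heavy)) next
      # oracle: nested linear scan over substrate atom lists
      oracle_src <- vapply(heavy$map, function(mp) {
        if (mp == 0L) return(NA_integer_)
        for (si in seq_along(rxn$substrates)) {
          if (mp %in% rxn$substrates[[si]]$atoms$map) return(si)
        }
        NA_integer_
      }, integer(1))
      prov <- atom_provenance(rxn, pi)
      expect_equal(prov$substrate, oracle_src, info = rxn$reaction_id)
      for (si in seq_along(rxn$substrates)) {
        frac_oracle <- sum(!is.na(oracle_src) & oracle_src == si) / nrow(heavy)
        pr <- suppressWarnings(extract_pairs(rxn, threshold = 0))
        row <- pr[pr$substrate_index == si & pr$product_index == pi, ]
        if (frac_oracle > 0)
          expect_equal(row$provenance_fraction, frac_oracle,
                       info = paste(rxn$reaction_id, si, pi))
      }
    }
  }
})

test_that("the majority rule is strict: exact 50% provenance is rejected", {
  rxn <- parse_mapped_reaction(
    paste0("[CH3:1][CH2:2][OH:5].[CH3:3][CH2:4][OH:6]>>",
           "[CH3:1][CH2:2][CH2:3][CH3:4].[OH2:5].[OH2:6]"), "sym")
  pairs <- suppressWarnings(extract_pairs(rxn))
  # butane derives exactly 2/4 atoms from each substrate: both pairs rejected
  expect_false(any(pairs$product_smiles == "CCCC"))
  # full provenance is retained
  rxn1 <- parse_mapped_reaction("[CH3:1][CH2:2][OH:3]>>[CH3:1][CH:2]=[O:3]", "r")
  expect_equal(extract_pairs(rxn1)$provenance_fraction, 1.0)
})

test_that("raising the threshold never increases the number of pairs", {
  rxns <- gen_mapped_reactions(synthetic_spec(seed = 23L))
  for (th in list(c(0, 0.25), c(0.25, 0.5), c(0.5, 0.75))) {
    n_lo <- sum(vapply(rxns, function(r)
      nrow(suppressWarnings(extract_pairs(r, th[1]))), numeric(1)))
    n_hi <- sum(vapply(rxns, function(r)
      nrow(suppressWarnings(extract_pairs(r, th[2]))), numeric(1)))
    expect_lte(n_hi, n_lo)
  }
})

test_that("zero-heavy-atom products are skipped with a warning", {
  rxn <- parse_mapped_reaction("[CH3:1][CH2:2][OH:3]>>[CH3:1][CH:2]=[O:3].[H+]",
                               "hp")
  expect_warning(pairs <- extract_pairs(rxn), "no heavy atoms")
  expect_equal(nrow(pairs), 1L)
})

test_that("filtering removes single-atom and cofactor pairs, keeps the rest", {
  pairs <- data.frame(
    reaction_id = "r", provenance_fraction = 1,
    substrate_smiles = c("CCO", canonical_smiles("O=C=O"), "CCO"),
    product_smiles = c("O", "CC=O", "CC=O"),
    stringsAsFactors = FALSE)
  out <- filter_pairs(pairs)
  expect_equal(nrow(out), 1L)                      # water (1 atom) and CO2 out
  expect_equal(out$substrate_smiles, "CCO")
  # ATP as substrate is dropped via the default cofactor list
  atp <- canonical_smiles(
    "Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)OP(=O)(O)OP(=O)(O)O)C(O)C1O")
  p2 <- data.frame(reaction_id = "r", provenance_fraction = 1,
                   substrate_smiles = atp, product_smiles = "CC=O",
                   stringsAsFactors = FALSE)
  expect_equal(nrow(filter_pairs(p2)), 0L)
  # idempotence
  expect_identical(filter_pairs(out), out)
})

test_that("canonicalization unifies SMILES dialects and dedup keys", {
  expect_identical(pair_to_reaction_smiles("OCC", "CC=O"),
                   pair_to_reaction_smiles("CCO", "CC=O"))
  expect_identical(pair_to_reaction_smiles("CCO", "CC=O"),
                   pair_to_reaction_smiles("CCO", "CC=O"))
  # map-stripped canonicalization
  expect_identical(canonical_smiles("[CH3:5][CH2:2][OH:9]"),
                   canonical_smiles("CCO"))
  expect_error(canonical_smiles("xy("), "failed to parse")
})

test_that("reactions TSV and cofactor list round-trip through files", {
  tmp <- withr::local_tempdir()
  rx_path <- file.path(tmp, "rx.tsv")
  writeLines(c("reaction_id\tmapped_rxn_smiles\tec_numbers",
               "r1\t[CH3:1][CH2:2][OH:3]>>[CH3:1][CH:2]=[O:3]\t1.1.1.1;1.1.1.2",
               "r2\t[CH3:1][OH:2]>>[CH3:1][OH:2]\t"), rx_path)
  rxns <- read_reactions(rx_path)
  expect_length(rxns, 2L)
  expect_equal(rxns[[1]]$ec_numbers, c("1.1.1.1", "1.1.1.2"))
  expect_length(rxns[[2]]$ec_numbers, 0L)
  cof_path <- file.path(tmp, "cof.smi")
  writeLines(c("# comment", "OCC   # ethanol written backwards", "O=C=O"),
             cof_path)
  expect_setequal(read_cofactor_list(cof_path),
                  c(canonical_smiles("CCO"), canonical_smiles("O=C=O")))
})
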