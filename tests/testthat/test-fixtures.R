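test_that("toy library is deterministic, valid, unique and seed-sensitive", {
  lib <- fixture_library()
  expect_length(lib, 50)
  expect_identical(lib, make_toy_library(50, 1))
  expect_equal(anyDuplicated(lib), 0)
  for (smi in lib) {
    expect_identical(parse_smiles(smi)$smiles_canonical, smi)
  }
  expect_false(identical(make_toy_library(20, 1), make_toy_library(20, 2)))
})

test_that("pseudo binding-site sequences are distinct and well-formed", {
  ctxs <- make_ligase_sequences()
  expect_setequal(names(ctxs), c("CRBN", "VHL", "MDM2"))
  seqs <- vapply(ctxs, `[[`, "", "sequence")
  expect_true(all(nchar(seqs) >= 24 & nchar(seqs) <= 32))
  for (s in seqs) {
    expect_true(all(strsplit(s, "")[[1]] %in% GG_AA_ALPHABET))
  }
  pos_identity <- function(a, b) {
    L <- min(nchar(a), nchar(b))
    mean(strsplit(substr(a, 1, L), "")[[1]] == strsplit(substr(b, 1, L), "")[[1]])
  }
  combs <- combn(length(seqs), 2)
  for (k in seq_len(ncol(combs))) {
    expect_lt(pos_identity(seqs[combs[1, k]], seqs[combs[2, k]]), 0.5)
  }
  expect_identical(seqs, vapply(make_ligase_sequences(), `[[`, "", "sequence"))
})

test_that("simulated property tables respect their distributions", {
  lib500 <- cached("lib500", function() make_toy_library(500, 7))
  props <- cached("props500", function() simulate_property_table(lib500, seed = 7))
  expect_identical(props, simulate_property_table(lib500, seed = 7))
  expect_true(all(props$logS >= -6.5 & props$logS <= 0.5))
  # analytic mean of Normal(-4.6, 1.3) truncated to [-6.5, 0.5]
  a <- (-6.5 + 4.6) / 1.3; b <- (0.5 + 4.6) / 1.3
  trunc_mean <- -4.6 + 1.3 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(props$logS) - trunc_mean), 0.2)
  expect_true(all(props$n_metab %in% 1:8))
  expect_true(all(props$MW > 0))
  expect_true(all(props$ro5_violations %in% 0:4))
})

test_that("simulated docking scores reproduce the drug-like class structure", {
  # Gaussian tail: a drug-like-window compound scores High with freq >= 0.85
  druglike <- data.frame(id = sprintf("x%04d", 1:1000), MW = 400, logP = 3.5,
                         logS = -5)
  sc <- simulate_docking_scores(druglike, "VHL", seed = 3)
  expect_gte(mean(sc$docking_score <= -5), 0.85)
  expect_identical(sc, simulate_docking_scores(druglike, "VHL", seed = 3))
  # internal consistency with the classifier
  expect_identical(sc$category,
                   vapply(sc$docking_score, classify_affinity, ""))

  lib500 <- cached("lib500", function() make_toy_library(500, 7))
  props <- cached("props500", function() simulate_property_table(lib500, seed = 7))
  sc2 <- simulate_docking_scores(props, "CRBN", seed = 9)
  high <- sc2$category == "High"
  no <- sc2$category == "No"
  expect_gte(sum(high), 5)
  # High-class records sit in the drug-like MW window, with lower solubility
  expect_true(mean(props$MW[high]) >= 300 && mean(props$MW[high]) <= 500)
  expect_lt(mean(props$logS[high]), mean(props$logS[no]))
})

test_that("the fixture writer emits byte-identical file sets per seed", {
  d1 <- tempfile(); d2 <- tempfile()
  write_fixtures(d1, n = 12, seed = 4)
  write_fixtures(d2, n = 12, seed = 4)
  for (f in c("smiles.txt", "ligases.fasta", "properties.csv", "scores.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_length(readLines(file.path(d1, "smiles.txt")), 12)
  sc <- read_score_table(file.path(d1, "scores.csv"))
  expect_setequal(unique(sc$ligase), c("CRBN", "VHL", "MDM2"))
})
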