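rec_template <- function(...) {
  base <- list(MW = 366.7, logP = 3.39, logS = -4.59, logHERG = -6,
               n_metab = 4, ro5_violations = 0)
  mod <- list(...)
  base[names(mod)] <- mod
  base
}

test_that("ADMET filter applies every window with inclusive bounds", {
  expect_true(apply_admet_filter(rec_template())$pass)
  r <- apply_admet_filter(rec_template(MW = 129))
  expect_false(r$pass)
  expect_equal(r$violations, "MW")
  # boundary values on the inclusive edges pass
  expect_true(apply_admet_filter(rec_template(MW = 130, logP = -2, logS = 0.5,
                                              logHERG = -5.01, n_metab = 1,
                                              ro5_violations = 1))$pass)
  expect_false(apply_admet_filter(rec_template(logHERG = -5))$pass)
  both <- apply_admet_filter(rec_template(logP = 7, n_metab = 0))
  expect_setequal(both$violations, c("logP", "n_metab"))
  expect_error(apply_admet_filter(list(MW = 100)),
               class = "gluegen_missing_field_error")

  # tightening any window can only shrink the pass set
  props <- cached("admet_props", function()
    simulate_property_table(fixture_library(), seed = 2))
  pass_rate <- function(rules) {
    mean(vapply(seq_len(nrow(props)), function(i)
      apply_admet_filter(props[i, ], rules)$pass, logical(1)))
  }
  base_rules <- GG_ADMET_RULES
  base <- pass_rate(base_rules)
  for (tweak in list(c("MW", 1), c("logP", 1), c("logS", 1))) {
    rules <- base_rules
    rules[[tweak[1]]] <- c(rules[[tweak[1]]][1] + 0.5,
                           rules[[tweak[1]]][2] - 0.5)
    expect_lte(pass_rate(rules), base)
  }
})

test_that("affinity classification is exact at the category boundaries", {
  expect_equal(classify_affinity(-5.98), "High")
  expect_equal(classify_affinity(-3.0), "Low")
  expect_equal(classify_affinity(0.5), "No")
  expect_equal(classify_affinity(-5), "High")   # boundary belongs to High
  expect_equal(classify_affinity(-4.999999), "Low")
  expect_equal(classify_affinity(-1), "Low")    # boundary belongs to Low
  expect_equal(classify_affinity(-0.999999), "No")
  expect_error(classify_affinity(NaN))
  # total and piecewise constant on a grid
  grid <- seq(-8, 2, by = 0.25)
  cats <- vapply(grid, classify_affinity, "")
  expect_true(all(cats %in% c("High", "Low", "No")))
  expect_true(all(diff(match(cats, c("High", "Low", "No"))) >= 0))
})

test_that("stratification totals equal the sum of their parts", {
  expect_equal(stratification_report(
    data.frame(ligase = character(0), library = character(0),
               category = character(0)))$grand_total, 0)
  set.seed(10)
  for (rep in 1:5) {
    n <- sample(30:80, 1)
    recs <- data.frame(
      ligase = sample(c("CRBN", "VHL", "MDM2"), n, replace = TRUE),
      library = sample(c("ChEMBL", "Vitas"), n, replace = TRUE),
      category = sample(c("High", "Low", "No"), n, replace = TRUE))
    rep_ <- stratification_report(recs)
    tab <- rep_$table
    expect_equal(tab$Total,
                 tab$High_Affinity + tab$Low_Affinity + tab$No_Affinity)
    expect_equal(rep_$grand_total, n)
  }
})

test_that("Murcko scaffolds strip side chains and rank by frequency", {
  expect_equal(murcko_scaffold("Cc1ccccc1"), "c1ccccc1")
  expect_equal(murcko_scaffold("c1ccccc1"), "c1ccccc1")
  expect_equal(murcko_scaffold("CCCC"), "")
  expect_equal(murcko_scaffold("CCc1ccncc1"),
               parse_smiles("c1ccncc1")$smiles_canonical)
  expect_error(murcko_scaffold("C1CC"), class = "gluegen_parse_error")

  recs <- data.frame(
    smiles = c("Cc1ccccc1", "CCc1ccccc1", "c1ccccc1", "Cc1ccncc1", "CCCC"),
    ligase = "CRBN", category = "High", stringsAsFactors = FALSE)
  tops <- top_scaffolds(recs, "CRBN", "High", n = 5)
  expect_equal(tops$scaffold[1], "c1ccccc1")
  expect_equal(tops$count[1], 3)
  expect_lte(sum(tops$count), nrow(recs))
  one <- top_scaffolds(recs[1:2, ], n = 3)
  expect_equal(nrow(one), 1)
  expect_equal(one$count, 2)
})

test_that("QED reproduces reference values on alert-free molecules", {
  # frozen from an independent implementation of the same parameterization
  expect_equal(qed_score("c1ccccc1"), 0.4426, tolerance = 2e-3)
  expect_equal(qed_score("Cc1ccccc1O"), 0.5359, tolerance = 2e-2)
  expect_equal(qed_score("c1ccc(-c2ccccc2)cc1"), 0.5905, tolerance = 2e-2)
  q <- vapply(fixture_library()[1:8], qed_score, 0)
  expect_true(all(q > 0 & q < 1))
})

test_that("generation metrics match hand counts and a set-arithmetic oracle", {
  gm <- generation_metrics(c("c1ccccc1", "c1ccccc1", "Cc1ccccc1", "C1CC"),
                           training = "Cc1ccccc1")
  expect_equal(gm$validity, 75.0)
  expect_equal(gm$uniqueness, 200 / 3, tolerance = 1e-6)
  expect_equal(gm$novelty, 50.0)

  expect_equal(generation_metrics(c("CC", "CC"), training = "CC")$novelty, 0)
  same <- generation_metrics(c("c1ccccc1", "c1ccccc1"), training = "c1ccccc1")
  expect_equal(same$validity, 100)
  expect_equal(same$uniqueness, 50)
  expect_equal(same$novelty, 0)
  expect_error(generation_metrics(character(0), character(0)),
               class = "gluegen_empty_input_error")
})

test_that("chemical-space projection is seeded and guards its inputs", {
  expect_error(chemspace_projection(c("CC", "CCC", "CCCC", "c1ccccc1")),
               class = "gluegen_too_few_points_error")
  expect_error(chemspace_projection(c("CC", "CCC", "CCCC", "C1CC", "bogus(")),
               class = "gluegen_too_few_points_error")
  smis <- fixture_library()[1:12]
  p1 <- chemspace_projection(smis, seed = 4)
  p2 <- chemspace_projection(smis, seed = 4)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 12)
  # duplicates have identical fingerprints (zero distance before embedding)
  fp1 <- circular_fingerprint("Cc1ccccc1")
  fp2 <- circular_fingerprint("Cc1ccccc1")
  expect_identical(fp1, fp2)
  expect_length(fp1, 2048)
})

test_that("screening CSV interfaces enforce their headers", {
  pp <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = "a", smiles = "CC", MW = 30, logP = 1, logS = -4,
                       logHERG = -6, n_metab = 2, ro5_violations = 0),
            pp, row.names = FALSE)
  expect_equal(nrow(read_property_table(pp)), 1)
  sp <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = "a", ligase = "VHL", library = "toy",
                       docking_score = -5.5), sp, row.names = FALSE)
  st <- read_score_table(sp)
  expect_equal(st$category, "High")
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_property_table(bad), class = "gluegen_missing_field_error")
})
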