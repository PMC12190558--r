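test_that("annealing, decay and clipping schedules match their definitions", {
  cfg <- train_config()
  expect_equal(beta_schedule(0, cfg), 0)
  expect_equal(beta_schedule(1, cfg), 0.002)
  expect_equal(beta_schedule(500, cfg), 1.0)
  expect_equal(beta_schedule(10000, cfg), 1.0)
  b <- beta_schedule(0:2000, cfg)
  expect_true(all(diff(b) >= 0))
  expect_true(all(b <= cfg$beta_cap))

  expect_equal(lr_schedule(0, cfg), 0.001)
  expect_equal(lr_schedule(1, cfg), 0.0009)
  expect_true(all(diff(lr_schedule(0:50, cfg)) < 0))

  v <- c(60, 80) # norm 100
  out <- clip_gradients(v, 50)
  expect_equal(sqrt(sum(out^2)), 50)
  expect_equal(out, v * 0.5)
  expect_equal(clip_gradients(c(3, 4), 50), c(3, 4))
  expect_equal(clip_gradients(c(0, 0), 50), c(0, 0))
  lst <- list(a = matrix(60), b = c(80))
  expect_equal(clip_gradients(lst, 50)$a[1], 30)
})

test_that("single-molecule overfit reaches perfect teacher-forced accuracy", {
  m <- overfit_model()
  final <- m$metrics[nrow(m$metrics), ]
  expect_equal(final$wacc, 1.0)
  expect_equal(final$tacc, 1.0)
  expect_equal(final$sacc, 1.0)
  expect_lt(final$loss_total, m$metrics$loss_total[1])
})

test_that("training is deterministic and logs well-formed metrics", {
  ctxs <- fixture_contexts()
  lib <- make_toy_library(5, 3)
  dat <- data.frame(id = sprintf("d%02d", 1:5), smiles = lib, ligase_id = "VHL")
  lp1 <- tempfile(); lp2 <- tempfile()
  m1 <- train(dat, ctxs["VHL"], cfg = train_config(epochs = 8, batch_size = 2, seed = 5),
              log_path = lp1)
  m2 <- train(dat, ctxs["VHL"], cfg = train_config(epochs = 8, batch_size = 2, seed = 5),
              log_path = lp2)
  expect_identical(m1$metrics, m2$metrics)
  expect_identical(m1$params, m2$params)
  expect_identical(readLines(lp1), readLines(lp2))
  rec <- jsonlite::fromJSON(readLines(lp1)[1])
  expect_true(all(c("epoch", "step", "loss_total", "kl", "wacc", "tacc",
                    "sacc", "beta", "lr") %in% names(rec)))
  expect_true(all(diff(m1$metrics$step) > 0))
  expect_true(all(m1$metrics$wacc >= 0 & m1$metrics$wacc <= 1))
})

test_that("an untrained model predicts labels near chance level", {
  ds <- cached("chance_ds", function() {
    ctxs <- fixture_contexts()
    lib <- make_toy_library(20, 1)
    prepare_dataset(data.frame(id = sprintf("c%02d", 1:20), smiles = lib,
                               ligase_id = "CRBN"),
                    ctxs["CRBN"], use_torsions = FALSE)
  })
  cfg <- model_config()
  params <- model_params(ds$vocab, cfg, seed = 77)
  model <- structure(list(params = params, cfg = cfg, vocab = ds$vocab,
                          contexts = list(CRBN = ds$contexts$CRBN$embedding),
                          train_cfg = train_config()), class = "gg_model")
  mm <- reconstruction_metrics(model, ds)
  V <- length(ds$vocab$labels)
  # a random model's argmax should sit well below trained accuracy
  expect_lt(mm$wacc, 1 / V + 0.25)
  expect_equal(mm$sacc, 1.0)
})

test_that("checkpoints round-trip and reject vocabulary mismatches", {
  m <- toy_model()
  cp <- tempfile(fileext = ".rds")
  save_checkpoint(m, cp)
  m2 <- load_checkpoint(cp, expected_vocab = m$vocab)
  g1 <- generate(m, "CRBN", n = 10, seed = 3)
  g2 <- generate(m2, "CRBN", n = 10, seed = 3)
  expect_identical(g1, g2)
  expect_error(load_checkpoint(cp, expected_vocab = c("c1ccccc1")),
               class = "gluegen_checkpoint_error")
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(version = "other", model = list()), bad)
  expect_error(load_checkpoint(bad), class = "gluegen_checkpoint_error")
})

test_that("data errors carry the offending molecule id", {
  ctxs <- fixture_contexts()
  expect_error(
    prepare_dataset(data.frame(id = "bad1", smiles = "C1CC", ligase_id = "CRBN"),
                    ctxs["CRBN"]),
    regexp = "bad1", class = "gluegen_data_error")
  expect_error(
    prepare_dataset(data.frame(id = "m", smiles = "CC", ligase_id = "NOPE"),
                    ctxs["CRBN"]),
    class = "gluegen_data_error")
})
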