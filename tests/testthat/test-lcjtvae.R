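toy_cfg <- function() model_config(hidden = 8, d_tree = 6, d_graph = 6,
                                   d_fused = 12, d_seq = 16, dec_hidden = 10,
                                   label_embed = 6, d_attn = 4, n_heads = 4)

toy_setup <- function() {
  cached("lcj_setup", function() {
    ctx <- ligase_context("CRBN", "ACDEFGHIKLMNPQRSTVWY",
                          encoder_config(d_out = 16))
    dat <- data.frame(id = paste0("m", 1:3),
                      smiles = c("Cc1ccccc1O", "CCOC(=O)c1ccncc1", "CC(=O)Nc1ccccc1"),
                      ligase_id = "CRBN")
    prepare_dataset(dat, list(CRBN = ctx), use_torsions = TRUE, seed = 3)
  })
}

test_that("zero-weight encoder emits the head biases; trained means differ", {
  ds <- toy_setup()
  cfg <- toy_cfg()
  params <- model_params(ds$vocab, cfg, seed = 1)
  zero <- lapply(params, function(x) x * 0)
  zero$gbmean <- rnorm(cfg$d_graph); zero$gbvar <- rnorm(cfg$d_graph)
  zero$tbmean <- rnorm(cfg$d_tree); zero$tbvar <- rnorm(cfg$d_tree)
  ex <- ds$examples[[1]]
  enc <- encode(ex$graph, ex$jtree, ds$vocab, zero, cfg)
  expect_equal(enc$g_mean, zero$gbmean)
  expect_equal(enc$g_logvar, zero$gbvar)
  expect_equal(enc$t_mean, zero$tbmean)
  expect_equal(enc$t_logvar, zero$tbvar)

  e1 <- encode(ds$examples[[1]]$graph, ds$examples[[1]]$jtree, ds$vocab, params, cfg)
  e2 <- encode(ds$examples[[2]]$graph, ds$examples[[2]]$jtree, ds$vocab, params, cfg)
  expect_gt(max(abs(e1$t_mean - e2$t_mean)), 1e-8)

  # unseen clique label is a vocabulary error
  other <- prepare_dataset(
    data.frame(id = "x", smiles = "C1CCNCC1", ligase_id = "CRBN"),
    list(CRBN = ds$contexts$CRBN), use_torsions = FALSE)
  expect_error(encode(other$examples[[1]]$graph, other$examples[[1]]$jtree,
                      ds$vocab, params, cfg),
               class = "gluegen_vocabulary_error")
})

test_that("encoder means are invariant under atom permutation", {
  ds <- toy_setup()
  cfg <- toy_cfg()
  params <- model_params(ds$vocab, cfg, seed = 2)
  set.seed(4)
  for (ex in ds$examples) {
    base <- encode(ex$graph, ex$jtree, ds$vocab, params, cfg)
    perm <- sample(nrow(ex$graph$atom_features))
    g2 <- permute_graph(ex$graph, perm)
    enc2 <- encode(g2, ex$jtree, ds$vocab, params, cfg)
    expect_equal(enc2$g_mean, base$g_mean, tolerance = 1e-5)
    expect_equal(enc2$g_logvar, base$g_logvar, tolerance = 1e-5)
  }
})

test_that("reparameterization is seeded and unbiased", {
  mean <- c(1, -2, 0.5); logvar <- c(0.2, -0.5, 0)
  r1 <- reparameterize(mean, logvar, seed = 9)
  r2 <- reparameterize(mean, logvar, seed = 9)
  expect_identical(r1$z, r2$z)
  # logvar -> -Inf limit collapses to the mean
  expect_equal(reparameterize(mean, rep(-1e6, 3), seed = 1)$z, mean)
  # Monte-Carlo mean within 4 sigma / sqrt(n)
  n <- 10000
  draws <- vapply(seq_len(n), function(i)
    reparameterize(0.7, 0, seed = i)$z, numeric(1))
  expect_lt(abs(mean(draws) - 0.7), 4 / sqrt(n))
  expect_error(reparameterize(c(1, 2), 0, seed = 1))
})

test_that("latent fusion matches its closed-form special cases", {
  cfg <- toy_cfg()
  ds <- toy_setup()
  params <- model_params(ds$vocab, cfg, seed = 3)
  z_mol <- rnorm(12); z_seq <- rnorm(16)
  # W = 0: fused latent is ReLU(b)
  p0 <- params; p0$fW <- params$fW * 0; p0$fb <- rnorm(cfg$d_fused)
  expect_equal(fuse(z_mol, z_seq, p0, cfg)$z_fused, pmax(0, p0$fb))
  # all-negative bias with W = 0 dies under the ReLU
  p0$fb <- -abs(rnorm(cfg$d_fused)) - 0.1
  expect_equal(fuse(z_mol, z_seq, p0, cfg)$z_fused, rep(0, cfg$d_fused))
  expect_error(fuse(rnorm(5), z_seq, params, cfg),
               class = "gluegen_dimension_error")

  # cross-attention with a single key position ignores the query
  acfg <- model_config(hidden = 8, d_tree = 6, d_graph = 6, d_fused = 12,
                       d_seq = 16, dec_hidden = 10, label_embed = 6,
                       d_attn = 4, n_heads = 4, fusion = "cross_attention")
  pa <- model_params(ds$vocab, acfg, seed = 3)
  S <- matrix(rnorm(16), nrow = 1)
  o1 <- fuse(rnorm(12), S, pa, acfg)$z_fused
  o2 <- fuse(rnorm(12), S, pa, acfg)$z_fused
  expect_equal(o1, o2, tolerance = 1e-12)
  v <- as.vector(S %*% t(pa$aWv))
  expect_equal(o1, as.vector(pa$aWo %*% rep(v, acfg$n_heads) + pa$abo),
               tolerance = 1e-12)
})

test_that("KL term matches the closed form and numerical integration", {
  expect_equal(kl_term(0, 0), 0)
  expect_equal(kl_term(1, 0), 0.5)
  kl_numeric <- function(mu, lv) {
    s <- exp(lv / 2)
    sum(vapply(seq_along(mu), function(i) {
      integrate(function(x) {
        p <- dnorm(x, mu[i], s[i])
        ifelse(p > 0, p * (dnorm(x, mu[i], s[i], log = TRUE) - dnorm(x, log = TRUE)), 0)
      }, mu[i] - 12 * s[i] - 12, mu[i] + 12 * s[i] + 12)$value
    }, numeric(1)))
  }
  set.seed(8)
  for (rep in 1:5) {
    mu <- rnorm(4); lv <- rnorm(4, sd = 0.7)
    expect_equal(kl_term(mu, lv), kl_numeric(mu, lv), tolerance = 1e-6)
    expect_gte(kl_term(mu, lv), 0)
  }
})

test_that("loss assembly respects the beta weighting", {
  lt <- loss_total(2.0, 1.0, 3.0, 0.5)
  expect_equal(lt$total, 4.5)
  expect_equal(loss_total(2, 1, 3, 0)$total, 3)
  expect_equal(loss_total(2, 1, 0, 1)$total, 3)
  expect_equal(lt$total, lt$recon_tree + lt$recon_graph + lt$beta * lt$kl,
               tolerance = 1e-6)
  expect_error(loss_total(1, 1, 1, 1.5))
})

test_that("greedy decoding is deterministic and honors the node budget", {
  m <- toy_model()
  z <- rep(0.3, m$cfg$d_fused)
  t1 <- decode_tree(z, m$vocab, m$params, m$cfg)
  t2 <- decode_tree(z, m$vocab, m$params, m$cfg)
  expect_identical(vapply(t1$nodes, `[[`, "", "label"),
                   vapply(t2$nodes, `[[`, "", "label"))
  expect_identical(t1$edges, t2$edges)
  tiny <- decode_tree(z, m$vocab, m$params, m$cfg, max_nodes = 1)
  expect_equal(length(tiny$nodes), 1)
  expect_equal(nrow(tiny$edges), 0)
})

test_that("graph decoding round-trips ground-truth trees", {
  # single-clique tree: benzene decodes to benzene with nothing to score
  m <- toy_model()
  bzds <- prepare_dataset(
    data.frame(id = "bz", smiles = "c1ccccc1", ligase_id = "CRBN"),
    list(CRBN = list(embedding = NULL)), vocab = m$vocab, use_torsions = FALSE)
  jt <- bzds$examples[[1]]$jtree
  out <- decode_graph(rep(0, m$cfg$d_fused), jt, m$params, m$cfg)
  expect_equal(out$smiles_canonical, "c1ccccc1")

  # recorded correspondences reproduce the original exactly
  lib <- fixture_library()[1:10]
  for (smi in lib) {
    jt <- tree_decompose(parse_smiles(smi))
    out <- decode_graph(rep(0, m$cfg$d_fused), jt, m$params, m$cfg,
                        use_recorded = TRUE)
    expect_equal(out$smiles_canonical, smi)
  }
})

test_that("the overfitted model recovers its molecule end to end", {
  m <- overfit_model()
  target <- parse_smiles("CCOC(=O)c1ccncc1")$smiles_canonical
  expect_equal(reconstruct(m, "CCOC(=O)c1ccncc1", "CRBN"), target)
})

test_that("ligase conditioning steers generated cliques to the right sublibrary", {
  res <- cached("conditioning", function() {
    ctxs <- fixture_contexts()
    libA <- make_toy_library(10, 11, scaffolds = c("benzene", "pyridine", "phthalimide"))
    libB <- make_toy_library(10, 12, scaffolds = c("piperidine", "cyclohexane"))
    dat <- data.frame(id = sprintf("m%02d", 1:20), smiles = c(libA, libB),
                      ligase_id = rep(c("CRBN", "VHL"), each = 10))
    ds <- prepare_dataset(dat, ctxs[c("CRBN", "VHL")], seed = 1)
    model <- train(ds, cfg = toy_train_config(epochs = 200, seed = 2))
    list(model = model,
         vocabA = build_vocabulary(lapply(libA, parse_smiles))$labels,
         vocabB = build_vocabulary(lapply(libB, parse_smiles))$labels)
  })
  frac_from <- function(lig, sub_vocab) {
    m <- res$model
    set.seed(5)
    labs <- unlist(lapply(1:40, function(i) {
      z <- rnorm(m$cfg$d_tree + m$cfg$d_graph)
      fu <- fuse(z, m$contexts[[lig]], m$params, m$cfg)
      jt <- decode_tree(fu$z_fused, m$vocab, m$params, m$cfg)
      vapply(jt$nodes, `[[`, "", "label")
    }))
    mean(labs %in% sub_vocab)
  }
  expect_gte(frac_from("CRBN", res$vocabA), 0.8)
  expect_gte(frac_from("VHL", res$vocabB), 0.8)
})
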