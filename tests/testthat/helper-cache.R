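# Shared, lazily built test objects. Heavyweight artifacts (the fixture
# library, trained toy models) are built once per test run and reused across
# files.

gg_test_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = gg_test_cache)) {
    assign(name, builder(), envir = gg_test_cache)
  }
  get(name, envir = gg_test_cache)
}

fixture_library <- function() cached("lib50", function() make_toy_library(50, 1))

fixture_contexts <- function() cached("ctxs", function() make_ligase_sequences())

# single-molecule overfit model (desk-scale config, 300 epochs)
overfit_model <- function() cached("overfit", function() {
  dat <- data.frame(id = "m1", smiles = "CCOC(=O)c1ccncc1", ligase_id = "CRBN")
  train(dat, fixture_contexts()["CRBN"], cfg = toy_train_config(epochs = 300, seed = 1))
})

# 20-molecule toy model used for loss-curve and generation checks
toy_model <- function() cached("toymodel", function() {
  lib <- make_toy_library(20, 1)
  dat <- data.frame(id = sprintf("m%02d", 1:20), smiles = lib,
                    ligase_id = "CRBN")
  train(dat, fixture_contexts()["CRBN"], cfg = toy_train_config(epochs = 200, seed = 1))
})

# permute the atoms of a featurized graph (consistent relabeling)
permute_graph <- function(g, perm) {
  inv <- order(perm)
  g2 <- g
  g2$atom_features <- g$atom_features[perm, , drop = FALSE]
  adj <- cbind(inv[g$adjacency[, 1]], inv[g$adjacency[, 2]])
  reord <- sample.int(nrow(adj))
  g2$adjacency <- adj[reord, , drop = FALSE]
  g2$bond_features <- g$bond_features[reord, , drop = FALSE]
  g2
}
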