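test_that("parse_smiles canonicalizes, counts, and rejects invalid input", {
  m <- parse_smiles("c1ccccc1")
  expect_equal(m$atom_count, 6)
  expect_equal(m$bond_count, 6)
  # idempotence of the canonical form
  for (smi in c("CC(=O)O", "Cc1ccccc1O", "O=C1NC(=O)c2ccccc21")) {
    can <- parse_smiles(smi)$smiles_canonical
    expect_identical(parse_smiles(can)$smiles_canonical, can)
  }
  expect_error(parse_smiles("C1CC"), class = "gluegen_parse_error")
  expect_error(parse_smiles(""), class = "gluegen_parse_error")
  expect_error(parse_smiles("CC.CC"), class = "gluegen_disconnected_error")
  expect_error(parse_smiles("C(C)(C)(C)(C)C"), class = "gluegen_parse_error")
})

test_that("molecular graphs have fixed-width features and torsion encoding", {
  bz <- parse_smiles("c1ccccc1")
  g <- mol_to_graph(bz)
  expect_equal(nrow(g$atom_features), bz$atom_count)
  expect_equal(nrow(g$bond_features), bz$bond_count)
  expect_true(all(g$bond_features[, "torsion_defined"] == 0))
  expect_true(all(g$bond_features[, c("torsion_sin", "torsion_cos")] == 0))

  bu <- parse_smiles("CCCC")
  g2 <- mol_to_graph(bu, torsions = c("2-3" = 180))
  row <- g2$bond_features[, "torsion_defined"] == 1
  expect_equal(sum(row), 1)
  expect_equal(unname(g2$bond_features[row, "torsion_sin"]), 0, tolerance = 1e-12)
  expect_equal(unname(g2$bond_features[row, "torsion_cos"]), -1)
  expect_error(mol_to_graph(bu, torsions = c("9-10" = 90)),
               class = "gluegen_key_error")

  # defined torsions sit on the unit circle
  tm <- torsion_map(bu, seed = 1)
  g3 <- mol_to_graph(bu, torsions = tm)
  def <- g3$bond_features[, "torsion_defined"] == 1
  expect_equal(unname(g3$bond_features[def, "torsion_sin"]^2 +
                        g3$bond_features[def, "torsion_cos"]^2),
               rep(1, sum(def)), tolerance = 1e-6)
  # edge list: each bond once, no duplicates
  keys <- paste(g3$adjacency[, 1], g3$adjacency[, 2])
  expect_equal(anyDuplicated(keys), 0)
})

test_that("tree decomposition matches hand-derived cliques", {
  jt_bz <- tree_decompose(parse_smiles("c1ccccc1"))
  expect_equal(length(jt_bz$nodes), 1)
  expect_equal(nrow(jt_bz$edges), 0)
  expect_equal(jt_bz$nodes[[1]]$kind, "ring")

  jt_et <- tree_decompose(parse_smiles("CC"))
  expect_equal(length(jt_et$nodes), 1)
  expect_equal(jt_et$nodes[[1]]$kind, "bond")

  jt_bp <- tree_decompose(parse_smiles("c1ccccc1-c1ccccc1"))
  kinds <- sort(vapply(jt_bp$nodes, `[[`, "", "kind"))
  expect_equal(kinds, c("bond", "ring", "ring"))
  expect_equal(nrow(jt_bp$edges), 2)
  # path: the bond clique is adjacent to both rings
  expect_setequal(as.vector(jt_bp$edges), c(1, 2, 3, 3))

  jt_tol <- tree_decompose(parse_smiles("Cc1ccccc1"))
  expect_equal(length(jt_tol$nodes), 2)
  shared <- intersect(jt_tol$nodes[[1]]$atom_indices,
                      jt_tol$nodes[[2]]$atom_indices)
  expect_equal(length(shared), 1)
})

test_that("vocabulary construction is deterministic and monotone", {
  bz <- parse_smiles("c1ccccc1")
  v1 <- build_vocabulary(list(bz))
  expect_equal(length(v1$labels), 1)
  v2 <- build_vocabulary(list(bz, parse_smiles("Cc1ccccc1")))
  expect_true(all(v1$labels %in% v2$labels))
  expect_equal(unname(v2$label_to_index[v2$labels]), seq_along(v2$labels))

  lib <- fixture_library()
  mols <- lapply(lib, parse_smiles)
  va <- build_vocabulary(mols)
  vb <- build_vocabulary(mols)
  expect_identical(va$labels, vb$labels)

  tmp <- tempfile(fileext = ".json")
  write_vocabulary(va, tmp)
  expect_identical(read_vocabulary_labels(tmp), va$labels)
})

test_that("decomposition invariants hold across the fixture library", {
  lib <- fixture_library()
  for (smi in lib) {
    mol <- parse_smiles(smi)
    jt <- tree_decompose(mol)
    nn <- length(jt$nodes)
    expect_equal(nrow(jt$edges), nn - 1)
    expect_true(gluegen:::jtree_is_valid(jt, mol$atom_count))
    # no ring clique contained in another ring clique
    rings <- Filter(function(nd) nd$kind == "ring", jt$nodes)
    if (length(rings) > 1) {
      for (i in seq_len(length(rings) - 1)) for (j in seq(i + 1, length(rings))) {
        expect_false(all(rings[[i]]$atom_indices %in% rings[[j]]$atom_indices))
        expect_false(all(rings[[j]]$atom_indices %in% rings[[i]]$atom_indices))
      }
    }
  }
})

test_that("preprocessing emits JSON-lines records and a vocabulary", {
  dirp <- tempfile()
  smip <- tempfile(fileext = ".txt")
  writeLines(c("c1ccccc1", "Cc1ccccc1"), smip)
  res <- preprocess_library(smip, dirp, with_torsions = FALSE)
  recs <- readLines(res$records)
  expect_equal(length(recs), 2)
  r1 <- jsonlite::fromJSON(recs[1])
  expect_equal(r1$smiles, "c1ccccc1")
  expect_equal(length(r1$cliques$label), 1)
  expect_identical(read_vocabulary_labels(res$vocabulary), res$vocab$labels)
})
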