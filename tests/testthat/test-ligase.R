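test_that("one-hot encoding follows the fixed alphabet", {
  m <- onehot_encode("ACD")
  expect_equal(dim(m), c(3, 21))
  expect_equal(rowSums(m), rep(1, 3))
  expect_equal(unname(which(onehot_encode("A")[1, ] == 1)), 1)
  expect_equal(colnames(m)[1:3], c("A", "C", "D"))
  expect_error(onehot_encode("ACB"), class = "gluegen_alphabet_error")
})

test_that("k-mer counts satisfy the window identity", {
  v1 <- kmer_encode("AAC", 1)
  expect_equal(unname(v1[c("A", "C")]), c(2, 1))
  expect_equal(sum(v1), 3)
  v2 <- kmer_encode("AAC", 2)
  expect_equal(unname(v2[c("AA", "AC")]), c(1, 1))
  expect_equal(sum(v2), 2)
  v3 <- kmer_encode("WYX", 3)
  expect_equal(sum(v3 != 0), 1)
  expect_equal(sum(v3), 1)
  expect_error(kmer_encode("AC", 3), class = "gluegen_length_error")
  # total-count identity across fixture sequences
  for (ctx in fixture_contexts()) {
    for (k in 1:3) {
      L <- nchar(ctx$sequence)
      expect_equal(sum(kmer_encode(ctx$sequence, k)), L - k + 1)
    }
  }
})

test_that("recurrent refinement is deterministic and direction-symmetric", {
  X <- matrix(rnorm(4 * 5), 4, 5)
  o1 <- refine_recurrent(X, seed = 3, hidden = 8)
  o2 <- refine_recurrent(X, seed = 3, hidden = 8)
  expect_identical(o1, o2)
  expect_equal(dim(o1), c(4, 16))
  expect_equal(dim(refine_recurrent(X[1, , drop = FALSE], seed = 1, hidden = 8)),
               c(1, 16))
  # mirrored parameters on the reversed input swap the direction blocks
  p <- gluegen:::lstm_params(5, 8, seed = 3)
  pm <- p; pm$forward <- p$backward; pm$backward <- p$forward
  a <- refine_recurrent(X, params = p)
  b <- refine_recurrent(X[4:1, , drop = FALSE], params = pm)
  expect_equal(a[, 1:8], b[4:1, 9:16], tolerance = 1e-12)
  expect_equal(a[, 9:16], b[4:1, 1:8], tolerance = 1e-12)
})

test_that("projection yields fixed-length, non-collapsed embeddings", {
  expect_equal(project_fixed(matrix(0, 3, 7), 128), rep(0, 128))
  expect_length(project_fixed(rnorm(10), 128), 128)
  expect_length(project_fixed(rnorm(10), 512), 512)
  ctxs <- fixture_contexts()
  embs <- lapply(ctxs, `[[`, "embedding")
  expect_length(embs$CRBN, 128)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gt(max(abs(embs[[i]] - embs[[j]])), 0)
  }
})

test_that("the pretrained-embedder adapter is a contract, not a model", {
  register_protein_embedder(NULL)
  expect_error(pretrained_adapter("ACD"), class = "gluegen_adapter_missing_error")
  register_protein_embedder(function(seq) matrix(1, nchar(seq), 1024))
  out <- pretrained_adapter("ACDEF")
  expect_equal(dim(out), c(5, 1024))
  # constant rows: projection equals the affine image of the constant
  ctx <- ligase_context("X", "ACDEF",
                        encoder_config(scheme = "pretrained_adapter", d_out = 128, seed = 5))
  direct <- project_fixed(matrix(1, 1, 1024), 128, seed = 5)
  expect_equal(ctx$embedding, direct, tolerance = 1e-12)
  register_protein_embedder(NULL)
})

test_that("FASTA round trip produces labeled contexts", {
  fp <- tempfile(fileext = ".fasta")
  writeLines(c(">CRBN", "WFYHWPHQNYWFAWYHGWF", ">VHL", "DESTDYDNPSDTQEHSE"), fp)
  ctxs <- read_ligase_fasta(fp, encoder_config(d_out = 128))
  expect_setequal(names(ctxs), c("CRBN", "VHL"))
  expect_length(ctxs$CRBN$embedding, 128)
})
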