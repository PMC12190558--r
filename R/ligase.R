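# Encoding of E3-ligase binding-site residue sequences into fixed-length
# conditioning vectors: one-hot, k-mer counts, an optional pluggable
# pretrained per-residue embedder, bidirectional LSTM refinement, and the
# mean-pool + affine projection to the molecular latent width.

#' Amino-acid alphabet used by the sequence encoders
#'
#' The 20 standard residues in alphabetical one-letter order, plus `X` for
#' any nonstandard residue.
#' @export
GG_AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

check_sequence <- function(sequence) {
  gg_assert(is.character(sequence) && length(sequence) == 1 && nzchar(sequence),
            "sequence must be a non-empty string", "gluegen_alphabet_error")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(chars, GG_AA_ALPHABET)
  if (length(bad)) {
    gg_stop(sprintf("invalid residue(s) in sequence: %s",
                    paste(unique(bad), collapse = ", ")),
            "gluegen_alphabet_error")
  }
  chars
}

#' One-hot encode a residue sequence
#'
#' @param sequence Residue string over [GG_AA_ALPHABET].
#' @return `L x 21` matrix; each row has exactly one 1, columns in alphabet
#'   order.
#' @export
onehot_encode <- function(sequence) {
  chars <- check_sequence(sequence)
  m <- matrix(0, nrow = length(chars), ncol = length(GG_AA_ALPHABET),
              dimnames = list(NULL, GG_AA_ALPHABET))
  m[cbind(seq_along(chars), match(chars, GG_AA_ALPHABET))] <- 1
  m
}

#' Overlapping k-mer count encoding
#'
#' @param sequence Residue string (length at least `k`).
#' @param k K-mer size (>= 1).
#' @return Numeric vector of length `21^k` (named by k-mer for `k <= 3`);
#'   entries sum to `L - k + 1`.
#' @export
kmer_encode <- function(sequence, k) {
  chars <- check_sequence(sequence)
  gg_assert(k >= 1, "k must be >= 1")
  L <- length(chars)
  if (L < k) {
    gg_stop(sprintf("sequence length %d is shorter than k = %d", L, k),
            "gluegen_length_error")
  }
  nA <- length(GG_AA_ALPHABET)
  idx <- match(chars, GG_AA_ALPHABET) - 1
  # base-21 positional code of each window
  codes <- vapply(seq_len(L - k + 1), function(s) {
    sum(idx[s:(s + k - 1)] * nA^((k - 1):0)) + 1
  }, numeric(1))
  v <- numeric(nA^k)
  for (cd in codes) v[cd] <- v[cd] + 1
  if (k <= 3) {
    grid <- do.call(expand.grid, c(rep(list(GG_AA_ALPHABET), k),
                                   stringsAsFactors = FALSE))[, k:1, drop = FALSE]
    names(v) <- do.call(paste0, grid)
  }
  v
}

# ---- BiLSTM refinement (forward inference; parameters seeded or supplied) --

lstm_params <- function(E, H, seed) {
  with_seed(seed, {
    make_dir <- function() list(
      Wx = xavier(4 * H, E), Wh = xavier(4 * H, H), b = numeric(4 * H)
    )
    list(forward = make_dir(), backward = make_dir(), H = H, E = E)
  })
}

lstm_run <- function(X, p, H) {
  L <- nrow(X)
  h <- numeric(H); cc <- numeric(H)
  out <- matrix(0, L, H)
  for (t in seq_len(L)) {
    g <- as.vector(p$Wx %*% X[t, ] + p$Wh %*% h + p$b)
    i <- sigmoid(g[1:H]); f <- sigmoid(g[(H + 1):(2 * H)])
    o <- sigmoid(g[(2 * H + 1):(3 * H)]); u <- tanh(g[(3 * H + 1):(4 * H)])
    cc <- f * cc + i * u
    h <- o * tanh(cc)
    out[t, ] <- h
  }
  out
}

#' Bidirectional recurrent refinement of per-residue embeddings
#'
#' Runs a forward and a backward LSTM pass over the rows of `embedding_rows`
#' and concatenates the per-position states. Parameters are a pure function
#' of `seed` (Xavier-normal weights, zero biases), so the refinement is a
#' deterministic reparameterization, not a trained layer.
#'
#' @param embedding_rows `L x E` matrix of per-residue features.
#' @param seed Parameter seed.
#' @param hidden Per-direction state width `H` (default 32).
#' @param params Optional explicit parameter list (as built internally);
#'   overrides `seed`.
#' @return `L x 2H` matrix: forward states in columns `1..H`, backward states
#'   in `H+1..2H`.
#' @export
refine_recurrent <- function(embedding_rows, seed = 1L, hidden = 32L,
                             params = NULL) {
  X <- as.matrix(embedding_rows)
  gg_assert(nrow(X) >= 1, "embedding_rows must have at least one row")
  p <- params %||% lstm_params(ncol(X), hidden, seed)
  H <- p$H
  fw <- lstm_run(X, p$forward, H)
  bw <- lstm_run(X[rev(seq_len(nrow(X))), , drop = FALSE], p$backward, H)
  cbind(fw, bw[rev(seq_len(nrow(X))), , drop = FALSE])
}

#' Project an embedding to a fixed output length
#'
#' Matrices are mean-pooled over positions (rows) first, then mapped by a
#' seeded affine layer (Xavier-normal weights, zero bias).
#'
#' @param embedding Numeric vector or `L x E` matrix.
#' @param d_out Output length (128 or 512 in the default configurations).
#' @param seed Parameter seed.
#' @return Numeric vector of length `d_out`.
#' @export
project_fixed <- function(embedding, d_out, seed = 1L) {
  gg_assert(length(embedding) > 0, "embedding must be non-empty")
  v <- if (is.matrix(embedding)) colMeans(embedding) else as.numeric(embedding)
  W <- with_seed(seed + 7919L, xavier(d_out, length(v)))
  as.vector(W %*% v)
}

# ---- pluggable pretrained embedder adapter ----

gg_adapter_env <- new.env(parent = emptyenv())

#' Register or clear an external per-residue protein embedder
#'
#' The package bundles no pretrained protein language model; users may plug
#' one in by registering a function `sequence -> L x E matrix`.
#' @param fun Function of one argument returning an `L x E` matrix, or
#'   `NULL` to clear.
#' @export
register_protein_embedder <- function(fun) {
  gg_assert(is.null(fun) || is.function(fun), "fun must be a function or NULL")
  assign("embedder", fun, envir = gg_adapter_env)
  invisible(fun)
}

#' Per-residue embedding via the registered external embedder
#'
#' @param sequence Residue string.
#' @return `L x E` matrix from the registered embedder.
#' @details Raises `gluegen_adapter_missing_error` when no embedder is
#'   registered; the default encoder configurations use the one-hot or k-mer
#'   schemes instead.
#' @export
pretrained_adapter <- function(sequence) {
  chars <- check_sequence(sequence)
  fun <- if (exists("embedder", envir = gg_adapter_env)) {
    get("embedder", envir = gg_adapter_env)
  } else NULL
  if (is.null(fun)) {
    gg_stop("no external protein embedder registered; use register_protein_embedder()",
            "gluegen_adapter_missing_error")
  }
  out <- fun(sequence)
  gg_assert(is.matrix(out) && nrow(out) == length(chars),
            "registered embedder must return an L x E matrix")
  out
}

#' Encoder configuration for ligase contexts
#'
#' @param scheme One of `"onehot"`, `"kmer"`, `"pretrained_adapter"`.
#' @param k K-mer size (k-mer scheme only; default 3).
#' @param use_recurrent_refinement Apply the BiLSTM refinement to per-position
#'   encodings (matrix schemes only).
#' @param d_out Embedding width, 128 or 512.
#' @param seed Parameter seed shared by refinement and projection.
#' @return An `gg_encoder_config` list.
#' @export
encoder_config <- function(scheme = c("kmer", "onehot", "pretrained_adapter"),
                           k = 3L, use_recurrent_refinement = FALSE,
                           d_out = 128L, seed = 1L) {
  scheme <- match.arg(scheme)
  gg_assert(d_out %in% c(128L, 512L) || d_out > 0,
            "d_out must be a positive integer")
  structure(list(scheme = scheme, k = as.integer(k),
                 use_recurrent_refinement = isTRUE(use_recurrent_refinement),
                 d_out = as.integer(d_out), seed = as.integer(seed)),
            class = "gg_encoder_config")
}

#' Build a ligase conditioning context
#'
#' Encodes a binding-site residue sequence with the configured scheme,
#' optionally refines per-position encodings with the bidirectional
#' recurrent pass, and projects to a fixed-length embedding.
#'
#' @param ligase_id Label, e.g. `"CRBN"`, `"VHL"`, `"MDM2"`.
#' @param sequence Residue string.
#' @param config An [encoder_config()].
#' @return A `gg_ligase_context` with `ligase_id`, `sequence`, `embedding`
#'   (length `d_out`) and the per-position `rows` matrix when the scheme
#'   produces one (used by the cross-attention fusion).
#' @export
ligase_context <- function(ligase_id, sequence, config = encoder_config()) {
  check_sequence(sequence)
  rows <- NULL
  enc <- switch(config$scheme,
    onehot = onehot_encode(sequence),
    kmer = kmer_encode(sequence, config$k),
    pretrained_adapter = pretrained_adapter(sequence)
  )
  if (is.matrix(enc)) {
    if (config$use_recurrent_refinement) {
      enc <- refine_recurrent(enc, seed = config$seed)
    }
    rows <- enc
  }
  emb <- project_fixed(enc, config$d_out, seed = config$seed)
  structure(list(ligase_id = ligase_id, sequence = sequence,
                 embedding = emb, rows = rows, config = config),
            class = "gg_ligase_context")
}

#' @export
print.gg_ligase_context <- function(x, ...) {
  cat(sprintf("<gg_ligase_context %s> %d residues -> %dD (%s%s)\n",
              x$ligase_id, nchar(x$sequence), length(x$embedding),
              x$config$scheme,
              if (x$config$use_recurrent_refinement) "+bilstm" else ""))
  invisible(x)
}

#' Read ligase binding-site sequences from FASTA
#'
#' @param path FASTA file; record ids are used as ligase ids.
#' @param config An [encoder_config()] applied to every record.
#' @return Named list of `gg_ligase_context` objects.
#' @export
read_ligase_fasta <- function(path, config = encoder_config()) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    ligase_context(ids[i], as.character(seqs[[i]]), config)
  })
  setNames(out, ids)
}
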