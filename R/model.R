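# Conditioned junction-tree VAE: model configuration, parameter container,
# message-passing encoders (atom graph + junction tree), Gaussian latent
# heads, reparameterization, the two latent-fusion strategies, and the
# beta-weighted loss. Gradients for every trainable component are written by
# hand; the whole model is plain matrices, no external framework.

#' Model configuration
#'
#' @param hidden Message/hidden width of both message-passing encoders.
#' @param d_tree,d_graph Widths of the tree and graph latent branches; the
#'   molecular latent is their concatenation.
#' @param d_fused Width of the fused (conditioned) latent fed to the decoders.
#' @param d_seq Width of the ligase conditioning embedding.
#' @param mpn_iters Message-passing iterations (default 3).
#' @param dec_hidden Decoder RNN state width.
#' @param label_embed Label-embedding width in the tree decoder.
#' @param fusion `"concat_linear_relu"` or `"cross_attention"`.
#' @param n_heads Attention heads (cross-attention only; must divide
#'   `d_tree + d_graph`).
#' @param d_attn Per-head key/value width for cross-attention.
#' @return A `gg_model_config` list.
#' @export
model_config <- function(hidden = 32L, d_tree = 28L, d_graph = 28L,
                         d_fused = 56L, d_seq = 128L, mpn_iters = 3L,
                         dec_hidden = 64L, label_embed = 32L,
                         fusion = c("concat_linear_relu", "cross_attention"),
                         n_heads = 4L, d_attn = 16L) {
  fusion <- match.arg(fusion)
  cfg <- list(hidden = as.integer(hidden), d_tree = as.integer(d_tree),
              d_graph = as.integer(d_graph), d_fused = as.integer(d_fused),
              d_seq = as.integer(d_seq), mpn_iters = as.integer(mpn_iters),
              dec_hidden = as.integer(dec_hidden),
              label_embed = as.integer(label_embed), fusion = fusion,
              n_heads = as.integer(n_heads), d_attn = as.integer(d_attn),
              n_atom_feat = length(GG_ATOM_FEATURES),
              n_bond_feat = length(GG_BOND_FEATURES),
              n_attach_feat = 24L, attach_hidden = 32L)
  gg_assert((cfg$d_tree + cfg$d_graph) %% cfg$n_heads == 0,
            "n_heads must divide d_tree + d_graph")
  structure(cfg, class = "gg_model_config")
}

#' Initialize model parameters
#'
#' Xavier-normal weights, zero biases (and zero label embeddings are replaced
#' by small Xavier draws), all drawn from the given seed.
#'
#' @param vocab A `gg_vocabulary`.
#' @param cfg A [model_config()].
#' @param seed Integer seed.
#' @return Named list of parameter matrices/vectors (`gg_params`).
#' @export
model_params <- function(vocab, cfg, seed = 1L) {
  V <- length(vocab$labels)
  h <- cfg$hidden; A <- cfg$n_atom_feat; B <- cfg$n_bond_feat
  dm <- cfg$d_tree + cfg$d_graph
  with_seed(seed, {
    p <- list(
      # atom-graph MPN
      gW1 = xavier(h, A), gW2 = xavier(h, B), gW3 = xavier(h, h), gbm = numeric(h),
      gU1 = xavier(h, A), gU2 = xavier(h, h), gbU = numeric(h),
      gWm = xavier(cfg$d_graph, h), gbmean = numeric(cfg$d_graph),
      gWv = xavier(cfg$d_graph, h), gbvar = numeric(cfg$d_graph),
      # junction-tree MPN (node features = label one-hot, edge feature = shared count)
      tW1 = xavier(h, V), tW2 = xavier(h, 1), tW3 = xavier(h, h), tbm = numeric(h),
      tU1 = xavier(h, V), tU2 = xavier(h, h), tbU = numeric(h),
      tWm = xavier(cfg$d_tree, h), tbmean = numeric(cfg$d_tree),
      tWv = xavier(cfg$d_tree, h), tbvar = numeric(cfg$d_tree),
      # decoder RNN
      Wzh = xavier(cfg$dec_hidden, cfg$d_fused), bzh = numeric(cfg$dec_hidden),
      Whh = xavier(cfg$dec_hidden, cfg$dec_hidden),
      Whx = xavier(cfg$dec_hidden, cfg$label_embed),
      Whz = xavier(cfg$dec_hidden, cfg$d_fused), bh = numeric(cfg$dec_hidden),
      Elab = xavier(cfg$label_embed, V),
      Wl = xavier(V, cfg$dec_hidden), Wlz = xavier(V, cfg$d_fused), bl = numeric(V),
      wd = rnorm(cfg$dec_hidden, sd = sqrt(2 / cfg$dec_hidden)),
      wdz = rnorm(cfg$d_fused, sd = sqrt(2 / cfg$d_fused)), bd = 0,
      # attachment scorer
      Ws = xavier(cfg$attach_hidden, cfg$d_fused + cfg$n_attach_feat),
      bs = numeric(cfg$attach_hidden),
      w2 = rnorm(cfg$attach_hidden, sd = sqrt(2 / cfg$attach_hidden))
    )
    if (cfg$fusion == "concat_linear_relu") {
      p$fW <- xavier(cfg$d_fused, dm + cfg$d_seq)
      p$fb <- numeric(cfg$d_fused)
    } else {
      qd <- dm / cfg$n_heads
      p$aWq <- xavier(cfg$d_attn, qd)
      p$aWk <- xavier(cfg$d_attn, cfg$d_seq)
      p$aWv <- xavier(cfg$d_attn, cfg$d_seq)
      p$aWo <- xavier(cfg$d_fused, cfg$d_attn * cfg$n_heads)
      p$abo <- numeric(cfg$d_fused)
    }
    p
  })
}

zero_like <- function(params) lapply(params, function(x) x * 0)

# ---- generic edge-wise message-passing network ----
# X: n x A node features; E: m x B bond features (one row per undirected
# edge); edges: m x 2. Messages live on 2m directed edges; T iterations of
#   m_uv <- ReLU(W1 x_u + W2 e_uv + W3 * sum_{w in N(u) \ v} m_wu + b)
# then node readout h_v = ReLU(U1 x_v + U2 sum_in m + bU) and sum pooling.
mpn_forward <- function(X, E, edges, W1, W2, W3, bm, U1, U2, bU, iters) {
  n <- nrow(X); m <- nrow(E); h <- nrow(W1)
  if (m > 0) {
    esrc <- c(edges[, 1], edges[, 2])
    edst <- c(edges[, 2], edges[, 1])
    erev <- c(seq_len(m) + m, seq_len(m))
    Edir <- rbind(E, E)
    P <- X[esrc, , drop = FALSE] %*% t(W1) + Edir %*% t(W2) +
      matrix(bm, 2 * m, h, byrow = TRUE)
    Ms <- vector("list", iters + 1)
    Ms[[1]] <- matrix(0, 2 * m, h)
    for (t in seq_len(iters)) {
      nin <- node_group_sum(Ms[[t]], edst, n)
      Agg <- nin[esrc, , drop = FALSE] - Ms[[t]][erev, , drop = FALSE]
      Ms[[t + 1]] <- relu(P + Agg %*% t(W3))
    }
    node_msg <- node_group_sum(Ms[[iters + 1]], edst, n)
  } else {
    esrc <- edst <- erev <- integer(0)
    Edir <- matrix(0, 0, ncol(E))
    Ms <- list(matrix(0, 0, h))
    node_msg <- matrix(0, n, h)
  }
  Hpre <- X %*% t(U1) + node_msg %*% t(U2) + matrix(bU, n, h, byrow = TRUE)
  Hn <- relu(Hpre)
  out <- colSums(Hn)
  list(out = out, cache = list(X = X, Edir = Edir, esrc = esrc, edst = edst,
                               erev = erev, Ms = Ms, node_msg = node_msg,
                               Hn = Hn, n = n, m = m, iters = iters))
}

node_group_sum <- function(M, idx, n) {
  out <- matrix(0, n, ncol(M))
  if (nrow(M)) {
    tmp <- rowsum(M, group = idx)
    out[as.integer(rownames(tmp)), ] <- tmp
  }
  out
}

# dOut: gradient wrt the pooled output vector. Returns parameter gradients.
mpn_backward <- function(cache, dOut, W1, W2, W3, U1, U2, iters) {
  n <- cache$n; m <- cache$m
  h <- length(dOut)
  dHn <- matrix(dOut, n, h, byrow = TRUE) * (cache$Hn > 0)
  dU1 <- t(dHn) %*% cache$X
  dU2 <- t(dHn) %*% cache$node_msg
  dbU <- colSums(dHn)
  g <- list(W1 = W1 * 0, W2 = W2 * 0, W3 = W3 * 0, bm = numeric(h),
            U1 = dU1, U2 = dU2, bU = dbU)
  if (m > 0) {
    dnode_msg <- dHn %*% U2
    dM <- dnode_msg[cache$edst, , drop = FALSE]
    for (t in rev(seq_len(iters))) {
      Mt1 <- cache$Ms[[t + 1]]
      dMpre <- dM * (Mt1 > 0)
      nin <- node_group_sum(cache$Ms[[t]], cache$edst, n)
      Agg <- nin[cache$esrc, , drop = FALSE] - cache$Ms[[t]][cache$erev, , drop = FALSE]
      g$W1 <- g$W1 + t(dMpre) %*% cache$X[cache$esrc, , drop = FALSE]
      g$W2 <- g$W2 + t(dMpre) %*% cache$Edir
      g$W3 <- g$W3 + t(dMpre) %*% Agg
      g$bm <- g$bm + colSums(dMpre)
      if (t > 1) {
        dAgg <- dMpre %*% W3
        dnodeagg <- node_group_sum(dAgg, cache$esrc, n)
        dM <- dnodeagg[cache$edst, , drop = FALSE] - dAgg[cache$erev, , drop = FALSE]
      }
    }
  }
  g
}

tree_node_features <- function(jtree, vocab) {
  V <- length(vocab$labels)
  nn <- length(jtree$nodes)
  X <- matrix(0, nn, V)
  for (i in seq_len(nn)) {
    lab <- jtree$nodes[[i]]$label
    j <- vocab$label_to_index[lab]
    if (is.na(j)) {
      gg_stop(sprintf("clique label '%s' not in vocabulary", lab),
              "gluegen_vocabulary_error")
    }
    X[i, j] <- 1
  }
  X
}

tree_edge_features <- function(jtree) {
  ne <- nrow(jtree$edges)
  E <- matrix(0, ne, 1)
  for (k in seq_len(ne)) {
    i <- jtree$edges[k, 1]; j <- jtree$edges[k, 2]
    ai <- jtree$nodes[[i]]$atom_indices; aj <- jtree$nodes[[j]]$atom_indices
    E[k, 1] <- if (is.null(ai) || is.null(aj)) 1 else length(intersect(ai, aj))
  }
  E
}

#' Encode a molecule into latent Gaussian parameters
#'
#' Runs the atom-graph and junction-tree message-passing encoders and the
#' affine latent heads.
#'
#' @param graph A `gg_graph` from [mol_to_graph()].
#' @param jtree The matching `gg_jtree`.
#' @param vocab Vocabulary covering all tree labels
#'   (`gluegen_vocabulary_error` otherwise).
#' @param params Model parameters ([model_params()]).
#' @param cfg The [model_config()] the parameters were built with.
#' @return A `gg_latent` list with `t_mean`, `t_logvar`, `g_mean`,
#'   `g_logvar` (and `caches` for backpropagation).
#' @export
encode <- function(graph, jtree, vocab, params, cfg) {
  fg <- mpn_forward(graph$atom_features, graph$bond_features, graph$adjacency,
                    params$gW1, params$gW2, params$gW3, params$gbm,
                    params$gU1, params$gU2, params$gbU, cfg$mpn_iters)
  Xt <- tree_node_features(jtree, vocab)
  Et <- tree_edge_features(jtree)
  edges_t <- jtree$edges
  ft <- mpn_forward(Xt, Et, edges_t,
                    params$tW1, params$tW2, params$tW3, params$tbm,
                    params$tU1, params$tU2, params$tbU, cfg$mpn_iters)
  structure(list(
    t_mean = as.vector(params$tWm %*% ft$out + params$tbmean),
    t_logvar = as.vector(params$tWv %*% ft$out + params$tbvar),
    g_mean = as.vector(params$gWm %*% fg$out + params$gbmean),
    g_logvar = as.vector(params$gWv %*% fg$out + params$gbvar),
    caches = list(graph = fg$cache, tree = ft$cache,
                  h_graph = fg$out, h_tree = ft$out)
  ), class = "gg_latent")
}

#' Sample a latent vector by reparameterization
#'
#' `z = mean + exp(logvar / 2) * eps`, `eps ~ N(0, I)` from the seeded
#' stream.
#' @param mean,logvar Equal-length numeric vectors.
#' @param seed Integer seed (identical seeds give identical draws).
#' @return List with `z` and the noise `eps` (needed for backpropagation).
#' @export
reparameterize <- function(mean, logvar, seed) {
  gg_assert(length(mean) == length(logvar), "mean and logvar lengths differ")
  eps <- with_seed(seed, rnorm(length(mean)))
  list(z = mean + exp(logvar / 2) * eps, eps = eps)
}

#' Fuse the molecular latent with the ligase embedding
#'
#' Concatenation strategy: `z_fused = ReLU(W [z_mol; z_seq] + b)`.
#' Cross-attention strategy: `z_mol` is split into `n_heads` query blocks
#' that attend over the positions (rows) of `z_seq`; head outputs are
#' concatenated and affine-projected to the fused width.
#'
#' @param z_mol Molecular latent vector (tree and graph branches
#'   concatenated).
#' @param z_seq Ligase conditioning: a vector (one position) or an
#'   `L x E` matrix of positions for cross-attention.
#' @param params Model parameters.
#' @param cfg Model configuration (selects the strategy).
#' @return List with `z_fused` and a `cache` for backpropagation.
#' @export
fuse <- function(z_mol, z_seq, params, cfg) {
  if (cfg$fusion == "concat_linear_relu") {
    zs <- as.numeric(z_seq)
    if (length(z_mol) + length(zs) != ncol(params$fW)) {
      gg_stop("fusion dimensions do not match parameters", "gluegen_dimension_error")
    }
    a <- c(z_mol, zs)
    pre <- as.vector(params$fW %*% a + params$fb)
    list(z_fused = relu(pre), cache = list(a = a, pre = pre))
  } else {
    S <- if (is.matrix(z_seq)) z_seq else matrix(z_seq, nrow = 1)
    nh <- cfg$n_heads
    qd <- length(z_mol) / nh
    if (qd != ncol(params$aWq) || ncol(S) != ncol(params$aWk)) {
      gg_stop("attention dimensions do not match parameters", "gluegen_dimension_error")
    }
    K <- S %*% t(params$aWk)                    # L x dk
    Vv <- S %*% t(params$aWv)                   # L x dv
    heads <- vector("list", nh)
    alphas <- vector("list", nh)
    qs <- vector("list", nh)
    for (i in seq_len(nh)) {
      q <- as.vector(params$aWq %*% z_mol[((i - 1) * qd + 1):(i * qd)])
      al <- softmax(as.vector(K %*% q) / sqrt(ncol(K)))
      heads[[i]] <- as.vector(t(Vv) %*% al)
      alphas[[i]] <- al
      qs[[i]] <- q
    }
    o <- unlist(heads)
    zf <- as.vector(params$aWo %*% o + params$abo)
    list(z_fused = zf, cache = list(S = S, K = K, V = Vv, alphas = alphas,
                                    qs = qs, o = o, qd = qd))
  }
}

fuse_backward <- function(dz, z_mol, params, cfg, cache, grads) {
  if (cfg$fusion == "concat_linear_relu") {
    dpre <- dz * (cache$pre > 0)
    grads$fW <- grads$fW + outer(dpre, cache$a)
    grads$fb <- grads$fb + dpre
    dzmol <- as.vector(t(params$fW) %*% dpre)[seq_along(z_mol)]
  } else {
    nh <- cfg$n_heads; qd <- cache$qd
    grads$aWo <- grads$aWo + outer(dz, cache$o)
    grads$abo <- grads$abo + dz
    do <- as.vector(t(params$aWo) %*% dz)
    dzmol <- numeric(length(z_mol))
    dk <- ncol(cache$K)
    for (i in seq_len(nh)) {
      doi <- do[((i - 1) * dk + 1):(i * dk)]
      al <- cache$alphas[[i]]
      # head output o_i = V^T alpha with V = S Wv^T
      dV <- outer(al, doi)                       # L x dv
      grads$aWv <- grads$aWv + t(dV) %*% cache$S
      dal <- as.vector(cache$V %*% doi)
      ds <- al * (dal - sum(al * dal))           # softmax jacobian
      dq <- as.vector(t(cache$K) %*% ds) / sqrt(dk)
      dK <- outer(ds, cache$qs[[i]]) / sqrt(dk)  # L x dk
      grads$aWk <- grads$aWk + t(dK) %*% cache$S
      idx <- ((i - 1) * qd + 1):(i * qd)
      grads$aWq <- grads$aWq + outer(dq, z_mol[idx])
      dzmol[idx] <- as.vector(t(params$aWq) %*% dq)
    }
  }
  list(dzmol = dzmol, grads = grads)
}

#' Kullback-Leibler divergence of the diagonal Gaussian posterior
#'
#' Closed form against the standard normal prior:
#' `-0.5 * sum(1 + logvar - mean^2 - exp(logvar))`.
#' @param means,logvars Equal-length numeric vectors (tree and graph
#'   branches concatenated).
#' @return Non-negative scalar.
#' @export
kl_term <- function(means, logvars) {
  gg_assert(length(means) == length(logvars), "means and logvars lengths differ")
  -0.5 * sum(1 + logvars - means^2 - exp(logvars))
}

#' Assemble the beta-weighted loss
#'
#' @param recon_tree,recon_graph Non-negative reconstruction terms.
#' @param kl KL divergence term.
#' @param beta Annealing coefficient in `[0, 1]`.
#' @return A `gg_loss_terms` list with `total = recon_tree + recon_graph +
#'   beta * kl`.
#' @export
loss_total <- function(recon_tree, recon_graph, kl, beta) {
  gg_assert(beta >= 0 && beta <= 1, "beta must lie in [0, 1]")
  structure(list(recon_tree = recon_tree, recon_graph = recon_graph,
                 kl = kl, beta = beta,
                 total = recon_tree + recon_graph + beta * kl),
            class = "gg_loss_terms")
}
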