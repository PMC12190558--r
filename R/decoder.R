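# Conditional decoding: depth-first tree decoder (recurrent topology + label
# heads) and graph decoder (enumeration and scoring of chemically valid
# inter-clique attachments), plus the teacher-forced losses and gradients
# used in training.

# ---- teacher-forced decode sequence -------------------------------------

tree_children <- function(jtree) {
  nn <- length(jtree$nodes)
  adj <- vector("list", nn)
  for (k in seq_len(nrow(jtree$edges))) {
    i <- jtree$edges[k, 1]; j <- jtree$edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  parent <- rep(NA_integer_, nn)
  order <- integer(0)
  stack <- 1L
  seen <- logical(nn)
  seen[1] <- TRUE
  children <- vector("list", nn)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    kids <- as.integer(sort(adj[[v]]))
    kids <- kids[!seen[kids]]
    children[[v]] <- kids
    seen[kids] <- TRUE
    parent[kids] <- v
    stack <- c(stack, rev(kids))
  }
  list(children = children, parent = parent, dfs = order)
}

# Events of the depth-first generation grammar for one tree:
#   label(root) from the initial state, then per node: one expand decision
#   (+ child label) per child, and a final backtrack decision.
build_decode_sequence <- function(jtree, vocab) {
  topo <- tree_children(jtree)
  labels <- vapply(jtree$nodes, `[[`, "", "label")
  lab_idx <- unname(vocab$label_to_index[labels])
  events <- list(list(type = "label", state = 0L, target = lab_idx[1]))
  inputs <- integer(0) # RNN input label index per step
  walk <- function(v) {
    for (c_ in topo$children[[v]]) {
      inputs[[length(inputs) + 1]] <<- lab_idx[v]
      s <- length(inputs)
      events[[length(events) + 1]] <<- list(type = "topo", state = s, target = 1)
      events[[length(events) + 1]] <<- list(type = "label", state = s,
                                            target = lab_idx[c_])
      walk(c_)
    }
    inputs[[length(inputs) + 1]] <<- lab_idx[v]
    events[[length(events) + 1]] <<- list(type = "topo",
                                          state = length(inputs), target = 0)
  }
  walk(1L)
  list(events = events, inputs = inputs, lab_idx = lab_idx, topo = topo)
}

decoder_states <- function(z, inputs, params) {
  hd <- length(params$bzh)
  S <- length(inputs)
  H <- matrix(0, S + 1, hd)
  H[1, ] <- tanh(as.vector(params$Wzh %*% z + params$bzh))
  zc <- as.vector(params$Whz %*% z + params$bh)
  for (s in seq_len(S)) {
    pre <- as.vector(params$Whh %*% H[s, ]) +
      as.vector(params$Whx %*% params$Elab[, inputs[s]]) + zc
    H[s + 1, ] <- tanh(pre)
  }
  H # row s+1 = state after step s; row 1 = initial state
}

# Teacher-forced decoder pass: losses, per-event correctness, gradients.
decoder_teacher_forward <- function(z, seqinfo, params, want_grads = TRUE) {
  H <- decoder_states(z, seqinfo$inputs, params)
  V <- nrow(params$Wl)
  loss_label <- 0; loss_topo <- 0
  n_lab <- 0; n_lab_ok <- 0; n_topo <- 0; n_topo_ok <- 0
  S <- length(seqinfo$inputs)
  dH <- matrix(0, S + 1, ncol(H))
  dz <- numeric(length(z))
  g <- list(Wl = params$Wl * 0, Wlz = params$Wlz * 0, bl = numeric(V),
            wd = params$wd * 0, wdz = params$wdz * 0, bd = 0)
  zl <- as.vector(params$Wlz %*% z)
  zd <- sum(params$wdz * z)
  for (ev in seqinfo$events) {
    hrow <- ev$state + 1
    hvec <- H[hrow, ]
    if (ev$type == "label") {
      u <- as.vector(params$Wl %*% hvec) + zl + params$bl
      p <- softmax(u)
      loss_label <- loss_label - log(max(p[ev$target], 1e-12))
      n_lab <- n_lab + 1
      if (which.max(u) == ev$target) n_lab_ok <- n_lab_ok + 1
      if (want_grads) {
        du <- p; du[ev$target] <- du[ev$target] - 1
        g$Wl <- g$Wl + outer(du, hvec)
        g$Wlz <- g$Wlz + outer(du, z)
        g$bl <- g$bl + du
        dH[hrow, ] <- dH[hrow, ] + as.vector(t(params$Wl) %*% du)
        dz <- dz + as.vector(t(params$Wlz) %*% du)
      }
    } else {
      l <- sum(params$wd * hvec) + zd + params$bd
      p <- sigmoid(l)
      loss_topo <- loss_topo - (ev$target * log(max(p, 1e-12)) +
                                  (1 - ev$target) * log(max(1 - p, 1e-12)))
      n_topo <- n_topo + 1
      if ((p >= 0.5) == (ev$target == 1)) n_topo_ok <- n_topo_ok + 1
      if (want_grads) {
        dl <- p - ev$target
        g$wd <- g$wd + dl * hvec
        g$wdz <- g$wdz + dl * z
        g$bd <- g$bd + dl
        dH[hrow, ] <- dH[hrow, ] + dl * params$wd
        dz <- dz + dl * params$wdz
      }
    }
  }
  if (want_grads) {
    # BPTT
    g$Whh <- params$Whh * 0; g$Whx <- params$Whx * 0; g$Whz <- params$Whz * 0
    g$bh <- numeric(ncol(H)); g$Elab <- params$Elab * 0
    g$Wzh <- params$Wzh * 0; g$bzh <- numeric(ncol(H))
    carry <- numeric(ncol(H))
    for (s in rev(seq_len(S))) {
      dh <- dH[s + 1, ] + carry
      dpre <- dh * (1 - H[s + 1, ]^2)
      g$Whh <- g$Whh + outer(dpre, H[s, ])
      xin <- params$Elab[, seqinfo$inputs[s]]
      g$Whx <- g$Whx + outer(dpre, xin)
      g$Whz <- g$Whz + outer(dpre, z)
      g$bh <- g$bh + dpre
      g$Elab[, seqinfo$inputs[s]] <- g$Elab[, seqinfo$inputs[s]] +
        as.vector(t(params$Whx) %*% dpre)
      dz <- dz + as.vector(t(params$Whz) %*% dpre)
      carry <- as.vector(t(params$Whh) %*% dpre)
    }
    dh0 <- dH[1, ] + carry
    dpre0 <- dh0 * (1 - H[1, ]^2)
    g$Wzh <- g$Wzh + outer(dpre0, z)
    g$bzh <- g$bzh + dpre0
    dz <- dz + as.vector(t(params$Wzh) %*% dpre0)
  }
  list(loss_label = loss_label, loss_topo = loss_topo,
       wacc_num = n_lab_ok, wacc_den = n_lab,
       tacc_num = n_topo_ok, tacc_den = n_topo,
       grads = if (want_grads) g else NULL, dz = dz)
}

# ---- label compatibility for constrained generation ---------------------

# Two clique labels are attachment-compatible when some atom of one can be
# identified with some atom of the other: same element and charge, combined
# kekulized bond order within the element's valence limit.
vocab_compat_matrix <- function(vocab) {
  V <- length(vocab$labels)
  frag_order_sums <- lapply(vocab$fragments, function(f) {
    n <- length(f$elements)
    os <- numeric(n)
    if (nrow(f$bonds)) for (k in seq_len(nrow(f$bonds))) {
      os[f$bonds$a1[k]] <- os[f$bonds$a1[k]] + f$bonds$order[k]
      os[f$bonds$a2[k]] <- os[f$bonds$a2[k]] + f$bonds$order[k]
    }
    os
  })
  M <- matrix(FALSE, V, V)
  for (i in seq_len(V)) for (j in i:V) {
    fi <- vocab$fragments[[vocab$labels[i]]]
    fj <- vocab$fragments[[vocab$labels[j]]]
    osi <- frag_order_sums[[vocab$labels[i]]]
    osj <- frag_order_sums[[vocab$labels[j]]]
    ok <- FALSE
    for (a in seq_along(fi$elements)) {
      lim <- GG_MAX_VALENCE[fi$elements[a]] %||% 4
      if (is.na(lim)) lim <- 4
      match_b <- which(fj$elements == fi$elements[a] & fj$charges == fi$charges[a])
      if (any(osi[a] + osj[match_b] <= lim)) { ok <- TRUE; break }
    }
    M[i, j] <- M[j, i] <- ok
  }
  M
}

#' Decode a junction tree from a fused latent vector
#'
#' Depth-first generation: at each step a topology head decides expand vs
#' backtrack and a label head picks a vocabulary clique compatible with the
#' current node; generation stops when the root backtracks or `max_nodes` is
#' reached (recorded in `$truncated`).
#'
#' @param z_fused Fused latent vector.
#' @param vocab A `gg_vocabulary` (with the label-compatibility matrix
#'   attached by [prepare_dataset()], or computed on the fly).
#' @param params Model parameters.
#' @param cfg Model configuration.
#' @param max_nodes Node budget (default 60).
#' @param temperature 0 (default) for greedy argmax decoding; positive values
#'   sample topology and labels from the tempered distributions using the
#'   caller's RNG stream.
#' @return A `gg_jtree` whose nodes carry vocabulary fragments (no global
#'   atom indices until [decode_graph()] assembles them).
#' @export
decode_tree <- function(z_fused, vocab, params, cfg, max_nodes = 60L,
                        temperature = 0) {
  compat <- vocab$compat %||% vocab_compat_matrix(vocab)
  V <- length(vocab$labels)
  hd <- length(params$bzh)
  zc <- as.vector(params$Whz %*% z_fused + params$bh)
  zl <- as.vector(params$Wlz %*% z_fused)
  zd <- sum(params$wdz * z_fused)
  h <- tanh(as.vector(params$Wzh %*% z_fused + params$bzh))
  pick_label <- function(hvec, allowed) {
    u <- as.vector(params$Wl %*% hvec) + zl + params$bl
    u[!allowed] <- -Inf
    if (all(!is.finite(u))) return(NA_integer_)
    if (temperature > 0) {
      p <- softmax(u / temperature)
      sample.int(V, 1, prob = p)
    } else which.max(u)
  }
  decide_expand <- function(hvec) {
    l <- sum(params$wd * hvec) + zd + params$bd
    p <- sigmoid(if (temperature > 0) l / temperature else l)
    if (temperature > 0) runif(1) < p else p >= 0.5
  }
  root_lab <- pick_label(h, rep(TRUE, V))
  nodes_lab <- root_lab
  edges <- matrix(integer(0), ncol = 2)
  stack <- 1L
  truncated <- FALSE
  hist <- list(h) # state stack not needed; single running state
  guard <- 0
  while (length(stack) && guard < 4 * max_nodes + 8) {
    guard <- guard + 1
    v <- stack[length(stack)]
    # one RNN step with the current node's label as input
    pre <- as.vector(params$Whh %*% h) +
      as.vector(params$Whx %*% params$Elab[, nodes_lab[v]]) + zc
    h <- tanh(pre)
    expand <- decide_expand(h)
    if (expand && length(nodes_lab) >= max_nodes) {
      truncated <- TRUE
      expand <- FALSE
    }
    if (expand) {
      lab <- pick_label(h, compat[nodes_lab[v], ])
      if (is.na(lab)) {
        expand <- FALSE
      } else {
        nodes_lab <- c(nodes_lab, lab)
        cid <- length(nodes_lab)
        edges <- rbind(edges, c(v, cid))
        stack <- c(stack, cid)
      }
    }
    if (!expand) stack <- stack[-length(stack)]
  }
  nodes <- lapply(seq_along(nodes_lab), function(i) {
    lab <- vocab$labels[nodes_lab[i]]
    fr <- vocab$fragments[[lab]]
    list(index = i, atom_indices = NULL, label = lab, kind = fr$kind,
         frag_elements = fr$elements, frag_charges = fr$charges,
         frag_bonds = fr$bonds)
  })
  colnames(edges) <- c("node_i", "node_j")
  structure(list(mol_id = NA_character_, nodes = nodes, edges = edges,
                 smiles_canonical = NA_character_, truncated = truncated,
                 generated = TRUE),
            class = "gg_jtree")
}

# ---- attachment enumeration and assembly --------------------------------

# Partial assembly state: atom table + bond table (global), and for each
# placed tree node the global ids of its fragment atoms.
assembly_init <- function(node, node_idx = 1L) {
  n <- length(node$frag_elements)
  placement <- list()
  placement[[node_idx]] <- seq_len(n)
  list(elements = node$frag_elements, charges = node$frag_charges,
       bonds = node$frag_bonds[, c("a1", "a2", "order"), drop = FALSE],
       placement = placement)
}

assembly_order_sums <- function(state) {
  os <- numeric(length(state$elements))
  b <- state$bonds
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    os[b$a1[k]] <- os[b$a1[k]] + b$order[k]
    os[b$a2[k]] <- os[b$a2[k]] + b$order[k]
  }
  os
}

# Enumerate valid attachments of `child` onto the placed parent clique.
# Single-atom sharing for all kind pairs; two-atom (fused bond) sharing
# additionally for ring-ring pairs. Deterministic order.
enumerate_attachments <- function(state, parent_node_idx, parent_kind, child) {
  pg <- state$placement[[parent_node_idx]]     # global ids of parent clique
  os <- assembly_order_sums(state)
  cn <- length(child$frag_elements)
  cos <- numeric(cn)
  cb <- child$frag_bonds
  if (nrow(cb)) for (k in seq_len(nrow(cb))) {
    cos[cb$a1[k]] <- cos[cb$a1[k]] + cb$order[k]
    cos[cb$a2[k]] <- cos[cb$a2[k]] + cb$order[k]
  }
  lim <- function(el) { v <- GG_MAX_VALENCE[el]; if (is.na(v)) 4 else v }
  cands <- list()
  for (p in pg) for (ca in seq_len(cn)) {
    if (state$elements[p] != child$frag_elements[ca]) next
    if (state$charges[p] != child$frag_charges[ca]) next
    if (os[p] + cos[ca] > lim(state$elements[p])) next
    cands[[length(cands) + 1]] <- list(shared_parent = p, shared_child = ca)
  }
  if (parent_kind == "ring" && child$kind == "ring" && nrow(cb)) {
    pb <- state$bonds[state$bonds$a1 %in% pg & state$bonds$a2 %in% pg, , drop = FALSE]
    for (k in seq_len(nrow(pb))) for (kc in seq_len(nrow(cb))) {
      for (orient in 1:2) {
        p1 <- pb$a1[k]; p2 <- pb$a2[k]
        c1 <- if (orient == 1) cb$a1[kc] else cb$a2[kc]
        c2 <- if (orient == 1) cb$a2[kc] else cb$a1[kc]
        if (state$elements[p1] != child$frag_elements[c1] ||
            state$elements[p2] != child$frag_elements[c2]) next
        if (state$charges[p1] != child$frag_charges[c1] ||
            state$charges[p2] != child$frag_charges[c2]) next
        if (pb$order[k] != cb$order[kc]) next
        ok1 <- os[p1] + cos[c1] - 2 * cb$order[kc] <= lim(state$elements[p1])
        ok2 <- os[p2] + cos[c2] - 2 * cb$order[kc] <= lim(state$elements[p2])
        if (ok1 && ok2) {
          cands[[length(cands) + 1]] <- list(shared_parent = c(p1, p2),
                                             shared_child = c(c1, c2))
        }
      }
    }
  }
  cands
}

# BFS distance (capped) from a start atom to the nearest heteroatom within
# an induced subgraph; discriminates attachment positions on heterocycles.
hetero_distance <- function(elements, bonds, subset, start, cap = 4L) {
  if (elements[start] != "C") return(0L)
  insub <- rep(FALSE, length(elements))
  insub[subset] <- TRUE
  dist <- rep(NA_integer_, length(elements))
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (dist[v] >= cap) next
    inc <- which((bonds$a1 == v & insub[bonds$a2]) |
                   (bonds$a2 == v & insub[bonds$a1]))
    nb <- ifelse(bonds$a1[inc] == v, bonds$a2[inc], bonds$a1[inc])
    for (w in nb) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        if (elements[w] != "C") return(dist[w])
        queue <- c(queue, w)
      }
    }
  }
  cap
}

attach_features <- function(state, cand, parent_kind, child, n_feat,
                            parent_atoms = NULL) {
  phi <- numeric(n_feat)
  el_idx <- match(state$elements[cand$shared_parent], GG_ELEMENTS)
  el_idx[is.na(el_idx)] <- length(GG_ELEMENTS) + 1
  for (e in el_idx) phi[e] <- phi[e] + 1
  phi[11] <- length(cand$shared_parent) / 2
  kinds <- c("ring", "bond", "junction_atom")
  phi[11 + match(parent_kind, kinds)] <- 1
  phi[14 + match(child$kind, kinds)] <- 1
  phi[18] <- length(child$frag_elements) / 8
  os <- assembly_order_sums(state)
  phi[19] <- sum(os[cand$shared_parent]) / 8
  phi[20] <- nrow(child$frag_bonds) / 8
  # positional context: distance to the nearest heteroatom within the parent
  # clique and within the child fragment (meta vs para attachment on a
  # heterocycle scores differently)
  pa <- parent_atoms %||% cand$shared_parent
  phi[21] <- sum(vapply(cand$shared_parent, function(p)
    hetero_distance(state$elements, state$bonds, pa, p), integer(1))) / 4
  phi[22] <- sum(vapply(cand$shared_child, function(ca)
    hetero_distance(child$frag_elements, child$frag_bonds,
                    seq_along(child$frag_elements), ca), integer(1))) / 4
  # heteroatom neighbors of the merged parent atom in the full assembly
  phi[23] <- sum(vapply(cand$shared_parent, function(p) {
    inc <- which(state$bonds$a1 == p | state$bonds$a2 == p)
    nb <- ifelse(state$bonds$a1[inc] == p, state$bonds$a2[inc], state$bonds$a1[inc])
    sum(state$elements[nb] != "C")
  }, numeric(1))) / 4
  phi[24] <- sum(vapply(cand$shared_child, function(ca) {
    inc <- which(child$frag_bonds$a1 == ca | child$frag_bonds$a2 == ca)
    nb <- ifelse(child$frag_bonds$a1[inc] == ca, child$frag_bonds$a2[inc],
                 child$frag_bonds$a1[inc])
    sum(child$frag_elements[nb] != "C")
  }, numeric(1))) / 4
  phi
}

apply_attachment <- function(state, cand, child, child_idx) {
  cn <- length(child$frag_elements)
  gmap <- integer(cn)
  gmap[cand$shared_child] <- cand$shared_parent
  newidx <- setdiff(seq_len(cn), cand$shared_child)
  base <- length(state$elements)
  gmap[newidx] <- base + seq_along(newidx)
  state$elements <- c(state$elements, child$frag_elements[newidx])
  state$charges <- c(state$charges, child$frag_charges[newidx])
  cb <- child$frag_bonds
  if (nrow(cb)) {
    for (k in seq_len(nrow(cb))) {
      a1 <- gmap[cb$a1[k]]; a2 <- gmap[cb$a2[k]]
      lo <- min(a1, a2); hi <- max(a1, a2)
      exists <- any(state$bonds$a1 == lo & state$bonds$a2 == hi)
      if (!exists) {
        state$bonds <- rbind(state$bonds,
                             data.frame(a1 = lo, a2 = hi, order = cb$order[k]))
      }
    }
  }
  state$placement[[child_idx]] <- gmap
  state
}

attachment_scores <- function(z, Phi, params) {
  K <- nrow(Phi)
  A <- cbind(matrix(z, K, length(z), byrow = TRUE), Phi)
  Hm <- relu(A %*% t(params$Ws) + matrix(params$bs, K, length(params$bs), byrow = TRUE))
  list(scores = as.vector(Hm %*% params$w2), A = A, Hm = Hm)
}

# Order in which tree edges are assembled: DFS from node 1.
assembly_edge_order <- function(jtree) {
  topo <- tree_children(jtree)
  out <- list()
  walk <- function(v) {
    for (c_ in topo$children[[v]]) {
      out[[length(out) + 1]] <<- c(v, c_)
      walk(c_)
    }
  }
  walk(1L)
  out
}

#' Assemble a molecule from a decoded junction tree
#'
#' Walks the tree from the root, enumerates chemically valid attachment
#' configurations between each placed parent clique and its child, scores
#' each candidate against the fused latent with the learned scorer, applies
#' the argmax (ties: lowest enumeration index), and converts the assembled
#' graph to a canonical molecule.
#'
#' @param z_fused Fused latent vector.
#' @param jtree A `gg_jtree` (generated by [decode_tree()] or ground truth).
#' @param params Model parameters.
#' @param cfg Model configuration.
#' @param use_recorded If the tree still carries original atom indices,
#'   bypass scoring and reassemble exactly from the recorded
#'   correspondences.
#' @return A `gg_molecule` (decoded molecules always parse and sanitize;
#'   impossible assemblies raise `gluegen_assembly_error`).
#' @export
decode_graph <- function(z_fused, jtree, params, cfg, use_recorded = FALSE) {
  if (use_recorded) {
    gg_assert(!is.null(jtree$nodes[[1]]$atom_indices),
              "tree carries no recorded atom correspondences")
    return(parse_smiles(reassemble_tree(jtree)))
  }
  state <- assembly_init(jtree$nodes[[1]])
  if (length(jtree$nodes) > 1) {
    for (e in assembly_edge_order(jtree)) {
      parent <- e[1]; childi <- e[2]
      child <- jtree$nodes[[childi]]
      cands <- enumerate_attachments(state, parent,
                                     jtree$nodes[[parent]]$kind, child)
      if (!length(cands)) {
        gg_stop(sprintf("no valid attachment for clique %d ('%s')",
                        childi, child$label),
                "gluegen_assembly_error")
      }
      Phi <- do.call(rbind, lapply(cands, attach_features, state = state,
                                   parent_kind = jtree$nodes[[parent]]$kind,
                                   child = child, n_feat = cfg$n_attach_feat,
                                   parent_atoms = state$placement[[parent]]))
      sc <- attachment_scores(z_fused, Phi, params)$scores
      best <- which.max(sc) # which.max takes the lowest index on ties
      state <- apply_attachment(state, cands[[best]], child, childi)
    }
  }
  smi <- molecule_to_smiles(state$elements, state$charges, state$bonds)
  mol <- tryCatch(parse_smiles(smi), error = function(e) {
    gg_stop(sprintf("assembled SMILES failed to sanitize: %s", smi),
            "gluegen_assembly_error")
  })
  mol
}

# Teacher-forced attachment loss along the ground-truth tree; the true
# candidate is identified through the recorded global atom correspondences.
graph_teacher_forward <- function(z, jtree, params, cfg, want_grads = TRUE) {
  loss <- 0
  dz <- numeric(length(z))
  g <- list(Ws = params$Ws * 0, bs = numeric(length(params$bs)),
            w2 = params$w2 * 0)
  n_edges <- 0; n_ok <- 0
  state <- assembly_init(jtree$nodes[[1]])
  # recorded global id for every placed atom: root atoms in sorted order
  rec2loc <- list(setNames(seq_along(jtree$nodes[[1]]$atom_indices),
                           jtree$nodes[[1]]$atom_indices))
  rec_of_local <- jtree$nodes[[1]]$atom_indices
  if (length(jtree$nodes) > 1) {
    for (e in assembly_edge_order(jtree)) {
      parent <- e[1]; childi <- e[2]
      child <- jtree$nodes[[childi]]
      cands <- enumerate_attachments(state, parent,
                                     jtree$nodes[[parent]]$kind, child)
      if (!length(cands)) next
      # true shared atoms in recorded (original molecule) indexing
      shared_rec <- intersect(jtree$nodes[[parent]]$atom_indices,
                              child$atom_indices)
      truth <- NA_integer_
      for (ci in seq_along(cands)) {
        cd <- cands[[ci]]
        rec_parent <- rec_of_local[cd$shared_parent]
        rec_child <- child$atom_indices[cd$shared_child]
        if (length(rec_parent) == length(shared_rec) &&
            all(rec_parent == rec_child) &&
            setequal(rec_parent, shared_rec)) { truth <- ci; break }
      }
      if (is.na(truth)) { # correspondence outside enumeration; skip edge
        cd <- NULL
      } else if (length(cands) > 1) {
        Phi <- do.call(rbind, lapply(cands, attach_features, state = state,
                                     parent_kind = jtree$nodes[[parent]]$kind,
                                     child = child, n_feat = cfg$n_attach_feat,
                                     parent_atoms = state$placement[[parent]]))
        sc <- attachment_scores(z, Phi, params)
        p <- softmax(sc$scores)
        loss <- loss - log(max(p[truth], 1e-12))
        n_edges <- n_edges + 1
        if (which.max(sc$scores) == truth) n_ok <- n_ok + 1
        if (want_grads) {
          ds <- p; ds[truth] <- ds[truth] - 1
          dHm <- outer(ds, params$w2) * (sc$Hm > 0)
          g$w2 <- g$w2 + as.vector(t(sc$Hm) %*% ds)
          g$Ws <- g$Ws + t(dHm) %*% sc$A
          g$bs <- g$bs + colSums(dHm)
          dA <- dHm %*% params$Ws
          dz <- dz + colSums(dA[, seq_along(z), drop = FALSE])
        }
      } else {
        n_edges <- n_edges + 1; n_ok <- n_ok + 1
      }
      # advance state along the TRUE attachment
      use <- if (!is.na(truth)) cands[[truth]] else NULL
      if (is.null(use)) {
        # fall back: attach by recorded correspondence directly
        loc_shared <- match(shared_rec, rec_of_local)
        use <- list(shared_parent = loc_shared,
                    shared_child = match(shared_rec, child$atom_indices))
      }
      state <- apply_attachment(state, use, child, childi)
      gmap <- state$placement[[childi]]
      newloc <- setdiff(seq_along(gmap), use$shared_child)
      rec_of_local[gmap[newloc]] <- child$atom_indices[newloc]
    }
  }
  list(loss = loss, grads = if (want_grads) g else NULL, dz = dz,
       n_edges = n_edges, n_ok = n_ok)
}
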