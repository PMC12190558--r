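# Seeded 3D embedding (classical distance geometry over the heavy-atom
# graph), rotatable-bond identification, torsional angle extraction, and the
# two-conformer RMSD plausibility audit.
#
# The embedder samples inter-atomic distances between idealized-geometry
# bounds (bond lengths from covalent radii, 1-3 distances from hybridization
# angles, aromatic rings as exact regular polygons), embeds the metric matrix
# by eigendecomposition, and refines coordinates by least squares. It is a
# deliberately simple, fully seeded generator of plausible geometries, not a
# force-field conformer search; see the methods vignette for its limits.

GG_COV_RADII <- c(C = 0.77, N = 0.70, O = 0.66, F = 0.64, P = 1.10,
                  S = 1.04, Cl = 0.99, Br = 1.14, I = 1.33)

bond_length_ideal <- function(e1, e2, order, aromatic) {
  r1 <- GG_COV_RADII[e1]; r1[is.na(r1)] <- 0.77
  r2 <- GG_COV_RADII[e2]; r2[is.na(r2)] <- 0.77
  scale <- ifelse(aromatic, 0.93, c(1.0, 0.87, 0.78)[pmin(order, 3)])
  unname((r1 + r2) * scale)
}

dg_bounds <- function(mol) {
  n <- mol$atom_count
  b <- mol$bonds
  L <- matrix(2.4, n, n)
  U <- matrix(100, n, n)
  diag(L) <- 0; diag(U) <- 0
  setb <- function(i, j, lo, hi) {
    L[i, j] <<- lo; L[j, i] <<- lo
    U[i, j] <<- hi; U[j, i] <<- hi
  }
  blen <- bond_length_ideal(mol$atoms$element[b$a1], mol$atoms$element[b$a2],
                            b$order, b$aromatic)
  for (k in seq_len(nrow(b))) setb(b$a1[k], b$a2[k], blen[k], blen[k])
  # 1-3 distances from hybridization angles at the central atom
  adj <- adjacency_list(n, b)
  has_mult <- logical(n); n_mult <- integer(n)
  for (k in seq_len(nrow(b))) {
    if (b$order[k] >= 2) {
      for (a in c(b$a1[k], b$a2[k])) {
        has_mult[a] <- TRUE; n_mult[a] <- n_mult[a] + (b$order[k] - 1)
      }
    }
  }
  ring_of <- function(i, j, c) {
    for (r in mol$rings) if (all(c(i, j, c) %in% r)) return(length(r))
    NA_integer_
  }
  dlen <- function(i, j) { # ideal bond length between bonded pair
    kk <- which((b$a1 == min(i, j)) & (b$a2 == max(i, j)))
    blen[kk]
  }
  for (cen in seq_len(n)) {
    nb <- sort(adj[[cen]])
    if (length(nb) < 2) next
    for (u in seq_len(length(nb) - 1)) for (v in seq(u + 1, length(nb))) {
      i <- nb[u]; j <- nb[v]
      rs <- ring_of(i, j, cen)
      if (!is.na(rs)) {
        theta <- pi * (rs - 2) / rs      # planar interior angle
        slack <- if (mol$atoms$aromatic[cen]) 0.0 else 0.12
      } else if (mol$atoms$aromatic[cen] || has_mult[cen]) {
        theta <- if (n_mult[cen] >= 2) pi else 2 * pi / 3
        slack <- 0.02
      } else {
        theta <- 109.47 * pi / 180
        slack <- 0.05
      }
      d1 <- dlen(cen, i); d2 <- dlen(cen, j)
      d13 <- sqrt(d1^2 + d2^2 - 2 * d1 * d2 * cos(theta))
      setb(i, j, d13 - slack, d13 + slack)
    }
  }
  # aromatic rings: exact regular polygons (forces planarity)
  for (r in mol$rings) {
    if (!all(mol$atoms$aromatic[r])) next
    # ring traversal order
    ringb <- which((b$a1 %in% r) & (b$a2 %in% r))
    side <- mean(blen[ringb])
    ord <- ring_traversal(r, b)
    s <- length(ord)
    R <- side / (2 * sin(pi / s))
    for (u in seq_len(s - 1)) for (v in seq(u + 1, s)) {
      d <- 2 * R * sin(pi * abs(u - v) / s)
      d <- min(d, 2 * R * sin(pi * (s - abs(u - v)) / s))
      setb(ord[u], ord[v], d, d)
    }
  }
  # triangle smoothing of upper bounds
  for (k in seq_len(n)) {
    Uk <- outer(U[, k], U[k, ], "+")
    U <- pmin(U, Uk)
  }
  L <- pmin(L, U)
  list(L = L, U = U)
}

ring_traversal <- function(r, bonds) {
  # order ring atoms along the cycle
  sub <- bonds[(bonds$a1 %in% r) & (bonds$a2 %in% r), , drop = FALSE]
  adj <- list()
  for (k in seq_len(nrow(sub))) {
    i <- as.character(sub$a1[k]); j <- as.character(sub$a2[k])
    adj[[i]] <- c(adj[[i]], sub$a2[k])
    adj[[j]] <- c(adj[[j]], sub$a1[k])
  }
  ord <- r[1]
  prev <- NA
  while (length(ord) < length(r)) {
    nbrs <- adj[[as.character(ord[length(ord)])]]
    nxt <- setdiff(nbrs, c(prev, ord))
    prev <- ord[length(ord)]
    ord <- c(ord, nxt[1])
  }
  ord
}

#' Generate one seeded 3D conformer
#'
#' Distance-geometry embedding of the heavy-atom graph: identical seeds give
#' bitwise-identical coordinates; different seeds sample different distance
#' matrices within the geometric bounds.
#'
#' @param mol A `gg_molecule`.
#' @param seed Integer seed for the distance sampling.
#' @return A `gg_conformer` with `mol_id`, `coords` (atom_count x 3, in
#'   Angstroms, heavy atoms in molecule atom order) and `seed`.
#' @details Raises `gluegen_embed_error` when the embedding degenerates
#'   (non-finite coordinates); callers may retry with `seed + 1`.
#' @export
embed_3d <- function(mol, seed) {
  gg_assert(inherits(mol, "gg_molecule"), "mol must be a gg_molecule")
  n <- mol$atom_count
  if (n == 1) {
    return(structure(list(mol_id = mol$id,
                          coords = matrix(0, 1, 3), seed = seed),
                     class = "gg_conformer"))
  }
  bounds <- dg_bounds(mol)
  X <- with_seed(seed, {
    W <- matrix(runif(n * n), n, n)
    D <- bounds$L + (bounds$U - bounds$L) * (W + t(W)) / 2
    diag(D) <- 0
    # classical MDS
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% (D^2) %*% J
    ev <- eigen(B, symmetric = TRUE)
    vals <- pmax(ev$values[1:3], 0)
    X0 <- ev$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(vals), 3)
    refine_coords(X0, bounds$L, bounds$U)
  })
  if (any(!is.finite(X))) {
    gg_stop(sprintf("embedding failed for '%s' (seed %d)", mol$id, seed),
            "gluegen_embed_error")
  }
  structure(list(mol_id = mol$id, coords = X, seed = seed),
            class = "gg_conformer")
}

# Least-squares refinement against the bounds: exact constraints (narrow
# bounds) pull to their midpoint; range constraints penalize violation only.
refine_coords <- function(X0, L, U) {
  n <- nrow(X0)
  pairs <- which(upper.tri(L), arr.ind = TRUE)
  lo <- L[pairs]; hi <- U[pairs]
  keep <- hi < 99 | lo > 0
  pairs <- pairs[keep, , drop = FALSE]; lo <- lo[keep]; hi <- hi[keep]
  exact <- (hi - lo) < 0.25
  mid <- (lo + hi) / 2
  obj <- function(p) {
    X <- matrix(p, n, 3)
    d <- sqrt(rowSums((X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE])^2)) + 1e-12
    err <- ifelse(exact, d - mid, pmax(0, lo - d) - pmax(0, d - hi) * -1)
    # note: range error is positive magnitude of violation either side
    err <- ifelse(exact, d - mid, pmax(0, lo - d) + pmax(0, d - hi))
    sum(err^2)
  }
  grad <- function(p) {
    X <- matrix(p, n, 3)
    diff <- X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE]
    d <- sqrt(rowSums(diff^2)) + 1e-12
    coefs <- ifelse(exact, 2 * (d - mid),
                    2 * (pmax(0, d - hi) - pmax(0, lo - d)))
    G <- matrix(0, n, 3)
    gpair <- diff * (coefs / d)
    for (col in 1:3) {
      G[, col] <- G[, col] +
        tapply(c(gpair[, col], -gpair[, col]),
               factor(c(pairs[, 1], pairs[, 2]), levels = seq_len(n)),
               sum, default = 0)
    }
    as.vector(G)
  }
  res <- optim(as.vector(X0), obj, grad, method = "BFGS",
               control = list(maxit = 400, reltol = 1e-12))
  matrix(res$par, n, 3)
}

#' Identify rotatable bonds
#'
#' Strict definition: single, non-aromatic, acyclic bonds whose two end atoms
#' both have heavy-atom degree at least 2, excluding amide C-N bonds.
#'
#' @param mol A `gg_molecule`.
#' @return Two-column matrix of atom index pairs (`a1 < a2`), ordered by
#'   `(a1, a2)`; zero rows when none.
#' @export
rotatable_bonds <- function(mol) {
  gg_assert(inherits(mol, "gg_molecule"), "mol must be a gg_molecule")
  b <- mol$bonds
  if (!nrow(b)) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("a1", "a2"))))
  deg <- mol$atoms$degree
  is_amide <- vapply(seq_len(nrow(b)), function(k) {
    pair <- c(b$a1[k], b$a2[k])
    el <- mol$atoms$element[pair]
    if (!setequal(el, c("C", "N"))) return(FALSE)
    cat_ <- pair[el == "C"][1]
    inc <- which(b$a1 == cat_ | b$a2 == cat_)
    partners <- ifelse(b$a1[inc] == cat_, b$a2[inc], b$a1[inc])
    any(b$order[inc] == 2 & mol$atoms$element[partners] == "O")
  }, logical(1))
  keep <- b$order == 1 & !b$aromatic & !b$in_ring &
    deg[b$a1] >= 2 & deg[b$a2] >= 2 & !is_amide
  m <- as.matrix(b[keep, c("a1", "a2"), drop = FALSE])
  rownames(m) <- NULL
  m
}

#' Count rotatable bonds
#' @param mol A `gg_molecule`.
#' @return Integer count, `nrow(rotatable_bonds(mol))`.
#' @export
count_rotatable <- function(mol) nrow(rotatable_bonds(mol))

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Extract torsional angles for every rotatable bond
#'
#' For a rotatable bond `i-j`, the reference atoms are the neighbor of `i`
#' (excluding `j`) and the neighbor of `j` (excluding `i`) with the highest
#' heavy-atom degree, ties broken by lowest atom index.
#'
#' @param mol A `gg_molecule`.
#' @param conf A `gg_conformer` of the same molecule.
#' @return A data frame with columns `a1`, `a2` (the bond), `d1`, `d2`, `d3`,
#'   `d4` (the dihedral quadruple) and `angle_deg` in `(-180, 180]`; zero
#'   rows when the molecule has no rotatable bonds.
#' @export
torsion_angles <- function(mol, conf) {
  gg_assert(inherits(conf, "gg_conformer") && conf$mol_id == mol$id,
            "conformer does not belong to this molecule")
  rb <- rotatable_bonds(mol)
  out <- data.frame(a1 = integer(0), a2 = integer(0), d1 = integer(0),
                    d2 = integer(0), d3 = integer(0), d4 = integer(0),
                    angle_deg = numeric(0))
  if (!nrow(rb)) return(out)
  adj <- adjacency_list(mol$atom_count, mol$bonds)
  pick_ref <- function(center, exclude) {
    cand <- setdiff(adj[[center]], exclude)
    cand[order(-mol$atoms$degree[cand], cand)][1]
  }
  for (k in seq_len(nrow(rb))) {
    i <- rb[k, 1]; j <- rb[k, 2]
    a <- pick_ref(i, j); bref <- pick_ref(j, i)
    ang <- dihedral_deg(conf$coords[a, ], conf$coords[i, ],
                        conf$coords[j, ], conf$coords[bref, ])
    out <- rbind(out, data.frame(a1 = i, a2 = j, d1 = a, d2 = i, d3 = j,
                                 d4 = bref, angle_deg = ang))
  }
  out
}

#' Named torsion vector for graph featurization
#'
#' Convenience wrapper producing the `torsions` argument of [mol_to_graph()]
#' from a seeded conformer.
#' @param mol A `gg_molecule`.
#' @param seed Embedding seed.
#' @return Named numeric vector keyed by `"i-j"` bond identity (possibly
#'   empty).
#' @export
torsion_map <- function(mol, seed = 1L) {
  tt <- torsion_angles(mol, embed_3d(mol, seed))
  if (!nrow(tt)) return(setNames(numeric(0), character(0)))
  setNames(tt$angle_deg, bond_key(tt$a1, tt$a2))
}

kabsch_rmsd <- function(A, B) {
  Ac <- scale(A, scale = FALSE)
  Bc <- scale(B, scale = FALSE)
  H <- t(Ac) %*% Bc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(mean(rowSums((Ac %*% t(R) - Bc)^2)))
}

#' Heavy-atom RMSD between two independently embedded conformers
#'
#' Both conformers are generated with [embed_3d()] at the given seeds and
#' aligned by the optimal rigid rotation/translation (Kabsch) before the RMSD
#' is taken.
#'
#' @param mol A `gg_molecule`.
#' @param seed_a,seed_b Seeds of the two embeddings.
#' @return RMSD in Angstroms (non-negative).
#' @export
conformer_rmsd <- function(mol, seed_a, seed_b) {
  ca <- embed_3d(mol, seed_a)
  cb <- embed_3d(mol, seed_b)
  if (mol$atom_count == 1) return(0)
  kabsch_rmsd(ca$coords, cb$coords)
}
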