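# Junction-tree (clique) decomposition, fragment labeling, vocabulary
# construction, and tree reassembly.
#
# Cliques follow the canonical junction-tree treatment: smallest rings (rings
# sharing more than two atoms merged), every non-ring bond, and a singleton
# clique for any atom shared by three or more cliques. Tree edges come from a
# maximum spanning tree over the clique-intersection graph (weight = number of
# shared atoms), ties broken by ascending clique-index pairs.

# Emit the canonical SMILES of an induced fragment (kekulized orders) by
# constructing a V2000 connection table through ChemmineR and canonicalizing
# through OpenBabel.
atom_token <- function(el, chg) {
  if (chg == 0) {
    if (el %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")) el
    else sprintf("[%s]", el)
  } else {
    sprintf("[%s%s%s]", el, if (chg > 0) "+" else "-",
            if (abs(chg) > 1) abs(chg) else "")
  }
}

frag_to_smiles <- function(elements, charges, bonds_local) {
  n <- length(elements)
  # one- and two-atom fragments map to SMILES directly
  if (n == 1) {
    return(ob_canonical(atom_token(elements[1], charges[1])))
  }
  if (n == 2 && nrow(bonds_local) == 1) {
    bc <- c("", "=", "#")[bonds_local$order[1]]
    return(ob_canonical(paste0(atom_token(elements[1], charges[1]), bc,
                               atom_token(elements[2], charges[2]))))
  }
  ab <- matrix(0, nrow = n, ncol = 16,
               dimnames = list(paste(elements, seq_len(n), sep = "_"),
                               paste0("C", 1:16)))
  ab[, "C6"] <- ob_charge_to_code(charges)
  nb <- nrow(bonds_local)
  if (nb > 0) {
    bb <- matrix(0, nrow = nb, ncol = 7,
                 dimnames = list(as.character(seq_len(nb)), paste0("C", 1:7)))
    bb[, "C1"] <- bonds_local$a1
    bb[, "C2"] <- bonds_local$a2
    bb[, "C3"] <- bonds_local$order
  } else {
    bb <- matrix(0, nrow = 0, ncol = 7, dimnames = list(NULL, paste0("C", 1:7)))
  }
  hdr <- c(Molecule_Name = "frag", Source = "", Comment = "",
           Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  sdf <- new("SDF", header = hdr, atomblock = ab, bondblock = bb,
             datablock = character(0))
  sset <- new("SDFset", SDF = list(sdf), ID = "frag")
  smi <- suppressWarnings(tryCatch(as.character(ChemmineR::sdf2smiles(sset)),
                                   error = function(e) NA_character_))
  if (is.na(smi) || !nzchar(smi)) return(NA_character_)
  ob_canonical(smi)
}

molecule_to_smiles <- function(elements, charges, bonds_local) {
  s <- frag_to_smiles(elements, charges, bonds_local)
  if (is.na(s)) {
    gg_stop("assembled graph could not be converted to a valid molecule",
            "gluegen_assembly_error")
  }
  s
}

clique_fragment <- function(mol, atom_indices) {
  sel <- sort(atom_indices)
  local <- match(seq_len(mol$atom_count), sel)
  b <- mol$bonds
  keep <- !is.na(local[b$a1]) & !is.na(local[b$a2])
  data.frame(
    a1 = local[b$a1[keep]],
    a2 = local[b$a2[keep]],
    order = b$order[keep]
  )
}

#' Decompose a molecule into its junction tree
#'
#' @param mol A `gg_molecule` (connected; multi-fragment input is rejected at
#'   parse time, and a disconnected table raises
#'   `gluegen_disconnected_error`).
#' @return A `gg_jtree` with `nodes` (list of cliques: `index`,
#'   `atom_indices`, `label`, `kind`, and the fragment tables used for
#'   reassembly) and `edges` (two-column matrix of node index pairs, empty
#'   when the tree has a single node).
#' @examples
#' jt <- tree_decompose(parse_smiles("c1ccccc1-c1ccccc1"))
#' length(jt$nodes) # 3: ring, bond, ring
#' @export
tree_decompose <- function(mol) {
  gg_assert(inherits(mol, "gg_molecule"), "mol must be a gg_molecule")
  n <- mol$atom_count
  if (n > 1 && max(graph_components(n, mol$bonds)) > 1) {
    gg_stop(sprintf("molecule '%s' is disconnected", mol$id),
            "gluegen_disconnected_error")
  }
  rings <- mol$rings
  # merge rings sharing more than two atoms (bridged systems)
  if (length(rings) > 1) {
    repeat {
      merged <- FALSE
      for (i in seq_len(length(rings) - 1)) {
        for (j in seq(i + 1, length(rings))) {
          if (length(intersect(rings[[i]], rings[[j]])) > 2) {
            rings[[i]] <- sort(union(rings[[i]], rings[[j]]))
            rings[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  ring_sets <- lapply(rings, sort)
  ring_bond_atoms <- lapply(ring_sets, function(r) r)
  # bonds not inside any ring clique
  in_ring_clique <- vapply(seq_len(mol$bond_count), function(k) {
    a1 <- mol$bonds$a1[k]; a2 <- mol$bonds$a2[k]
    any(vapply(ring_sets, function(r) (a1 %in% r) && (a2 %in% r), logical(1)))
  }, logical(1))
  nonring <- which(!in_ring_clique)

  cliques <- list()
  for (r in ring_sets) {
    cliques[[length(cliques) + 1]] <- list(atom_indices = r, kind = "ring")
  }
  for (k in nonring) {
    cliques[[length(cliques) + 1]] <- list(
      atom_indices = c(mol$bonds$a1[k], mol$bonds$a2[k]), kind = "bond")
  }
  # junction atoms: atoms appearing in >= 3 cliques
  counts <- tabulate(unlist(lapply(cliques, `[[`, "atom_indices")), nbins = n)
  for (a in which(counts >= 3)) {
    cliques[[length(cliques) + 1]] <- list(atom_indices = a, kind = "junction_atom")
  }
  if (!length(cliques)) { # single atom, no bonds
    cliques <- list(list(atom_indices = 1L, kind = "junction_atom"))
  }

  nodes <- lapply(seq_along(cliques), function(i) {
    cl <- cliques[[i]]
    sel <- as.integer(sort(cl$atom_indices))
    frag_bonds <- clique_fragment(mol, sel)
    lab <- frag_to_smiles(mol$atoms$element[sel], mol$atoms$charge[sel], frag_bonds)
    list(index = i, atom_indices = sel, label = lab, kind = cl$kind,
         frag_elements = mol$atoms$element[sel],
         frag_charges = mol$atoms$charge[sel],
         frag_bonds = frag_bonds)
  })

  # maximum spanning tree over the clique-intersection graph
  nn <- length(nodes)
  cand <- list()
  if (nn > 1) {
    for (i in seq_len(nn - 1)) {
      for (j in seq(i + 1, nn)) {
        w <- length(intersect(nodes[[i]]$atom_indices, nodes[[j]]$atom_indices))
        if (w > 0) cand[[length(cand) + 1]] <- c(i, j, w)
      }
    }
  }
  edges <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("node_i", "node_j")))
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, 3], cm[, 1], cm[, 2]), , drop = FALSE]
    parent <- seq_len(nn)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (k in seq_len(nrow(cm))) {
      ri <- find(cm[k, 1]); rj <- find(cm[k, 2])
      if (ri != rj) {
        parent[ri] <- rj
        edges <- rbind(edges, cm[k, 1:2])
      }
    }
  }
  jt <- structure(list(mol_id = mol$id, nodes = nodes, edges = edges,
                       smiles_canonical = mol$smiles_canonical,
                       truncated = FALSE),
                  class = "gg_jtree")
  if (nn > 1 && nrow(edges) != nn - 1) {
    gg_stop(sprintf("junction tree of '%s' is not connected", mol$id),
            "gluegen_disconnected_error")
  }
  jt
}

#' @export
print.gg_jtree <- function(x, ...) {
  kinds <- vapply(x$nodes, `[[`, "", "kind")
  cat(sprintf("<gg_jtree %s> %d cliques (%s), %d edges\n",
              x$mol_id %||% "?", length(x$nodes),
              paste(sprintf("%d %s", table(kinds), names(table(kinds))),
                    collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Reassemble a junction tree using its recorded atom correspondences
#'
#' Inverse of [tree_decompose()] for trees that still carry their original
#' atom indices: the union of all clique fragments reproduces the molecule.
#'
#' @param jtree A `gg_jtree` from [tree_decompose()].
#' @return Canonical SMILES of the reassembled molecule.
#' @export
reassemble_tree <- function(jtree) {
  gg_assert(inherits(jtree, "gg_jtree"), "jtree must be a gg_jtree")
  atom_ids <- sort(unique(unlist(lapply(jtree$nodes, `[[`, "atom_indices"))))
  lookup <- match(seq_len(max(atom_ids)), atom_ids)
  elements <- character(length(atom_ids))
  charges <- numeric(length(atom_ids))
  bonds <- list()
  for (nd in jtree$nodes) {
    loc <- lookup[nd$atom_indices]
    elements[loc] <- nd$frag_elements
    charges[loc] <- nd$frag_charges
    if (nrow(nd$frag_bonds)) {
      b <- nd$frag_bonds
      bonds[[length(bonds) + 1]] <- data.frame(
        a1 = pmin(loc[b$a1], loc[b$a2]),
        a2 = pmax(loc[b$a1], loc[b$a2]),
        order = b$order)
    }
  }
  if (length(bonds)) {
    bl <- unique(do.call(rbind, bonds))
  } else {
    bl <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  molecule_to_smiles(elements, charges, bl)
}

#' Build a clique-label vocabulary from a molecule list
#'
#' @param mols List of `gg_molecule` objects (non-empty).
#' @return A `gg_vocabulary`: ordered label set (first-seen order),
#'   `label_to_index` bijection, and one representative fragment per label
#'   (used by the decoders).
#' @export
build_vocabulary <- function(mols) {
  gg_assert(is.list(mols) && length(mols) > 0, "mols must be a non-empty list")
  labels <- character(0)
  fragments <- list()
  kinds <- character(0)
  for (mol in mols) {
    jt <- tryCatch(tree_decompose(mol), error = function(e) {
      gg_stop(sprintf("decomposition failed for molecule '%s': %s",
                      mol$id, conditionMessage(e)),
              "gluegen_vocabulary_error")
    })
    for (nd in jt$nodes) {
      if (!(nd$label %in% labels)) {
        labels <- c(labels, nd$label)
        kinds <- c(kinds, nd$kind)
        fragments[[nd$label]] <- list(
          elements = nd$frag_elements,
          charges = nd$frag_charges,
          bonds = nd$frag_bonds,
          kind = nd$kind
        )
      }
    }
  }
  structure(list(
    labels = labels,
    label_to_index = setNames(seq_along(labels), labels),
    kinds = kinds,
    fragments = fragments
  ), class = "gg_vocabulary")
}

#' @export
print.gg_vocabulary <- function(x, ...) {
  cat(sprintf("<gg_vocabulary> %d clique labels: %s%s\n",
              length(x$labels),
              paste(head(x$labels, 8), collapse = " "),
              if (length(x$labels) > 8) " ..." else ""))
  invisible(x)
}

#' Write / read a vocabulary label list as JSON
#'
#' Only the ordered label list is serialized; fragment tables are rebuilt
#' from molecules when needed (checkpoints store the full object).
#' @param vocab A `gg_vocabulary`.
#' @param path Output / input JSON path.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(vocab$labels, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary_labels <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}

# tree invariant checks used by tests and decode_tree postconditions
jtree_is_valid <- function(jtree, n_atoms = NULL) {
  nn <- length(jtree$nodes)
  if (nn == 0) return(FALSE)
  if (nrow(jtree$edges) != nn - 1 && nn > 1) return(FALSE)
  if (nn > 1) {
    eb <- data.frame(a1 = jtree$edges[, 1], a2 = jtree$edges[, 2], order = 1)
    if (max(graph_components(nn, eb)) != 1) return(FALSE)
    for (k in seq_len(nrow(jtree$edges))) {
      i <- jtree$edges[k, 1]; j <- jtree$edges[k, 2]
      if (!length(intersect(jtree$nodes[[i]]$atom_indices,
                            jtree$nodes[[j]]$atom_indices))) return(FALSE)
    }
  }
  if (!is.null(n_atoms)) {
    cov <- sort(unique(unlist(lapply(jtree$nodes, `[[`, "atom_indices"))))
    if (!identical(as.integer(cov), seq_len(n_atoms))) return(FALSE)
  }
  for (nd in jtree$nodes) {
    sz <- length(nd$atom_indices)
    ok <- switch(nd$kind,
                 bond = sz == 2, junction_atom = sz == 1, ring = sz >= 3, FALSE)
    if (!ok) return(FALSE)
  }
  TRUE
}
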