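# Molecule parsing and perception.
#
# SMILES handling is delegated to OpenBabel (via ChemmineOB/ChemmineR):
# canonicalization, kekulized connection tables, and SMILES emission all go
# through it. Ring perception (SSSR), aromaticity and conjugation flags are
# perceived here on the kekulized heavy-atom graph so that every downstream
# feature is a deterministic function of the connection table.

GG_ELEMENTS <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

# maximum total bond order (kekulized, heavy-atom neighbors + implicit H not
# counted) tolerated per element; used as a chemical sanity check on input
# and as the feasibility rule during graph assembly
GG_MAX_VALENCE <- c(
  C = 4, N = 4, O = 2, F = 1, P = 5, S = 6, Cl = 1, Br = 1, I = 1,
  B = 3, Si = 4
)

ob_canonical <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles),
    error = function(e) ""
  )
  out <- gsub("[\t\n ].*$", "", out)
  if (!nzchar(out)) NA_character_ else out
}

# Old-style ctab charge codes (column 6 of a V2000 atom line).
ob_charge_from_code <- function(code) {
  map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)
  unname(map[as.character(code)])
}

ob_charge_to_code <- function(charge) {
  map <- c(`3` = 1, `2` = 2, `1` = 3, `0` = 0, `-1` = 5, `-2` = 6, `-3` = 7)
  unname(map[as.character(charge)])
}

#' Parse and canonicalize a SMILES string
#'
#' Parses a single-fragment SMILES, canonicalizes it through OpenBabel,
#' applies a standard-valence sanity check, and perceives rings, aromaticity
#' and conjugation on the kekulized heavy-atom graph.
#'
#' @param smiles A non-empty SMILES string (single fragment; `.` is rejected).
#' @param id Identifier carried through downstream tables.
#' @return An object of class `gg_molecule` with fields `id`, `smiles_input`,
#'   `smiles_canonical`, `atom_count`, `bond_count`, `has_coords`, plus the
#'   perceived `atoms`, `bonds` and `rings` tables used by the rest of the
#'   package. Atom and bond indices are 1-based.
#' @details Invalid input (syntax errors, unclosed rings, valence violations)
#'   raises a condition of class `gluegen_parse_error`; callers that count
#'   validity of generated structures should catch that class.
#' @examples
#' m <- parse_smiles("c1ccccc1")
#' m$atom_count # 6
#' @export
parse_smiles <- function(smiles, id = NULL) {
  gg_assert(is.character(smiles) && length(smiles) == 1 && nzchar(smiles),
            "smiles must be a non-empty string", "gluegen_parse_error")
  if (grepl(".", smiles, fixed = TRUE)) {
    gg_stop(sprintf("multi-fragment SMILES rejected: '%s'", smiles),
            c("gluegen_disconnected_error", "gluegen_parse_error"))
  }
  can <- ob_canonical(smiles)
  if (is.na(can)) {
    gg_stop(sprintf("invalid SMILES: '%s'", smiles), "gluegen_parse_error")
  }
  single_atom <- grepl("^(\\[[^][]+\\]|[A-IK-Za-ik-z][a-z]?)$", can)
  if (single_atom) {
    el <- regmatches(can, regexpr("[A-Z][a-z]?", can))
    chg <- (nchar(gsub("[^+]", "", can)) - nchar(gsub("[^-]", "", can)))
    atoms <- data.frame(element = el, charge = chg, degree = 0L,
                        in_ring = FALSE, aromatic = FALSE,
                        stringsAsFactors = FALSE)
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                        aromatic = logical(0), in_ring = logical(0),
                        conjugated = logical(0))
    return(structure(list(id = id %||% can, smiles_input = smiles,
                          smiles_canonical = can, atom_count = 1L,
                          bond_count = 0L, has_coords = FALSE,
                          atoms = atoms, bonds = bonds, rings = list()),
                     class = "gg_molecule"))
  }
  sdf <- suppressWarnings(tryCatch(ChemmineR::smiles2sdf(can), error = function(e) NULL))
  if (is.null(sdf)) gg_stop(sprintf("invalid SMILES: '%s'", smiles), "gluegen_parse_error")
  mol <- mol_from_sdf(sdf[[1]], id = id %||% can,
                      smiles_input = smiles, smiles_canonical = can)
  bad <- valence_violations(mol$atoms, mol$bonds)
  if (length(bad)) {
    gg_stop(sprintf("valence violation at atom(s) %s in '%s'",
                    paste(bad, collapse = ","), smiles),
            "gluegen_parse_error")
  }
  mol
}

# Build the internal molecule from a ChemmineR SDF (kekulized, from OpenBabel).
mol_from_sdf <- function(sdf, id, smiles_input, smiles_canonical) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (!is.null(bb) && is.null(dim(bb))) bb <- matrix(bb, nrow = 1, dimnames = list("1", names(bb)))
  if (is.null(dim(ab))) ab <- matrix(ab, nrow = 1, dimnames = list(rownames(ChemmineR::atomblock(sdf)), names(ab)))
  n <- nrow(ab)
  element <- sub("_.*$", "", rownames(ab))
  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charge <- ob_charge_from_code(charge_code)
  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(
      a1 = as.integer(pmin(bb[, "C1"], bb[, "C2"])),
      a2 = as.integer(pmax(bb[, "C1"], bb[, "C2"])),
      order = as.integer(bb[, "C3"])
    )
    bonds <- bonds[order(bonds$a1, bonds$a2), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  atoms <- data.frame(element = element, charge = charge,
                      stringsAsFactors = FALSE)
  atoms$degree <- tabulate(c(bonds$a1, bonds$a2), nbins = n)

  rings <- perceive_sssr(n, bonds)
  ring_bond <- bond_in_ring(bonds, n)
  atoms$in_ring <- seq_len(n) %in% unlist(rings)
  arom <- perceive_aromatic(atoms, bonds, rings)
  atoms$aromatic <- arom$atom
  bonds$aromatic <- arom$bond
  bonds$in_ring <- ring_bond
  bonds$conjugated <- perceive_conjugation(atoms, bonds)

  structure(list(
    id = id,
    smiles_input = smiles_input,
    smiles_canonical = smiles_canonical,
    atom_count = n,
    bond_count = nrow(bonds),
    has_coords = FALSE,
    atoms = atoms,
    bonds = bonds,
    rings = rings
  ), class = "gg_molecule")
}

valence_violations <- function(atoms, bonds) {
  n <- nrow(atoms)
  osum <- numeric(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      osum[bonds$a1[k]] <- osum[bonds$a1[k]] + bonds$order[k]
      osum[bonds$a2[k]] <- osum[bonds$a2[k]] + bonds$order[k]
    }
  }
  lim <- GG_MAX_VALENCE[atoms$element]
  lim <- lim + pmax(atoms$charge, 0) * ifelse(atoms$element %in% c("N", "O"), 1, 0)
  which(!is.na(lim) & osum > lim)
}

#' @export
print.gg_molecule <- function(x, ...) {
  cat(sprintf("<gg_molecule %s> %s  (%d atoms, %d bonds%s)\n",
              x$id, x$smiles_canonical, x$atom_count, x$bond_count,
              if (x$has_coords) ", 3D" else ""))
  invisible(x)
}

# ---- graph primitives (heavy-atom graph, 1-based indices) ----

adjacency_list <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$a1[k]; j <- bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

graph_components <- function(n, bonds) {
  adj <- adjacency_list(n, bonds)
  comp <- integer(n)
  cur <- 0
  for (s in seq_len(n)) {
    if (comp[s] == 0) {
      cur <- cur + 1
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) {
          if (comp[w] == 0) {
            comp[w] <- cur
            queue <- c(queue, w)
          }
        }
      }
    }
  }
  comp
}

# shortest path between a and b avoiding one forbidden bond (by row index);
# returns atom index vector or NULL
bfs_path_avoiding <- function(n, bonds, a, b, forbid) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    if (k == forbid) next
    i <- bonds$a1[k]; j <- bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  prev <- integer(n)
  seen <- logical(n)
  seen[a] <- TRUE
  queue <- a
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == b) break
    for (w in sort(adj[[v]])) {
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  if (!seen[b]) return(NULL)
  path <- b
  while (path[1] != a) path <- c(prev[path[1]], path)
  path
}

bond_index_map <- function(bonds) {
  setNames(seq_len(nrow(bonds)), paste(bonds$a1, bonds$a2, sep = "-"))
}

ring_to_bondrows <- function(ring, bmap) {
  m <- length(ring)
  nxt <- c(ring[-1], ring[1])
  keys <- paste(pmin(ring, nxt), pmax(ring, nxt), sep = "-")
  unname(bmap[keys])
}

# Smallest set of smallest rings. For every non-bridge bond, take the
# smallest cycle through it; keep cycles in ascending size order while they
# are linearly independent (GF(2) over the bond incidence space) until the
# cyclomatic number is reached.
perceive_sssr <- function(n, bonds) {
  nb <- nrow(bonds)
  if (nb == 0) return(list())
  ncomp <- max(graph_components(n, bonds))
  n_rings <- nb - n + ncomp
  if (n_rings <= 0) return(list())
  bmap <- bond_index_map(bonds)
  cand <- list()
  for (k in seq_len(nb)) {
    p <- bfs_path_avoiding(n, bonds, bonds$a1[k], bonds$a2[k], k)
    if (!is.null(p)) cand[[length(cand) + 1]] <- p # cycle atoms in order
  }
  if (!length(cand)) return(list())
  key <- vapply(cand, function(r) paste(sort(r), collapse = ","), "")
  cand <- cand[!duplicated(key)]
  sizes <- lengths(cand)
  ord <- order(sizes, vapply(cand, function(r) paste(sprintf("%05d", sort(r)), collapse = ""), ""))
  cand <- cand[ord]
  basis <- matrix(FALSE, nrow = 0, ncol = nb)
  chosen <- list()
  for (r in cand) {
    vec <- rep(FALSE, nb)
    vec[ring_to_bondrows(r, bmap)] <- TRUE
    red <- vec
    # reduce against current (row-echelon) basis
    if (nrow(basis)) {
      for (i in seq_len(nrow(basis))) {
        piv <- which(basis[i, ])[1]
        if (red[piv]) red <- xor(red, basis[i, ])
      }
    }
    if (any(red)) {
      basis <- rbind(basis, red)
      chosen[[length(chosen) + 1]] <- r
      if (length(chosen) == n_rings) break
    }
  }
  chosen
}

bond_in_ring <- function(bonds, n) {
  nb <- nrow(bonds)
  if (nb == 0) return(logical(0))
  vapply(seq_len(nb), function(k) {
    !is.null(bfs_path_avoiding(n, bonds, bonds$a1[k], bonds$a2[k], k))
  }, logical(1))
}

# Simplified Hueckel perception on SSSR rings of the kekulized graph:
# an atom contributes 1 pi electron if it carries a multiple bond to a ring
# atom, 2 if it is an N/O/S with only single bonds, and poisons the ring
# otherwise (sp3 carbon, or carbon with an exocyclic multiple bond to a
# non-ring atom, e.g. a cyclic-imide carbonyl). A ring is aromatic when no
# atom poisons it and the pi count is 4n+2.
perceive_aromatic <- function(atoms, bonds, rings) {
  n <- nrow(atoms)
  atom_arom <- logical(n)
  bond_arom <- logical(nrow(bonds))
  if (!length(rings)) return(list(atom = atom_arom, bond = bond_arom))
  in_any_ring <- seq_len(n) %in% unlist(rings)
  bmap <- bond_index_map(bonds)
  for (r in rings) {
    pi_total <- 0
    ok <- TRUE
    for (a in r) {
      inc <- which(bonds$a1 == a | bonds$a2 == a)
      mult <- inc[bonds$order[inc] >= 2]
      if (length(mult)) {
        partner <- ifelse(bonds$a1[mult] == a, bonds$a2[mult], bonds$a1[mult])
        if (any(in_any_ring[partner])) {
          pi_total <- pi_total + 1
        } else {
          ok <- FALSE; break # exocyclic multiple bond (e.g. C=O) poisons
        }
      } else if (atoms$element[a] %in% c("N", "O", "S")) {
        pi_total <- pi_total + 2
      } else {
        ok <- FALSE; break
      }
    }
    if (ok && pi_total %% 4 == 2) {
      atom_arom[r] <- TRUE
      bond_arom[ring_to_bondrows(r, bmap)] <- TRUE
    }
  }
  list(atom = atom_arom, bond = bond_arom)
}

# A bond is flagged conjugated when both end atoms participate in some
# multiple or aromatic bond (pi centers), covering alternating systems and
# the multiple bonds themselves.
perceive_conjugation <- function(atoms, bonds) {
  if (!nrow(bonds)) return(logical(0))
  n <- nrow(atoms)
  pi_atom <- logical(n)
  for (k in seq_len(nrow(bonds))) {
    if (bonds$order[k] >= 2 || bonds$aromatic[k]) {
      pi_atom[bonds$a1[k]] <- TRUE
      pi_atom[bonds$a2[k]] <- TRUE
    }
  }
  pi_atom[bonds$a1] & pi_atom[bonds$a2]
}
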