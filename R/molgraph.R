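# Torsion-aware molecular graph featurization.

GG_ATOM_FEATURES <- c(GG_ELEMENTS, "other", "degree", "charge", "aromatic", "in_ring")
GG_BOND_FEATURES <- c("single", "double", "triple", "aromatic",
                      "in_ring", "conjugated",
                      "torsion_sin", "torsion_cos", "torsion_defined")

bond_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")

#' Build a featurized molecular graph
#'
#' Converts a parsed molecule into fixed-width atom and bond feature matrices
#' for the message-passing encoder. Bond rows carry the dihedral angle of
#' rotatable bonds encoded as `(sin, cos, defined)`; bonds without a supplied
#' torsion get `(0, 0, 0)`.
#'
#' @param mol A `gg_molecule`.
#' @param torsions Optional named numeric vector of dihedral angles in
#'   degrees; names are bond keys `"i-j"` (1-based atom indices, `i < j`),
#'   e.g. as produced by [torsion_angles()].
#' @return A `gg_graph` list with `atom_features` (atoms x 14), `bond_features`
#'   (bonds x 9), and `adjacency`, an undirected edge list (each bond once,
#'   `a1 < a2`, 1-based).
#' @examples
#' g <- mol_to_graph(parse_smiles("CCCC"), torsions = c("2-3" = 180))
#' g$bond_features[, c("torsion_sin", "torsion_cos", "torsion_defined")]
#' @export
mol_to_graph <- function(mol, torsions = NULL) {
  gg_assert(inherits(mol, "gg_molecule"), "mol must be a gg_molecule")
  a <- mol$atoms
  n <- mol$atom_count
  af <- matrix(0, nrow = n, ncol = length(GG_ATOM_FEATURES),
               dimnames = list(NULL, GG_ATOM_FEATURES))
  elcol <- ifelse(a$element %in% GG_ELEMENTS, a$element, "other")
  af[cbind(seq_len(n), match(elcol, colnames(af)))] <- 1
  af[, "degree"] <- a$degree / 4
  af[, "charge"] <- a$charge
  af[, "aromatic"] <- as.numeric(a$aromatic)
  af[, "in_ring"] <- as.numeric(a$in_ring)

  b <- mol$bonds
  m <- mol$bond_count
  bf <- matrix(0, nrow = m, ncol = length(GG_BOND_FEATURES),
               dimnames = list(NULL, GG_BOND_FEATURES))
  if (m > 0) {
    ordcol <- ifelse(b$aromatic, "aromatic",
                     c("single", "double", "triple")[pmin(b$order, 3)])
    bf[cbind(seq_len(m), match(ordcol, colnames(bf)))] <- 1
    bf[, "in_ring"] <- as.numeric(b$in_ring)
    bf[, "conjugated"] <- as.numeric(b$conjugated)
    if (!is.null(torsions) && length(torsions)) {
      gg_assert(!is.null(names(torsions)) && all(nzchar(names(torsions))),
                "torsions must be a named vector keyed by 'i-j' bond identity")
      keys <- bond_key(b$a1, b$a2)
      unknown <- setdiff(names(torsions), keys)
      if (length(unknown)) {
        gg_stop(sprintf("torsion key(s) not a bond of the molecule: %s",
                        paste(unknown, collapse = ", ")),
                "gluegen_key_error")
      }
      idx <- match(names(torsions), keys)
      rad <- torsions * pi / 180
      bf[idx, "torsion_sin"] <- sin(rad)
      bf[idx, "torsion_cos"] <- cos(rad)
      bf[idx, "torsion_defined"] <- 1
    }
  }
  structure(list(
    mol_id = mol$id,
    atom_features = af,
    bond_features = bf,
    adjacency = as.matrix(b[, c("a1", "a2"), drop = FALSE])
  ), class = "gg_graph")
}
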