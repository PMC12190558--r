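# Text interfaces: SMILES libraries (plain text or id,smiles CSV) and the
# per-molecule graph+tree preprocessing records (JSON lines).

#' Read a SMILES library
#'
#' Plain-text files hold one SMILES per line (ids are generated); CSV files
#' must carry an `id,smiles` header.
#' @param path Input file.
#' @return Data frame with columns `id`, `smiles`.
#' @export
read_smiles_input <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    gg_assert(all(c("id", "smiles") %in% names(df)),
              "CSV input must have columns id, smiles",
              "gluegen_missing_field_error")
    df[, c("id", "smiles")]
  } else {
    smis <- readLines(path, warn = FALSE)
    smis <- smis[nzchar(trimws(smis))]
    data.frame(id = sprintf("mol%04d", seq_along(smis)),
               smiles = trimws(smis), stringsAsFactors = FALSE)
  }
}

#' Preprocess a SMILES library into graph + junction-tree records
#'
#' Writes one JSON record per molecule (`records.jsonl`: id, canonical
#' SMILES, atom/bond features, adjacency, cliques with labels/kinds/atom
#' indices, tree edges, optional torsions) and the vocabulary
#' (`vocabulary.json`, ordered label list).
#'
#' @param smiles_path Input library ([read_smiles_input()] formats).
#' @param out_dir Output directory.
#' @param with_torsions Attach seeded-conformer dihedrals to bond features.
#' @param seed Conformer seed.
#' @return Invisibly, list with paths and the vocabulary.
#' @export
preprocess_library <- function(smiles_path, out_dir, with_torsions = FALSE,
                               seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- read_smiles_input(smiles_path)
  mols <- lapply(seq_len(nrow(inp)), function(i)
    parse_smiles(inp$smiles[i], id = inp$id[i]))
  vocab <- build_vocabulary(mols)
  rec_path <- file.path(out_dir, "records.jsonl")
  con <- file(rec_path, "w")
  on.exit(close(con))
  for (mol in mols) {
    tors <- if (with_torsions) tryCatch(torsion_map(mol, seed), error = function(e) NULL)
            else NULL
    g <- mol_to_graph(mol, torsions = tors)
    jt <- tree_decompose(mol)
    rec <- list(
      id = mol$id, smiles = mol$smiles_canonical,
      atom_features = unname(as.data.frame(g$atom_features)),
      bond_features = unname(as.data.frame(g$bond_features)),
      adjacency = unname(as.data.frame(g$adjacency)),
      cliques = lapply(jt$nodes, function(nd)
        list(index = nd$index, label = nd$label, kind = nd$kind,
             atom_indices = nd$atom_indices)),
      tree_edges = unname(as.data.frame(jt$edges))
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  vpath <- file.path(out_dir, "vocabulary.json")
  write_vocabulary(vocab, vpath)
  invisible(list(records = rec_path, vocabulary = vpath, vocab = vocab))
}

#' Two-conformer RMSD audit over a library
#'
#' For every molecule, embeds two independent seeded conformers and reports
#' the heavy-atom best-fit RMSD together with the rotatable-bond count.
#' Embedding failures are retried up to 5 times with incremented seeds, then
#' recorded.
#'
#' @param smiles_path Input library.
#' @param seed_a,seed_b Seeds of the two embeddings.
#' @return Data frame `id`, `n_rotatable`, `rmsd_angstrom`, `embed_status`.
#' @export
audit_conformers <- function(smiles_path, seed_a = 1L, seed_b = 2L) {
  inp <- read_smiles_input(smiles_path)
  rows <- lapply(seq_len(nrow(inp)), function(i) {
    mol <- tryCatch(parse_smiles(inp$smiles[i], id = inp$id[i]),
                    error = function(e) NULL)
    if (is.null(mol)) {
      return(data.frame(id = inp$id[i], n_rotatable = NA_integer_,
                        rmsd_angstrom = NA_real_, embed_status = "parse_error"))
    }
    rmsd <- NA_real_; status <- "embed_error"
    for (try in 0:4) {
      rmsd <- tryCatch(conformer_rmsd(mol, seed_a + try, seed_b + try),
                       error = function(e) NA_real_)
      if (!is.na(rmsd)) { status <- "ok"; break }
    }
    data.frame(id = inp$id[i], n_rotatable = count_rotatable(mol),
               rmsd_angstrom = rmsd, embed_status = status)
  })
  do.call(rbind, rows)
}
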