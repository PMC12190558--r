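# Deterministic synthetic fixtures: a toy molecule library over a fixed
# scaffold pool, labeled pseudo binding-site sequences for the three E3
# ligases, and simulated property / docking-score tables whose class
# structure mirrors the reported screen (high-affinity compounds cluster in
# the drug-like MW/logP window with low solubility).

GG_FIXTURE_SCAFFOLDS <- list(
  benzene = c("c1ccccc1", "c1ccc(%s)cc1", "c1cc(%s)ccc1%s"),
  pyridine = c("c1ccncc1", "c1cc(%s)ccn1", "c1cc(%s)cnc1%s"),
  piperidine = c("C1CCNCC1", "C1CCN(%s)CC1", "C1CC(%s)CCN1"),
  cyclohexane = c("C1CCCCC1", "C1CCC(%s)CC1", "C1CC(%s)CCC1%s"),
  phthalimide = c("O=C1NC(=O)c2ccccc21", "O=C1N(%s)C(=O)c2ccccc21"),
  # heavier, drug-sized combinations (biaryls, benzanilides, benzyl
  # piperidines, N-benzyl phthalimides) so the library also populates the
  # 300-500 Da window
  biphenyl = c("c1ccc(-c2ccccc2)cc1", "c1ccc(-c2ccc(%s)cc2)cc1",
               "c1cc(%s)ccc1-c1ccc(%s)cc1"),
  benzanilide = c("O=C(Nc1ccccc1)c1ccccc1", "O=C(Nc1ccc(%s)cc1)c1ccc(%s)cc1"),
  benzylpiperidine = c("c1ccc(CN2CCCCC2)cc1", "c1cc(%s)ccc1CN1CCC(%s)CC1"),
  benzylphthalimide = c("O=C1N(Cc2ccccc2)C(=O)c2ccccc21",
                        "O=C1N(Cc2ccc(%s)cc2)C(=O)c2ccccc21",
                        "O=C1N(CCc2ccc(%s)cc2%s)C(=O)c2ccccc21"),
  aryloxy = c("c1ccc(Oc2ccccc2)cc1", "c1cc(%s)ccc1OCc1ccc(%s)cc1")
)

GG_FIXTURE_SUBSTITUENTS <- c("C", "CC", "O", "OC", "OCC", "C(N)=O", "NC(C)=O",
                             "F", "Cl", "Br", "CO", "CCO")

#' Generate a deterministic toy molecule library
#'
#' Enumerates substituted variants of a fixed scaffold pool (benzene,
#' pyridine, piperidine, cyclohexane, and a phthalimide-like bicyclic) with
#' small substituents chosen by a seeded stream. Every output parses and
#' sanitizes; no duplicates (by canonical SMILES); never multi-fragment.
#'
#' @param n Number of molecules (1 to 500).
#' @param seed Integer seed.
#' @param scaffolds Optional subset of scaffold pool names (default: all).
#' @return Character vector of `n` canonical SMILES.
#' @export
make_toy_library <- function(n, seed = 1L,
                             scaffolds = names(GG_FIXTURE_SCAFFOLDS)) {
  gg_assert(n >= 1 && n <= 500, "n must be between 1 and 500")
  pool <- unlist(GG_FIXTURE_SCAFFOLDS[scaffolds], use.names = FALSE)
  subs <- GG_FIXTURE_SUBSTITUENTS
  with_seed(seed, {
    out <- character(0)
    guard <- 0
    while (length(out) < n && guard < 50 * n + 1000) {
      guard <- guard + 1
      tmpl <- pool[sample.int(length(pool), 1)]
      nslot <- lengths(regmatches(tmpl, gregexpr("%s", tmpl, fixed = TRUE)))
      smi <- if (nslot == 0) tmpl else {
        do.call(sprintf, c(list(tmpl), as.list(subs[sample.int(length(subs), nslot,
                                                               replace = TRUE)])))
      }
      can <- tryCatch(parse_smiles(smi)$smiles_canonical,
                      error = function(e) NA_character_)
      if (!is.na(can) && !(can %in% out)) out <- c(out, can)
    }
    if (length(out) < n) {
      gg_stop("scaffold pool exhausted before reaching n unique molecules",
              "gluegen_data_error")
    }
    out
  })
}

#' Labeled pseudo binding-site sequences for CRBN, VHL and MDM2
#'
#' The real binding-site residue lists are not bundled; these are fixed,
#' composition-distinct stand-ins (aromatic-rich, acidic/polar-rich, and
#' mixed hydrophobic) of 24-32 residues, pairwise below 50% positional
#' identity. Real sequences can be supplied via [read_ligase_fasta()].
#'
#' @param config An [encoder_config()] used to embed each sequence.
#' @return Named list of three `gg_ligase_context` objects.
#' @export
make_ligase_sequences <- function(config = encoder_config()) {
  seqs <- c(
    CRBN = "WFYHWPHQNYWFAWYHGWFNWYPH",        # aromatic-rich pocket
    VHL  = "DESTDYDNPSDTQEHSEDYDTPRESNDE",    # acidic / hydroxyl-rich
    MDM2 = "LIVGMKLAVGILKMRGAVLIGMKLVLGAIKVM" # mixed hydrophobic
  )
  setNames(lapply(names(seqs), function(id) {
    ligase_context(id, unname(seqs[id]), config)
  }), names(seqs))
}

# truncated-normal draw by rejection (seeded by the ambient stream)
rtnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate an ADMET-style property table for a molecule list
#'
#' Molecular weight, logP and rule-of-five violations are computed from
#' structure; the proprietary predictor outputs are simulated: logS from a
#' truncated Normal(-4.6, 1.3) on `[-6.5, 0.5]`, logHERG from
#' Normal(-5.8, 0.5), and the metabolic-reaction count uniform on 1..8.
#'
#' @param smiles_list Character vector of SMILES.
#' @param seed Integer seed.
#' @return Data frame with columns `id`, `smiles`, `MW`, `logP`, `logS`,
#'   `logHERG`, `n_metab`, `ro5_violations`.
#' @export
simulate_property_table <- function(smiles_list, seed = 1L) {
  props <- compute_mol_properties(smiles_list)
  n <- length(smiles_list)
  with_seed(seed, {
    data.frame(
      id = sprintf("cmpd%04d", seq_len(n)),
      smiles = props$smiles_canonical,
      MW = props$MW,
      logP = props$logP,
      logS = rtnorm(n, -4.6, 1.3, -6.5, 0.5),
      logHERG = rnorm(n, -5.8, 0.5),
      n_metab = sample.int(8, n, replace = TRUE),
      ro5_violations = props$ro5_violations,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate docking scores with the reported affinity-class structure
#'
#' Compounds inside the drug-like window (MW in 300-500 Da, logP in 2-5,
#' logS below -4) draw scores from Normal(-6.0, 0.7); all others from
#' Normal(-2.5, 1.2). Categories are assigned with [classify_affinity()].
#'
#' @param records Property table from [simulate_property_table()].
#' @param ligase Ligase id stamped on every row.
#' @param seed Integer seed.
#' @param library Library label stamped on every row.
#' @return Data frame with columns `id`, `ligase`, `library`,
#'   `docking_score`, `category`.
#' @export
simulate_docking_scores <- function(records, ligase, seed = 1L,
                                    library = "toy") {
  druglike <- records$MW >= 300 & records$MW <= 500 &
    records$logP >= 2 & records$logP <= 5 & records$logS < -4
  n <- nrow(records)
  with_seed(seed, {
    score <- ifelse(druglike, rnorm(n, -6.0, 0.7), rnorm(n, -2.5, 1.2))
    data.frame(
      id = records$id,
      ligase = ligase,
      library = library,
      docking_score = score,
      category = vapply(score, classify_affinity, ""),
      stringsAsFactors = FALSE
    )
  })
}

#' Write the full fixture set to a directory
#'
#' Emits `smiles.txt` (one SMILES per line), `ligases.fasta`,
#' `properties.csv` and `scores.csv` (one block per ligase).
#'
#' @param out_dir Output directory (created if missing).
#' @param n Library size.
#' @param seed Integer seed.
#' @return Invisibly, the list of written paths.
#' @export
write_fixtures <- function(out_dir, n = 50L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  smis <- make_toy_library(n, seed)
  writeLines(smis, file.path(out_dir, "smiles.txt"))
  ctxs <- make_ligase_sequences()
  fasta <- unlist(lapply(ctxs, function(cc) c(paste0(">", cc$ligase_id), cc$sequence)))
  writeLines(fasta, file.path(out_dir, "ligases.fasta"))
  props <- simulate_property_table(smis, seed = seed + 1L)
  write.csv(props, file.path(out_dir, "properties.csv"), row.names = FALSE)
  scores <- do.call(rbind, lapply(seq_along(ctxs), function(i) {
    simulate_docking_scores(props, names(ctxs)[i], seed = seed + 1L + i)
  }))
  write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
  invisible(file.path(out_dir, c("smiles.txt", "ligases.fasta",
                                 "properties.csv", "scores.csv")))
}
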