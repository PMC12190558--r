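# Screening analytics: ADMET-style threshold filter, docking-score affinity
# stratification, Murcko-scaffold frequency analysis, generative-set metrics
# (validity / uniqueness / novelty / QED / Lipinski adherence), and the 2D
# chemical-space projection of circular fingerprints.

# ---- structure-derived properties (OpenBabel descriptors) ----------------

ob_mol <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", smiles, identity)
}

#' Structure-derived physicochemical properties
#'
#' MW, logP, TPSA, H-bond donors/acceptors from OpenBabel's descriptors,
#' plus rotatable-bond and aromatic-ring counts and the Lipinski
#' rule-of-five violation count (MW > 500, logP > 5, HBD > 5, HBA > 10).
#'
#' @param smiles_list Character vector of SMILES (all must parse).
#' @return Data frame, one row per molecule.
#' @export
compute_mol_properties <- function(smiles_list) {
  rows <- lapply(smiles_list, function(smi) {
    mol <- parse_smiles(smi)
    p <- ChemmineOB::prop_OB(ob_mol(mol$smiles_canonical))
    n_arom <- sum(vapply(mol$rings, function(r) all(mol$atoms$aromatic[r]),
                         logical(1)))
    viol <- sum(p$MW > 500, p$logP > 5, p$HBD > 5, p$HBA1 > 10)
    data.frame(smiles_canonical = mol$smiles_canonical, MW = p$MW,
               logP = p$logP, TPSA = p$TPSA, HBD = p$HBD, HBA = p$HBA1,
               n_rotatable = count_rotatable(mol), n_aromatic_rings = n_arom,
               ro5_violations = viol, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- ADMET threshold filter ---------------------------------------------

GG_ADMET_RULES <- list(
  MW = c(130, 725), logP = c(-2, 6.5), logS = c(-6.5, 0.5),
  logHERG_max = -5, n_metab = c(1, 8), ro5_max = 1
)

#' Apply the ADMET threshold filter to one property record
#'
#' Pass requires every window: MW in `[130, 725]` Da, logP in `[-2, 6.5]`,
#' logS in `[-6.5, 0.5]`, logHERG strictly below -5, metabolic-reaction
#' count in 1..8, and at most one Lipinski violation.
#'
#' @param record List or one-row data frame with fields `MW`, `logP`,
#'   `logS`, `logHERG`, `n_metab`, `ro5_violations`.
#' @param rules Rule list (see `GG_ADMET_RULES`); exposed so windows can be
#'   tightened.
#' @return List with `pass` (logical) and `violations` (character vector of
#'   violated rule names, empty on pass).
#' @export
apply_admet_filter <- function(record, rules = GG_ADMET_RULES) {
  need <- c("MW", "logP", "logS", "logHERG", "n_metab", "ro5_violations")
  missing <- need[!vapply(need, function(f)
    !is.null(record[[f]]) && !is.na(record[[f]]), logical(1))]
  if (length(missing)) {
    gg_stop(sprintf("missing field(s): %s", paste(missing, collapse = ", ")),
            "gluegen_missing_field_error")
  }
  v <- character(0)
  if (record$MW < rules$MW[1] || record$MW > rules$MW[2]) v <- c(v, "MW")
  if (record$logP < rules$logP[1] || record$logP > rules$logP[2]) v <- c(v, "logP")
  if (record$logS < rules$logS[1] || record$logS > rules$logS[2]) v <- c(v, "logS")
  if (record$logHERG >= rules$logHERG_max) v <- c(v, "logHERG")
  if (record$n_metab < rules$n_metab[1] || record$n_metab > rules$n_metab[2])
    v <- c(v, "n_metab")
  if (record$ro5_violations > rules$ro5_max) v <- c(v, "ro5_violations")
  list(pass = length(v) == 0, violations = v)
}

#' Classify a docking score into an affinity category
#'
#' High if the score is at most -5 kcal/mol, Low on `(-5, -1]`, No above
#' -1 kcal/mol (exhaustive and mutually exclusive; the -5 boundary belongs
#' to High).
#'
#' @param score Docking score in kcal/mol (finite).
#' @param high_cut,low_cut Category boundaries (kcal/mol).
#' @return `"High"`, `"Low"` or `"No"`.
#' @export
classify_affinity <- function(score, high_cut = -5, low_cut = -1) {
  gg_assert(is.finite(score), "score must be finite")
  if (score <= high_cut) "High" else if (score <= low_cut) "Low" else "No"
}

#' Affinity stratification report
#'
#' Per-(ligase, library) counts of High/Low/No affinity compounds with row
#' totals and the grand total.
#'
#' @param records Data frame with columns `ligase`, `library`, `category`
#'   (e.g. from [simulate_docking_scores()]).
#' @return List with `table` (one row per ligase x library:
#'   `High_Affinity`, `Low_Affinity`, `No_Affinity`, `Total`) and
#'   `grand_total`.
#' @export
stratification_report <- function(records) {
  if (!nrow(records)) {
    return(list(table = data.frame(ligase = character(0), library = character(0),
                                   High_Affinity = integer(0),
                                   Low_Affinity = integer(0),
                                   No_Affinity = integer(0), Total = integer(0)),
                grand_total = 0L))
  }
  key <- interaction(records$ligase, records$library, drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(kk) {
    sub <- records[key == kk, , drop = FALSE]
    counts <- table(factor(sub$category, levels = c("High", "Low", "No")))
    data.frame(ligase = sub$ligase[1], library = sub$library[1],
               High_Affinity = as.integer(counts["High"]),
               Low_Affinity = as.integer(counts["Low"]),
               No_Affinity = as.integer(counts["No"]),
               Total = nrow(sub), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, grand_total = sum(tab$Total))
}

# ---- Murcko scaffolds ----------------------------------------------------

#' Murcko scaffold of a molecule
#'
#' Ring systems plus linkers: terminal atoms attached by a single bond are
#' pruned iteratively (atoms held by a multiple bond, e.g. carbonyl oxygens
#' on a linker, are retained). Acyclic molecules have no scaffold and map to
#' the empty-string sentinel.
#'
#' @param smiles A valid SMILES (parse failures propagate).
#' @return Canonical scaffold SMILES, or `""` for acyclic molecules.
#' @export
murcko_scaffold <- function(smiles) {
  mol <- parse_smiles(smiles)
  keep <- rep(TRUE, mol$atom_count)
  bonds <- mol$bonds
  repeat {
    deg <- numeric(mol$atom_count)
    for (k in seq_len(nrow(bonds))) {
      if (keep[bonds$a1[k]] && keep[bonds$a2[k]]) {
        deg[bonds$a1[k]] <- deg[bonds$a1[k]] + 1
        deg[bonds$a2[k]] <- deg[bonds$a2[k]] + 1
      }
    }
    prune <- which(keep & deg <= 1)
    # retain atoms held by a multiple bond
    prune <- prune[vapply(prune, function(a) {
      inc <- which((bonds$a1 == a | bonds$a2 == a) &
                     keep[bonds$a1] & keep[bonds$a2])
      !any(bonds$order[inc] >= 2)
    }, logical(1))]
    if (!length(prune)) break
    keep[prune] <- FALSE
  }
  # drop fully isolated leftovers (acyclic molecules prune to nothing or to
  # isolated multiply-bonded pairs without any ring)
  if (!any(keep) || !length(mol$rings)) return("")
  sel <- which(keep)
  local <- match(seq_len(mol$atom_count), sel)
  bk <- bonds[keep[bonds$a1] & keep[bonds$a2], , drop = FALSE]
  molecule_to_smiles(mol$atoms$element[sel], mol$atoms$charge[sel],
                     data.frame(a1 = local[bk$a1], a2 = local[bk$a2],
                                order = bk$order))
}

#' Most frequent scaffolds in an affinity stratum
#'
#' @param records Data frame with columns `smiles`, `ligase`, `category`.
#' @param ligase,category Stratum selectors (NULL = no filter).
#' @param n Number of top scaffolds.
#' @return Data frame `scaffold`, `count`, descending count, ties broken
#'   lexicographically by scaffold string.
#' @export
top_scaffolds <- function(records, ligase = NULL, category = NULL, n = 10L) {
  gg_assert(n >= 1, "n must be >= 1")
  sub <- records
  if (!is.null(ligase)) sub <- sub[sub$ligase == ligase, , drop = FALSE]
  if (!is.null(category)) sub <- sub[sub$category == category, , drop = FALSE]
  if (!nrow(sub)) return(data.frame(scaffold = character(0), count = integer(0)))
  scaf <- vapply(sub$smiles, murcko_scaffold, "", USE.NAMES = FALSE)
  tab <- table(scaf)
  out <- data.frame(scaffold = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$scaffold), , drop = FALSE]
  rownames(out) <- NULL
  head(out, n)
}

# ---- QED drug-likeness ---------------------------------------------------

# Desirability-function parameters (a, b, c, d, e, f, dmax) and weights of
# the standard weighted QED formulation over the eight properties.
GG_QED_ADS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000091, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610),
  ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140)
)
GG_QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                    PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

# Curated structural-alert patterns (a reduced, OpenBabel-compatible set of
# common reactive/undesirable motifs).
GG_ALERT_SMARTS <- c(
  nitro = "[N+](=O)[O-]", nitro2 = "N(=O)=O", aldehyde = "[CX3H1]=O",
  acyl_halide = "C(=O)[F,Cl,Br,I]", epoxide = "C1OC1", aziridine = "C1NC1",
  michael_acceptor = "C=CC(=O)", azo = "N=N", hydrazine = "[NX3][NX3]",
  peroxide = "OO", thiol = "[SH]", isocyanate = "N=C=O",
  alkyl_halide = "[Cl,Br,I][CX4]", quaternary_N = "[NX4+]",
  long_chain = "CCCCCCCC"
)

ads <- function(x, p) {
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]; e <- p[5]; f <- p[6]; dmax <- p[7]
  (a + b / (1 + exp(-(x - cc + d / 2) / e)) *
     (1 - 1 / (1 + exp(-(x - cc - d / 2) / f)))) / dmax
}

count_alerts <- function(smiles) {
  m <- ob_mol(smiles)
  sum(vapply(GG_ALERT_SMARTS, function(pat) {
    n <- tryCatch(ChemmineOB::smartsSearch_OB(m, pat, uniqueMatches = TRUE),
                  error = function(e) 0)
    as.numeric(n) > 0
  }, logical(1)))
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted geometric mean of desirability functions over MW, logP, H-bond
#' acceptors/donors, polar surface area, rotatable bonds, aromatic rings and
#' structural alerts. Property values come from OpenBabel descriptors and
#' this package's own rotatable-bond/ring perception; the alert term uses a
#' curated reduced SMARTS set, so values can differ slightly from other
#' toolkits' QED implementations.
#'
#' @param smiles A valid SMILES.
#' @return QED score in `[0, 1]`.
#' @export
qed_score <- function(smiles) {
  pr <- compute_mol_properties(smiles)
  x <- c(MW = pr$MW, ALOGP = pr$logP, HBA = pr$HBA, HBD = pr$HBD,
         PSA = pr$TPSA, ROTB = pr$n_rotatable, AROM = pr$n_aromatic_rings,
         ALERTS = count_alerts(pr$smiles_canonical))
  d <- vapply(names(GG_QED_ADS), function(nm) {
    max(ads(x[[nm]], GG_QED_ADS[[nm]]), 1e-6)
  }, numeric(1))
  w <- GG_QED_WEIGHTS[names(GG_QED_ADS)]
  exp(sum(w * log(d)) / sum(w))
}

# ---- generative-set metrics ---------------------------------------------

#' Evaluate a generated molecule set against a training set
#'
#' Validity is the fraction of generated entries that parse and sanitize
#' (`NA` entries, e.g. failed assemblies, count as invalid); uniqueness and
#' novelty are computed over the valid subset (unique canonical forms, and
#' unique forms absent from the training set); `mean_qed` averages
#' [qed_score()] over valid molecules; Lipinski adherence is the percentage
#' of valid molecules with at most one rule-of-five violation.
#'
#' @param generated Character vector of SMILES (possibly with `NA`).
#' @param training Character vector of canonical training SMILES.
#' @return A `gg_generation_report` with `n_generated`, `validity`,
#'   `uniqueness`, `novelty` (percent), `mean_qed`, `lipinski_adherence`.
#' @export
generation_metrics <- function(generated, training) {
  if (!length(generated)) {
    gg_stop("generated set is empty", "gluegen_empty_input_error")
  }
  canon <- vapply(generated, function(s) {
    if (is.na(s)) return(NA_character_)
    tryCatch(parse_smiles(s)$smiles_canonical, error = function(e) NA_character_)
  }, "", USE.NAMES = FALSE)
  valid <- canon[!is.na(canon)]
  validity <- 100 * length(valid) / length(generated)
  uniq <- unique(valid)
  uniqueness <- if (length(valid)) 100 * length(uniq) / length(valid) else 0
  novel <- setdiff(uniq, training)
  novelty <- if (length(uniq)) 100 * length(novel) / length(uniq) else 0
  mean_qed <- NA_real_
  lip <- NA_real_
  if (length(valid)) {
    qed_u <- setNames(vapply(uniq, qed_score, 0), uniq)
    mean_qed <- mean(qed_u[valid])
    pr <- compute_mol_properties(uniq)
    viol_u <- setNames(pr$ro5_violations, uniq)
    lip <- 100 * mean(viol_u[valid] <= 1)
  }
  structure(list(n_generated = length(generated), validity = validity,
                 uniqueness = uniqueness, novelty = novelty,
                 mean_qed = mean_qed, lipinski_adherence = lip),
            class = "gg_generation_report")
}

#' @export
print.gg_generation_report <- function(x, ...) {
  cat(sprintf(paste0("<generation report> n=%d  validity %.1f%%  uniqueness %.1f%%",
                     "  novelty %.1f%%  mean QED %.3f  Lipinski %.1f%%\n"),
              x$n_generated, x$validity, x$uniqueness, x$novelty,
              x$mean_qed, x$lipinski_adherence))
  invisible(x)
}

# ---- fingerprints and chemical-space projection -------------------------

#' Circular (ECFP4-type) fingerprint, folded to 2048 bits
#'
#' @param smiles A valid SMILES.
#' @return 0/1 integer vector of length 2048.
#' @export
circular_fingerprint <- function(smiles) {
  fp <- ChemmineOB::fingerprint_OB(ob_mol(smiles), "ECFP4")
  fp <- as.integer(fp != 0)
  as.integer(fp[1:2048] | fp[2049:4096])
}

# Exact t-SNE (O(n^2)) with perplexity-calibrated Gaussian affinities;
# written here because no t-SNE implementation ships with the environment's
# R libraries. Deterministic under the supplied seed.
tsne_exact <- function(D, perplexity, seed, iters = 500, lr = 100) {
  n <- nrow(D)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D[i, -i]^2
    lo <- -Inf; hi <- Inf; beta <- 1
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { beta <- beta / 2; next }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / max(sum(p), 1e-12)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    for (it in seq_len(iters)) {
      ex <- if (it <= 100) 4 else 1
      num <- 1 / (1 + as.matrix(dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (ex * P - Q) * num
      G <- 4 * (diag(rowSums(W)) - W) %*% Y
      mom <- if (it <= 250) 0.5 else 0.8
      inc <- mom * inc - lr * G
      Y <- Y + inc
      Y <- scale(Y, scale = FALSE)
    }
    Y
  })
}

#' Project molecules into 2D chemical space
#'
#' Folded circular fingerprints (radius 2, 2048 bits) are compared by
#' Tanimoto distance and embedded in two dimensions with an exact
#' t-distributed stochastic neighbor embedding
#' (perplexity `min(30, (n - 1) / 3)`); a fixed seed gives an identical
#' layout.
#'
#' @param smiles_list SMILES vector; at least 5 must be valid
#'   (`gluegen_too_few_points_error` otherwise).
#' @param seed Integer seed.
#' @return Data frame with columns `smiles`, `x`, `y` (one row per valid
#'   molecule, input order preserved).
#' @export
chemspace_projection <- function(smiles_list, seed = 1L) {
  canon <- vapply(smiles_list, function(s) {
    tryCatch(parse_smiles(s)$smiles_canonical, error = function(e) NA_character_)
  }, "", USE.NAMES = FALSE)
  keep <- !is.na(canon)
  if (sum(keep) < 5) {
    gg_stop("need at least 5 valid molecules for a 2D projection",
            "gluegen_too_few_points_error")
  }
  smis <- canon[keep]
  FP <- do.call(rbind, lapply(smis, circular_fingerprint))
  n <- nrow(FP)
  inter <- FP %*% t(FP)
  ones <- rowSums(FP)
  uni <- outer(ones, ones, "+") - inter
  D <- 1 - inter / pmax(uni, 1)
  Y <- tsne_exact(D, perplexity = min(30, (n - 1) / 3), seed = seed)
  data.frame(smiles = smis, x = Y[, 1], y = Y[, 2], stringsAsFactors = FALSE)
}

# ---- CSV interfaces ------------------------------------------------------

#' Read / write the screening CSV tables
#'
#' Property tables use the header
#' `id,smiles,MW,logP,logS,logHERG,n_metab,ro5_violations`; score tables use
#' `id,ligase,library,docking_score` (a `category` column is added on read
#' when absent).
#' @param path CSV path.
#' @export
read_property_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smiles", "MW", "logP", "logS", "logHERG", "n_metab",
            "ro5_violations")
  gg_assert(all(need %in% names(df)),
            paste("property table must have columns:", paste(need, collapse = ",")),
            "gluegen_missing_field_error")
  df
}

#' @rdname read_property_table
#' @export
read_score_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "ligase", "library", "docking_score")
  gg_assert(all(need %in% names(df)),
            paste("score table must have columns:", paste(need, collapse = ",")),
            "gluegen_missing_field_error")
  if (is.null(df$category)) {
    df$category <- vapply(df$docking_score, classify_affinity, "")
  }
  df
}
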