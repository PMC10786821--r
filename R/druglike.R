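# Drug-likeness screening: Lipinski Rule of 5 descriptors, the Ertl
# synthetic-accessibility (SA) score, and a pluggable toxicity-predictor
# interface over the Tox21 12-assay panel.

#' Tox21 assay panel names
#' @export
TOX21_TARGETS <- c("NR-AR", "NR-AR-LBD", "NR-AhR", "NR-Aromatase", "NR-ER",
                   "NR-ER-LBD", "NR-PPAR-gamma", "SR-ARE", "SR-ATAD5",
                   "SR-HSE", "SR-MMP", "SR-p53")

#' Lipinski Rule-of-5 descriptors
#'
#' Molecular weight and logP (atom-contribution estimate) come from
#' OpenBabel; hydrogen-bond donors are N/O atoms bearing at least one
#' hydrogen and acceptors are counted as all N + O atoms (the original
#' rule-of-5 convention). The rule: `hbd <= 5`, `hba <= 10`, `mw < 500` Da
#' (strict), `logp < 5` (strict).
#'
#' @param smiles character vector.
#' @return data.frame(smiles, mw, hbd, hba, logp, ro5_pass).
#' @examples
#' \donttest{lipinski("c1ccc2ncccc2c1")  # quinoline: hbd 0, hba 1, ~129.2 Da}
#' @export
lipinski <- function(smiles) {
  can <- canonicalize(smiles)
  if (anyNA(can))
    stop_molwgan("parse", "SMILES failed to parse: %s",
                 paste(smiles[is.na(can)], collapse = ", "))
  props <- ob_descriptors(can)
  hbd <- integer(length(can)); hba <- integer(length(can))
  for (k in seq_along(can)) {
    mol <- smiles_to_mol(can[k])
    no <- mol$elem %in% c("N", "O")
    hba[k] <- sum(no)
    # donors: N/O with >= 1 attached hydrogen (implicit or explicit)
    hx <- mol$hcount
    adjl <- mol_adjlist(mol)
    for (a in which(no)) {
      nb <- adjl[[a]]
      if (!is.null(nb)) hx[a] <- hx[a] + sum(mol$elem[nb[, 1]] == "H")
    }
    hbd[k] <- sum(no & hx > 0L)
  }
  mw <- as.numeric(props$MW); logp <- as.numeric(props$logP)
  data.frame(smiles = smiles, mw = mw, hbd = hbd, hba = hba, logp = logp,
             ro5_pass = hbd <= 5L & hba <= 10L & mw < 500 & logp < 5,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Ertl synthetic-accessibility score
## ---------------------------------------------------------------------------

.sa_table_env <- new.env(parent = emptyenv())

.sa_fragment_scores <- function() {
  if (!is.null(.sa_table_env$tab)) return(.sa_table_env$tab)
  path <- system.file("extdata", "sa_fragment_scores.tsv", package = "molwgan")
  if (path == "") path <- file.path("inst", "extdata", "sa_fragment_scores.tsv")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  env <- new.env(parent = emptyenv(), size = nrow(tab))
  for (k in seq_len(nrow(tab))) env[[as.character(tab$sig[k])]] <- tab$score[k]
  .sa_table_env$tab <- env
  env
}

# environments are keyed by a pair of 31-bit string hashes of the canonical
# signature (compact on disk; collision-checked at table build time)
.sig_key <- function(sig) {
  paste0(.str_hash31(sig), "_", .str_hash31(paste0("x", sig)))
}

#' Ertl synthetic-accessibility score
#'
#' The fragment-contribution term averages precomputed frequency-derived
#' scores of the molecule's circular environments (radii 0-2, count-weighted;
#' environments missing from the shipped table take the rare-fragment default
#' of -4). Complexity penalties cover size (`nAtoms^1.005 - nAtoms`),
#' stereocentres, spiro atoms, bridgehead atoms and macrocycles (log10
#' terms), plus a symmetry correction when a molecule has fewer distinct
#' environments than heavy atoms. The raw score is mapped to the 1 (easy) -
#' 10 (hard) scale with logarithmic smoothing of the top end.
#'
#' The shipped fragment table is quinoline-space focused; scores for
#' molecules far outside it lean on the rare-fragment default and should be
#' read as rough estimates.
#'
#' @param smiles character vector.
#' @return numeric vector of scores in [1, 10].
#' @export
sa_score <- function(smiles) {
  tab <- .sa_fragment_scores()
  can <- canonicalize(smiles)
  if (anyNA(can))
    stop_molwgan("parse", "SMILES failed to parse: %s",
                 paste(smiles[is.na(can)], collapse = ", "))
  vapply(can, function(s) {
    mol <- smiles_to_mol(s)
    mol <- mol_suppress_h(mol)
    envs <- mol_morgan_envs(mol, radius = 2L)
    counts <- table(envs$sig)
    nf <- sum(counts)
    score1 <- sum(vapply(names(counts), function(sg) {
      v <- tab[[.sig_key(sg)]]
      (if (is.null(v)) -4 else v) * counts[[sg]]
    }, 0)) / nf

    n_atoms <- mol_n_atoms(mol)
    n_chiral <- mol_count_stereocentres(mol)
    rc <- mol_ring_complexity(mol)
    size_pen <- n_atoms^1.005 - n_atoms
    stereo_pen <- log10(n_chiral + 1)
    spiro_pen <- log10(rc$n_spiro + 1)
    bridge_pen <- log10(rc$n_bridgehead + 1)
    macro_pen <- if (rc$n_macrocycles > 0) log10(2) else 0
    score2 <- -size_pen - stereo_pen - spiro_pen - bridge_pen - macro_pen

    n_bits <- length(counts)
    score3 <- if (n_atoms > n_bits) log(n_atoms / n_bits) * 0.5 else 0

    raw <- score1 + score2 + score3
    sa <- 11 - (raw - (-4) + 1) / (2.5 - (-4)) * 9
    if (sa > 8) sa <- 8 + log(sa + 1 - 9)
    min(10, max(1, sa))
  }, 0, USE.NAMES = FALSE)
}

## ---------------------------------------------------------------------------
## Screening
## ---------------------------------------------------------------------------

#' A deterministic stub toxicity predictor
#'
#' Stands in for a trained Tox21 activity model in tests and examples
#' (training one is outside this package's scope). Produces stable
#' pseudo-probabilities in [0, 1] per target from a hash of the canonical
#' SMILES -- synthetic values with no toxicological meaning.
#' @param smiles character vector.
#' @return matrix length(smiles) x 12 with columns [TOX21_TARGETS].
#' @export
stub_tox_predictor <- function(smiles) {
  out <- matrix(0, length(smiles), length(TOX21_TARGETS),
                dimnames = list(NULL, TOX21_TARGETS))
  for (k in seq_along(smiles)) {
    for (t in seq_along(TOX21_TARGETS)) {
      h <- .str_hash31(paste0(smiles[k], "#", TOX21_TARGETS[t]))
      out[k, t] <- (h %% 1000L) / 999
    }
  }
  out
}

#' Drug-likeness screen
#'
#' Per-molecule Rule-of-5 descriptors, SA score (pass when `< 6`), and --
#' when a predictor is supplied -- a 12-target toxicity vector with
#' `tox_inactive_all` true when every activity probability is below 0.5.
#' The summary reports pass counts and percentages; records can be ranked by
#' ascending mean toxicity to shortlist the least-flagged candidates.
#'
#' @param smiles character vector.
#' @param tox_predictor optional function(smiles) returning a matrix with 12
#'   columns of activity probabilities.
#' @param rank_by_tox reorder records by mean toxicity (ascending).
#' @return list(records = data.frame, summary = list), class
#'   `druglikeness_report`.
#' @export
screen <- function(smiles, tox_predictor = NULL, rank_by_tox = FALSE) {
  lp <- lipinski(smiles)
  sa <- sa_score(smiles)
  rec <- data.frame(canonical_smiles = canonicalize(smiles),
                    mw = lp$mw, hbd = lp$hbd, hba = lp$hba, logp = lp$logp,
                    ro5_pass = lp$ro5_pass,
                    sa_score = sa, sa_pass = sa < 6,
                    stringsAsFactors = FALSE)
  if (!is.null(tox_predictor)) {
    tox <- tox_predictor(smiles)
    if (!is.matrix(tox) || ncol(tox) != length(TOX21_TARGETS) ||
        nrow(tox) != length(smiles))
      stop_molwgan("tox", "toxicity predictor must return a %d x %d matrix",
                   length(smiles), length(TOX21_TARGETS))
    colnames(tox) <- paste0("tox_", TOX21_TARGETS)
    rec$tox_inactive_all <- apply(tox, 1, function(v) all(v < 0.5))
    rec$tox_mean <- rowMeans(tox)
    rec <- cbind(rec, as.data.frame(tox))
    if (rank_by_tox) rec <- rec[order(rec$tox_mean), , drop = FALSE]
  }
  summary <- list(
    n = nrow(rec),
    ro5_pass = sum(rec$ro5_pass), ro5_pct = 100 * mean(rec$ro5_pass),
    sa_pass = sum(rec$sa_pass), sa_pct = 100 * mean(rec$sa_pass))
  if (!is.null(tox_predictor)) {
    summary$tox_inactive_all <- sum(rec$tox_inactive_all)
    summary$tox_inactive_pct <- 100 * mean(rec$tox_inactive_all)
  }
  structure(list(records = rec, summary = summary),
            class = "druglikeness_report")
}

#' @export
print.druglikeness_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("drug-likeness screen of %d molecules\n", s$n))
  cat(sprintf("  Rule of 5 pass: %d (%.1f%%)\n", s$ro5_pass, s$ro5_pct))
  cat(sprintf("  SA < 6 pass   : %d (%.1f%%)\n", s$sa_pass, s$sa_pct))
  if (!is.null(s$tox_inactive_all))
    cat(sprintf("  predicted inactive on all 12 targets: %d (%.1f%%)\n",
                s$tox_inactive_all, s$tox_inactive_pct))
  invisible(x)
}
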