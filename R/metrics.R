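# Generation quality metrics and the exhaustive-generation procedure.
#
# Denominator conventions (they differ on purpose, which is why connected
# validity can exceed validity):
#   validity            over all generated graphs
#   connected validity  over valid molecules
#   scaffold rate       over connected valid molecules
#   novelty, uniqueness over valid molecules

new_metric_report <- function(n_generated, validity, connected_validity,
                              scaffold_rate, novelty, uniqueness) {
  structure(list(n_generated = as.integer(n_generated), validity = validity,
                 connected_validity = connected_validity,
                 scaffold_rate = scaffold_rate, novelty = novelty,
                 uniqueness = uniqueness),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("generation metrics (n = %d)\n",
                     "  validity           %.3f\n",
                     "  connected validity %.3f\n",
                     "  scaffold rate      %.3f\n",
                     "  novelty            %.3f\n",
                     "  uniqueness         %.3f\n"),
              x$n_generated, x$validity, x$connected_validity,
              x$scaffold_rate, x$novelty, x$uniqueness))
  invisible(x)
}

#' Compute generation metrics for a decoded batch
#'
#' `validity` = valid / all; `connected_validity` = connected / valid;
#' `scaffold_rate` = scaffold-matching connected / connected;
#' `novelty` = valid not in the reference set / valid;
#' `uniqueness` = distinct canonical SMILES among valid / valid. Empty
#' denominators give 0 by convention.
#'
#' @param decoded list of `decoded_molecule` (from [decode_graph()]).
#' @param reference_canon_set character vector of canonical SMILES the
#'   novelty comparison runs against (e.g. the training set).
#' @param scaffold_query substructure query for the scaffold rate.
#' @return a `metric_report`.
#' @export
compute_metrics <- function(decoded, reference_canon_set = character(0),
                            scaffold_query = QUINOLINE_QUERY) {
  stopifnot(length(decoded) > 0L)
  n <- length(decoded)
  valid <- vapply(decoded, `[[`, TRUE, "valid")
  conn <- vapply(decoded, `[[`, TRUE, "connected")
  smi <- vapply(decoded, `[[`, "", "canonical_smiles")
  nv <- sum(valid)
  validity <- nv / n
  connected_validity <- if (nv == 0L) 0 else sum(conn) / nv
  nconn <- sum(conn)
  scaffold_rate <- if (nconn == 0L) 0 else {
    cnt <- smarts_match_count(smi[conn], scaffold_query)
    sum(!is.na(cnt) & cnt > 0L) / nconn
  }
  novelty <- if (nv == 0L) 0 else
    sum(!(smi[valid] %in% reference_canon_set)) / nv
  uniqueness <- if (nv == 0L) 0 else length(unique(smi[valid])) / nv
  new_metric_report(n, validity, connected_validity, scaffold_rate,
                    novelty, uniqueness)
}

#' Exhaustive generation with the consecutive-failure stopping rule
#'
#' Repeats runs of `run_size` generated graphs. After each run, connected,
#' valid, scaffold-matching molecules that are novel against the reference
#' and not yet archived are added to the accepted set. Generation stops once
#' `patience` consecutive runs add nothing.
#'
#' @param generator either a fitted source of graphs -- a
#'   list(params, config) pair using the package generator -- or a
#'   function(n, seed) returning a list of `decoded_molecule` (stub-friendly
#'   for analyses).
#' @param schema a `graph_schema`.
#' @param reference_canon_set canonical SMILES of the training molecules.
#' @param scaffold_query scaffold the accepted molecules must contain.
#' @param run_size graphs per run (default 100).
#' @param patience consecutive empty runs that end generation (default 100).
#' @param seed integer; generation is deterministic given it.
#' @return a `generation_archive`: list(accepted, runs_executed,
#'   runs_since_last_accept).
#' @export
exhaustive_generate <- function(generator, schema,
                                reference_canon_set = character(0),
                                scaffold_query = QUINOLINE_QUERY,
                                run_size = 100L, patience = 100L, seed = 1L) {
  if (run_size < 1L || patience < 1L)
    stop_molwgan("generate", "run_size and patience must be >= 1")
  sample_run <- if (is.function(generator)) {
    function(run_idx) generator(run_size, seed + run_idx)
  } else {
    function(run_idx) {
      z <- sample_latent(run_size, generator$config$latent_dim,
                         seed = seed + run_idx)
      outs <- generator_forward(z, generator$params, schema, generator$config)
      lapply(seq_along(outs), function(k)
        decode_graph(discretize(outs[[k]], schema, mode = "categorical",
                                seed = seed + run_idx * 1009L + k), schema))
    }
  }
  accepted <- character(0)
  runs <- 0L; dry <- 0L
  while (dry < patience) {
    runs <- runs + 1L
    dec <- sample_run(runs)
    cand <- vapply(dec, function(d) {
      if (isTRUE(d$valid) && isTRUE(d$connected)) d$canonical_smiles
      else NA_character_
    }, "")
    cand <- unique(cand[!is.na(cand)])
    cand <- setdiff(cand, c(reference_canon_set, accepted))
    if (length(cand) > 0L) {
      cnt <- smarts_match_count(cand, scaffold_query)
      cand <- cand[!is.na(cnt) & cnt > 0L]
    }
    if (length(cand) > 0L) {
      accepted <- c(accepted, cand)
      dry <- 0L
    } else {
      dry <- dry + 1L
    }
  }
  structure(list(accepted = accepted, runs_executed = runs,
                 runs_since_last_accept = dry),
            class = "generation_archive")
}

#' @export
print.generation_archive <- function(x, ...) {
  cat(sprintf("generation archive: %d accepted molecules in %d runs\n",
              length(x$accepted), x$runs_executed))
  invisible(x)
}

#' Sample latent noise
#' @param n number of rows.
#' @param latent_dim width.
#' @param seed integer.
#' @return n x latent_dim matrix of standard normals.
#' @export
sample_latent <- function(n, latent_dim, seed = 1L) {
  rng <- rng_stream(seed, "latent")
  with_rng(rng, matrix(stats::rnorm(n * latent_dim), n, latent_dim))
}

#' Internal similarity-based diversity (not one of the headline metrics)
#'
#' Mean pairwise Tanimoto distance (1 - similarity) between circular
#' fingerprints of the given molecules.
#' @param smiles character vector.
#' @return numeric in [0, 1].
#' @export
internal_diversity <- function(smiles) {
  fps <- fingerprint_matrix(smiles)
  fps <- fps[rowSums(is.na(fps)) == 0L, , drop = FALSE]
  n <- nrow(fps)
  if (n < 2L) return(0)
  sims <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sims <- c(sims, .tanimoto(fps[i, ], fps[j, ]))
    }
  }
  1 - mean(sims)
}
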