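# Chemical-space comparison: circular substructure fingerprints folded to a
# fixed length, and a seeded exact t-SNE embedding to 2D. Intended for
# comparing a generated set against (a subsample of) the training set.

#' Circular substructure fingerprints
#'
#' Radius-2 circular environments (the same perception used by the
#' synthetic-accessibility fragment term) folded into a fixed-length binary
#' vector by hashing the environment signature.
#'
#' @param smiles character vector.
#' @param nbits fingerprint length.
#' @return matrix (length(smiles) x nbits) of 0/1; rows of `NA` for
#'   unparseable molecules.
#' @export
fingerprint_matrix <- function(smiles, nbits = 1024L) {
  out <- matrix(NA_real_, length(smiles), nbits)
  can <- canonicalize(smiles)
  for (k in seq_along(smiles)) {
    if (is.na(can[k])) next
    mol <- tryCatch(smiles_to_mol(can[k]), error = function(e) NULL)
    if (is.null(mol)) next
    envs <- mol_morgan_envs(mol, radius = 2L)
    v <- numeric(nbits)
    if (nrow(envs) > 0L)
      v[vapply(unique(envs$sig), .str_hash31, 0L) %% nbits + 1L] <- 1
    out[k, ] <- v
  }
  out
}

.tanimoto <- function(a, b) {
  num <- sum(a * b)
  den <- sum(a) + sum(b) - num
  if (den == 0) 0 else num / den
}

#' Exact t-SNE to 2D
#'
#' Textbook t-distributed stochastic neighbour embedding: per-point
#' perplexity calibration by bisection, symmetrized affinities, Student-t
#' low-dimensional kernel, gradient descent with momentum and early
#' exaggeration. Quadratic in the number of points; meant for the
#' desk-scale set sizes this package works at.
#'
#' @param D symmetric distance matrix.
#' @param perplexity effective neighbourhood size.
#' @param n_iter gradient steps.
#' @param seed integer.
#' @return n x 2 coordinate matrix.
#' @keywords internal
tsne_embed <- function(D, perplexity = 30, n_iter = 300L, seed = 1L) {
  n <- nrow(D)
  perplexity <- min(perplexity, (n - 1) / 3)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D[i, -i]^2
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) { beta <- beta / 2; next }
      H <- log(sump) + beta * sum(di * p) / sump
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    p <- exp(-di * beta); p <- p / max(sum(p), .Machine$double.eps)
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  rng <- rng_stream(seed, "tsne")
  Y <- with_rng(rng, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  eta <- 100
  for (iter in seq_len(n_iter)) {
    ex <- if (iter <= 100L) 4 else 1
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * Y %*% t(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    if (iter == 20L) momentum <- 0.8
    inc <- momentum * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Embed labelled molecule sets into a shared 2D chemical space
#'
#' Computes circular fingerprints per molecule, subsamples the reference set
#' (the first set, or the one named `"reference"`) to `n_reference_sample`,
#' and embeds everything jointly with seeded t-SNE on Tanimoto distances.
#'
#' @param smiles_sets named list of character vectors.
#' @param n_reference_sample reference subsample size.
#' @param seed integer.
#' @param perplexity t-SNE perplexity.
#' @return data.frame(label, smiles, x, y); attribute `"n_skipped"` counts
#'   unparseable molecules.
#' @export
embed_chemspace <- function(smiles_sets, n_reference_sample = 1000L, seed = 1L,
                            perplexity = 30) {
  stopifnot(is.list(smiles_sets), length(smiles_sets) > 0L,
            !is.null(names(smiles_sets)))
  stopifnot(all(vapply(smiles_sets, length, 0L) > 0L))
  ref_name <- if ("reference" %in% names(smiles_sets)) "reference"
              else names(smiles_sets)[1]
  rng <- rng_stream(seed, "chemspace")
  ref <- smiles_sets[[ref_name]]
  if (length(ref) > n_reference_sample)
    smiles_sets[[ref_name]] <-
      ref[with_rng(rng, sort(sample.int(length(ref), n_reference_sample)))]

  labels <- rep(names(smiles_sets), vapply(smiles_sets, length, 0L))
  smi <- unlist(smiles_sets, use.names = FALSE)
  fps <- fingerprint_matrix(smi)
  ok <- rowSums(is.na(fps)) == 0L
  n_skipped <- sum(!ok)
  fps <- fps[ok, , drop = FALSE]
  labels <- labels[ok]; smi <- smi[ok]
  n <- nrow(fps)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) D[i, j] <- D[j, i] <- 1 - .tanimoto(fps[i, ], fps[j, ])
    }
  }
  Y <- tsne_embed(D, perplexity = perplexity, seed = seed)
  out <- data.frame(label = labels, smiles = smi, x = Y[, 1], y = Y[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}
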