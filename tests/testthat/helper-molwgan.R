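# Shared fixtures for the test suite. Libraries are generated once per
# session and memoized; everything is deterministic in the seeds below.

.test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

schema_chno <- function(max_atoms = 50L)
  memo(paste0("chno", max_atoms), build_schema(c("C", "H", "N", "O"), max_atoms))

schema_seven <- function() memo("seven", schema_preset("zinc15-ii-like"))
schema_full <- function() memo("full", schema_preset("zinc15-iii-like"))

fixture_library <- function(schema, count = 60L, seed = 7L,
                            max_substitutions = 2L) {
  key <- paste0("fx_", substr(paste(schema$atom_types, collapse = ""), 1, 10),
                "_", length(schema$charge_classes), "_", schema$max_atoms,
                "_", count, "_", seed, "_", max_substitutions)
  memo(key, enumerate_quinolines(
    fixture_spec(count = count, seed = seed,
                 max_substitutions = max_substitutions, schema = schema)))
}

tiny_config <- function(seed = 3L, batch_size = 4L)
  model_config("tiny", latent_dim = 8L, gen_units = 32L, disc_units = 32L,
               gcn_units = 16L, gcn_layers = 2L, batch_size = batch_size,
               optimizer = "rmsprop", learning_rate = 1e-4, dropout = 0.1,
               activation = "tanh_relu", seed = seed)

# brute-force connectivity oracle on a one-hot adjacency array: BFS over the
# non-pad, non-no-bond edge set
bfs_connected <- function(graph, schema) {
  X <- graph$features
  keep <- which(X[, length(schema$atom_types) + 1L] != 1)
  if (length(keep) <= 1L) return(length(keep) == 1L)
  A <- graph$adjacency
  bonded <- matrix(FALSE, length(keep), length(keep))
  for (p in seq_along(keep)) for (q in seq_along(keep)) {
    if (p != q) bonded[p, q] <- A[keep[p], keep[q], 1L] != 1
  }
  seen <- logical(length(keep)); seen[1L] <- TRUE; queue <- 1L
  while (length(queue) > 0L) {
    a <- queue[1L]; queue <- queue[-1L]
    nxt <- which(bonded[a, ] & !seen)
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  all(seen)
}

# construct a decoded_molecule record directly (for metric tests)
dec <- function(valid, connected, smiles = NA_character_) {
  structure(list(valid = valid, connected = connected,
                 canonical_smiles = if (valid) smiles else NA_character_,
                 failure_reason = if (valid) NA_character_ else "sanitization"),
            class = "decoded_molecule")
}
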