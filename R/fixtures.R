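# Deterministic synthetic quinoline libraries. These emulate, at desk scale,
# the kind of scaffold-constrained training sets the pipeline expects
# (substituted quinolines), so every downstream stage is testable offline.
# They make no attempt at realistic medicinal-chemistry property
# distributions.

#' Default substituent panel
#'
#' Small fragments attachable at an aromatic CH position, written as branch
#' SMILES. The sec-butyl fragment carries a tetrahedral centre so chirality
#' columns are exercised under schemas that encode them.
#' @return named character vector of branch SMILES.
#' @export
default_substituents <- function() {
  c(methyl = "C", hydroxyl = "O", amino = "N", fluoro = "F", chloro = "Cl",
    methoxy = "OC", thiomethyl = "SC", carboxamide = "C(=O)N",
    n_methylamino = "NC", sec_butyl = "[C@@H](C)CC")
}

#' Specification of a synthetic quinoline library
#'
#' @param core_smiles scaffold SMILES; substitution sites are its aromatic CH
#'   positions in written atom order.
#' @param substituents named character vector of branch SMILES.
#' @param max_substitutions maximum simultaneous substitutions per molecule.
#' @param count number of distinct molecules requested.
#' @param seed integer seed; the whole library is a deterministic function of
#'   the spec.
#' @param schema `graph_schema` every emitted molecule must satisfy.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(core_smiles = "c1ccc2ncccc2c1",
                         substituents = default_substituents(),
                         max_substitutions = 2L,
                         count = 100L,
                         seed = 1L,
                         schema = schema_preset("pubchem-like")) {
  if (length(substituents) == 0L) stop_molwgan("fixtures", "zero substituents")
  if (count < 1L) stop_molwgan("fixtures", "count must be >= 1")
  structure(list(core_smiles = core_smiles, substituents = substituents,
                 max_substitutions = as.integer(max_substitutions),
                 count = as.integer(count), seed = as.integer(seed),
                 schema = schema),
            class = "fixture_spec")
}

# token positions (character offsets) of substitutable aromatic CH atoms,
# with insertion offsets placed after any trailing ring-closure digits
.substitution_sites <- function(core_smiles) {
  mol <- tryCatch(smiles_to_mol(core_smiles),
                  error = function(e) stop_molwgan("fixtures", "core fails to parse: %s",
                                                   conditionMessage(e)))
  toks <- .smiles_tokens(core_smiles)
  # map atom tokens to end-of-insertion character offsets
  offs <- integer(0); pos <- 0L; atom_ends <- integer(0)
  k <- 0L
  for (t in toks) {
    pos <- pos + nchar(t$text)
    if (t$kind == "atom") {
      k <- k + 1L
      atom_ends[k] <- pos
    } else if (t$kind == "ring" && k > 0L) {
      atom_ends[k] <- pos + (if (nchar(t$text) > 1L) 1L else 0L)  # %nn spans 3 chars
      if (nchar(t$text) > 1L) atom_ends[k] <- pos
    }
  }
  ch <- which(mol$arom & mol$elem == "C" & mol$hcount >= 1L)
  list(mol = mol, sites = ch, insert_at = atom_ends[ch])
}

.insert_branches <- function(core_smiles, insert_at, branches) {
  # insert in decreasing offset order so earlier offsets stay valid
  ord <- order(insert_at, decreasing = TRUE)
  s <- core_smiles
  for (k in ord) {
    at <- insert_at[k]
    s <- paste0(substr(s, 1L, at), "(", branches[k], ")",
                substr(s, at + 1L, nchar(s)))
  }
  s
}

#' Enumerate a deterministic library of substituted quinolines
#'
#' Candidate molecules are all placements of 1..`max_substitutions`
#' substituents on the core's aromatic CH positions. The candidate order is a
#' seeded permutation; candidates are canonicalized, de-duplicated and
#' filtered against the schema (via [encode_molecule()]) until `count`
#' distinct molecules are found. If the combinatorial space is exhausted
#' first, the shorter library is returned with a warning.
#'
#' @param spec a [fixture_spec()].
#' @return character vector of canonical SMILES (stereo-aware iff the schema
#'   encodes chirality), with attribute `"spec"`.
#' @examples
#' \donttest{
#' sp <- fixture_spec(substituents = c(methyl = "C"), max_substitutions = 1,
#'                    count = 7)
#' enumerate_quinolines(sp)   # the 7 monomethylquinolines
#' }
#' @export
enumerate_quinolines <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  st <- .substitution_sites(spec$core_smiles)
  if (length(st$sites) == 0L)
    stop_molwgan("fixtures", "core has no substitutable aromatic CH positions")
  nsub <- length(spec$substituents)
  nsite <- length(st$sites)
  use_stereo <- length(spec$schema$chiral_classes) > 0L

  # enumerate candidate (site-set, substituent-assignment) combinations
  combos <- list()
  for (k in seq_len(min(spec$max_substitutions, nsite))) {
    site_sets <- utils::combn(seq_len(nsite), k, simplify = FALSE)
    assign_grid <- as.matrix(expand.grid(rep(list(seq_len(nsub)), k)))
    for (ss in site_sets) {
      for (r in seq_len(nrow(assign_grid))) {
        combos[[length(combos) + 1L]] <- list(sites = ss,
                                              subs = assign_grid[r, ])
      }
    }
  }

  rng <- rng_stream(spec$seed, "fixtures")
  ord <- with_rng(rng, sample.int(length(combos)))

  found <- character(0)
  batch <- 256L
  i <- 1L
  while (length(found) < spec$count && i <= length(combos)) {
    take <- ord[i:min(i + batch - 1L, length(combos))]
    i <- i + batch
    cand <- vapply(combos[take], function(cb) {
      .insert_branches(spec$core_smiles, st$insert_at[cb$sites],
                       spec$substituents[cb$subs])
    }, "")
    can <- canonicalize(cand, use_stereo = use_stereo)
    for (s in can) {
      if (is.na(s) || s %in% found) next
      ok <- tryCatch({ encode_molecule(s, spec$schema); TRUE },
                     molwgan_error = function(e) FALSE)
      if (ok) {
        found <- c(found, s)
        if (length(found) == spec$count) break
      }
    }
  }
  if (length(found) < spec$count)
    warning(sprintf("combinatorial space exhausted: %d of %d requested molecules",
                    length(found), spec$count))
  attr(found, "spec") <- spec
  found
}

#' The 50-molecule synthetic-accessibility reference panel
#'
#' A fixed library of substituted quinolines (charges/chirality-capable
#' schema, up to three substitutions) used to benchmark the SA score against
#' the reference Ertl implementation.
#' @return character vector of 50 canonical SMILES.
#' @export
sa_reference_panel <- function() {
  enumerate_quinolines(fixture_spec(count = 50L, seed = 2025L,
                                    max_substitutions = 3L,
                                    schema = schema_preset("zinc15-iii-like")))
}

#' Split a molecule list into training and holdout sets
#'
#' Disjoint, exhaustive, deterministic given the seed. The holdout supports
#' novelty evaluation against a known reference.
#'
#' @param smiles character vector.
#' @param holdout_fraction in (0, 1).
#' @param seed integer.
#' @return list(train, holdout).
#' @export
make_split <- function(smiles, holdout_fraction, seed = 1L) {
  if (!is.numeric(holdout_fraction) || holdout_fraction <= 0 ||
      holdout_fraction >= 1)
    stop_molwgan("fixtures", "holdout_fraction must be in (0, 1)")
  n <- length(smiles)
  n_hold <- round(n * holdout_fraction)
  rng <- rng_stream(seed, "split")
  idx <- with_rng(rng, sample.int(n, n_hold))
  list(train = smiles[setdiff(seq_len(n), idx)], holdout = smiles[sort(idx)])
}

#' Write a fixture library to disk (SMILES + JSON sidecar)
#' @param smiles result of [enumerate_quinolines()].
#' @param path output SMILES file; a `.json` sidecar records the spec.
#' @export
write_fixtures <- function(smiles, path) {
  writeLines(smiles, path)
  sp <- attr(smiles, "spec")
  if (!is.null(sp)) {
    js <- list(core_smiles = sp$core_smiles,
               substituents = as.list(sp$substituents),
               max_substitutions = sp$max_substitutions,
               count = sp$count, seed = sp$seed,
               schema = unclass(sp$schema))
    jsonlite::write_json(js, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}
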