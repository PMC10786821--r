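# Molecule <-> one-hot tensor conversion (the representation the GAN sees).
#
# A molecular graph holds a symmetric N x N x B one-hot adjacency tensor over
# bond classes (class 1 is the explicit no-bond class) and an N x F one-hot
# node-feature tensor whose blocks are atom type (incl. a pad class), formal
# charge and tetrahedral chirality. Explicit hydrogens are ordinary nodes and
# count toward N.

#' Construct a molecular graph object
#' @param adjacency N x N x B array.
#' @param features N x F matrix.
#' @param n_atoms number of non-pad rows.
#' @keywords internal
new_molgraph <- function(adjacency, features, n_atoms) {
  structure(list(adjacency = adjacency, features = features,
                 n_atoms = as.integer(n_atoms)), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  d <- dim(x$adjacency)
  cat(sprintf("molecular graph: %d atoms (N = %d, B = %d, F = %d)\n",
              x$n_atoms, d[1], d[3], ncol(x$features)))
  invisible(x)
}

#' Validate molecular-graph tensor invariants
#'
#' Checks one-hot rows (adjacency pair distributions and every feature block),
#' symmetry, a no-bond diagonal, and pad consistency (pad rows carry no bonds
#' and sit in the designated neutral/none slots). Violations are structural
#' errors, distinct from chemical invalidity.
#'
#' @param graph a `molgraph`.
#' @param schema the `graph_schema` it claims to follow.
#' @return `TRUE` invisibly, or a classed error of code `"structural"`.
#' @export
validate_molgraph <- function(graph, schema) {
  A <- graph$adjacency; X <- graph$features
  N <- schema$max_atoms; B <- length(schema$bond_classes)
  if (!identical(dim(A), c(N, N, B)))
    stop_molwgan("structural", "adjacency has shape (%s), expected (%d,%d,%d)",
                 paste(dim(A), collapse = ","), N, N, B)
  if (!identical(dim(X), c(N, schema$feature_width)))
    stop_molwgan("structural", "features have shape (%s), expected (%d,%d)",
                 paste(dim(X), collapse = ","), N, schema$feature_width)
  if (!all(A %in% c(0, 1)) || !all(X %in% c(0, 1)))
    stop_molwgan("structural", "tensors are not binary")
  sums <- apply(A, c(1, 2), sum)
  if (!all(sums == 1))
    stop_molwgan("structural", "adjacency rows are not one-hot")
  for (b in seq_len(B)) {
    if (!isTRUE(all.equal(A[, , b], t(A[, , b]))))
      stop_molwgan("structural", "adjacency is not symmetric")
  }
  if (!all(A[cbind(1:N, 1:N, 1L)] == 1))
    stop_molwgan("structural", "diagonal is not the no-bond class")
  atom_block <- X[, seq_len(length(schema$atom_types) + 1L), drop = FALSE]
  if (!all(rowSums(atom_block) == 1))
    stop_molwgan("structural", "atom-type block is not one-hot")
  cc <- schema_charge_cols(schema)
  if (length(cc) > 0L && !all(rowSums(X[, cc, drop = FALSE]) == 1))
    stop_molwgan("structural", "charge block is not one-hot")
  hc <- schema_chiral_cols(schema)
  if (length(hc) > 0L && !all(rowSums(X[, hc, drop = FALSE]) == 1))
    stop_molwgan("structural", "chirality block is not one-hot")
  pad_col <- schema_pad_col(schema)
  pads <- which(X[, pad_col] == 1)
  if (length(pads) > 0L) {
    if (!all(A[pads, , 1L] == 1))
      stop_molwgan("structural", "pad rows carry bonds")
    if (length(cc) > 0L) {
      neutral <- cc[match(0L, schema$charge_classes)]
      if (!all(X[pads, neutral] == 1))
        stop_molwgan("structural", "pad rows are not in the neutral charge slot")
    }
    if (length(hc) > 0L && !all(X[pads, hc[1L]] == 1))
      stop_molwgan("structural", "pad rows are not in the 'none' chirality slot")
  }
  invisible(TRUE)
}

#' Encode a molecule as one-hot graph tensors
#'
#' The SMILES is canonicalized, parsed, and expanded to explicit hydrogens
#' (which count toward `max_atoms`). Aromatic bonds are encoded as the
#' aromatic bond class (no kekulization). Formal charges must fall in the
#' schema's charge classes (all zero when the schema has none); tetrahedral
#' chirality is encoded per atom when the schema supports it and dropped
#' otherwise. Failure modes carry distinct error codes -- `"parse"`,
#' `"size"`, `"element"`, `"charge"` -- so dataset filters can count causes.
#'
#' @param smiles a single SMILES string.
#' @param schema a `graph_schema`.
#' @return a `molgraph`.
#' @examples
#' \donttest{
#' sch <- build_schema(c("C", "H", "N", "O"), 50)
#' g <- encode_molecule("c1ccc2ncccc2c1", sch)  # quinoline: 17 atoms with H
#' g$n_atoms
#' }
#' @export
encode_molecule <- function(smiles, schema) {
  stopifnot(inherits(schema, "graph_schema"))
  use_stereo <- length(schema$chiral_classes) > 0L
  can <- canonicalize(smiles, use_stereo = use_stereo)
  if (is.na(can) || !nzchar(can))
    stop_molwgan("parse", "SMILES failed to parse: %s", smiles)
  mol <- tryCatch(smiles_to_mol(can),
                  error = function(e) stop_molwgan("parse", "%s", conditionMessage(e)))
  mol <- mol_expand_h(mol)
  n <- mol_n_atoms(mol)
  if (n > schema$max_atoms)
    stop_molwgan("size", "%d atoms after hydrogen expansion exceeds max_atoms = %d",
                 n, schema$max_atoms)
  bad_elem <- setdiff(unique(mol$elem), schema$atom_types)
  if (length(bad_elem) > 0L)
    stop_molwgan("element", "element(s) outside schema vocabulary: %s",
                 paste(bad_elem, collapse = ", "))
  if (length(schema$charge_classes) == 0L) {
    if (any(mol$charge != 0L))
      stop_molwgan("charge", "schema does not encode formal charges")
  } else if (!all(mol$charge %in% schema$charge_classes)) {
    stop_molwgan("charge", "formal charge outside schema charge classes")
  }
  if (!use_stereo) mol$chiral[] <- 0L
  mol_to_graph(mol, schema)
}

#' Tensorize an internal mol that already satisfies the schema
#' @keywords internal
mol_to_graph <- function(mol, schema) {
  N <- schema$max_atoms; B <- length(schema$bond_classes)
  Fw <- schema$feature_width
  n <- mol_n_atoms(mol)
  A <- array(0, dim = c(N, N, B))
  A[, , 1L] <- 1
  X <- matrix(0, N, Fw)
  pad_col <- schema_pad_col(schema)
  cc <- schema_charge_cols(schema)
  hc <- schema_chiral_cols(schema)
  # pad rows
  if (n < N) {
    X[(n + 1L):N, pad_col] <- 1
    if (length(cc) > 0L) X[(n + 1L):N, cc[match(0L, schema$charge_classes)]] <- 1
    if (length(hc) > 0L) X[(n + 1L):N, hc[1L]] <- 1
  }
  for (a in seq_len(n)) {
    X[a, match(mol$elem[a], schema$atom_types)] <- 1
    if (length(cc) > 0L) X[a, cc[match(mol$charge[a], schema$charge_classes)]] <- 1
    if (length(hc) > 0L) X[a, hc[1L + mol$chiral[a]]] <- 1
  }
  for (b in seq_len(mol_n_bonds(mol))) {
    i <- mol$bond_i[b]; j <- mol$bond_j[b]
    cls <- mol$bond_type[b] + 1L       # 1/2/3/4 -> classes 2..5
    A[i, j, 1L] <- 0; A[j, i, 1L] <- 0
    A[i, j, cls] <- 1; A[j, i, cls] <- 1
  }
  new_molgraph(A, X, n)
}

#' Decode graph tensors into a molecule
#'
#' Structural invariants are enforced first (violations raise a classed
#' `"structural"` error, counted separately from chemical invalidity). Non-pad
#' rows become atoms (pads may be interleaved) and non-no-bond channels become
#' bonds; chemistry is then sanitized: aromatic-system consistency, a Kekule
#' structure, and valence limits with implicit-hydrogen completion. `valid`
#' reports sanitization success; `connected` additionally requires a single
#' connected component; `canonical_smiles` is the canonical SMILES of the
#' whole decoded molecule (fragments joined by '.'), present iff valid.
#'
#' @param graph a `molgraph` (e.g. from [discretize()]).
#' @param schema a `graph_schema`.
#' @return a `decoded_molecule` list: `valid`, `connected`,
#'   `canonical_smiles`, `failure_reason`.
#' @export
decode_graph <- function(graph, schema) {
  validate_molgraph(graph, schema)
  A <- graph$adjacency; X <- graph$features
  pad_col <- schema_pad_col(schema)
  keep <- which(X[, pad_col] != 1)
  fail <- function(reason) {
    structure(list(valid = FALSE, connected = FALSE,
                   canonical_smiles = NA_character_, failure_reason = reason),
              class = "decoded_molecule")
  }
  if (length(keep) == 0L) return(fail("empty"))

  mol <- new_mol()
  cc <- schema_charge_cols(schema)
  hc <- schema_chiral_cols(schema)
  n_types <- length(schema$atom_types)
  for (a in keep) {
    t_idx <- which(X[a, seq_len(n_types)] == 1)
    charge <- if (length(cc) > 0L)
      schema$charge_classes[which(X[a, cc] == 1)] else 0L
    chiral <- if (length(hc) > 0L) which(X[a, hc] == 1) - 1L else 0L
    mol <- mol_add_atom(mol, schema$atom_types[t_idx], charge,
                        arom = FALSE, hcount = 0L, chiral = chiral)
  }
  for (p in seq_along(keep)) {
    for (q in seq_along(keep)) {
      if (q <= p) next
      cls <- which(A[keep[p], keep[q], ] == 1)
      if (cls > 1L) mol <- mol_add_bond(mol, p, q, cls - 1L)
    }
  }
  # aromatic flags from bonds (sanitization re-derives and checks them)
  ar <- which(mol$bond_type == 4L)
  mol$arom[unique(c(mol$bond_i[ar], mol$bond_j[ar]))] <- TRUE

  san <- mol_sanitize(mol)
  if (!san$ok) return(fail(if (san$reason == "empty") "empty" else "sanitization"))
  mol <- san$mol

  # drop chiral tags that are not on resolvable tetrahedral centres
  adj <- mol_adjlist(mol)
  for (a in which(mol$chiral > 0L)) {
    deg <- if (is.null(adj[[a]])) 0L else nrow(adj[[a]])
    if (deg + mol$hcount[a] != 4L || mol$hcount[a] > 1L) mol$chiral[a] <- 0L
  }

  comp <- mol_components(mol)
  connected <- length(unique(comp)) == 1L
  smi <- mol_to_smiles(mol)
  can <- canonicalize(smi, use_stereo = length(schema$chiral_classes) > 0L)
  if (is.na(can)) return(fail("sanitization"))
  structure(list(valid = TRUE, connected = connected,
                 canonical_smiles = can, failure_reason = NA_character_),
            class = "decoded_molecule")
}

#' @export
print.decoded_molecule <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("decoded molecule: %s (%s)\n", x$canonical_smiles,
                if (x$connected) "connected" else "fragmented"))
  } else {
    cat(sprintf("decoded molecule: invalid (%s)\n", x$failure_reason))
  }
  invisible(x)
}
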