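# Graph encoding schema: the contract between molecules and tensors.

.known_elements <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

stop_molwgan <- function(code, msg, ...) {
  stop(structure(class = c(paste0("molwgan_error_", code),
                           "molwgan_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1),
                      code = code)))
}

#' Build a graph encoding schema
#'
#' A schema fixes the one-hot vocabularies of the tensor representation: the
#' element vocabulary, the maximum number of atoms `N` (explicit hydrogens
#' count as atoms), the bond classes (an explicit no-bond class followed by
#' single, double, triple, aromatic), the supported formal charges and the
#' tetrahedral chirality classes. The node feature width is
#' `F = |atom_types| + 1 (pad) + |charge_classes| + |chiral_classes|`.
#'
#' @param atom_types character vector of element symbols (order preserved).
#' @param max_atoms maximum atoms per molecule, `>= 2`.
#' @param charge_classes integer vector of allowed formal charges (must
#'   contain 0 when non-empty), or `integer(0)` for neutral-only encoding.
#' @param chiral_classes `character(0)` or `c("none","cw","ccw")`.
#' @return object of class `graph_schema`.
#' @examples
#' build_schema(c("C", "H", "N", "O"), 50)
#' @export
build_schema <- function(atom_types, max_atoms = 50L,
                         charge_classes = integer(0),
                         chiral_classes = character(0)) {
  if (length(atom_types) == 0L) stop_molwgan("schema", "atom_types is empty")
  if (anyDuplicated(atom_types))
    stop_molwgan("schema", "duplicate atom types: %s",
                 paste(unique(atom_types[duplicated(atom_types)]), collapse = ", "))
  bad <- setdiff(atom_types, .known_elements)
  if (length(bad) > 0L)
    stop_molwgan("schema", "unsupported element symbols: %s", paste(bad, collapse = ", "))
  if (!is.numeric(max_atoms) || max_atoms < 2L)
    stop_molwgan("schema", "max_atoms must be >= 2")
  charge_classes <- as.integer(charge_classes)
  if (length(charge_classes) > 0L) {
    if (anyDuplicated(charge_classes)) stop_molwgan("schema", "duplicate charge classes")
    if (!0L %in% charge_classes)
      stop_molwgan("schema", "charge_classes must include 0 (the neutral slot)")
  }
  if (length(chiral_classes) > 0L) {
    if (!identical(tolower(chiral_classes), c("none", "cw", "ccw")))
      stop_molwgan("schema", "chiral_classes must be empty or c('none','cw','ccw')")
    chiral_classes <- c("none", "cw", "ccw")
  }
  bond_classes <- c("none", "single", "double", "triple", "aromatic")
  s <- structure(list(
    atom_types = as.character(atom_types),
    max_atoms = as.integer(max_atoms),
    bond_classes = bond_classes,
    charge_classes = charge_classes,
    chiral_classes = as.character(chiral_classes),
    feature_width = length(atom_types) + 1L + length(charge_classes) +
      length(chiral_classes)
  ), class = "graph_schema")
  s
}

#' @export
print.graph_schema <- function(x, ...) {
  cat("graph encoding schema\n")
  cat("  atom types   :", paste(x$atom_types, collapse = " "), "+ pad\n")
  cat("  max atoms (N):", x$max_atoms, "\n")
  cat("  bond classes :", paste(x$bond_classes, collapse = " "),
      sprintf("(B = %d)\n", length(x$bond_classes)))
  if (length(x$charge_classes) > 0L)
    cat("  charges      :", paste(x$charge_classes, collapse = " "), "\n")
  if (length(x$chiral_classes) > 0L)
    cat("  chirality    :", paste(x$chiral_classes, collapse = " "), "\n")
  cat("  feature width:", x$feature_width, "\n")
  invisible(x)
}

# feature column layout helpers
schema_pad_col <- function(schema) length(schema$atom_types) + 1L
schema_charge_cols <- function(schema) {
  if (length(schema$charge_classes) == 0L) return(integer(0))
  length(schema$atom_types) + 1L + seq_along(schema$charge_classes)
}
schema_chiral_cols <- function(schema) {
  if (length(schema$chiral_classes) == 0L) return(integer(0))
  length(schema$atom_types) + 1L + length(schema$charge_classes) +
    seq_along(schema$chiral_classes)
}

#' Named schema presets mirroring the study's dataset designs
#'
#' `"pubchem-like"`: C/H/N/O, 50 atoms. `"zinc15-ii-like"`: seven atom types
#' (C, H, N, O, Cl, S, F), 50 atoms. `"zinc15-iii-like"`: the seven types plus
#' formal charges (-1, 0, +1) and tetrahedral chirality. `"zinc15-i-like"`:
#' the seven types at 100 atoms (reproduces the harder, collapse-prone
#' regime only qualitatively).
#'
#' @param name preset name.
#' @param max_atoms optional override of the preset's atom budget.
#' @return a `graph_schema`.
#' @export
schema_preset <- function(name = c("pubchem-like", "zinc15-ii-like",
                                   "zinc15-iii-like", "zinc15-i-like"),
                          max_atoms = NULL) {
  name <- match.arg(name)
  seven <- c("C", "H", "N", "O", "Cl", "S", "F")
  s <- switch(name,
    "pubchem-like" = build_schema(c("C", "H", "N", "O"), max_atoms %||% 50L),
    "zinc15-ii-like" = build_schema(seven, max_atoms %||% 50L),
    "zinc15-iii-like" = build_schema(seven, max_atoms %||% 50L,
                                     charge_classes = c(-1L, 0L, 1L),
                                     chiral_classes = c("none", "cw", "ccw")),
    "zinc15-i-like" = build_schema(seven, max_atoms %||% 100L)
  )
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
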