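# Dataset construction: scaffold filtering, schema-constraint filtering and
# tensor serialization, mirroring how scaffold-specific training subsets are
# assembled from raw SMILES collections.

QUINOLINE_QUERY <- "c1ccc2ncccc2c1"

new_filter_report <- function(n_input, n_kept, rejection_counts) {
  structure(list(n_input = as.integer(n_input), n_kept = as.integer(n_kept),
                 rejection_counts = rejection_counts),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter report: kept %d / %d\n", x$n_kept, x$n_input))
  rc <- x$rejection_counts[x$rejection_counts > 0]
  if (length(rc) > 0)
    cat("  rejected:", paste(sprintf("%s=%d", names(rc), rc), collapse = ", "), "\n")
  invisible(x)
}

#' Keep molecules containing a scaffold substructure
#'
#' Substructure containment (not Murcko-scaffold equality): a molecule passes
#' if the query matches anywhere, so further-fused systems containing the
#' scaffold also pass. Unparseable molecules are counted, not raised.
#'
#' @param smiles character vector.
#' @param scaffold_query SMARTS/SMILES substructure query (default the
#'   quinoline bicyclic with nitrogen at the 1-position).
#' @return list(kept, report) with order preserved.
#' @export
filter_scaffold <- function(smiles, scaffold_query = QUINOLINE_QUERY) {
  if (length(smiles) == 0L)
    return(list(kept = character(0),
                report = new_filter_report(0L, 0L, c(parse = 0L, scaffold = 0L))))
  if (is.na(canonicalize(scaffold_query)))
    stop_molwgan("query", "scaffold query fails to parse: %s", scaffold_query)
  cnt <- smarts_match_count(smiles, scaffold_query)
  keep <- !is.na(cnt) & cnt > 0L
  rej <- c(parse = sum(is.na(cnt)), scaffold = sum(!is.na(cnt) & cnt == 0L))
  list(kept = smiles[keep],
       report = new_filter_report(length(smiles), sum(keep), rej))
}

#' Keep molecules that tensorize under a schema
#'
#' A molecule is kept iff [encode_molecule()] succeeds; rejections are broken
#' down by encode error code (`parse`, `size`, `element`, `charge`).
#'
#' @param smiles character vector.
#' @param schema a `graph_schema`.
#' @return list(kept, report).
#' @export
filter_constraints <- function(smiles, schema) {
  codes <- c("parse", "size", "element", "charge")
  rej <- stats::setNames(integer(length(codes)), codes)
  keep <- logical(length(smiles))
  for (k in seq_along(smiles)) {
    res <- tryCatch({ encode_molecule(smiles[k], schema); NA_character_ },
                    molwgan_error = function(e) e$code)
    if (is.na(res)) keep[k] <- TRUE
    else rej[res] <- rej[res] + 1L
  }
  list(kept = smiles[keep],
       report = new_filter_report(length(smiles), sum(keep), rej))
}

#' Serialize a filtered molecule list as stacked graph tensors
#'
#' Writes a compressed array archive (`tensors.rds`: arrays `adjacency`
#' M x N x N x B and `features` M x N x F) plus a JSON manifest recording the
#' schema, counts and a checksum of the source SMILES. Input must already pass
#' [filter_constraints()]; an encode failure is a hard error naming the
#' offending index.
#'
#' @param smiles character vector of schema-conformant molecules.
#' @param schema a `graph_schema`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
build_tensor_dataset <- function(smiles, schema, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  M <- length(smiles)
  N <- schema$max_atoms; B <- length(schema$bond_classes)
  A <- array(0, dim = c(M, N, N, B))
  X <- array(0, dim = c(M, N, schema$feature_width))
  n_atoms <- integer(M)
  for (k in seq_len(M)) {
    g <- tryCatch(encode_molecule(smiles[k], schema),
                  molwgan_error = function(e)
                    stop_molwgan("unfiltered",
                                 "molecule %d ('%s') fails to encode (%s); run filter_constraints first",
                                 k, smiles[k], e$code))
    A[k, , , ] <- g$adjacency
    X[k, , ] <- g$features
    n_atoms[k] <- g$n_atoms
  }
  tmp <- tempfile(); writeLines(smiles, tmp)
  checksum <- unname(tools::md5sum(tmp)); unlink(tmp)
  saveRDS(list(adjacency = A, features = X), file.path(out_dir, "tensors.rds"),
          compress = "gzip")
  manifest <- list(n_molecules = M, n_atoms = n_atoms,
                   schema = unclass(schema), source_md5 = checksum,
                   smiles = smiles)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back a tensor dataset
#' @param dir directory written by [build_tensor_dataset()].
#' @return list(adjacency, features, manifest, schema).
#' @export
load_tensor_dataset <- function(dir) {
  tens <- readRDS(file.path(dir, "tensors.rds"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sc <- manifest$schema
  schema <- build_schema(sc$atom_types, sc$max_atoms,
                         charge_classes = if (length(sc$charge_classes) > 0)
                           as.integer(sc$charge_classes) else integer(0),
                         chiral_classes = if (length(sc$chiral_classes) > 0)
                           sc$chiral_classes else character(0))
  list(adjacency = tens$adjacency, features = tens$features,
       manifest = manifest, schema = schema)
}

#' Read a SMILES text file
#'
#' One molecule per line, with an optional whitespace-separated identifier
#' that is attached as names.
#' @param path file path.
#' @return character vector of SMILES (named when identifiers are present).
#' @export
read_smiles <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(trimws(x))]
  smi <- sub("[ \t].*$", "", x)
  ids <- ifelse(grepl("[ \t]", x), sub("^[^ \t]+[ \t]+", "", x), NA)
  if (any(!is.na(ids))) names(smi) <- ids
  smi
}

#' Preprocess a raw SMILES list into a training dataset
#'
#' Scaffold filter, then schema-constraint filter, then tensor serialization;
#' the composed filters commute as set operations. Optionally de-duplicates by
#' canonical SMILES (duplicates are retained by default).
#'
#' @param smiles character vector of raw SMILES.
#' @param schema a `graph_schema` (e.g. [schema_preset()]).
#' @param scaffold_query substructure the molecules must contain; `NULL`
#'   skips the scaffold filter.
#' @param out_dir if non-NULL, tensors + manifest are written there.
#' @param dedupe canonicalize and uniquify first.
#' @return list(kept, scaffold_report, constraint_report, manifest).
#' @export
preprocess_dataset <- function(smiles, schema,
                               scaffold_query = QUINOLINE_QUERY,
                               out_dir = NULL, dedupe = FALSE) {
  if (dedupe) {
    can <- canonicalize(smiles, use_stereo = length(schema$chiral_classes) > 0L)
    smiles <- unique(can[!is.na(can)])
  }
  sr <- NULL
  if (!is.null(scaffold_query)) {
    fs <- filter_scaffold(smiles, scaffold_query)
    smiles <- fs$kept; sr <- fs$report
  }
  fc <- filter_constraints(smiles, schema)
  manifest <- NULL
  if (!is.null(out_dir))
    manifest <- build_tensor_dataset(fc$kept, schema, out_dir)
  list(kept = fc$kept, scaffold_report = sr, constraint_report = fc$report,
       manifest = manifest)
}
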