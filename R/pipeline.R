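# End-to-end pipeline driver: fixtures -> preprocess -> train -> generate ->
# evaluate -> screen -> chemspace, configured from one YAML file, with a run
# manifest sufficient to re-run bit-compatibly.

#' Run the pipeline from a config file
#'
#' The YAML config holds a `seed`, a `stages` vector (any of `fixtures`,
#' `preprocess`, `train`, `generate`, `evaluate`, `screen`, `chemspace`), an
#' `out_dir`, a `schema` section (`preset` or explicit fields), a `model`
#' section (`preset` or explicit [model_config()] fields plus stage options
#' such as `max_iters`), and per-stage option blocks. One global seed fans
#' out to named streams so stages can be re-run independently. Artifacts and
#' a `manifest.json` are written under `out_dir`.
#'
#' @param config_path path to the YAML config.
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config_path) {
  cfgy <- yaml::read_yaml(config_path)
  out_dir <- cfgy$out_dir %||% "molwgan-run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfgy$seed %||% 1L)
  stages <- cfgy$stages %||% c("fixtures", "preprocess", "train", "generate",
                               "evaluate", "screen")

  schema <- if (!is.null(cfgy$schema$preset)) {
    schema_preset(cfgy$schema$preset, max_atoms = cfgy$schema$max_atoms)
  } else {
    build_schema(cfgy$schema$atom_types %||% c("C", "H", "N", "O"),
                 cfgy$schema$max_atoms %||% 50L,
                 charge_classes = as.integer(cfgy$schema$charge_classes %||% integer(0)),
                 chiral_classes = as.character(cfgy$schema$chiral_classes %||% character(0)))
  }
  mc <- cfgy$model %||% list()
  config <- if (!is.null(mc$preset)) make_config(mc$preset, seed = seed) else {
    args <- mc[intersect(names(mc), .config_fields)]
    args$seed <- args$seed %||% seed
    do.call(model_config, args)
  }

  manifest <- list(command = "run_pipeline", config_path = config_path,
                   config_snapshot = cfgy, resolved_model = unclass(config),
                   resolved_schema = unclass(schema), seed = seed,
                   input_checksums = list(), artifact_paths = list(),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  smiles <- NULL
  if ("fixtures" %in% stages) {
    fo <- cfgy$fixtures %||% list()
    sp <- fixture_spec(core_smiles = fo$core_smiles %||% "c1ccc2ncccc2c1",
                       substituents = unlist(fo$substituents) %||% default_substituents(),
                       max_substitutions = fo$max_substitutions %||% 2L,
                       count = fo$count %||% 200L, seed = seed, schema = schema)
    smiles <- enumerate_quinolines(sp)
    path <- file.path(out_dir, "fixtures.smi")
    write_fixtures(smiles, path)
    manifest$artifact_paths$fixtures <- path
  } else if (!is.null(cfgy$input)) {
    smiles <- readLines(cfgy$input)
    smiles <- sub("[ \t].*$", "", smiles[nzchar(smiles)])
    manifest$input_checksums[[cfgy$input]] <- unname(tools::md5sum(cfgy$input))
  }

  pre <- NULL
  if ("preprocess" %in% stages) {
    po <- cfgy$preprocess %||% list()
    pre <- preprocess_dataset(smiles, schema,
                              scaffold_query = po$scaffold %||% QUINOLINE_QUERY,
                              out_dir = file.path(out_dir, "data"),
                              dedupe = isTRUE(po$dedupe))
    jsonlite::write_json(list(scaffold = unclass(pre$scaffold_report),
                              constraints = unclass(pre$constraint_report)),
                         file.path(out_dir, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA)
    smiles <- pre$kept
    manifest$artifact_paths$data <- file.path(out_dir, "data")
  }

  fit <- NULL
  if ("train" %in% stages) {
    to <- cfgy$train %||% list()
    fit <- molwgan(smiles, schema = schema, config = config,
                   scaffold_query = NULL,   # already filtered upstream
                   max_iters = to$max_iters %||% 100L,
                   eval_every = to$eval_every %||% 1L,
                   eval_samples = to$eval_samples %||% 100L,
                   stop_rules = to$stop_rules %||% list(),
                   seed = seed,
                   checkpoint_dir = file.path(out_dir, "checkpoints"))
    saveRDS(fit, file.path(out_dir, "fit.rds"))
    log_path <- file.path(out_dir, "training_log.jsonl")
    con <- file(log_path, "w")
    st <- fit$state
    for (k in seq_along(st$d_loss)) {
      rec <- list(iteration = k, d_loss = st$d_loss[k], g_loss = st$g_loss[k])
      hh <- Filter(function(h) h$iteration == k, st$metric_history)
      if (length(hh) > 0L) rec <- c(rec, unclass(hh[[1L]]$report))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
    close(con)
    manifest$artifact_paths$fit <- file.path(out_dir, "fit.rds")
  }

  archive <- NULL
  if ("generate" %in% stages && !is.null(fit)) {
    go <- cfgy$generate %||% list()
    archive <- exhaustive_generate(
      list(params = fit$state$params_best$gen, config = config),
      schema, reference_canon_set = fit$reference,
      run_size = go$run_size %||% 100L, patience = go$patience %||% 100L,
      seed = seed)
    writeLines(archive$accepted, file.path(out_dir, "accepted.smi"))
    if (length(archive$accepted) > 0L)
      write_sdf(archive$accepted, file.path(out_dir, "accepted.sdf"))
    manifest$artifact_paths$accepted <- file.path(out_dir, "accepted.smi")
  }

  if ("evaluate" %in% stages && !is.null(fit)) {
    rep <- evaluate_snapshot(fit$state$params_best$gen, schema, config,
                             n_samples = (cfgy$evaluate %||% list())$n_samples %||% 100L,
                             reference_canon_set = fit$reference,
                             seed = seed + 1L)
    jsonlite::write_json(unclass(rep), file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$artifact_paths$metrics <- file.path(out_dir, "metrics.json")
  }

  if ("screen" %in% stages && !is.null(archive) && length(archive$accepted) > 0L) {
    sc <- screen(archive$accepted, tox_predictor = stub_tox_predictor)
    utils::write.csv(sc$records, file.path(out_dir, "screen.csv"),
                     row.names = FALSE)
    jsonlite::write_json(sc$summary, file.path(out_dir, "screen_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$artifact_paths$screen <- file.path(out_dir, "screen.csv")
  }

  if ("chemspace" %in% stages && !is.null(archive) &&
      length(archive$accepted) >= 3L) {
    co <- cfgy$chemspace %||% list()
    emb <- embed_chemspace(list(reference = smiles,
                                generated = archive$accepted),
                           n_reference_sample = co$n_reference_sample %||% 200L,
                           seed = seed)
    utils::write.csv(emb, file.path(out_dir, "chemspace.csv"), row.names = FALSE)
    manifest$artifact_paths$chemspace <- file.path(out_dir, "chemspace.csv")
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
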