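# The modelling front-end: fit a scaffold-constrained graph WGAN to a set of
# molecules and interact with it through the usual generic verbs
# (print / summary / plot / simulate).

#' Fit a molecular-graph WGAN
#'
#' Filters the input molecules to the scaffold and schema, tensorizes them,
#' and runs adversarial training. The returned object carries the trained
#' parameters (best-by-connected-validity and last), the loss and metric
#' traces, and the canonical reference set used for novelty.
#'
#' @param x character vector of SMILES (the training library).
#' @param schema a `graph_schema` (default the C/H/N/O, 50-atom preset).
#' @param config a `model_config` (default `make_config("model3")` scaled
#'   down is usually preferable for CPU work; see [model_config()]).
#' @param scaffold_query substructure all training molecules must contain;
#'   `NULL` to skip.
#' @param max_iters generator updates.
#' @param eval_every,eval_samples snapshot cadence and size.
#' @param stop_rules early-stopping rules ([early_stop()]).
#' @param seed master seed.
#' @param verbose print progress.
#' @param ... passed to [train()].
#' @return an object of class `molwgan`.
#' @export
molwgan <- function(x, schema = schema_preset("pubchem-like"),
                    config = make_config("base"),
                    scaffold_query = QUINOLINE_QUERY,
                    max_iters = 100L, eval_every = 1L, eval_samples = 100L,
                    stop_rules = list(), seed = config$seed, verbose = FALSE,
                    ...) {
  stopifnot(is.character(x), length(x) > 0L)
  pre <- preprocess_dataset(x, schema, scaffold_query = scaffold_query)
  kept <- pre$kept
  if (length(kept) == 0L)
    stop_molwgan("train", "no molecules survive the scaffold/schema filters")
  reference <- canonicalize(kept,
                            use_stereo = length(schema$chiral_classes) > 0L)
  st <- train(kept, config, schema, max_iters = max_iters,
              eval_every = eval_every, eval_samples = eval_samples,
              reference_canon_set = reference, stop_rules = stop_rules,
              seed = seed, verbose = verbose, ...)
  structure(list(state = st, schema = schema, config = config,
                 reference = reference,
                 filter_reports = list(scaffold = pre$scaffold_report,
                                       constraints = pre$constraint_report),
                 call = match.call()),
            class = "molwgan")
}

#' @export
print.molwgan <- function(x, ...) {
  st <- x$state
  cat("molecular-graph WGAN fit\n")
  cat(sprintf("  config '%s', %d training molecules, %d iterations (%s)\n",
              x$config$name, length(x$reference), st$iteration,
              st$stop_reason))
  if (length(st$metric_history) > 0L) {
    last <- st$metric_history[[length(st$metric_history)]]$report
    cat(sprintf("  last snapshot: validity %.2f, connected %.2f, unique %.2f\n",
                last$validity, last$connected_validity, last$uniqueness))
  }
  invisible(x)
}

#' @export
summary.molwgan <- function(object, ...) {
  st <- object$state
  hist <- lapply(st$metric_history, `[[`, "report")
  its <- vapply(st$metric_history, `[[`, 0L, "iteration")
  df <- data.frame(
    iteration = its,
    validity = vapply(hist, `[[`, 0, "validity"),
    connected_validity = vapply(hist, `[[`, 0, "connected_validity"),
    scaffold_rate = vapply(hist, `[[`, 0, "scaffold_rate"),
    novelty = vapply(hist, `[[`, 0, "novelty"),
    uniqueness = vapply(hist, `[[`, 0, "uniqueness"))
  out <- list(config = object$config, n_train = length(object$reference),
              iterations = st$iteration, stop_reason = st$stop_reason,
              metrics = df,
              best_connected_validity = st$best_cv,
              param_counts = c(generator = count_params(st$params_best$gen),
                               discriminator = count_params(st$params_best$disc)),
              d_loss = st$d_loss, g_loss = st$g_loss)
  class(out) <- "summary.molwgan"
  out
}

#' @export
print.summary.molwgan <- function(x, ...) {
  cat(sprintf("WGAN '%s': %d molecules, %d iterations, stopped by %s\n",
              x$config$name, x$n_train, x$iterations, x$stop_reason))
  cat(sprintf("  trainable parameters: generator %s, discriminator %s\n",
              format(x$param_counts[1], big.mark = ","),
              format(x$param_counts[2], big.mark = ",")))
  cat(sprintf("  best connected validity: %.3f\n", x$best_connected_validity))
  if (nrow(x$metrics) > 0L) {
    cat("  final metrics:\n")
    print(utils::tail(x$metrics, 1L), row.names = FALSE)
  }
  invisible(x)
}

#' Plot training traces of a fitted graph WGAN
#'
#' Left panel: critic and generator losses. Right panel: validity and
#' connected validity snapshots, smoothed with a five-point moving average
#' (the raw history is retained in the object).
#' @param x a `molwgan` fit.
#' @param window moving-average window.
#' @param ... ignored.
#' @export
plot.molwgan <- function(x, window = 5L, ...) {
  st <- x$state
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(st$d_loss, type = "l", xlab = "iteration", ylab = "loss",
                 main = "Wasserstein losses", col = "firebrick")
  graphics::lines(st$g_loss, col = "steelblue")
  graphics::legend("topright", c("critic", "generator"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  if (length(st$metric_history) > 0L) {
    its <- vapply(st$metric_history, `[[`, 0L, "iteration")
    v <- moving_average(vapply(st$metric_history,
                               function(h) h$report$validity, 0), window)
    cv <- moving_average(vapply(st$metric_history,
                                function(h) h$report$connected_validity, 0),
                         window)
    graphics::plot(its, v, type = "l", ylim = c(0, 1), xlab = "iteration",
                   ylab = "rate", main = "generation quality", col = "darkgreen")
    graphics::lines(its, cv, col = "purple")
    graphics::legend("topleft", c("validity", "connected validity"), lty = 1,
                     col = c("darkgreen", "purple"), bty = "n")
  }
  invisible(x)
}

#' Generate molecules from a fitted graph WGAN
#'
#' Samples latent vectors, runs the generator (best checkpoint by default),
#' discretizes categorically and decodes.
#'
#' @param object a `molwgan` fit.
#' @param nsim number of graphs to sample.
#' @param seed integer seed.
#' @param use one of `"best"`, `"last"`.
#' @param ... ignored.
#' @return data.frame with columns `smiles`, `valid`, `connected`, `novel`;
#'   attribute `"decoded"` holds the full decoded list.
#' @export
simulate.molwgan <- function(object, nsim = 100L, seed = 1L,
                             use = c("best", "last"), ...) {
  use <- match.arg(use)
  params <- if (use == "best") object$state$params_best else
    object$state$params_last
  z <- sample_latent(nsim, object$config$latent_dim, seed = seed)
  outs <- generator_forward(z, params$gen, object$schema, object$config)
  decoded <- lapply(seq_along(outs), function(k)
    decode_graph(discretize(outs[[k]], object$schema, mode = "categorical",
                            seed = seed * 7919L + k), object$schema))
  smi <- vapply(decoded, `[[`, "", "canonical_smiles")
  df <- data.frame(
    smiles = smi,
    valid = vapply(decoded, `[[`, TRUE, "valid"),
    connected = vapply(decoded, `[[`, TRUE, "connected"),
    novel = !is.na(smi) & !(smi %in% object$reference),
    stringsAsFactors = FALSE)
  attr(df, "decoded") <- decoded
  df
}

#' Residual-style diagnostics are not defined for an adversarial generator
#' @export
residuals.molwgan <- function(object, ...) {
  stop("a GAN has no residuals; use summary() for training diagnostics")
}
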