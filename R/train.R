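# Adversarial training: n_critic critic updates (Wasserstein loss + gradient
# penalty, double backpropagation through the input gradient) per generator
# update (straight-through Gumbel discretization on the training path).
# Terminology: one "iteration" = one generator update together with its
# n_critic critic updates (the literature also calls this an epoch when one
# pass covers the data).

## ---------------------------------------------------------------------------
## internal: one training step's forward/backward passes
## ---------------------------------------------------------------------------

# convert stacked dataset arrays into a per-sample list of plain arrays
.dataset_samples <- function(dataset, schema) {
  B <- length(schema$bond_classes)
  if (is.character(dataset)) {
    return(lapply(dataset, function(s) {
      g <- encode_molecule(s, schema)
      list(A = lapply(seq_len(B), function(b) g$adjacency[, , b]),
           X = g$features)
    }))
  }
  if (!is.null(dataset$adjacency) && length(dim(dataset$adjacency)) == 4L) {
    M <- dim(dataset$adjacency)[1]
    lapply(seq_len(M), function(k) list(
      A = lapply(seq_len(B), function(b) dataset$adjacency[k, , , b]),
      X = matrix(dataset$features[k, , ], dim(dataset$features)[2])))
  } else stop_molwgan("train", "dataset must be tensor arrays or SMILES")
}

# Gumbel sampling of hard one-hot arrays from soft distributions (plain
# arrays; `soft_A` is a list of B N x N matrices)
.st_hard <- function(soft_A, Xsoft, schema, rng) {
  N <- schema$max_atoms; B <- length(schema$bond_classes)
  draws <- .sample_onehot(soft_A, Xsoft, schema,
                          noise = with_rng(rng,
                            stats::runif(N * N * B + N * ncol(Xsoft))),
                          temperature = 1)
  Ahard <- draws$A; Xhard <- draws$X
  pads <- which(Xhard[, schema_pad_col(schema)] == 1)
  for (i in pads) {
    Ahard[i, , ] <- 0; Ahard[, i, ] <- 0
    Ahard[i, , 1L] <- 1; Ahard[, i, 1L] <- 1
  }
  for (i in seq_len(N)) { Ahard[i, i, ] <- 0; Ahard[i, i, 1L] <- 1 }
  list(A = Ahard, X = Xhard)
}

.drop_masks <- function(config, rng) {
  p <- config$dropout
  if (p <= 0) return(NULL)
  mk <- function(nc) with_rng(rng,
    matrix((stats::runif(nc) >= p) / (1 - p), 1, nc))
  list(mk(config$disc_units), mk(config$disc_units))
}

## ---------------------------------------------------------------------------
## evaluation snapshot and early stopping
## ---------------------------------------------------------------------------

#' Evaluate a generator snapshot
#'
#' Samples `n_samples` latent vectors (seeded, on a stream independent of
#' training), discretizes categorically, decodes, and computes the metric
#' suite.
#'
#' @param generator_params generator parameter list.
#' @param schema a `graph_schema`.
#' @param config a `model_config`.
#' @param n_samples graphs to generate (the evaluation batch; default 100).
#' @param reference_canon_set canonical SMILES for novelty.
#' @param seed integer.
#' @param scaffold_query scaffold for the scaffold rate.
#' @return a `metric_report`.
#' @export
evaluate_snapshot <- function(generator_params, schema, config,
                              n_samples = 100L,
                              reference_canon_set = character(0), seed = 1L,
                              scaffold_query = QUINOLINE_QUERY) {
  stopifnot(n_samples >= 1L)
  z <- sample_latent(n_samples, config$latent_dim, seed = seed)
  outs <- generator_forward(z, generator_params, schema, config)
  decoded <- lapply(seq_along(outs), function(k)
    decode_graph(discretize(outs[[k]], schema, mode = "categorical",
                            seed = seed * 131L + k), schema))
  compute_metrics(decoded, reference_canon_set, scaffold_query)
}

#' Early-stopping decision over a metric history
#'
#' `connectivity_collapse`: connected validity has been 0 for
#' `collapse_patience` consecutive evaluations after once being positive.
#' `plateau`: the best connected validity has not improved by more than
#' `min_delta` for `plateau_patience` evaluations.
#'
#' @param history list of `metric_report` (oldest first).
#' @param rules list(collapse_patience = 10, min_delta = 0.01,
#'   plateau_patience = 50).
#' @return list(stop, reason) with reason one of
#'   `"connectivity_collapse"`, `"plateau"`, or `NA`.
#' @export
early_stop <- function(history, rules = list()) {
  stopifnot(length(history) > 0L)
  cp <- rules$collapse_patience %||% 10L
  md <- rules$min_delta %||% 0.01
  pp <- rules$plateau_patience %||% 50L
  cv <- vapply(history, `[[`, 0, "connected_validity")
  n <- length(cv)
  if (n >= cp + 1L) {
    tail_zero <- all(cv[(n - cp + 1L):n] == 0)
    had_positive <- any(cv[seq_len(n - cp)] > 0)
    if (tail_zero && had_positive)
      return(list(stop = TRUE, reason = "connectivity_collapse"))
  }
  if (n >= pp + 1L) {
    best_then <- max(cv[seq_len(n - pp)])
    best_since <- max(cv[(n - pp + 1L):n])
    if (best_since - best_then <= md)
      return(list(stop = TRUE, reason = "plateau"))
  }
  list(stop = FALSE, reason = NA_character_)
}

## ---------------------------------------------------------------------------
## training loop
## ---------------------------------------------------------------------------

#' Train the WGAN (low-level loop)
#'
#' Alternates `n_critic` critic updates (Wasserstein loss with gradient
#' penalty) and one generator update per iteration, evaluating a metric
#' snapshot every `eval_every` iterations, applying the early-stopping rules,
#' and tracking the best parameters by connected validity (the snapshot at
#' the first evaluation counts, so a best checkpoint always exists).
#'
#' @param dataset training data: a character vector of SMILES, or the
#'   list(adjacency, features) arrays from [load_tensor_dataset()].
#' @param config a `model_config`.
#' @param schema a `graph_schema`.
#' @param max_iters generator updates to run.
#' @param eval_every snapshot cadence in iterations (default 1).
#' @param eval_samples graphs per snapshot.
#' @param reference_canon_set canonical SMILES for novelty during snapshots.
#' @param stop_rules early-stopping rules, see [early_stop()].
#' @param seed master seed; fans out to independent init/training/eval
#'   streams.
#' @param callbacks optional list of functions called as
#'   `fn(state, iteration)` after each evaluation; a callback returning a
#'   `metric_report` replaces the snapshot (hook for injecting synthetic
#'   metric traces when exercising the stopping rules).
#' @param checkpoint_dir optional directory for `best.rds` / `last.rds`.
#' @param verbose print progress lines.
#' @return a `train_state` list: `iteration`, `d_loss`, `g_loss` (traces),
#'   `metric_history` (list of list(iteration, report)), `stop_reason`,
#'   `params_best`, `params_last`, `opt`, `config`, `schema`.
#' @export
train <- function(dataset, config, schema, max_iters = 100L, eval_every = 1L,
                  eval_samples = 100L, reference_canon_set = character(0),
                  stop_rules = list(), seed = config$seed, callbacks = list(),
                  checkpoint_dir = NULL, verbose = FALSE) {
  samples <- .dataset_samples(dataset, schema)
  if (length(samples) == 0L) stop_molwgan("train", "dataset is empty")
  N <- schema$max_atoms; B <- length(schema$bond_classes)
  bs <- min(config$batch_size, length(samples))

  params <- init_gan_params(config, schema)
  opt_g <- opt_init(params$gen, config)
  opt_d <- opt_init(params$disc, config)
  rng_train <- rng_stream(seed, "training")
  rng_eval_base <- seed

  state <- list(iteration = 0L, d_loss = numeric(0), g_loss = numeric(0),
                metric_history = list(), stop_reason = NA_character_,
                params_best = params, params_last = params,
                best_cv = -Inf, best_val = -Inf, config = config,
                schema = schema)
  class(state) <- "train_state"
  if (max_iters == 0L) {
    state$stop_reason <- "max_iters"
    return(state)
  }

  critic_step <- function(params) {
    idx <- with_rng(rng_train, sample.int(length(samples), bs, replace = TRUE))
    real <- samples[idx]
    z <- with_rng(rng_train,
                  matrix(stats::rnorm(bs * config$latent_dim), bs, config$latent_dim))
    Pd <- .params_to_nodes(params$disc)
    dm <- .drop_masks(config, rng_train)
    fakes <- lapply(seq_len(bs), function(k) {
      gp <- .gen_forward_plain(z[k, , drop = FALSE], params$gen, schema, config)
      st <- .st_hard(gp$edge_probs, gp$node_probs, schema, rng_train)
      list(A = lapply(seq_len(B), function(b) st$A[, , b]), X = st$X)
    })
    eps <- with_rng(rng_train, stats::runif(bs))

    stk_r <- .stack_graphs(lapply(real, `[[`, "A"), lapply(real, `[[`, "X"), B)
    stk_f <- .stack_graphs(lapply(fakes, `[[`, "A"), lapply(fakes, `[[`, "X"), B)
    ind <- ag_const(stk_r$ind)
    scores_r <- .disc_forward_batch(lapply(stk_r$A, ag_const),
                                    ag_const(stk_r$X), Pd, schema, config,
                                    dm, ind)
    scores_f <- .disc_forward_batch(lapply(stk_f$A, ag_const),
                                    ag_const(stk_f$X), Pd, schema, config,
                                    dm, ind)
    # gradient penalty on the batch: per-sample interpolation, one stacked
    # critic pass, per-sample input-gradient norms restricted to each block
    Ai <- lapply(seq_len(B), function(b) {
      M <- stk_r$A[[b]]
      for (s in seq_len(bs)) {
        rows <- (s - 1L) * stk_r$N + seq_len(stk_r$N)
        M[rows, rows] <- eps[s] * stk_r$A[[b]][rows, rows] +
          (1 - eps[s]) * stk_f$A[[b]][rows, rows]
      }
      ag_input(M)
    })
    Xi_v <- stk_r$X
    for (s in seq_len(bs)) {
      rows <- (s - 1L) * stk_r$N + seq_len(stk_r$N)
      Xi_v[rows, ] <- eps[s] * stk_r$X[rows, ] + (1 - eps[s]) * stk_f$X[rows, ]
    }
    Xi <- ag_input(Xi_v)
    Di <- ag_sum(.disc_forward_batch(Ai, Xi, Pd, schema, config, dm, ind))
    gs_in <- ag_grad(Di, c(Ai, list(Xi)))
    bm <- ag_const(stk_r$blockmask)
    per_sample_ss <- Reduce(ag_add, c(
      lapply(gs_in[seq_len(B)], function(g)
        ag_matmul(ind, ag_rowsums(ag_mul(ag_mul(g, g), bm)))),
      list(ag_matmul(ind, ag_rowsums(ag_mul(gs_in[[B + 1L]], gs_in[[B + 1L]]))))))
    pen <- ag_mean(ag_pow(ag_sub(ag_sqrt(per_sample_ss), ag_const(1)), 2))

    d_loss <- ag_add(ag_sub(ag_mean(scores_f), ag_mean(scores_r)),
                     ag_mul(ag_const(config$gp_lambda), pen))
    flat <- .param_nodes_flat(Pd)
    gs <- ag_grad(d_loss, flat)
    grads <- .grads_from_nodes(Pd, gs)
    list(loss = ag_val(d_loss)[1], grads = grads)
  }

  gen_step <- function(params) {
    z <- with_rng(rng_train,
                  matrix(stats::rnorm(bs * config$latent_dim), bs, config$latent_dim))
    Pg <- .params_to_nodes(params$gen)
    Pd_const <- rapply(params$disc, ag_const, how = "replace", classes = "matrix")
    sts <- lapply(seq_len(bs), function(k) {
      gn <- .gen_forward_one(ag_const(z[k, , drop = FALSE]), Pg, schema, config)
      st <- .st_hard(lapply(gn$edge_probs, ag_val), ag_val(gn$node_probs),
                     schema, rng_train)
      list(A_nodes = lapply(seq_along(gn$edge_probs), function(b)
             ag_st(gn$edge_probs[[b]], st$A[, , b])),
           X_node = ag_st(gn$node_probs, st$X))
    })
    # stack the straight-through samples block-diagonally for one critic pass
    N <- schema$max_atoms
    ind <- matrix(0, bs, bs * N)
    for (s in seq_len(bs)) ind[s, (s - 1L) * N + seq_len(N)] <- 1
    embed <- function(node, s, nrow_total) {
      E <- matrix(0, nrow_total, N); E[(s - 1L) * N + seq_len(N), ] <- diag(N)
      ag_matmul(ag_const(E), node)
    }
    Abig <- lapply(seq_len(B), function(b) {
      Reduce(ag_add, lapply(seq_len(bs), function(s) {
        E <- matrix(0, bs * N, N); E[(s - 1L) * N + seq_len(N), ] <- diag(N)
        Ec <- ag_const(E)
        ag_matmul(ag_matmul(Ec, sts[[s]]$A_nodes[[b]]), ag_t(Ec))
      }))
    })
    Xbig <- Reduce(ag_add, lapply(seq_len(bs), function(s)
      embed(sts[[s]]$X_node, s, bs * N)))
    scores <- .disc_forward_batch(Abig, Xbig, Pd_const, schema, config, NULL,
                                  ag_const(ind))
    g_loss <- ag_neg(ag_mean(scores))
    flat <- .param_nodes_flat(Pg)
    gs <- ag_grad(g_loss, flat)
    grads <- .grads_from_nodes(Pg, gs)
    list(loss = ag_val(g_loss)[1], grads = grads)
  }

  for (it in seq_len(max_iters)) {
    d_last <- NA_real_
    for (ci in seq_len(config$n_critic)) {
      cs <- critic_step(params)
      if (!is.finite(cs$loss)) {
        state$stop_reason <- "nan_loss"
        state$diagnostic <- list(iteration = it, critic_step = ci,
                                 d_loss = cs$loss)
        warning("non-finite critic loss; aborting with diagnostic state")
        return(state)
      }
      up <- opt_step(params$disc, cs$grads, opt_d)
      params$disc <- up$params; opt_d <- up$state
      d_last <- cs$loss
    }
    gsr <- gen_step(params)
    if (!is.finite(gsr$loss)) {
      state$stop_reason <- "nan_loss"
      state$diagnostic <- list(iteration = it, g_loss = gsr$loss)
      warning("non-finite generator loss; aborting with diagnostic state")
      return(state)
    }
    up <- opt_step(params$gen, gsr$grads, opt_g)
    params$gen <- up$params; opt_g <- up$state

    state$iteration <- it
    state$d_loss <- c(state$d_loss, d_last)
    state$g_loss <- c(state$g_loss, gsr$loss)
    state$params_last <- params

    if (it %% eval_every == 0L) {
      rep <- evaluate_snapshot(params$gen, schema, config,
                               n_samples = eval_samples,
                               reference_canon_set = reference_canon_set,
                               seed = rng_eval_base + it)
      for (cb in callbacks) {
        r <- cb(state, it)
        if (inherits(r, "metric_report")) rep <- r
      }
      state$metric_history[[length(state$metric_history) + 1L]] <-
        list(iteration = it, report = rep)
      # best checkpoint: lexicographic on (connected validity, validity)
      if (rep$connected_validity > state$best_cv ||
          (rep$connected_validity == state$best_cv &&
           rep$validity > state$best_val)) {
        state$best_cv <- rep$connected_validity
        state$best_val <- rep$validity
        state$params_best <- params
        state$opt_best <- list(gen = opt_g, disc = opt_d)
      }
      if (verbose)
        message(sprintf("iter %d: d %.4f g %.4f | val %.2f conn %.2f",
                        it, d_last, gsr$loss, rep$validity,
                        rep$connected_validity))
      hist <- lapply(state$metric_history, `[[`, "report")
      es <- early_stop(hist, stop_rules)
      if (es$stop) {
        state$stop_reason <- es$reason
        break
      }
    }
  }
  if (is.na(state$stop_reason)) state$stop_reason <- "max_iters"
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(list(params = state$params_best,
                 opt = state$opt_best %||% list(gen = opt_g, disc = opt_d),
                 config = config, schema = schema, version = 1L),
            file.path(checkpoint_dir, "best.rds"))
    saveRDS(list(params = state$params_last,
                 opt = list(gen = opt_g, disc = opt_d),
                 config = config, schema = schema, version = 1L),
            file.path(checkpoint_dir, "last.rds"))
  }
  state
}

#' Moving-average view of a metric trace
#'
#' Pure view used for plotting (window 5 by default); the raw history is what
#' is persisted.
#' @param x numeric vector.
#' @param window window width.
#' @return numeric vector of the same length (leading values average the
#'   available prefix).
#' @export
moving_average <- function(x, window = 5L) {
  vapply(seq_along(x), function(i) mean(x[max(1L, i - window + 1L):i]), 0)
}
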