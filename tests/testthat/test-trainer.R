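# Training loop mechanics: state handling, determinism, early stopping and
# evaluation snapshots. The long smoke run lives in the acceptance tests.

test_that("zero iterations return the initial state", {
  sch <- schema_chno(20L)
  lib <- fixture_library(sch, count = 5L, seed = 2L)[1:3]
  st <- train(lib, tiny_config(), sch, max_iters = 0L)
  expect_s3_class(st, "train_state")
  expect_equal(st$iteration, 0L)
  expect_identical(st$stop_reason, "max_iters")
  expect_length(st$metric_history, 0L)
})

test_that("training traces are deterministic under a fixed seed", {
  sch <- schema_chno(20L)
  lib <- fixture_library(sch, count = 8L, seed = 4L)
  cfg <- tiny_config(batch_size = 2L)
  st1 <- train(lib, cfg, sch, max_iters = 3L, eval_every = 1L,
               eval_samples = 5L, seed = 17L)
  st2 <- train(lib, cfg, sch, max_iters = 3L, eval_every = 1L,
               eval_samples = 5L, seed = 17L)
  expect_identical(st1$d_loss, st2$d_loss)
  expect_identical(st1$g_loss, st2$g_loss)
  expect_identical(lapply(st1$metric_history, `[[`, "report"),
                   lapply(st2$metric_history, `[[`, "report"))
  st3 <- train(lib, cfg, sch, max_iters = 3L, eval_every = 1L,
               eval_samples = 5L, seed = 18L)
  expect_false(identical(st1$d_loss, st3$d_loss))
})

test_that("early stopping implements collapse and plateau rules", {
  mk <- function(cv) molwgan:::new_metric_report(10L, 0.5, cv, 0, 0, 0)
  # collapse: positive once, then zero for collapse_patience evaluations
  hist <- lapply(c(0.3, 0, 0, 0), mk)
  r <- early_stop(hist, list(collapse_patience = 3L))
  expect_true(r$stop)
  expect_identical(r$reason, "connectivity_collapse")
  # never positive: not a collapse
  r0 <- early_stop(lapply(c(0, 0, 0, 0), mk), list(collapse_patience = 3L))
  expect_false(r0$stop)
  # monotone improvement never stops
  r1 <- early_stop(lapply(seq(0.1, 0.9, by = 0.1), mk),
                   list(plateau_patience = 5L, collapse_patience = 3L))
  expect_false(r1$stop)
  # flat trace of length plateau_patience + 1 stops with plateau
  r2 <- early_stop(lapply(rep(0.4, 6), mk), list(plateau_patience = 5L))
  expect_true(r2$stop)
  expect_identical(r2$reason, "plateau")
})

test_that("evaluation snapshots are bounded, seeded and reproducible", {
  sch <- schema_chno(15L)
  cfg <- tiny_config()
  p <- init_gan_params(cfg, sch)
  r1 <- evaluate_snapshot(p$gen, sch, cfg, n_samples = 10L, seed = 5L)
  r2 <- evaluate_snapshot(p$gen, sch, cfg, n_samples = 10L, seed = 5L)
  expect_identical(r1, r2)
  for (f in c("validity", "connected_validity", "scaffold_rate", "novelty",
              "uniqueness")) {
    expect_gte(r1[[f]], 0)
    expect_lte(r1[[f]], 1)
  }
  expect_equal(r1$n_generated, 10L)
})

test_that("synthetic metric traces injected via callback drive early stop", {
  sch <- schema_chno(20L)
  lib <- fixture_library(sch, count = 5L, seed = 2L)[1:4]
  trace <- c(0.5, 0.4, 0, 0, 0)
  cb <- function(state, iteration)
    molwgan:::new_metric_report(5L, 0.5, trace[iteration], 0, 0, 0)
  st <- train(lib, tiny_config(batch_size = 2L), sch, max_iters = 10L,
              eval_every = 1L, eval_samples = 2L, callbacks = list(cb),
              stop_rules = list(collapse_patience = 3L))
  expect_identical(st$stop_reason, "connectivity_collapse")
  expect_equal(st$iteration, 5L)   # stops right when the rule first fires
})

test_that("checkpoints are written and the best tracks connected validity", {
  sch <- schema_chno(20L)
  lib <- fixture_library(sch, count = 5L, seed = 2L)[1:4]
  ckdir <- file.path(tempdir(), "cks")
  st <- train(lib, tiny_config(batch_size = 2L), sch, max_iters = 2L,
              eval_every = 1L, eval_samples = 4L, checkpoint_dir = ckdir)
  expect_true(file.exists(file.path(ckdir, "best.rds")))
  expect_true(file.exists(file.path(ckdir, "last.rds")))
  ck <- readRDS(file.path(ckdir, "best.rds"))
  expect_named(ck, c("params", "opt", "config", "schema", "version"))
  first_cv <- st$metric_history[[1]]$report$connected_validity
  expect_gte(st$best_cv, first_cv)
  unlink(ckdir, recursive = TRUE)
})

test_that("moving average is a pure view with a warm-up prefix", {
  x <- c(1, 2, 3, 4, 5, 6)
  m <- moving_average(x, window = 5L)
  expect_equal(m[1], 1)
  expect_equal(m[2], 1.5)
  expect_equal(m[6], mean(2:6))
  expect_length(m, length(x))
})

test_that("the fitted-model front end exposes the usual verbs", {
  sch <- schema_chno(20L)
  lib <- fixture_library(sch, count = 12L, seed = 4L)
  fit <- molwgan(lib, schema = sch, config = tiny_config(batch_size = 2L),
                 max_iters = 2L, eval_every = 1L, eval_samples = 5L,
                 seed = 19L)
  expect_s3_class(fit, "molwgan")
  expect_output(print(fit), "WGAN")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.molwgan")
  expect_equal(nrow(sm$metrics), 2L)
  expect_output(print(sm), "trainable parameters")
  sims <- simulate(fit, nsim = 6L, seed = 3L)
  expect_equal(nrow(sims), 6L)
  expect_true(all(c("smiles", "valid", "connected", "novel") %in% names(sims)))
  sims2 <- simulate(fit, nsim = 6L, seed = 3L)
  expect_identical(sims, sims2)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  expect_error(residuals(fit), "no residuals")
})
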