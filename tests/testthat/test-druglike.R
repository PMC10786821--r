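# Drug-likeness screen: Rule-of-5 descriptors and boundary semantics, the
# Ertl synthetic-accessibility score against frozen reference values, and
# the toxicity-predictor interface.

test_that("quinoline descriptors match the expected values", {
  r <- lipinski("c1ccc2ncccc2c1")
  expect_equal(r$hbd, 0L)
  expect_equal(r$hba, 1L)
  expect_equal(r$mw, 129.16, tolerance = 0.01)
  expect_lt(r$logp, 5)
  expect_true(r$ro5_pass)
})

test_that("rule-of-5 boundaries are inclusive for counts, strict for mw/logp", {
  # glucose: exactly 5 donors (boundary), passes
  glu <- lipinski("OCC1OC(O)C(O)C(O)C1O")
  expect_equal(glu$hbd, 5L)
  expect_true(glu$ro5_pass)
  # sorbitol: 6 donors, fails -> the donor bound is <= 5, not < 5
  sor <- lipinski("OCC(O)C(O)C(O)C(O)CO")
  expect_equal(sor$hbd, 6L)
  expect_false(sor$ro5_pass)
  # an oversized greasy molecule fails the strict mw/logp bounds
  c40 <- lipinski(paste(rep("C", 40), collapse = ""))
  expect_gt(c40$mw, 500)
  expect_false(c40$ro5_pass)
  expect_error(lipinski("bad(("), class = "molwgan_error_parse")
})

test_that("SA scores reproduce the reference Ertl implementation", {
  ref <- utils::read.delim(test_path("sa_panel_reference.tsv"),
                           comment.char = "#")
  panel <- sa_reference_panel()
  expect_identical(unname(panel[seq_len(nrow(ref))]), ref$smiles)
  mine <- sa_score(ref$smiles)
  expect_lt(max(abs(mine - ref$sa_ref)), 1e-3)
})

test_that("SA score orders molecules by synthetic complexity", {
  expect_lt(sa_score("CCO"), 2)                       # trivially synthesizable
  sq <- sa_score("c1ccc2ncccc2c1")
  expect_lt(sq, 3)
  caged <- sa_score("CC12C[C@H]3C[C@@](C)(C1)C[C@](O)(C3)[C@H]2N")
  expect_gt(caged, sq)
  expect_true(all(sa_score(c("CCO", "CCN")) >= 1))
  expect_error(sa_score("bad(("), class = "molwgan_error_parse")
})

test_that("screen records are internally consistent and recomputable", {
  lib <- fixture_library(schema_chno(), count = 30L, seed = 8L)
  sc <- screen(lib)
  r <- sc$records
  expect_equal(r$ro5_pass,
               r$hbd <= 5 & r$hba <= 10 & r$mw < 500 & r$logp < 5)
  expect_equal(r$sa_pass, r$sa_score < 6)
  expect_equal(sc$summary$n, 30L)
  expect_equal(sc$summary$ro5_pass, sum(r$ro5_pass))
  expect_null(r$tox_inactive_all)
})

test_that("the toxicity interface applies the 0.5 inactivity threshold", {
  smi <- c("c1ccc2ncccc2c1", "Cc1ccc2ncccc2c1")
  below <- function(x) matrix(0.4, length(x), 12)
  sc <- screen(smi, tox_predictor = below)
  expect_true(all(sc$records$tox_inactive_all))
  expect_equal(sc$summary$tox_inactive_pct, 100)

  one_high <- function(x) {
    m <- matrix(0.4, length(x), 12); m[, 7] <- 0.6; m
  }
  sc2 <- screen(smi, tox_predictor = one_high)
  expect_false(any(sc2$records$tox_inactive_all))

  wrong <- function(x) matrix(0.4, length(x), 11)
  expect_error(screen(smi, tox_predictor = wrong),
               class = "molwgan_error_tox")
})

test_that("ranking by mean toxicity sorts ascending and the stub is stable", {
  smi <- fixture_library(schema_chno(), count = 8L, seed = 12L)
  sc <- screen(smi, tox_predictor = stub_tox_predictor, rank_by_tox = TRUE)
  expect_false(is.unsorted(sc$records$tox_mean))
  expect_identical(stub_tox_predictor(smi), stub_tox_predictor(smi))
  expect_true(all(stub_tox_predictor(smi) >= 0 & stub_tox_predictor(smi) <= 1))
})
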