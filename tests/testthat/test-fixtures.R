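# Synthetic quinoline libraries: exhaustiveness, determinism, schema
# compliance and the train/holdout split.

test_that("monomethyl substitution enumerates one product per ring CH", {
  sp <- fixture_spec(substituents = c(methyl = "C"), max_substitutions = 1L,
                     count = 7L, seed = 1L)
  m <- enumerate_quinolines(sp)
  expect_length(m, 7L)
  expect_length(unique(m), 7L)
  # each product is a methylquinoline: contains the scaffold, formula C10H9N
  cnt <- molwgan:::smarts_match_count(m, "c1ccc2ncccc2c1")
  expect_true(all(cnt >= 1L))
  # asking for more than the space holds warns and returns the full space
  sp8 <- fixture_spec(substituents = c(methyl = "C"), max_substitutions = 1L,
                      count = 8L, seed = 1L)
  expect_warning(m8 <- enumerate_quinolines(sp8), "exhausted")
  expect_length(m8, 7L)
})

test_that("libraries are deterministic in the seed and differ across seeds", {
  a <- enumerate_quinolines(fixture_spec(count = 15L, seed = 42L))
  b <- enumerate_quinolines(fixture_spec(count = 15L, seed = 42L))
  c <- enumerate_quinolines(fixture_spec(count = 15L, seed = 43L))
  expect_identical(unname(a), unname(b))
  expect_false(identical(unname(a), unname(c)))
})

test_that("out-of-vocabulary substituents yield a warning and empty library", {
  sp <- fixture_spec(substituents = c(bromo = "Br"), max_substitutions = 1L,
                     count = 5L)
  expect_warning(m <- enumerate_quinolines(sp), "exhausted")
  expect_length(m, 0L)
})

test_that("every fixture matches the scaffold and encodes under its schema", {
  sch <- schema_full()
  lib <- fixture_library(sch, count = 40L, seed = 5L)
  fs <- filter_scaffold(lib)
  expect_equal(fs$report$n_kept, length(lib))
  fc <- filter_constraints(lib, sch)
  expect_equal(fc$report$n_kept, length(lib))
})

test_that("fixture errors are raised for degenerate specs", {
  expect_error(fixture_spec(substituents = character(0)),
               class = "molwgan_error_fixtures")
  expect_error(fixture_spec(count = 0L), class = "molwgan_error_fixtures")
  expect_error(enumerate_quinolines(fixture_spec(core_smiles = "xx(",
                                                 count = 3L)),
               class = "molwgan_error_fixtures")
})

test_that("train/holdout split is disjoint, exhaustive and deterministic", {
  lib <- fixture_library(schema_chno(), count = 50L, seed = 9L)
  s <- make_split(lib, 0.2, seed = 7L)
  expect_length(s$holdout, 10L)
  expect_length(s$train, 40L)
  expect_length(intersect(s$train, s$holdout), 0L)
  expect_setequal(c(s$train, s$holdout), lib)
  s2 <- make_split(lib, 0.2, seed = 7L)
  expect_identical(s, s2)
  expect_error(make_split(lib, 1.5), class = "molwgan_error_fixtures")
  expect_error(make_split(lib, 0), class = "molwgan_error_fixtures")
})

test_that("fixture files round-trip with their JSON sidecar", {
  lib <- fixture_library(schema_chno(), count = 10L, seed = 3L)
  path <- file.path(tempdir(), "fx.smi")
  write_fixtures(lib, path)
  expect_identical(readLines(path), as.vector(lib))
  js <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(js$count, 10L)
  unlink(c(path, paste0(path, ".json")))
})
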