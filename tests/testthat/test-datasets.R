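# Dataset filtering and tensor serialization.

test_that("scaffold filter keeps quinolines and drops lookalikes", {
  smi <- c("c1ccc2ncccc2c1",     # quinoline
           "c1ccc2cnccc2c1",     # isoquinoline (N at the 2-ring position)
           "c1ccccc1",           # benzene
           "Cc1ccc2ccccc2n1")    # 2-methylquinoline
  r <- filter_scaffold(smi)
  expect_identical(r$kept, smi[c(1, 4)])
  expect_equal(r$report$n_input, 4L)
  expect_equal(unname(r$report$rejection_counts["scaffold"]), 2L)
  # containment, not scaffold equality: a further-fused system passes
  acridine_like <- "c1ccc2cc3ccccc3nc2c1"
  expect_length(filter_scaffold(acridine_like)$kept, 1L)
})

test_that("scaffold filter handles empty input and bad queries", {
  r <- filter_scaffold(character(0))
  expect_equal(r$report$n_input, 0L)
  expect_length(r$kept, 0L)
  expect_error(filter_scaffold("CCO", scaffold_query = "((("),
               class = "molwgan_error_query")
})

test_that("constraint filter counts rejection causes by encode error code", {
  sch <- schema_chno()
  alkane60 <- paste(rep("C", 60), collapse = "")
  smi <- c("c1ccc2ncccc2c1", alkane60, "Clc1ccc2ncccc2c1", "garbage(((")
  r <- filter_constraints(smi, sch)
  expect_identical(r$kept, smi[1])
  rc <- r$report$rejection_counts
  expect_equal(unname(rc["size"]), 1L)
  expect_equal(unname(rc["element"]), 1L)
  expect_equal(unname(rc["parse"]), 1L)
})

test_that("filter reports satisfy the conservation identity", {
  sch <- schema_chno()
  lib <- c(fixture_library(schema_seven(), count = 30L, seed = 21L),
           "c1ccccc1", "CCCCS", "bad((")
  set.seed(1)
  for (k in 1:20) {
    sub <- sample(lib, sample.int(length(lib), 1L))
    fs <- filter_scaffold(sub)
    expect_equal(fs$report$n_kept + sum(fs$report$rejection_counts),
                 fs$report$n_input)
    fc <- filter_constraints(sub, sch)
    expect_equal(fc$report$n_kept + sum(fc$report$rejection_counts),
                 fc$report$n_input)
  }
})

test_that("scaffold and constraint filters commute as sets", {
  sch <- schema_chno()
  lib <- c(fixture_library(schema_seven(), count = 25L, seed = 22L),
           "c1ccccc1", "CCO", "CSc1ccc2ncccc2c1")
  a <- filter_constraints(filter_scaffold(lib)$kept, sch)$kept
  b <- filter_scaffold(filter_constraints(lib, sch)$kept)$kept
  expect_setequal(a, b)
})

test_that("tensor datasets serialize with the documented shapes and read back", {
  sch <- schema_chno()
  lib <- fixture_library(sch, count = 12L, seed = 13L)
  out <- file.path(tempdir(), "tensords")
  man <- build_tensor_dataset(lib, sch, out)
  expect_equal(man$n_molecules, 12L)
  ds <- load_tensor_dataset(out)
  expect_identical(dim(ds$adjacency), c(12L, 50L, 50L, 5L))
  expect_identical(dim(ds$features), c(12L, 50L, 5L))
  # bit-identical round trip against fresh encodes
  g1 <- encode_molecule(lib[1], sch)
  expect_identical(ds$adjacency[1, , , ], g1$adjacency)
  expect_identical(ds$features[1, , ], g1$features)
  expect_identical(ds$schema$atom_types, sch$atom_types)
  unlink(out, recursive = TRUE)
})

test_that("unfiltered input fails hard naming the offending molecule", {
  sch <- schema_chno()
  expect_error(
    build_tensor_dataset(c("CCO", "CS(=O)C"), sch, file.path(tempdir(), "bad")),
    regexp = "molecule 2", class = "molwgan_error_unfiltered")
})

test_that("preprocess composes the filters and optionally dedupes", {
  sch <- schema_chno()
  lib <- fixture_library(sch, count = 10L, seed = 31L)
  withdup <- c(lib, lib[1], "C(C)c1ccc2ncccc2c1", "Cc1ccc2ccccc2n1")
  pre <- preprocess_dataset(withdup, sch)
  expect_equal(length(pre$kept), length(withdup))   # duplicates retained
  pre2 <- preprocess_dataset(withdup, sch, dedupe = TRUE)
  expect_lt(length(pre2$kept), length(withdup))
  expect_false(anyDuplicated(pre2$kept) > 0)
})
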