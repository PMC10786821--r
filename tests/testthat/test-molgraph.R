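# Molecule <-> tensor conversion: schema construction, encoding failure
# modes, decode semantics and canonicalization.

test_that("schema construction derives widths and rejects bad inputs", {
  s <- build_schema(c("C", "H", "N", "O"), 50)
  expect_equal(length(s$bond_classes), 5L)
  expect_identical(s$bond_classes[1], "none")
  expect_equal(s$feature_width, 5L)

  s7 <- build_schema(c("C", "H", "N", "O", "Cl", "S", "F"), 50,
                     charge_classes = c(-1L, 0L, 1L),
                     chiral_classes = c("none", "cw", "ccw"))
  expect_equal(s7$feature_width, 7L + 1L + 3L + 3L)

  expect_error(build_schema(c("C", "C"), 50), class = "molwgan_error_schema")
  expect_error(build_schema(character(0), 50), class = "molwgan_error_schema")
  expect_error(build_schema("C", 1), class = "molwgan_error_schema")
  expect_error(build_schema(c("C", "Xx"), 50), class = "molwgan_error_schema")
})

test_that("quinoline encodes to 17 atoms with explicit hydrogens", {
  g <- encode_molecule("c1ccc2ncccc2c1", schema_chno())
  expect_s3_class(g, "molgraph")
  expect_equal(g$n_atoms, 17L)     # 10 heavy + 7 explicit H
  expect_true(validate_molgraph(g, schema_chno()))
})

test_that("encode failure modes carry distinct error codes", {
  sch <- schema_chno()
  expect_error(encode_molecule("CS(=O)C", sch), class = "molwgan_error_element")
  expect_error(encode_molecule("c1ccc2ncccc2c1", schema_chno(10L)),
               class = "molwgan_error_size")
  expect_error(encode_molecule("not a molecule", sch),
               class = "molwgan_error_parse")
  expect_error(encode_molecule("[O-]C(=O)c1ccc2ncccc2c1", sch),
               class = "molwgan_error_charge")
  # out-of-vocabulary charge under a charge-carrying schema
  sch_q <- build_schema(c("C", "H", "N", "O"), 50, charge_classes = c(-1L, 0L, 1L))
  expect_error(encode_molecule("CC[N+2]", sch_q), class = "molwgan_error_charge")
})

test_that("canonicalization is deterministic, idempotent and stereo-aware", {
  expect_identical(canonicalize("C(C)O"), canonicalize("CCO"))
  q1 <- canonicalize("c1ccc2ncccc2c1")
  expect_identical(q1, canonicalize("c1ccc2ncccc2c1"))
  expect_identical(canonicalize(q1), q1)
  cis <- canonicalize("F/C=C\\F", use_stereo = TRUE)
  trans <- canonicalize("F/C=C/F", use_stereo = TRUE)
  expect_false(identical(cis, trans))
  expect_identical(canonicalize("F/C=C\\F", use_stereo = FALSE),
                   canonicalize("F/C=C/F", use_stereo = FALSE))
  expect_true(is.na(canonicalize("xyz123")))
})

test_that("decode inverts encode and reports connectivity", {
  sch <- schema_chno()
  d <- decode_graph(encode_molecule("c1ccc2ncccc2c1", sch), sch)
  expect_true(d$valid)
  expect_true(d$connected)
  expect_identical(d$canonical_smiles, canonicalize("c1ccc2ncccc2c1"))

  # two disjoint fragments: valid but not connected
  d2 <- decode_graph(encode_molecule("C.C", sch), sch)
  expect_true(d2$valid)
  expect_false(d2$connected)
})

test_that("chemically impossible graphs decode as invalid, not as errors", {
  sch <- schema_chno()
  N <- sch$max_atoms
  # a carbon with five single bonds to other carbons
  A <- array(0, dim = c(N, N, 5)); A[, , 1] <- 1
  X <- matrix(0, N, 5); X[, 5] <- 1
  X[1:6, 5] <- 0; X[1:6, 1] <- 1
  for (j in 2:6) {
    A[1, j, 1] <- 0; A[j, 1, 1] <- 0
    A[1, j, 2] <- 1; A[j, 1, 2] <- 1
  }
  g <- molwgan:::new_molgraph(A, X, 6L)
  d <- decode_graph(g, sch)
  expect_false(d$valid)
  expect_identical(d$failure_reason, "sanitization")

  # an aromatic bond outside any ring cannot kekulize
  A2 <- array(0, dim = c(N, N, 5)); A2[, , 1] <- 1
  X2 <- matrix(0, N, 5); X2[, 5] <- 1
  X2[1:2, 5] <- 0; X2[1:2, 1] <- 1
  A2[1, 2, 1] <- 0; A2[2, 1, 1] <- 0
  A2[1, 2, 5] <- 1; A2[2, 1, 5] <- 1
  d2 <- decode_graph(molwgan:::new_molgraph(A2, X2, 2L), sch)
  expect_false(d2$valid)
})

test_that("malformed tensors raise structural errors distinct from invalidity", {
  sch <- schema_chno()
  g <- encode_molecule("CCO", sch)
  g$adjacency[1, 2, ] <- 0     # not one-hot
  expect_error(decode_graph(g, sch), class = "molwgan_error_structural")

  g2 <- encode_molecule("CCO", sch)
  g2$adjacency[1, 3, 2] <- 1; g2$adjacency[1, 3, 1] <- 0  # asymmetric
  expect_error(decode_graph(g2, sch), class = "molwgan_error_structural")
})

test_that("encode satisfies tensor invariants and decode matches a BFS oracle", {
  sch <- schema_chno()
  lib <- fixture_library(sch, count = 25L, seed = 11L)
  for (s in lib[1:12]) {
    g <- encode_molecule(s, sch)
    expect_true(validate_molgraph(g, sch))
    d <- decode_graph(g, sch)
    expect_true(d$valid)
    expect_identical(d$connected, bfs_connected(g, sch))
  }
  # fragmented case agrees with the oracle too
  gfrag <- encode_molecule("C.CC", sch)
  expect_identical(decode_graph(gfrag, sch)$connected,
                   bfs_connected(gfrag, sch))
})

test_that("pads may be interleaved: decode does not assume a contiguous tail", {
  sch <- schema_chno(10L)
  g <- encode_molecule("CO", sch)    # 6 atoms + 4 pads
  perm <- c(7L, 1L, 8L, 2L, 3L, 9L, 4L, 5L, 10L, 6L)
  g2 <- molwgan:::new_molgraph(g$adjacency[perm, perm, , drop = FALSE],
                               g$features[perm, , drop = FALSE], g$n_atoms)
  d <- decode_graph(g2, sch)
  expect_true(d$valid)
  expect_identical(d$canonical_smiles, canonicalize("CO"))
})

test_that("stereo round-trips only under a chirality-encoding schema", {
  chiral <- "C[C@@H](CC)c1ccc2ncccc2c1"
  sch3 <- schema_full()
  d3 <- decode_graph(encode_molecule(chiral, sch3), sch3)
  expect_identical(d3$canonical_smiles, canonicalize(chiral, use_stereo = TRUE))
  # under a stereo-blind schema the tag is dropped on encode
  sch7 <- schema_seven()
  d7 <- decode_graph(encode_molecule(chiral, sch7), sch7)
  expect_identical(d7$canonical_smiles, canonicalize(chiral, use_stereo = FALSE))
})

test_that("charged molecules round-trip under the charge-encoding schema", {
  sch3 <- schema_full()
  for (s in c("[O-]C(=O)c1ccc2ncccc2c1", "C[NH+](C)Cc1ccc2ncccc2c1")) {
    d <- decode_graph(encode_molecule(s, sch3), sch3)
    expect_true(d$valid)
    expect_identical(d$canonical_smiles, canonicalize(s, use_stereo = TRUE))
  }
})
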