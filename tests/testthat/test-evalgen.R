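# Metric suite, exhaustive generation stopping rule and chemical-space
# embedding.

test_that("metric denominators follow the documented conventions", {
  # 4 decoded: 2 valid, of which 1 connected quinoline; neither in the
  # reference; the 2 valid are distinct
  batch <- list(dec(TRUE, TRUE, canonicalize("Cc1ccc2ncccc2c1")),
                dec(TRUE, FALSE, canonicalize("C.C")),
                dec(FALSE, FALSE), dec(FALSE, FALSE))
  r <- compute_metrics(batch, character(0))
  expect_equal(r$validity, 0.5)
  expect_equal(r$connected_validity, 0.5)
  expect_equal(r$scaffold_rate, 1.0)
  expect_equal(r$novelty, 1.0)
  expect_equal(r$uniqueness, 1.0)

  # all invalid: every other rate is 0 by convention
  r0 <- compute_metrics(list(dec(FALSE, FALSE), dec(FALSE, FALSE)))
  expect_equal(unlist(r0[c("validity", "connected_validity", "scaffold_rate",
                           "novelty", "uniqueness")], use.names = FALSE),
               rep(0, 5))

  # 10 valid copies of one training molecule
  q <- canonicalize("c1ccc2ncccc2c1")
  rep10 <- compute_metrics(replicate(10, dec(TRUE, TRUE, q), simplify = FALSE),
                           reference_canon_set = q)
  expect_equal(rep10$novelty, 0)
  expect_equal(rep10$uniqueness, 0.1)
})

test_that("connected validity can exceed validity because denominators differ", {
  # 100 graphs: 25 valid, 16 of them connected -> validity 0.25, connected 0.64
  q <- canonicalize("Cc1ccc2ncccc2c1")
  batch <- c(replicate(16, dec(TRUE, TRUE, q), simplify = FALSE),
             replicate(9, dec(TRUE, FALSE, "C.C"), simplify = FALSE),
             replicate(75, dec(FALSE, FALSE), simplify = FALSE))
  r <- compute_metrics(batch)
  expect_equal(r$validity, 0.25)
  expect_equal(r$connected_validity, 0.64)
  expect_gt(r$connected_validity, r$validity)
})

test_that("metrics equal a brute-force set-arithmetic oracle", {
  q <- canonicalize(c("c1ccc2ncccc2c1", "Cc1ccc2ncccc2c1", "CCO", "C.C",
                      "Nc1ccc2ncccc2c1", "c1ccccc1"))
  scaffold_members <- q[c(1, 2, 5)]
  set.seed(33)
  for (case in 1:60) {
    n <- sample(3:20, 1)
    batch <- lapply(seq_len(n), function(i) {
      v <- runif(1) < 0.6
      s <- sample(q, 1)
      dec(v, v && runif(1) < 0.7 && !grepl(".", s, fixed = TRUE), s)
    })
    ref <- sample(q, sample.int(4, 1))
    r <- compute_metrics(batch, ref)
    valid <- vapply(batch, `[[`, TRUE, "valid")
    conn <- vapply(batch, `[[`, TRUE, "connected")
    smi <- vapply(batch, `[[`, "", "canonical_smiles")
    expect_equal(r$validity, sum(valid) / n)
    expect_equal(r$connected_validity,
                 if (sum(valid) == 0) 0 else sum(conn) / sum(valid))
    expect_equal(r$scaffold_rate,
                 if (sum(conn) == 0) 0 else
                   sum(smi[conn] %in% scaffold_members) / sum(conn))
    expect_equal(r$novelty,
                 if (sum(valid) == 0) 0 else
                   sum(!(smi[valid] %in% ref)) / sum(valid))
    expect_equal(r$uniqueness,
                 if (sum(valid) == 0) 0 else
                   length(unique(smi[valid])) / sum(valid))
  }
})

test_that("exhaustive generation obeys the consecutive-failure stopping rule", {
  q <- canonicalize("Cc1ccc2ncccc2c1")
  one_fixed <- function(n, seed) replicate(n, dec(TRUE, TRUE, q),
                                           simplify = FALSE)
  arch <- exhaustive_generate(one_fixed, schema_chno(), run_size = 5L,
                              patience = 7L, seed = 1L)
  expect_length(arch$accepted, 1L)
  expect_equal(arch$runs_executed, 8L)     # 1 accepting run + patience dry runs

  all_invalid <- function(n, seed) replicate(n, dec(FALSE, FALSE),
                                             simplify = FALSE)
  arch0 <- exhaustive_generate(all_invalid, schema_chno(), run_size = 5L,
                               patience = 6L, seed = 1L)
  expect_length(arch0$accepted, 0L)
  expect_equal(arch0$runs_executed, 6L)
})

test_that("a cycling stub is mined until its emission set is exhausted", {
  pool <- canonicalize(c("Cc1ccc2ncccc2c1", "Nc1ccc2ncccc2c1",
                         "Oc1ccc2ncccc2c1"))
  idx <- 0L
  cycler <- function(n, seed) {
    lapply(seq_len(n), function(i) {
      idx <<- idx + 1L
      dec(TRUE, TRUE, pool[(idx %% 3L) + 1L])
    })
  }
  arch <- exhaustive_generate(cycler, schema_chno(), run_size = 10L,
                              patience = 4L, seed = 1L)
  expect_setequal(arch$accepted, pool)
  expect_equal(arch$runs_executed, 5L)
})

test_that("the archive excludes the reference set and survives re-decoding", {
  pool <- canonicalize(c("Cc1ccc2ncccc2c1", "Nc1ccc2ncccc2c1", "c1ccccc1",
                         "CCO"))
  stub <- function(n, seed) lapply(seq_len(n), function(i)
    dec(TRUE, TRUE, pool[(i %% 4L) + 1L]))
  ref <- pool[1]
  arch <- exhaustive_generate(stub, schema_chno(), reference_canon_set = ref,
                              run_size = 8L, patience = 3L, seed = 1L)
  expect_length(intersect(arch$accepted, ref), 0L)
  # only scaffold-matching molecules are archived
  expect_setequal(arch$accepted, pool[2])
  # accepted molecules re-encode and re-decode as connected valid quinolines
  sch <- schema_chno()
  for (s in arch$accepted) {
    d <- decode_graph(encode_molecule(s, sch), sch)
    expect_true(d$valid && d$connected)
  }
})

test_that("fingerprints are deterministic and identical for duplicates", {
  fp <- fingerprint_matrix(c("CCO", "C(C)O", "c1ccc2ncccc2c1"))
  expect_identical(fp[1, ], fp[2, ])
  expect_false(identical(fp[1, ], fp[3, ]))
  expect_true(all(fp %in% c(0, 1)))
  expect_true(anyNA(fingerprint_matrix("xx((")))
})

test_that("homologous series separate in fingerprint space and embedding", {
  alkanes <- vapply(3:17, function(k) paste(rep("C", k), collapse = ""), "")
  quins <- fixture_library(schema_chno(), count = 15L, seed = 6L)
  fps <- fingerprint_matrix(c(alkanes, quins))
  tan <- function(i, j) molwgan:::.tanimoto(fps[i, ], fps[j, ])
  na <- length(alkanes)
  intra <- c(unlist(lapply(1:(na - 1), function(i)
              vapply((i + 1):na, function(j) tan(i, j), 0))),
             unlist(lapply((na + 1):(na + 14), function(i)
              vapply((i + 1):(na + 15), function(j) tan(i, j), 0))))
  inter <- unlist(lapply(1:na, function(i)
    vapply((na + 1):(na + 15), function(j) tan(i, j), 0)))
  expect_lt(mean(inter), mean(intra))

  emb <- embed_chemspace(list(reference = alkanes, generated = quins),
                         seed = 4L, perplexity = 5)
  expect_equal(nrow(emb), 30L)
  expect_setequal(unique(emb$label), c("reference", "generated"))
  emb2 <- embed_chemspace(list(reference = alkanes, generated = quins),
                          seed = 4L, perplexity = 5)
  expect_identical(emb, emb2)
})

test_that("reference subsampling and parse skipping are reported", {
  quins <- fixture_library(schema_chno(), count = 12L, seed = 6L)
  emb <- embed_chemspace(list(reference = quins,
                              generated = c("CCO", "CCN", "bad((", "CCCO")),
                         n_reference_sample = 5L, seed = 2L, perplexity = 2)
  expect_equal(attr(emb, "n_skipped"), 1L)
  expect_equal(sum(emb$label == "reference"), 5L)
})

test_that("internal diversity is low for duplicates, higher for mixtures", {
  expect_equal(internal_diversity(c("CCO", "CCO", "CCO")), 0)
  mix <- internal_diversity(c("CCO", "c1ccc2ncccc2c1", "CCCCCCCC"))
  expect_gt(mix, 0.5)
})
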