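# Networks and losses: configurations, the relational GCN layer, generator
# output contracts, critic symmetries, discretization and the Wasserstein
# losses. The heavier batteries (1,000-draw sweeps, 100-graph symmetry
# suites) live in the acceptance tests.

test_that("configuration constructor validates fields", {
  expect_error(model_config(dropout = 1.5), class = "molwgan_error_config")
  expect_error(model_config(latent_dim = 0), class = "molwgan_error_config")
  expect_error(model_config(learning_rate = -1), class = "molwgan_error_config")
  expect_error(make_config("model9"), class = "molwgan_error_config")
})

test_that("the four presets round-trip through YAML losslessly", {
  for (nm in c("base", "model1", "model2", "model3")) {
    cfg <- make_config(nm)
    path <- file.path(tempdir(), paste0(nm, ".yaml"))
    write_config(cfg, path)
    cfg2 <- read_config(path)
    expect_identical(cfg, cfg2)
    unlink(path)
  }
})

test_that("relational GCN layer matches its closed form on small cases", {
  H <- matrix(c(1, 2, 3, 4), 2, 2)
  # all no-bond: output depends only on the self transform
  A0 <- array(0, dim = c(2, 2, 3)); A0[, , 1] <- 1
  lp <- list(W_self = diag(2), W_rel = list(diag(2), diag(2)),
             bias = matrix(0, 1, 2), activation = "identity")
  expect_equal(relational_gcn_layer(H, A0, lp), H)
  # one single bond, identity weights, linear activation: h'_i = h_i + h_j
  A1 <- A0
  A1[1, 2, 1] <- 0; A1[2, 1, 1] <- 0
  A1[1, 2, 2] <- 1; A1[2, 1, 2] <- 1
  out <- relational_gcn_layer(H, A1, lp)
  expect_equal(out[1, ], H[1, ] + H[2, ])
  expect_equal(out[2, ], H[2, ] + H[1, ])
})

test_that("the GCN layer is equivariant under atom permutation", {
  set.seed(4)
  N <- 7L
  lp <- list(W_self = matrix(rnorm(9), 3, 3),
             W_rel = lapply(1:4, function(b) matrix(rnorm(9), 3, 3)),
             bias = matrix(rnorm(3), 1, 3), activation = "relu")
  for (k in 1:5) {
    H <- matrix(rnorm(N * 3), N, 3)
    A <- array(stats::runif(N * N * 5), dim = c(N, N, 5))
    for (b in 1:5) A[, , b] <- (A[, , b] + t(A[, , b])) / 2
    perm <- sample(N)
    o1 <- relational_gcn_layer(H, A, lp)[perm, ]
    o2 <- relational_gcn_layer(H[perm, ], A[perm, perm, ], lp)
    expect_lt(max(abs(o1 - o2)), 1e-10)
  }
})

test_that("generator output satisfies its distribution contracts", {
  sch <- schema_full()
  cfg <- tiny_config()
  p <- init_gan_params(cfg, sch)
  z <- sample_latent(4, cfg$latent_dim, seed = 8)
  outs <- generator_forward(z, p$gen, sch, cfg)
  for (o in outs) {
    sums <- apply(o$edge_probs, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-5)
    expect_lt(max(abs(o$edge_probs - aperm(o$edge_probs, c(2, 1, 3)))), 1e-10)
    expect_equal(unname(o$edge_probs[cbind(1:sch$max_atoms, 1:sch$max_atoms, 1)]),
                 rep(1, sch$max_atoms))
    for (blk in list(1:8, 9:11, 12:14))
      expect_lt(max(abs(rowSums(o$node_probs[, blk]) - 1)), 1e-5)
  }
  # identical latent rows give identical outputs
  z2 <- rbind(z[1, ], z[1, ])
  o2 <- generator_forward(z2, p$gen, sch, cfg)
  expect_identical(o2[[1]], o2[[2]])
})

test_that("critic scores are permutation invariant and soft/hard consistent", {
  sch <- schema_chno(15L)
  cfg <- tiny_config()
  p <- init_gan_params(cfg, sch)
  g <- encode_molecule("Cc1ccccc1", sch)
  s0 <- discriminator_forward(g, p$disc, sch, cfg)
  set.seed(9)
  for (k in 1:5) {
    perm <- sample(15L)
    gp <- molwgan:::new_molgraph(g$adjacency[perm, perm, ],
                                 g$features[perm, ], g$n_atoms)
    expect_lt(abs(discriminator_forward(gp, p$disc, sch, cfg) - s0), 1e-8)
  }
  # a soft input numerically equal to the one-hot graph scores identically
  soft <- structure(list(edge_probs = g$adjacency * 1.0,
                         node_probs = g$features * 1.0),
                    class = "generator_output")
  expect_equal(discriminator_forward(soft, p$disc, sch, cfg), s0)
})

test_that("critic does not collapse to a constant across random inits", {
  sch <- schema_chno(12L)
  cfg <- tiny_config()
  g1 <- encode_molecule("CCO", sch)
  g2 <- encode_molecule("c1ccccc1", sch)
  diffs <- vapply(1:20, function(s) {
    p <- init_gan_params(model_config("t", latent_dim = 8, gen_units = 16,
                                      disc_units = 16, gcn_units = 8,
                                      gcn_layers = 2, batch_size = 2,
                                      seed = s), sch)
    abs(discriminator_forward(g1, p$disc, sch, cfg) -
          discriminator_forward(g2, p$disc, sch, cfg))
  }, 0)
  expect_gt(mean(diffs > 1e-8), 0.9)
})

test_that("discretization honours delta distributions and seeds", {
  sch <- schema_chno(10L)
  g <- encode_molecule("CCO", sch)
  delta <- structure(list(edge_probs = g$adjacency * 1.0,
                          node_probs = g$features * 1.0),
                     class = "generator_output")
  for (mode in c("argmax", "categorical", "gumbel_st")) {
    gg <- discretize(delta, sch, mode = mode, seed = 5)
    expect_identical(gg$adjacency, g$adjacency)
    expect_identical(gg$features, g$features)
  }
  cfg <- tiny_config()
  p <- init_gan_params(cfg, sch)
  o <- generator_forward(sample_latent(1, 8, seed = 2), p$gen, sch, cfg)[[1]]
  a <- discretize(o, sch, mode = "categorical", seed = 77)
  b <- discretize(o, sch, mode = "categorical", seed = 77)
  expect_identical(a, b)
  expect_true(validate_molgraph(a, sch))
  expect_error(discretize(o, sch, temperature = 0),
               class = "molwgan_error_discretize")
})

test_that("categorical discretization samples the stated distribution", {
  # uniform edge distribution over 5 classes: each class ~ 0.2 +- 0.02
  N <- 30L
  sch <- schema_chno(N)
  uni <- structure(list(
    edge_probs = array(0.2, dim = c(N, N, 5)),
    node_probs = matrix(c(rep(1, N), rep(0, N * 4)), N, 5)),
    class = "generator_output")
  counts <- numeric(5)
  npairs <- 0
  for (s in 1:25) {
    g <- discretize(uni, sch, mode = "categorical", seed = s)
    for (b in 1:5) counts[b] <- counts[b] + sum(g$adjacency[, , b][upper.tri(diag(N))])
    npairs <- npairs + N * (N - 1) / 2
  }
  freq <- counts / npairs     # ~10,875 draws
  expect_true(all(abs(freq - 0.2) < 0.02))
})

test_that("wasserstein losses follow their closed form", {
  l <- wgan_losses(real_scores = c(5, 5), fake_scores = c(2, 2),
                   penalty = 0.1, gp_lambda = 10)
  expect_equal(l$d_loss, -2.0)
  expect_equal(l$g_loss, -2.0)
  expect_equal(wgan_losses(c(1, 1), c(1, 1), 0, 10)$d_loss, 0)
})

test_that("gradient penalty matches analytic values for simple critics", {
  sch <- schema_chno(8L)
  real <- lapply(c("C", "N", "O"), encode_molecule, schema = sch)
  fake <- lapply(c("CC", "CO", "CN"), encode_molecule, schema = sch)
  ag <- asNamespace("molwgan")
  lin_critic <- function(w) function(Alist, X) {
    total <- ag$ag_const(matrix(0, 1, 1)); off <- 0L
    for (b in seq_along(Alist)) {
      n2 <- length(Alist[[b]]$val)
      wb <- matrix(w[off + seq_len(n2)], nrow(Alist[[b]]$val))
      total <- ag$ag_add(total, ag$ag_sum(ag$ag_mul(Alist[[b]], ag$ag_const(wb))))
      off <- off + n2
    }
    wx <- matrix(w[off + seq_len(length(X$val))], nrow(X$val))
    ag$ag_add(total, ag$ag_sum(ag$ag_mul(X, ag$ag_const(wx))))
  }
  ncoord <- 8 * 8 * 5 + 8 * 5
  set.seed(11)
  w <- rnorm(ncoord); w <- w / sqrt(sum(w^2))
  expect_lt(abs(gradient_penalty(real, fake, lin_critic(w), seed = 1)), 1e-6)
  expect_lt(abs(gradient_penalty(real, fake, lin_critic(3 * w), seed = 1) - 4),
            1e-6)
  const_critic <- function(Alist, X) ag$ag_const(matrix(42, 1, 1))
  expect_equal(gradient_penalty(real, fake, const_critic, seed = 1), 1)
})

test_that("parameter counts scale with the configured widths", {
  sch <- schema_chno(25L)
  small <- init_gan_params(tiny_config(), sch)
  big <- init_gan_params(model_config("w", latent_dim = 8, gen_units = 64,
                                      disc_units = 64, gcn_units = 16,
                                      gcn_layers = 2, batch_size = 2), sch)
  expect_gt(count_params(big$gen), count_params(small$gen))
  expect_gt(count_params(big$disc), count_params(small$disc))
})
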