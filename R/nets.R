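# Generator and critic: relational graph convolutions over the one-hot
# (or softened) adjacency tensor, dense stacks, Wasserstein losses and the
# gradient penalty. Forward passes are built on the autodiff engine so the
# same code serves inference, training, and the penalty's double backward.

## ---------------------------------------------------------------------------
## Parameter initialization
## ---------------------------------------------------------------------------

.glorot <- function(nr, nc, rng) {
  lim <- sqrt(6 / (nr + nc))
  with_rng(rng, matrix(stats::runif(nr * nc, -lim, lim), nr, nc))
}

# log marginal bond-class frequencies of typical organic graphs at this
# density (no-bond, single, double, triple, aromatic), shifted so the
# no-bond logit is +4
.edge_prior_logits <- function() {
  # heavily single-bond dominated: aromatic bonds only make chemical sense
  # in ring context, which independently sampled edges cannot provide, so
  # the starting distribution leans on single bonds and lets training grow
  # the aromatic systems
  prior <- c(0.93, 0.06, 0.006, 0.001, 0.003)
  log(prior) - log(prior[1]) + 4
}

# log marginal node-class frequencies: C/H dominate, heteroatoms and pad are
# minorities; neutral charge and no chiral tag are the defaults
.node_prior_logits <- function(schema) {
  tp <- schema$atom_types
  ap <- ifelse(tp %in% c("C", "H"), 0.38, 0.02)
  atom <- c(ap, 0.15)                      # pad class
  out <- log(atom / sum(atom))
  if (length(schema$charge_classes) > 0L) {
    chg <- ifelse(schema$charge_classes == 0L, 0.96,
                  0.04 / (length(schema$charge_classes) - 1L))
    out <- c(out, log(chg))
  }
  if (length(schema$chiral_classes) > 0L)
    out <- c(out, log(c(0.94, 0.03, 0.03)))
  out
}

#' Initialize generator and critic parameters
#'
#' Uniform Glorot initialization, seeded from `config$seed`. Output-head
#' biases start at the log marginal class frequencies typical of organic
#' molecular graphs (overwhelmingly no-bond, then single and aromatic bonds;
#' C/H-dominated atom types; neutral charges; no chiral tag), the usual
#' initialize-to-the-prior trick: the untrained generator then emits sparse,
#' single-bond-dominated graphs instead of uniformly dense garbage, and
#' training adjusts the distribution from a chemically sane starting point.
#'
#' @param config a `model_config`.
#' @param schema a `graph_schema`.
#' @return list(gen, disc) of named parameter arrays.
#' @export
init_gan_params <- function(config, schema) {
  rng <- rng_stream(config$seed, "init")
  N <- schema$max_atoms; B <- length(schema$bond_classes)
  Fw <- schema$feature_width
  gu <- config$gen_units; du <- config$disc_units; cu <- config$gcn_units
  L <- config$gcn_layers

  gcn_block <- function() {
    lapply(seq_len(L), function(l) list(
      W_self = .glorot(cu, cu, rng),
      W_rel = lapply(seq_len(B - 1L), function(b) .glorot(cu, cu, rng)),
      bias = matrix(0, 1, cu)))
  }

  gen <- list(
    W1 = .glorot(config$latent_dim, gu, rng), b1 = matrix(0, 1, gu),
    W2 = .glorot(gu, gu, rng), b2 = matrix(0, 1, gu),
    W_node = .glorot(gu, N * cu, rng), b_node = matrix(0, 1, N * cu),
    W_edge = .glorot(gu, N * N * B, rng),
    b_edge = matrix(rep(.edge_prior_logits(), each = N * N), 1, N * N * B),
    gcn = gcn_block(),
    W_head = .glorot(cu, Fw, rng),
    b_head = matrix(.node_prior_logits(schema), 1, Fw),
    # zero-initialized so the prior-biased raw logits dominate at the start;
    # gradients through the node states still reach it
    W_bil = lapply(seq_len(B - 1L), function(b) matrix(0, cu, cu))
  )
  disc <- list(
    W_emb = .glorot(Fw, cu, rng), b_emb = matrix(0, 1, cu),
    gcn = gcn_block(),
    W1 = .glorot(cu, du, rng), b1 = matrix(0, 1, du),
    W2 = .glorot(du, du, rng), b2 = matrix(0, 1, du),
    W_out = .glorot(du, 1, rng), b_out = matrix(0, 1, 1)
  )
  list(gen = gen, disc = disc)
}

# wrap a (nested) parameter list into input nodes; returns parallel structure
.params_to_nodes <- function(p) {
  rapply(p, function(v) ag_input(v), how = "replace", classes = "matrix")
}
.param_nodes_flat <- function(pn) {
  out <- list()
  rec <- function(x) {
    if (inherits(x, "ag_node")) out[[length(out) + 1L]] <<- x
    else if (is.list(x)) for (e in x) rec(e)
  }
  rec(pn)
  out
}

## ---------------------------------------------------------------------------
## Building blocks
## ---------------------------------------------------------------------------

.act_fn <- function(activation, where = c("dense", "gcn")) {
  where <- match.arg(where)
  if (activation == "leaky_relu") return(function(x) ag_lrelu(x, 0.2))
  if (where == "dense") function(x) ag_tanh(x) else function(x) ag_relu(x)
}

.addbias <- function(x, b) {
  n <- nrow(x$val)
  ag_add(x, ag_matmul(ag_const(matrix(1, n, 1)), b))
}

# one relational GCN layer on nodes: per-bond-class transforms, degree-
# normalized sum aggregation, self-connection, nonlinearity
.rgcn_nodes <- function(H, Alist, layer, act) {
  out <- ag_matmul(H, layer$W_self)
  for (b in seq_along(layer$W_rel)) {
    Ab <- Alist[[b + 1L]]                     # class 1 = no-bond, excluded
    deg <- ag_maxc(ag_rowsums(Ab), 1)
    Anorm <- ag_mul(Ab, ag_pow(deg, -1))
    out <- ag_add(out, ag_matmul(Anorm, ag_matmul(H, layer$W_rel[[b]])))
  }
  act(.addbias(out, layer$bias))
}

#' Relational graph convolution layer
#'
#' `h'_i = act( W_self h_i + sum_b sum_j A[i,j,b] W_b h_j / d_{i,b} )` with
#' `d_{i,b} = max(1, sum_j A[i,j,b])`, bond classes beyond the no-bond class
#' each having their own transform. Operates on plain arrays; the same
#' computation backs the generator refinement and the critic.
#'
#' @param node_states N x H matrix.
#' @param adjacency N x N x B array (one-hot or soft; class 1 = no-bond).
#' @param layer_params list(W_self, W_rel = list of B-1 matrices, bias,
#'   activation = "relu"|"tanh"|"leaky_relu"|"identity").
#' @return N x H' matrix.
#' @export
relational_gcn_layer <- function(node_states, adjacency, layer_params) {
  B <- dim(adjacency)[3]
  Alist <- lapply(seq_len(B), function(b) ag_const(adjacency[, , b]))
  act <- switch(layer_params$activation %||% "identity",
                relu = ag_relu, tanh = ag_tanh,
                leaky_relu = function(x) ag_lrelu(x, 0.2),
                identity = function(x) x)
  layer <- list(W_self = ag_const(layer_params$W_self),
                W_rel = lapply(layer_params$W_rel, ag_const),
                bias = ag_const(layer_params$bias %||%
                                  matrix(0, 1, ncol(layer_params$W_self))))
  ag_val(.rgcn_nodes(ag_const(node_states), Alist, layer, act))
}

# per-pair softmax over bond classes with exact no-bond diagonal;
# Llist: B symmetrized logit matrices (nodes)
.edge_softmax <- function(Llist, N) {
  mx <- Reduce(function(a, b) pmax(a, b), lapply(Llist, ag_val))
  elist <- lapply(Llist, function(L) ag_exp(ag_sub(L, ag_const(mx))))
  denom <- Reduce(ag_add, elist)
  probs <- lapply(elist, function(e) ag_div(e, denom))
  off <- ag_const(1 - diag(N)); eye <- ag_const(diag(N))
  probs <- lapply(seq_along(probs), function(b) {
    p <- ag_mul(probs[[b]], off)
    if (b == 1L) ag_add(p, eye) else p
  })
  probs
}

# per-block row softmax over node feature logits
.node_softmax <- function(logits, schema) {
  blocks <- list(seq_len(length(schema$atom_types) + 1L),
                 schema_charge_cols(schema), schema_chiral_cols(schema))
  blocks <- blocks[vapply(blocks, length, 0L) > 0L]
  parts <- lapply(blocks, function(js) ag_softmax_rows(ag_cols(logits, js)))
  Reduce(.ag_cbind, parts)
}

.ag_cbind <- function(a, b) {
  na <- ncol(a$val); nb <- ncol(b$val)
  Pa <- ag_const(cbind(diag(na), matrix(0, na, nb)))
  Pb <- ag_const(cbind(matrix(0, nb, na), diag(nb)))
  ag_add(ag_matmul(a, Pa), ag_matmul(b, Pb))
}

## ---------------------------------------------------------------------------
## Generator
## ---------------------------------------------------------------------------

# node-level generator forward for one latent row (node), returning node-level
# outputs; P = parameter nodes
.gen_forward_one <- function(z, P, schema, config) {
  N <- schema$max_atoms; B <- length(schema$bond_classes)
  cu <- config$gcn_units
  dense_act <- .act_fn(config$activation, "dense")
  gcn_act <- .act_fn(config$activation, "gcn")

  h <- dense_act(.addbias(ag_matmul(z, P$W1), P$b1))
  h <- dense_act(.addbias(ag_matmul(h, P$W2), P$b2))

  node0 <- ag_reshape(.addbias(ag_matmul(h, P$W_node), P$b_node), N, cu)
  eraw <- .addbias(ag_matmul(h, P$W_edge), P$b_edge)   # 1 x (N*N*B)
  Lraw <- lapply(seq_len(B), function(b) {
    ag_reshape(ag_slice_cols(eraw, ((b - 1L) * N * N) + seq_len(N * N)), N, N)
  })
  Lsym <- lapply(Lraw, function(L) ag_mul(ag_add(L, ag_t(L)), ag_const(0.5)))
  A_soft <- .edge_softmax(Lsym, N)

  H <- node0
  for (layer in P$gcn) H <- .rgcn_nodes(H, A_soft, layer, gcn_act)

  node_logits <- .addbias(ag_matmul(H, P$W_head), P$b_head)
  node_probs <- .node_softmax(node_logits, schema)

  Lfin <- lapply(seq_len(B), function(b) {
    bil <- if (b == 1L) NULL else ag_matmul(ag_matmul(H, P$W_bil[[b - 1L]]), ag_t(H))
    L <- if (is.null(bil)) Lraw[[b]] else ag_add(Lraw[[b]], bil)
    ag_mul(ag_add(L, ag_t(L)), ag_const(0.5))
  })
  edge_probs <- .edge_softmax(Lfin, N)
  list(edge_probs = edge_probs, node_probs = node_probs)
}

# plain-array generator forward (no gradient tracking); numerically
# identical to .gen_forward_one and used wherever no generator gradient is
# needed (sampling for critic updates, evaluation, generation)
.gen_forward_plain <- function(zrow, params, schema, config) {
  N <- schema$max_atoms; B <- length(schema$bond_classes)
  cu <- config$gcn_units
  act_d <- if (config$activation == "leaky_relu")
    function(x) ifelse(x > 0, x, 0.2 * x) else tanh
  act_g <- if (config$activation == "leaky_relu")
    function(x) ifelse(x > 0, x, 0.2 * x) else function(x) pmax(x, 0)
  addb <- function(x, b) sweep(x, 2, as.vector(b), `+`)

  h <- act_d(addb(zrow %*% params$W1, params$b1))
  h <- act_d(addb(h %*% params$W2, params$b2))
  node0 <- matrix(addb(h %*% params$W_node, params$b_node), N, cu)
  eraw <- addb(h %*% params$W_edge, params$b_edge)
  Lraw <- lapply(seq_len(B), function(b)
    matrix(eraw[1, ((b - 1L) * N * N) + seq_len(N * N)], N, N))
  Lsym <- lapply(Lraw, function(L) (L + t(L)) / 2)

  esoft <- function(Llist) {
    mx <- Reduce(pmax, Llist)
    es <- lapply(Llist, function(L) exp(L - mx))
    den <- Reduce(`+`, es)
    probs <- lapply(es, function(e) e / den)
    off <- 1 - diag(N)
    probs <- lapply(seq_along(probs), function(b) {
      p <- probs[[b]] * off
      if (b == 1L) p + diag(N) else p
    })
    probs
  }
  A_soft <- esoft(Lsym)

  H <- node0
  for (layer in params$gcn) {
    out <- H %*% layer$W_self
    for (b in seq_along(layer$W_rel)) {
      Ab <- A_soft[[b + 1L]]
      deg <- pmax(rowSums(Ab), 1)
      out <- out + (Ab / deg) %*% (H %*% layer$W_rel[[b]])
    }
    H <- act_g(addb(out, layer$bias))
  }

  node_logits <- addb(H %*% params$W_head, params$b_head)
  blocks <- list(seq_len(length(schema$atom_types) + 1L),
                 schema_charge_cols(schema), schema_chiral_cols(schema))
  node_probs <- matrix(0, N, schema$feature_width)
  for (js in blocks[vapply(blocks, length, 0L) > 0L]) {
    L <- node_logits[, js, drop = FALSE]
    e <- exp(L - apply(L, 1, max))
    node_probs[, js] <- e / rowSums(e)
  }
  Lfin <- lapply(seq_len(B), function(b) {
    L <- if (b == 1L) Lraw[[b]] else
      Lraw[[b]] + H %*% params$W_bil[[b - 1L]] %*% t(H)
    (L + t(L)) / 2
  })
  list(edge_probs = esoft(Lfin), node_probs = node_probs)
}

#' Generator forward pass
#'
#' Dense stack from latent noise to initial node states and raw edge logits;
#' the softened edge distribution then drives `gcn_layers` rounds of
#' relational graph convolution refining the node states; dense heads emit
#' final node logits (per-block softmax) and edge logits (symmetrized as
#' `(L + t(L))/2`, diagonal masked to no-bond, per-pair softmax).
#'
#' @param z matrix (batch x latent_dim) of noise.
#' @param params generator parameters (`init_gan_params()$gen`).
#' @param schema a `graph_schema`.
#' @param config a `model_config`.
#' @return list of `generator_output` objects (edge_probs N x N x B array,
#'   node_probs N x F matrix).
#' @export
generator_forward <- function(z, params, schema, config) {
  stopifnot(ncol(z) == config$latent_dim)
  N <- schema$max_atoms; B <- length(schema$bond_classes)
  lapply(seq_len(nrow(z)), function(k) {
    o <- .gen_forward_plain(z[k, , drop = FALSE], params, schema, config)
    A <- array(0, dim = c(N, N, B))
    for (b in seq_len(B)) A[, , b] <- o$edge_probs[[b]]
    structure(list(edge_probs = A, node_probs = o$node_probs),
              class = "generator_output")
  })
}

## ---------------------------------------------------------------------------
## Critic
## ---------------------------------------------------------------------------

# critic forward on nodes. Alist: list of B N x N nodes; X: N x F node.
.disc_forward_nodes <- function(Alist, X, P, schema, config,
                                drop_masks = NULL) {
  dense_act <- .act_fn(config$activation, "dense")
  gcn_act <- .act_fn(config$activation, "gcn")
  H <- gcn_act(.addbias(ag_matmul(X, P$W_emb), P$b_emb))
  for (layer in P$gcn) H <- .rgcn_nodes(H, Alist, layer, gcn_act)
  w <- ag_sub(ag_const(1), ag_col(X, schema_pad_col(schema)))
  pooled <- ag_matmul(ag_t(w), H)            # 1 x gcn_units
  h <- dense_act(.addbias(ag_matmul(pooled, P$W1), P$b1))
  if (!is.null(drop_masks)) h <- ag_mul(h, ag_const(drop_masks[[1]]))
  h <- dense_act(.addbias(ag_matmul(h, P$W2), P$b2))
  if (!is.null(drop_masks)) h <- ag_mul(h, ag_const(drop_masks[[2]]))
  .addbias(ag_matmul(h, P$W_out), P$b_out)   # 1 x 1, no output nonlinearity
}

# Stack a batch of graphs block-diagonally: one big graph whose connected
# blocks are the samples. The critic is evaluated once on the stack; the
# block structure keeps samples independent (messages cannot cross blocks),
# so batched scores and per-sample input gradients match the per-sample runs.
.stack_graphs <- function(As, Xs, B) {
  n <- length(As)
  N <- nrow(Xs[[1]])
  NN <- n * N
  Abig <- lapply(seq_len(B), function(b) matrix(0, NN, NN))
  Xbig <- matrix(0, NN, ncol(Xs[[1]]))
  ind <- matrix(0, n, NN)
  blockmask <- matrix(0, NN, NN)
  for (s in seq_len(n)) {
    rows <- (s - 1L) * N + seq_len(N)
    for (b in seq_len(B)) Abig[[b]][rows, rows] <- As[[s]][[b]]
    Xbig[rows, ] <- Xs[[s]]
    ind[s, rows] <- 1
    blockmask[rows, rows] <- 1
  }
  list(A = Abig, X = Xbig, ind = ind, blockmask = blockmask, n = n, N = N)
}

# batched critic: block-diagonal inputs -> n x 1 scores (node)
.disc_forward_batch <- function(Abig_nodes, Xbig_node, P, schema, config,
                                drop_masks, ind) {
  n <- nrow(ind$val)
  dense_act <- .act_fn(config$activation, "dense")
  gcn_act <- .act_fn(config$activation, "gcn")
  H <- gcn_act(.addbias(ag_matmul(Xbig_node, P$W_emb), P$b_emb))
  for (layer in P$gcn) H <- .rgcn_nodes(H, Abig_nodes, layer, gcn_act)
  w <- ag_sub(ag_const(1), ag_col(Xbig_node, schema_pad_col(schema)))
  pooled <- ag_matmul(ind, ag_mul(H, w))       # n x gcn_units
  h <- dense_act(.addbias(ag_matmul(pooled, P$W1), P$b1))
  if (!is.null(drop_masks))
    h <- ag_mul(h, ag_const(matrix(drop_masks[[1]], n, config$disc_units,
                                   byrow = TRUE)))
  h <- dense_act(.addbias(ag_matmul(h, P$W2), P$b2))
  if (!is.null(drop_masks))
    h <- ag_mul(h, ag_const(matrix(drop_masks[[2]], n, config$disc_units,
                                   byrow = TRUE)))
  .addbias(ag_matmul(h, P$W_out), P$b_out)     # n x 1
}

.graph_arrays <- function(graph) {
  # accepts molgraph, generator_output, or a bare list(adjacency, features)
  if (inherits(graph, "generator_output"))
    list(A = graph$edge_probs, X = graph$node_probs)
  else list(A = graph$adjacency, X = graph$features)
}

#' Critic (discriminator) forward pass
#'
#' Relational GCN rounds on the node features, a pad-weighted sum readout
#' (`weight_i = 1 - P(pad_i)`, which stays differentiable for soft and
#' interpolated inputs), a dense stack with dropout, and a final linear map
#' to an unbounded scalar (Wasserstein critic).
#'
#' @param graphs a `molgraph`/`generator_output` or list of them; soft inputs
#'   are allowed.
#' @param params critic parameters (`init_gan_params()$disc`).
#' @param schema a `graph_schema`.
#' @param config a `model_config`.
#' @return numeric vector of critic scores.
#' @export
discriminator_forward <- function(graphs, params, schema, config) {
  if (inherits(graphs, c("molgraph", "generator_output")) ||
      (is.list(graphs) && !is.null(graphs$adjacency)))
    graphs <- list(graphs)
  P <- .params_to_nodes(params)
  B <- length(schema$bond_classes)
  vapply(graphs, function(g) {
    ar <- .graph_arrays(g)
    Alist <- lapply(seq_len(B), function(b) ag_const(ar$A[, , b]))
    ag_val(.disc_forward_nodes(Alist, ag_const(ar$X), P, schema, config))[1]
  }, 0)
}

## ---------------------------------------------------------------------------
## Discretization
## ---------------------------------------------------------------------------

# Vectorized one-hot sampling from soft edge/node distributions via the
# Gumbel-argmax construction (exact categorical sampling); `noise` is a
# vector of uniforms (N*N*B edge draws then N*F node draws) or NULL for
# deterministic argmax. Pad consistency is the caller's responsibility.
.sample_onehot <- function(soft_A, Xsoft, schema, noise = NULL,
                           temperature = 1) {
  N <- schema$max_atoms; B <- length(schema$bond_classes)
  Fw <- ncol(Xsoft)
  Zedge <- matrix(0, N * N, B)
  for (b in seq_len(B)) Zedge[, b] <- log(pmax(as.vector(soft_A[[b]]), 1e-12)) / temperature
  if (!is.null(noise)) {
    Zedge <- Zedge + matrix(-log(-log(noise[seq_len(N * N * B)])), N * N, B)
  }
  pick_e <- max.col(Zedge, ties.method = "first")
  A <- array(0, dim = c(N, N, B))
  for (i in seq_len(N)) {
    A[i, i, 1L] <- 1
    if (i < N) for (j in (i + 1L):N) {
      cls <- pick_e[(j - 1L) * N + i]
      A[i, j, cls] <- 1; A[j, i, cls] <- 1
    }
  }
  Znode <- log(pmax(Xsoft, 1e-12)) / temperature
  if (!is.null(noise))
    Znode <- Znode + matrix(-log(-log(noise[N * N * B + seq_len(N * Fw)])), N, Fw)
  X <- matrix(0, N, Fw)
  blocks <- list(seq_len(length(schema$atom_types) + 1L),
                 schema_charge_cols(schema), schema_chiral_cols(schema))
  for (js in blocks[vapply(blocks, length, 0L) > 0L]) {
    sel <- max.col(Znode[, js, drop = FALSE], ties.method = "first")
    X[cbind(seq_len(N), js[sel])] <- 1
  }
  list(A = A, X = X)
}

#' Discretize generator output into a one-hot molecular graph
#'
#' `argmax` picks the mode of every distribution; `categorical` samples each
#' distribution (seeded, with optional temperature: probabilities are raised
#' to 1/T and renormalized); `gumbel_st` perturbs log-probabilities with
#' Gumbel noise and takes the argmax (the hard part of the straight-through
#' estimator used on the training path). All modes decide the upper triangle
#' and mirror it, force the diagonal to no-bond, and restore pad consistency
#' (pad rows lose their bonds and sit in the neutral/none slots).
#'
#' @param output a `generator_output`.
#' @param schema a `graph_schema`.
#' @param mode `"argmax"`, `"categorical"` or `"gumbel_st"`.
#' @param temperature positive sampling temperature.
#' @param seed integer seed (ignored for argmax).
#' @return a `molgraph` satisfying all tensor invariants.
#' @export
discretize <- function(output, schema, mode = c("categorical", "argmax", "gumbel_st"),
                       temperature = 1, seed = 1L) {
  mode <- match.arg(mode)
  if (temperature <= 0) stop_molwgan("discretize", "temperature must be positive")
  N <- schema$max_atoms; B <- length(schema$bond_classes)
  Fw <- schema$feature_width
  soft_A <- lapply(seq_len(B), function(b) output$edge_probs[, , b])
  noise <- if (mode == "argmax") NULL else {
    rng <- rng_stream(seed, "discretize")
    with_rng(rng, stats::runif(N * N * B + N * Fw))
  }
  d <- .sample_onehot(soft_A, output$node_probs, schema, noise = noise,
                      temperature = temperature)
  A <- d$A; X <- d$X
  cc <- schema_charge_cols(schema); hc <- schema_chiral_cols(schema)
  pads <- which(X[, schema_pad_col(schema)] == 1)
  for (i in pads) {
    A[i, , ] <- 0; A[, i, ] <- 0
    A[i, , 1L] <- 1; A[, i, 1L] <- 1
    if (length(cc) > 0L) { X[i, cc] <- 0; X[i, cc[match(0L, schema$charge_classes)]] <- 1 }
    if (length(hc) > 0L) { X[i, hc] <- 0; X[i, hc[1L]] <- 1 }
  }
  for (i in seq_len(N)) { A[i, i, ] <- 0; A[i, i, 1L] <- 1 }
  new_molgraph(A, X, N - length(pads))
}

## ---------------------------------------------------------------------------
## Gradient penalty and losses
## ---------------------------------------------------------------------------

# node-level penalty for one (real, fake) pair given a critic-node builder
.gp_one <- function(Ar, Xr, Af, Xf, critic_builder, eps) {
  B <- length(Ar)
  Ai <- lapply(seq_len(B), function(b)
    ag_input(eps * Ar[[b]] + (1 - eps) * Af[[b]]))
  Xi <- ag_input(eps * Xr + (1 - eps) * Xf)
  D <- critic_builder(Ai, Xi)
  gs <- ag_grad(D, c(Ai, list(Xi)))
  ss <- Reduce(ag_add, lapply(gs, function(g) ag_sum(ag_mul(g, g))))
  nrm <- ag_sqrt(ss)
  ag_pow(ag_sub(nrm, ag_const(1)), 2)
}

#' WGAN gradient penalty
#'
#' For each real/fake pair an interpolation point `x^ = eps*real +
#' (1-eps)*fake` (one `eps ~ U(0,1)` per pair, seeded) is formed jointly on
#' adjacency and features; the penalty is the batch mean of
#' `(||grad_x^ D(x^)||_2 - 1)^2`, the norm running over all interpolated
#' coordinates of one sample.
#'
#' @param real,fake lists of graphs (`molgraph`/`generator_output`), equal
#'   length.
#' @param critic either a list(params, schema, config) using the package
#'   critic, or a function(adjacency_nodes, features_node) returning a scalar
#'   engine node (for custom critics in analyses).
#' @param seed integer seed for the interpolation coefficients.
#' @return numeric penalty.
#' @export
gradient_penalty <- function(real, fake, critic, seed = 1L) {
  stopifnot(length(real) == length(fake), length(real) > 0L)
  rng <- rng_stream(seed, "gp")
  builder <- if (is.function(critic)) critic else {
    P <- .params_to_nodes(critic$params)
    function(Alist, X) .disc_forward_nodes(Alist, X, P, critic$schema,
                                           critic$config)
  }
  pen <- 0
  for (k in seq_along(real)) {
    r <- .graph_arrays(real[[k]]); f <- .graph_arrays(fake[[k]])
    B <- dim(r$A)[3]
    Ar <- lapply(seq_len(B), function(b) r$A[, , b])
    Af <- lapply(seq_len(B), function(b) f$A[, , b])
    eps <- with_rng(rng, stats::runif(1))
    pen <- pen + ag_val(.gp_one(Ar, r$X, Af, f$X, builder, eps))[1]
  }
  pen / length(real)
}

#' Wasserstein losses
#'
#' `d_loss = mean(fake) - mean(real) + gp_lambda * penalty`;
#' `g_loss = -mean(fake)`.
#'
#' @param real_scores,fake_scores numeric critic scores.
#' @param penalty gradient penalty.
#' @param gp_lambda penalty weight.
#' @return list(d_loss, g_loss).
#' @export
wgan_losses <- function(real_scores, fake_scores, penalty = 0, gp_lambda = 10) {
  list(d_loss = mean(fake_scores) - mean(real_scores) + gp_lambda * penalty,
       g_loss = -mean(fake_scores))
}
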