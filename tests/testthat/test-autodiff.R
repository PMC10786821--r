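# The reverse-mode engine that powers the networks: first-order gradients
# against numerical differentiation, and double backpropagation (gradient of
# a gradient-norm penalty), which the WGAN gradient penalty relies on.

num_grad <- function(f, v, eps = 1e-6) {
  g <- array(0, dim = dim(v))
  for (k in seq_along(v)) {
    vp <- v; vp[k] <- vp[k] + eps
    vm <- v; vm[k] <- vm[k] - eps
    g[k] <- (f(vp) - f(vm)) / (2 * eps)
  }
  g
}

test_that("composite forward passes match numerical gradients", {
  ag <- asNamespace("molwgan")
  set.seed(1)
  W1v <- matrix(rnorm(12), 3, 4); W2v <- matrix(rnorm(8), 4, 2)
  xv <- matrix(rnorm(6), 2, 3)
  fwd <- function(W1, W2, x) {
    h <- ag$ag_tanh(ag$ag_matmul(x, W1))
    sm <- ag$ag_softmax_rows(ag$ag_matmul(h, W2))
    ag$ag_sum(ag$ag_mul(sm, ag$ag_matmul(h, W2)))
  }
  W1 <- ag$ag_input(W1v); W2 <- ag$ag_input(W2v)
  y <- fwd(W1, W2, ag$ag_const(xv))
  gs <- ag$ag_grad(y, list(W1, W2))
  f1 <- function(W) ag$ag_val(fwd(ag$ag_const(W), ag$ag_const(W2v),
                                  ag$ag_const(xv)))[1]
  f2 <- function(W) ag$ag_val(fwd(ag$ag_const(W1v), ag$ag_const(W),
                                  ag$ag_const(xv)))[1]
  expect_lt(max(abs(ag$ag_val(gs[[1]]) - num_grad(f1, W1v))), 1e-6)
  expect_lt(max(abs(ag$ag_val(gs[[2]]) - num_grad(f2, W2v))), 1e-6)
})

test_that("gradients of gradient norms (double backward) are exact", {
  ag <- asNamespace("molwgan")
  set.seed(2)
  Wv <- matrix(rnorm(9) * 0.5, 3, 3)
  xv <- matrix(rnorm(3), 1, 3)
  build <- function(Wv_) {
    W <- ag$ag_input(Wv_); x <- ag$ag_input(xv)
    D <- ag$ag_sum(ag$ag_tanh(ag$ag_matmul(x, W)))
    gx <- ag$ag_grad(D, list(x))[[1]]
    nrm <- ag$ag_sqrt(ag$ag_sum(ag$ag_mul(gx, gx)))
    list(pen = ag$ag_pow(ag$ag_sub(nrm, ag$ag_const(1)), 2), W = W)
  }
  r <- build(Wv)
  gW <- ag$ag_grad(r$pen, list(r$W))[[1]]
  fP <- function(W_) ag$ag_val(build(W_)$pen)[1]
  expect_lt(max(abs(ag$ag_val(gW) - num_grad(fP, Wv, 1e-5))), 1e-6)
})

test_that("broadcasting ops reduce gradients to the operand shapes", {
  ag <- asNamespace("molwgan")
  A <- ag$ag_input(matrix(1:6 / 10, 2, 3))
  v <- ag$ag_input(matrix(c(2, 3), 2, 1))      # column broadcast
  s <- ag$ag_input(matrix(0.5, 1, 1))          # scalar broadcast
  y <- ag$ag_sum(ag$ag_mul(ag$ag_mul(A, v), s))
  gs <- ag$ag_grad(y, list(A, v, s))
  expect_identical(dim(ag$ag_val(gs[[1]])), c(2L, 3L))
  expect_identical(dim(ag$ag_val(gs[[2]])), c(2L, 1L))
  expect_equal(ag$ag_val(gs[[3]])[1], sum(matrix(1:6 / 10, 2, 3) * c(2, 3)))
  # slice/scatter pair is an exact adjoint
  M <- ag$ag_input(matrix(rnorm(12), 2, 6))
  y2 <- ag$ag_sum(ag$ag_mul(ag$ag_slice_cols(M, 3:5), ag$ag_const(matrix(1:6, 2, 3))))
  g2 <- ag$ag_val(ag$ag_grad(y2, list(M))[[1]])
  expect_equal(g2[, 3:5], matrix(1:6, 2, 3))
  expect_true(all(g2[, c(1, 2, 6)] == 0))
})

test_that("straight-through nodes pass hard values forward, gradients back", {
  ag <- asNamespace("molwgan")
  soft <- ag$ag_input(matrix(c(0.2, 0.8), 1, 2))
  hard <- matrix(c(0, 1), 1, 2)
  st <- ag$ag_st(soft, hard)
  expect_identical(ag$ag_val(st), hard)
  w <- matrix(c(3, 7), 2, 1)
  y <- ag$ag_matmul(st, ag$ag_const(w))
  g <- ag$ag_val(ag$ag_grad(ag$ag_sum(y), list(soft))[[1]])
  expect_equal(g, t(w))
})
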