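# Minimal reverse-mode automatic differentiation on R matrices.
#
# The WGAN critic's gradient penalty needs d/d(theta) of || d D(x) / dx ||,
# i.e. differentiating through a gradient. Every backward rule below is
# itself composed of engine operations, so calling ag_grad() on the result of
# a previous ag_grad() performs exact double backpropagation. Values are
# plain R matrices (scalars are 1x1); nodes are environments carrying the
# value, parents and a vector-Jacobian product closure.

.ag_counter <- local({ i <- 0L; function() { i <<- i + 1L; i } })

ag_node <- function(val, parents = list(), vjp = NULL, requires = FALSE) {
  if (!requires) {
    for (p in parents) if (p$requires) { requires <- TRUE; break }
  }
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$parents <- parents
  e$vjp <- vjp
  e$requires <- requires
  e$id <- .ag_counter()
  class(e) <- "ag_node"
  e
}

#' @keywords internal
ag_const <- function(val) ag_node(as_mat(val))

#' @keywords internal
ag_input <- function(val) ag_node(as_mat(val), requires = TRUE)

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = if (length(x) == 1L) 1L else length(x))
}

.is_scalar <- function(x) length(x$val) == 1L

# elementwise binary op with scalar or column-vector broadcasting
.bcast_case <- function(a, b) {
  if (identical(dim(a$val), dim(b$val))) return("same")
  if (.is_scalar(b)) return("sb")
  if (.is_scalar(a)) return("sa")
  if (ncol(b$val) == 1L && nrow(b$val) == nrow(a$val)) return("colb")
  if (ncol(a$val) == 1L && nrow(a$val) == nrow(b$val)) return("cola")
  stop("ag: incompatible shapes ", paste(dim(a$val), collapse = "x"), " vs ",
       paste(dim(b$val), collapse = "x"))
}

.reduce_to <- function(g, case, which) {
  # reduce gradient g to the broadcast operand's shape
  if (case == "same") return(g)
  if ((case == "sb" && which == 2L) || (case == "sa" && which == 1L))
    return(ag_sum(g))
  if ((case == "colb" && which == 2L) || (case == "cola" && which == 1L))
    return(ag_rowsums(g))
  g
}

.bval <- function(a, b, f, case) {
  switch(case,
         same = f(a$val, b$val),
         sb   = f(a$val, b$val[1L]),
         sa   = f(a$val[1L], b$val),
         colb = f(a$val, as.vector(b$val)),
         cola = f(as.vector(a$val), b$val))
}

ag_add <- function(a, b) {
  case <- .bcast_case(a, b)
  ag_node(.bval(a, b, `+`, case), list(a, b), function(g, self)
    list(.reduce_to(g, case, 1L), .reduce_to(g, case, 2L)))
}

ag_sub <- function(a, b) {
  case <- .bcast_case(a, b)
  ag_node(.bval(a, b, `-`, case), list(a, b), function(g, self)
    list(.reduce_to(g, case, 1L), ag_neg(.reduce_to(g, case, 2L))))
}

ag_neg <- function(a) ag_node(-a$val, list(a), function(g, self) list(ag_neg(g)))

ag_mul <- function(a, b) {
  case <- .bcast_case(a, b)
  ag_node(.bval(a, b, `*`, case), list(a, b), function(g, self)
    list(.reduce_to(ag_mul(g, b), case, 1L),
         .reduce_to(ag_mul(g, a), case, 2L)))
}

ag_div <- function(a, b) {
  case <- .bcast_case(a, b)
  ag_node(.bval(a, b, `/`, case), list(a, b), function(g, self) {
    ga <- .reduce_to(ag_div(g, b), case, 1L)
    gb <- .reduce_to(ag_neg(ag_div(ag_mul(g, a), ag_mul(b, b))), case, 2L)
    list(ga, gb)
  })
}

ag_matmul <- function(a, b) {
  ag_node(a$val %*% b$val, list(a, b), function(g, self)
    list(ag_matmul(g, ag_t(b)), ag_matmul(ag_t(a), g)))
}

ag_t <- function(a) ag_node(t(a$val), list(a), function(g, self) list(ag_t(g)))

ag_sum <- function(a) {
  ag_node(matrix(sum(a$val), 1, 1), list(a), function(g, self)
    list(ag_mul(g, ag_const(array(1, dim = dim(a$val))))))
}

ag_mean <- function(a) ag_mul(ag_sum(a), ag_const(1 / length(a$val)))

ag_rowsums <- function(a) {
  m <- ncol(a$val)
  ag_node(matrix(rowSums(a$val), ncol = 1), list(a), function(g, self)
    list(ag_matmul(g, ag_const(matrix(1, 1, m)))))
}

ag_exp <- function(a) {
  ag_node(exp(a$val), list(a), function(g, self) list(ag_mul(g, self)))
}

ag_log <- function(a) {
  ag_node(log(a$val), list(a), function(g, self) list(ag_div(g, a)))
}

ag_pow <- function(a, p) {
  ag_node(a$val^p, list(a), function(g, self)
    list(ag_mul(g, ag_mul(ag_const(p), ag_pow(a, p - 1)))))
}

ag_sqrt <- function(a) {
  ag_node(sqrt(a$val), list(a), function(g, self)
    list(ag_div(g, ag_mul(ag_const(2), self))))
}

ag_tanh <- function(a) {
  ag_node(tanh(a$val), list(a), function(g, self)
    list(ag_mul(g, ag_sub(ag_const(1), ag_mul(self, self)))))
}

ag_relu <- function(a) {
  mask <- (a$val > 0) * 1
  ag_node(a$val * mask, list(a), function(g, self)
    list(ag_mul(g, ag_const(mask))))
}

ag_lrelu <- function(a, alpha = 0.2) {
  mask <- ifelse(a$val > 0, 1, alpha)
  ag_node(a$val * mask, list(a), function(g, self)
    list(ag_mul(g, ag_const(mask))))
}

# pmax against a constant threshold (used for degree clamping)
ag_maxc <- function(a, c) {
  mask <- (a$val > c) * 1
  ag_node(pmax(a$val, c), list(a), function(g, self)
    list(ag_mul(g, ag_const(mask))))
}

ag_row <- function(a, i) {
  n <- nrow(a$val)
  ag_node(a$val[i, , drop = FALSE], list(a), function(g, self) {
    e <- matrix(0, n, 1); e[i, 1] <- 1
    list(ag_matmul(ag_const(e), g))
  })
}

ag_col <- function(a, j) {
  m <- ncol(a$val)
  ag_node(a$val[, j, drop = FALSE], list(a), function(g, self) {
    e <- matrix(0, 1, m); e[1, j] <- 1
    list(ag_matmul(g, ag_const(e)))
  })
}

ag_cols <- function(a, js) {
  m <- ncol(a$val)
  sel <- matrix(0, m, length(js))
  for (k in seq_along(js)) sel[js[k], k] <- 1
  ag_matmul(a, ag_const(sel))
}

# direct column slicing with a zero-scatter adjoint (avoids dense selection
# matrices for wide tensors such as flattened edge logits)
ag_slice_cols <- function(a, js) {
  m <- ncol(a$val)
  ag_node(a$val[, js, drop = FALSE], list(a), function(g, self)
    list(ag_scatter_cols(g, js, m)))
}

ag_scatter_cols <- function(g, js, m) {
  v <- matrix(0, nrow(g$val), m)
  v[, js] <- g$val
  ag_node(v, list(g), function(gg, self) list(ag_slice_cols(gg, js)))
}

ag_reshape <- function(a, nr, nc) {
  d <- dim(a$val)
  ag_node(matrix(as.vector(a$val), nr, nc), list(a), function(g, self)
    list(ag_reshape(g, d[1], d[2])))
}

# straight-through estimator: forward takes the hard (discretized) values,
# backward passes gradients to the soft distribution unchanged
ag_st <- function(soft, hard_val) {
  ag_node(as_mat(hard_val), list(soft), function(g, self) list(g))
}

# row-wise softmax (numerically shifted; the shift is an exact invariance)
ag_softmax_rows <- function(a) {
  shift <- ag_const(matrix(apply(a$val, 1, max), ncol = 1))
  e <- ag_exp(ag_sub(a, shift))
  ag_div(e, ag_rowsums(e))
}

#' Reverse-mode gradients
#'
#' @param y scalar output node.
#' @param wrt list of nodes to differentiate with respect to.
#' @return list of gradient nodes (same order as `wrt`); differentiable
#'   again, enabling higher-order derivatives.
#' @keywords internal
ag_grad <- function(y, wrt) {
  stopifnot(length(y$val) == 1L)
  tag <- .ag_counter()   # unique visit stamp for this backward pass
  # collect the differentiable subgraph; ids increase during construction,
  # so reverse-id order is a valid reverse-topological order
  nodes <- vector("list", 256L); nn <- 0L
  stack <- vector("list", 64L); sp <- 1L
  stack[[1L]] <- y
  while (sp > 0L) {
    nd <- stack[[sp]]; sp <- sp - 1L
    if (identical(nd$.tag, tag)) next
    nd$.tag <- tag
    nd$.grad <- NULL
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) {
      if (p$requires && !identical(p$.tag, tag)) {
        sp <- sp + 1L
        if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
        stack[[sp]] <- p
      }
    }
  }
  nodes <- nodes[seq_len(nn)]
  nodes <- nodes[order(vapply(nodes, function(nd) nd$id, 0L),
                       decreasing = TRUE)]

  y$.grad <- ag_const(matrix(1, 1, 1))
  for (nd in nodes) {
    g <- nd$.grad
    if (is.null(g) || is.null(nd$vjp)) next
    pgs <- nd$vjp(g, nd)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (!p$requires || is.null(pgs[[k]])) next
      p$.grad <- if (is.null(p$.grad) || !identical(p$.tag, tag)) pgs[[k]]
                 else ag_add(p$.grad, pgs[[k]])
      p$.tag <- tag
    }
  }
  lapply(wrt, function(w) {
    g <- if (identical(w$.tag, tag)) w$.grad else NULL
    if (is.null(g)) ag_const(array(0, dim = dim(w$val))) else g
  })
}

ag_val <- function(x) x$val
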