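# Optimizers over nested parameter lists. RMSprop: moving average of squared
# gradients, decay 0.9, no momentum. Adam: beta = (0.5, 0.9), the usual GAN
# setting rather than the (0.9, 0.999) default.

opt_init <- function(params, config) {
  zeros <- rapply(params, function(v) array(0, dim = dim(v)),
                  how = "replace", classes = "matrix")
  list(kind = config$optimizer, lr = config$learning_rate, t = 0L,
       m = zeros, v = zeros)
}

opt_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  if (state$kind == "rmsprop") {
    dec <- 0.9; eps <- 1e-8
    rec <- function(p, g, v) {
      if (is.matrix(p)) {
        v2 <- dec * v + (1 - dec) * g * g
        list(p = p - state$lr * g / (sqrt(v2) + eps), v = v2, m = v)
      } else {
        out <- Map(rec, p, g, v)
        list(p = lapply(out, `[[`, "p"), v = lapply(out, `[[`, "v"),
             m = lapply(out, `[[`, "m"))
      }
    }
    r <- rec(params, grads, state$v)
    state$v <- r$v
    return(list(params = r$p, state = state))
  }
  b1 <- 0.5; b2 <- 0.9; eps <- 1e-8
  t <- state$t
  rec <- function(p, g, m, v) {
    if (is.matrix(p)) {
      m2 <- b1 * m + (1 - b1) * g
      v2 <- b2 * v + (1 - b2) * g * g
      mh <- m2 / (1 - b1^t); vh <- v2 / (1 - b2^t)
      list(p = p - state$lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
    } else {
      out <- Map(rec, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    }
  }
  r <- rec(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

# extract plain gradient arrays matching the nested parameter structure
.grads_from_nodes <- function(param_nodes, grad_nodes_flat) {
  k <- 0L
  rec <- function(x) {
    if (inherits(x, "ag_node")) {
      k <<- k + 1L
      v <- ag_val(grad_nodes_flat[[k]])
      if (!is.matrix(v)) v <- as_mat(v)
      v
    } else lapply(x, rec)
  }
  rec(param_nodes)
}

#' Count trainable parameters
#' @param params nested parameter list (or `init_gan_params()` result).
#' @return integer count.
#' @export
count_params <- function(params) {
  tot <- 0L
  rec <- function(x) {
    if (is.matrix(x)) tot <<- tot + length(x) else for (e in x) rec(e)
  }
  rec(params)
  tot
}
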