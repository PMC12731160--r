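# Minimal Adam optimizer over an arbitrarily nested list of numeric
# parameter arrays. Gradients must mirror the parameter structure.

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else array(0, dim = dim(x) %||% length(x))
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = state$t))
}
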