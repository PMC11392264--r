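# Shared fixtures: tiny network configurations and finite-difference
# utilities. All fixtures are generated in code under fixed seeds.

ps <- asNamespace("polypseg")

# A small architecture for unit tests (full-size nets are exercised in the
# acceptance suite).
tiny_config <- function(...) {
  network_config(
    filters = c(8L, 16L, 16L, 16L, 16L),
    input_size = 64L,
    decoder_widths = c(16L, 8L, 8L, 4L),
    aux_width = 8L,
    ...
  )
}

# central finite-difference gradient of scalar-valued get() at val
num_grad <- function(get, val, eps = 1e-6) {
  g <- val * 0
  for (i in seq_along(val)) {
    v1 <- val; v1[i] <- val[i] + eps
    v2 <- val; v2[i] <- val[i] - eps
    g[i] <- (get(v1) - get(v2)) / (2 * eps)
  }
  g
}

# run fn under a scalar objective sum(y^2) and return grads of the leaves
backward_sumsq <- function(node) {
  loss <- ps$ag_node(sum(node$value^2), list(node),
                     function(g) list(2 * g * node$value))
  ps$ag_backward(loss)
  invisible(loss$value)
}

rand4 <- function(n, c, h, w, sd = 1) array(rnorm(n * c * h * w, sd = sd), c(n, c, h, w))

# fraction of parameters with a nonzero accumulated gradient
grad_coverage <- function(params) {
  ok <- vapply(params, function(p) !is.null(p$grad) && any(p$grad != 0), logical(1))
  mean(ok)
}

names_without_grad <- function(params) {
  names(params)[vapply(params, function(p) is.null(p$grad) || all(p$grad == 0),
                       logical(1))]
}
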