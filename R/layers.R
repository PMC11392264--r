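# Neural-network module constructors on top of the autodiff engine.
#
# A module is a list with class "nn_module" holding:
#   $params  named list of ag_param leaves
#   $modules named list of submodules
#   $state   named list of non-trainable buffers (e.g. batch-norm statistics)
#   $forward a closure over the parameters
# Parameter initialisation draws from the session RNG, so seeding the R RNG
# before construction makes builds reproducible.

nn_module <- function(forward, params = list(), modules = list(), state = list()) {
  structure(list(forward = forward, params = params, modules = modules, state = state),
            class = "nn_module")
}

# Kaiming/He normal initialisation for rectified units
.he_init <- function(fan_in, n) rnorm(n, sd = sqrt(2 / fan_in))

nn_conv2d <- function(in_ch, out_ch, kernel, stride = 1L, pad = NULL, bias = TRUE) {
  if (is.null(pad)) pad <- (kernel - 1L) %/% 2L  # same padding for odd kernels
  w <- ag_param(array(.he_init(in_ch * kernel * kernel, out_ch * in_ch * kernel * kernel),
                      c(out_ch, in_ch, kernel, kernel)))
  b <- if (bias) ag_param(numeric(out_ch)) else ag_leaf(numeric(out_ch))
  params <- list(weight = w)
  if (bias) params$bias <- b
  nn_module(
    forward = function(x) ag_conv2d(x, w, b, stride = stride, pad = pad),
    params = params
  )
}

nn_batch_norm2d <- function(ch, momentum = 0.1, eps = 1e-5) {
  gamma <- ag_param(rep(1, ch))
  beta <- ag_param(numeric(ch))
  state <- new.env(parent = emptyenv())
  state$running_mean <- numeric(ch)
  state$running_var <- rep(1, ch)
  nn_module(
    forward = function(x) ag_batch_norm(x, gamma, beta, state, momentum = momentum, eps = eps),
    params = list(gamma = gamma, beta = beta),
    state = list(bn = state)
  )
}

nn_linear <- function(in_f, out_f) {
  w <- ag_param(matrix(.he_init(in_f, out_f * in_f), out_f, in_f))
  b <- ag_param(numeric(out_f))
  nn_module(
    forward = function(x) ag_linear(x, w, b),
    params = list(weight = w, bias = b)
  )
}

# conv -> batch norm -> ReLU, the standard encoder unit
nn_conv_bn_relu <- function(in_ch, out_ch, kernel, stride = 1L, pad = NULL) {
  conv <- nn_conv2d(in_ch, out_ch, kernel, stride = stride, pad = pad, bias = FALSE)
  bn <- nn_batch_norm2d(out_ch)
  nn_module(
    forward = function(x) ag_relu(bn$forward(conv$forward(x))),
    modules = list(conv = conv, bn = bn)
  )
}

# ---- parameter bookkeeping --------------------------------------------------

# Flatten a module tree into a named list of ag_param leaves,
# names joined with "." as in torch state dicts.
collect_parameters <- function(module, prefix = "") {
  out <- list()
  for (nm in names(module$params)) {
    out[[paste0(prefix, nm)]] <- module$params[[nm]]
  }
  for (nm in names(module$modules)) {
    out <- c(out, collect_parameters(module$modules[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

# Named list of batch-norm (and other) state buffers in the tree
collect_state <- function(module, prefix = "") {
  out <- list()
  for (nm in names(module$state)) {
    out[[paste0(prefix, nm)]] <- module$state[[nm]]
  }
  for (nm in names(module$modules)) {
    out <- c(out, collect_state(module$modules[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

n_parameters <- function(module) {
  sum(vapply(collect_parameters(module), function(p) length(p$value), numeric(1)))
}
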