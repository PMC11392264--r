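# Gradient correctness of the autodiff engine: every op is checked against
# central finite differences on small random tensors.

test_that("conv2d forward matches a direct sliding-window computation", {
  set.seed(11)
  x <- rand4(1, 2, 5, 5)
  w <- array(rnorm(3 * 2 * 3 * 3), c(3, 2, 3, 3))
  b <- rnorm(3)
  y <- ps$cpp_conv2d_forward(x, w, b, 1L, 1L)
  # brute-force oracle: loop over output positions with explicit padding
  xp <- array(0, c(2, 7, 7))
  xp[, 2:6, 2:6] <- x[1, , , ]
  for (co in 1:3) for (oh in 1:5) for (ow in 1:5) {
    patch <- xp[, oh:(oh + 2), ow:(ow + 2)]
    expect_equal(y[1, co, oh, ow], sum(patch * w[co, , , ]) + b[co],
                 tolerance = 1e-12)
  }
})

test_that("strided conv2d halves spatial dimensions", {
  set.seed(12)
  x <- rand4(2, 3, 8, 8)
  w <- array(rnorm(4 * 3 * 3 * 3), c(4, 3, 3, 3))
  y <- ps$cpp_conv2d_forward(x, w, numeric(4), 2L, 1L)
  expect_equal(dim(y), c(2L, 4L, 4L, 4L))
})

test_that("all autodiff ops pass finite-difference gradient checks", {
  set.seed(13)
  checks <- list(
    conv = function() {
      x <- rand4(2, 2, 6, 6); w <- array(rnorm(12 * 2), c(3, 2, 2, 2)); b <- rnorm(3)
      list(
        leaves = list(x = x, w = w, b = b),
        fwd = function(l) ps$ag_conv2d(l$x, l$w, l$b, stride = 2L, pad = 1L),
        num = function(l) sum(ps$cpp_conv2d_forward(l$x, l$w, l$b, 2L, 1L)^2)
      )
    },
    bilinear = function() {
      x <- rand4(1, 2, 4, 5)
      list(leaves = list(x = x),
           fwd = function(l) ps$ag_bilinear(l$x, 7L, 9L),
           num = function(l) sum(ps$cpp_bilinear_forward(l$x, 7L, 9L)^2))
    },
    maxpool = function() {
      x <- rand4(1, 2, 6, 6)
      list(leaves = list(x = x),
           fwd = function(l) ps$ag_maxpool(l$x),
           num = function(l) sum(ps$cpp_maxpool_forward(l$x, 3L, 2L, 1L)$y^2))
    },
    gap = function() {
      x <- rand4(2, 3, 4, 4)
      list(leaves = list(x = x),
           fwd = function(l) ps$ag_gap(l$x),
           num = function(l) sum(ps$.ag_val(ps$ag_gap(ps$ag_leaf(l$x)))^2))
    },
    channel_mean = function() {
      x <- rand4(2, 3, 3, 3)
      list(leaves = list(x = x),
           fwd = function(l) ps$ag_channel_mean(l$x),
           num = function(l) sum(ps$ag_channel_mean(ps$ag_leaf(l$x))$value^2))
    },
    channel_max = function() {
      x <- rand4(2, 3, 3, 3)
      list(leaves = list(x = x),
           fwd = function(l) ps$ag_channel_max(l$x),
           num = function(l) sum(ps$ag_channel_max(ps$ag_leaf(l$x))$value^2))
    },
    linear = function() {
      x <- matrix(rnorm(8), 2, 4); w <- matrix(rnorm(12), 3, 4); b <- rnorm(3)
      list(leaves = list(x = x, w = w, b = b),
           fwd = function(l) ps$ag_linear(l$x, l$w, l$b),
           num = function(l) sum(ps$ag_linear(ps$ag_leaf(l$x), ps$ag_leaf(l$w),
                                              ps$ag_leaf(l$b))$value^2))
    },
    scale_channel = function() {
      x <- rand4(2, 3, 3, 3); s <- matrix(runif(6), 2, 3)
      list(leaves = list(x = x, s = s),
           fwd = function(l) ps$ag_scale_channel(l$x, l$s),
           num = function(l) sum(ps$ag_scale_channel(ps$ag_leaf(l$x),
                                                     ps$ag_leaf(l$s))$value^2))
    },
    spatial_gate = function() {
      x <- rand4(2, 3, 4, 4); m <- rand4(2, 1, 4, 4)
      list(leaves = list(x = x, m = m),
           fwd = function(l) ps$ag_spatial_gate(l$x, l$m),
           num = function(l) sum(ps$ag_spatial_gate(ps$ag_leaf(l$x),
                                                    ps$ag_leaf(l$m))$value^2))
    },
    attention_mix = function() {
      x <- rand4(2, 4, 3, 3); ch <- matrix(runif(8), 2, 4); sp <- rand4(2, 1, 3, 3)
      list(leaves = list(x = x, ch = ch, sp = sp),
           fwd = function(l) ps$ag_attention_mix(l$x, l$ch, l$sp),
           num = function(l) sum(ps$ag_attention_mix(ps$ag_leaf(l$x), ps$ag_leaf(l$ch),
                                                     ps$ag_leaf(l$sp))$value^2))
    }
  )
  for (nm in names(checks)) {
    case <- checks[[nm]]()
    ps$ag_tape_start()
    nodes <- lapply(case$leaves, ps$ag_param)
    out <- case$fwd(nodes)
    backward_sumsq(out)
    ps$ag_tape_stop()
    for (leaf in names(case$leaves)) {
      gnum <- num_grad(function(v) {
        l <- case$leaves
        l[[leaf]] <- v
        case$num(l)
      }, case$leaves[[leaf]])
      expect_lt(max(abs(gnum - nodes[[leaf]]$grad)), 1e-6,
                label = paste0("op ", nm, ", leaf ", leaf, " grad error"))
    }
  }
})

test_that("batch norm gradients are exact in training and inference modes", {
  set.seed(14)
  x <- rand4(2, 3, 4, 4)
  gam <- rnorm(3) + 1
  bet <- rnorm(3)
  for (training in c(TRUE, FALSE)) {
    ps$ag_set_training(training)
    fwd_num <- function(xx, gg, bb) {
      st <- new.env(); st$running_mean <- c(0.1, -0.2, 0.3); st$running_var <- c(1.1, 0.9, 1.4)
      sum(ps$ag_batch_norm(ps$ag_leaf(xx), ps$ag_leaf(gg), ps$ag_leaf(bb), st)$value^2)
    }
    st <- new.env(); st$running_mean <- c(0.1, -0.2, 0.3); st$running_var <- c(1.1, 0.9, 1.4)
    ps$ag_tape_start()
    xn <- ps$ag_param(x); gn <- ps$ag_param(gam); bn <- ps$ag_param(bet)
    y <- ps$ag_batch_norm(xn, gn, bn, st)
    backward_sumsq(y)
    ps$ag_tape_stop()
    expect_lt(max(abs(num_grad(function(v) fwd_num(v, gam, bet), x) - xn$grad)), 1e-5)
    expect_lt(max(abs(num_grad(function(v) fwd_num(x, v, bet), gam) - gn$grad)), 1e-5)
    expect_lt(max(abs(num_grad(function(v) fwd_num(x, gam, v), bet) - bn$grad)), 1e-5)
  }
  ps$ag_set_training(FALSE)
})

test_that("loss primitives have exact analytic gradients", {
  set.seed(15)
  p <- array(runif(16, 0.05, 0.95), c(1, 1, 4, 4))
  q <- array(rbinom(16, 1, 0.4), c(1, 1, 4, 4))
  ps$ag_tape_start()
  pn <- ps$ag_param(p)
  l <- ps$ag_bce(pn, q)
  l$grad <- 1
  ps$ag_backward(l)
  ps$ag_tape_stop()
  gnum <- num_grad(function(v) bce_loss(v, q), p)
  expect_lt(max(abs(gnum - pn$grad)), 1e-6)

  ps$ag_tape_start()
  pn <- ps$ag_param(p)
  l <- ps$ag_dice_coef(pn, q)
  l$grad <- 1
  ps$ag_backward(l)
  ps$ag_tape_stop()
  gnum <- num_grad(function(v) dice_coefficient(v, q), p)
  expect_lt(max(abs(gnum - pn$grad)), 1e-6)
})

test_that("concatenation splits gradients back to the right inputs", {
  set.seed(16)
  a <- rand4(1, 2, 3, 3)
  b <- rand4(1, 3, 3, 3)
  ps$ag_tape_start()
  an <- ps$ag_param(a); bn <- ps$ag_param(b)
  y <- ps$ag_concat(list(an, bn))
  # weight the two blocks differently so a swap would be detected
  wgt <- array(rep(1:5, times = 9), c(1, 5, 3, 3))
  loss <- ps$ag_node(sum(y$value * wgt), list(y), function(g) list(g * wgt))
  ps$ag_backward(loss)
  ps$ag_tape_stop()
  expect_equal(dim(y$value), c(1L, 5L, 3L, 3L))
  expect_equal(unique(as.vector(an$grad[1, 1, , ])), 1)
  expect_equal(unique(as.vector(an$grad[1, 2, , ])), 2)
  expect_equal(unique(as.vector(bn$grad[1, 3, , ])), 5)
})

test_that("inference without a tape computes values but records nothing", {
  set.seed(17)
  x <- rand4(1, 2, 4, 4)
  w <- ps$ag_param(array(rnorm(8), c(1, 2, 2, 2)))
  y <- ps$ag_conv2d(x, w, numeric(1), stride = 2L, pad = 0L)
  expect_equal(dim(y$value), c(1L, 1L, 2L, 2L))
  expect_null(y$backward)
  expect_null(w$grad)
})
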