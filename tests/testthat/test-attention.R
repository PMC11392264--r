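# The supervision head, mask-gated skip fusion, and multi-kernel decoder
# block: shape contracts, analytic limit cases, attention bounds, batch
# independence, and gradient flow.

test_that("supervision head emits a one-channel mask at the shallow scale", {
  set.seed(61)
  head <- ps$supervision_head(8L, 16L, width = 8L)
  low <- rand4(2, 8, 32, 32)
  high <- rand4(2, 16, 2, 2)
  out <- head$forward(low, high)
  expect_equal(dim(out$logits$value), c(2L, 1L, 32L, 32L))
  expect_true(all(out$prob$value > 0 & out$prob$value < 1))
  expect_error(head$forward(low, rand4(1, 16, 2, 2)), "batch sizes")
})

test_that("zero-weight final 1x1 head makes the mask constant at its bias", {
  set.seed(62)
  head <- ps$supervision_head(4L, 8L, width = 4L)
  head$modules$head$params$weight$value <- head$modules$head$params$weight$value * 0
  head$modules$head$params$bias$value <- 0.7
  out <- head$forward(rand4(1, 4, 16, 16), rand4(1, 8, 4, 4))
  expect_true(all(abs(out$logits$value - 0.7) < 1e-12))
  expect_true(all(abs(out$prob$value - 1 / (1 + exp(-0.7))) < 1e-12))
})

test_that("bilinear interpolation preserves constant deep features", {
  cst <- array(2.5, c(1, 3, 4, 4))
  up <- ps$cpp_bilinear_forward(cst, 32L, 32L)
  expect_true(all(abs(up - 2.5) < 1e-12))
})

test_that("mask-gated skip: saturation, annihilation, and shape preservation", {
  set.seed(63)
  skip <- ps$mask_gated_skip(6L)
  e <- rand4(1, 6, 8, 8)
  ones <- array(1, c(1, 1, 4, 4))
  zeros <- array(0, c(1, 1, 4, 4))
  out1 <- skip$forward(e, ones)
  expect_equal(dim(out1$value), c(1L, 6L, 8L, 8L))
  # mask == 1: the gate passes E + 1 into the convolution
  w <- skip$modules$conv$params$weight$value
  b <- skip$modules$conv$params$bias$value
  conv_ref <- ps$cpp_conv2d_forward(e + 1, w, b, 1L, 1L)
  scale <- 1 / (1 + exp(-ps$.nc_sum(conv_ref) / 64))
  expect_equal(out1$value, conv_ref * ps$.nc_bcast(scale, dim(conv_ref)),
               tolerance = 1e-12)
  # mask == 0: the convolution sees a zero field, so X' is its bias response
  out0 <- skip$forward(e, zeros)
  bias_resp <- ps$cpp_conv2d_forward(e * 0, w, b, 1L, 1L)
  for (ch in 1:6) expect_true(all(bias_resp[1, ch, , ] == b[ch]))
  scale0 <- 1 / (1 + exp(-ps$.nc_sum(bias_resp) / 64))
  expect_equal(out0$value, bias_resp * ps$.nc_bcast(scale0, dim(bias_resp)),
               tolerance = 1e-12)
  expect_error(skip$forward(e, rand4(1, 2, 4, 4)), "one channel")
})

test_that("channel attention scales a lone constant channel by sigmoid(c)", {
  # direct evaluation of the squeeze step: X' with one nonzero channel of
  # constant value c; the channel scale is sigmoid(c), others stay zero
  c_val <- 1.3
  xp <- array(0, c(1, 3, 4, 4))
  xp[1, 2, , ] <- c_val
  s <- ps$ag_sigmoid(ps$ag_gap(ps$ag_leaf(xp)))
  out <- ps$ag_scale_channel(ps$ag_leaf(xp), s)
  expect_equal(s$value[1, 2], 1 / (1 + exp(-c_val)), tolerance = 1e-12)
  expect_true(all(abs(out$value[1, 2, , ] - c_val / (1 + exp(-c_val))) < 1e-12))
  expect_true(all(out$value[1, c(1, 3), , ] == 0))
})

test_that("multi-kernel block: branch widths, output shape, attention bound", {
  set.seed(64)
  blk <- ps$multi_kernel_block(16L, 8L)
  x <- rand4(2, 16, 8, 8)
  y <- blk$forward(x)
  expect_equal(dim(y$value), c(2L, 8L, 8L, 8L))
  expect_equal(dim(blk$modules$branch_k9$params$weight$value), c(2L, 16L, 9L, 9L))
  expect_error(ps$multi_kernel_block(16L, 10L), "divisible")
  # attention factor = channel sigmoid + spatial sigmoid is in (0, 2):
  # |output| < 2 * |trunk| elementwise
  trunk <- ps$ag_concat(lapply(c(3L, 5L, 7L, 9L), function(k) {
    b <- blk$modules[[paste0("branch_k", k)]]
    b$forward(ps$ag_leaf(x))
  }))
  ratio <- abs(y$value) / pmax(abs(trunk$value), 1e-12)
  expect_true(all(ratio < 2))
  expect_true(all(ratio > 0))
})

test_that("unit attention reduces the block to its multi-kernel trunk", {
  set.seed(65)
  trunk <- rand4(1, 8, 5, 5)
  ones <- matrix(1, 1, 8)
  zeros <- array(0, c(1, 1, 5, 5))
  out <- ps$ag_attention_mix(ps$ag_leaf(trunk), ps$ag_leaf(ones), ps$ag_leaf(zeros))
  expect_identical(out$value, trunk)
})

test_that("spatial submodule pools a constant input into equal flat planes", {
  cst <- array(1.7, c(1, 6, 13, 13))
  m <- ps$ag_channel_mean(ps$ag_leaf(cst))
  mx <- ps$ag_channel_max(ps$ag_leaf(cst))
  expect_identical(m$value, mx$value)
  expect_true(all(abs(m$value - 1.7) < 1e-12))
  # away from the zero-padded border, the 7x7 conv of a flat field is flat
  set.seed(66)
  blk <- ps$multi_kernel_block(6L, 8L)
  pooled <- ps$ag_concat(list(m, mx))
  plane <- ps$ag_sigmoid(blk$modules$spatial_conv$forward(pooled))
  interior <- plane$value[1, 1, 4:10, 4:10]
  expect_true(all(abs(interior - interior[1, 1]) < 1e-12))
})

test_that("per-sample outputs match batched outputs (no cross-sample leakage)", {
  set.seed(67)
  head <- ps$supervision_head(4L, 8L, width = 4L)
  low <- rand4(3, 4, 16, 16)
  high <- rand4(3, 8, 4, 4)
  batched <- head$forward(low, high)$prob$value
  for (i in 1:3) {
    single <- head$forward(low[i, , , , drop = FALSE],
                           high[i, , , , drop = FALSE])$prob$value
    expect_equal(single[1, , , ], batched[i, , , ], tolerance = 1e-12)
  }
})

test_that("gradients reach every parameter of all three blocks", {
  set.seed(68)
  head <- ps$supervision_head(4L, 8L, width = 4L)
  skip <- ps$mask_gated_skip(6L)
  blk <- ps$multi_kernel_block(6L, 8L)
  ps$ag_set_training(TRUE)
  ps$ag_tape_start()
  aux <- head$forward(rand4(2, 4, 16, 16), rand4(2, 8, 4, 4))
  fused <- skip$forward(rand4(2, 6, 8, 8), aux$prob)
  out <- blk$forward(fused)
  backward_sumsq(out)
  ps$ag_tape_stop()
  ps$ag_set_training(FALSE)
  for (mod in list(head, skip, blk)) {
    params <- ps$collect_parameters(mod)
    expect_equal(grad_coverage(params), 1,
                 info = paste("missing:", paste(names_without_grad(params), collapse = ", ")))
  }
})
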