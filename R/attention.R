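# The three architectural building blocks beyond the residual encoder:
#
#  * supervision_head  — fuses the shallow stem features (rich spatial
#    detail) with the deepest encoder features (rich semantics) into a
#    one-channel coarse lesion mask at stem resolution; trained directly
#    by the local Dice loss (deep supervision).
#  * mask_gated_skip   — gates an encoder skip feature with the resized
#    supervision mask (soft spatial attention, with the mask itself added
#    back as a residual), refines with a 3x3 convolution, then rescales
#    channels by a sigmoid of their global average (channel attention).
#  * multi_kernel_block — the decoder unit: four parallel convolutions
#    with kernel sizes 3/5/7/9 capture context at several receptive
#    fields; the concatenated trunk is modulated by per-branch channel
#    attention plus a single-plane spatial attention computed from the
#    block input. The attention factor is a sum of two sigmoids, bounded
#    in (0, 2).

#' Deep-supervision mask head
#'
#' Projects both inputs to a common width with 1x1 convolutions, bilinearly
#' upsamples the deep branch to the shallow branch's resolution,
#' concatenates, refines with two 3x3 conv-BN-ReLU units, and maps to
#' one-channel mask logits with a final 1x1 convolution.
#'
#' @param low_ch channels of the shallow (stem) input.
#' @param high_ch channels of the deep (last-stage) input.
#' @param width internal common width (default 64).
#' @return an `nn_module`; `forward(low, high)` returns
#'   `list(logits, prob)`, both (N, 1, H_low, W_low).
#' @keywords internal
supervision_head <- function(low_ch, high_ch, width = 64L) {
  proj_low <- nn_conv2d(low_ch, width, 1L, pad = 0L)
  proj_high <- nn_conv2d(high_ch, width, 1L, pad = 0L)
  refine1 <- nn_conv_bn_relu(2L * width, width, 3L)
  refine2 <- nn_conv_bn_relu(width, width, 3L)
  head <- nn_conv2d(width, 1L, 1L, pad = 0L)
  forward <- function(low, high) {
    low <- .ag_wrap(low); high <- .ag_wrap(high)
    if (dim(low$value)[1] != dim(high$value)[1]) {
      stop("supervision_head: batch sizes differ between inputs")
    }
    d <- dim(low$value)
    a <- proj_low$forward(low)
    b <- ag_bilinear(proj_high$forward(high), d[3], d[4])
    x <- refine2$forward(refine1$forward(ag_concat(list(a, b))))
    logits <- head$forward(x)
    list(logits = logits, prob = ag_sigmoid(logits))
  }
  nn_module(forward = forward,
            modules = list(proj_low = proj_low, proj_high = proj_high,
                           refine1 = refine1, refine2 = refine2, head = head))
}

#' Mask-gated skip fusion with channel attention
#'
#' With a mask: the mask probability is bilinearly resized to the skip
#' feature's resolution and broadcast over channels; the gated feature
#' `E * m + m` is refined by a channel-preserving 3x3 convolution, then
#' each channel is scaled by the sigmoid of its global average (squeeze
#' attention without a bottleneck). Without a mask (supervision head
#' ablated) the gate is skipped and the same conv + channel attention is
#' applied to the raw skip feature.
#'
#' @param ch channel count of the skip feature (preserved).
#' @return an `nn_module`; `forward(e, mask_prob = NULL)` maps
#'   (N, ch, H, W) to (N, ch, H, W).
#' @keywords internal
mask_gated_skip <- function(ch) {
  conv <- nn_conv2d(ch, ch, 3L)
  forward <- function(e, mask_prob = NULL) {
    e <- .ag_wrap(e)
    x <- if (is.null(mask_prob)) {
      e
    } else {
      mask_prob <- .ag_wrap(mask_prob)
      if (dim(mask_prob$value)[2] != 1L) {
        stop("mask_gated_skip: mask must have exactly one channel")
      }
      d <- dim(e$value)
      ag_spatial_gate(e, ag_bilinear(mask_prob, d[3], d[4]))
    }
    refined <- conv$forward(x)
    ag_scale_channel(refined, ag_sigmoid(ag_gap(refined)))
  }
  nn_module(forward = forward, modules = list(conv = conv))
}

#' Parallel multi-kernel decoder block
#'
#' Four same-padded convolutions with kernel sizes `kernels` each produce
#' `out_ch / 4` channels. Each branch feeds a channel-attention submodule
#' (global average pool, bottleneck MLP with the given reduction ratio,
#' sigmoid). A spatial submodule pools the block input over channels
#' (mean and max), applies a 7x7 convolution and a sigmoid to give one
#' attention plane. Output: `concat(branches) * (channel + spatial)`.
#'
#' @param in_ch input channels.
#' @param out_ch output channels, divisible by the number of kernels.
#' @param kernels odd kernel sizes (default 3, 5, 7, 9).
#' @param reduction channel-attention bottleneck ratio (default 4).
#' @return an `nn_module`; `forward(x)` maps (N, in_ch, H, W) to
#'   (N, out_ch, H, W).
#' @keywords internal
multi_kernel_block <- function(in_ch, out_ch, kernels = c(3L, 5L, 7L, 9L),
                               reduction = 4L) {
  nk <- length(kernels)
  if (out_ch %% nk != 0L) {
    stop("multi_kernel_block: out_ch (", out_ch,
         ") must be divisible by the number of kernels (", nk, ")")
  }
  bw <- out_ch %/% nk
  branches <- lapply(kernels, function(k) nn_conv2d(in_ch, bw, as.integer(k)))
  names(branches) <- paste0("branch_k", kernels)
  hidden <- max(1L, bw %/% reduction)
  ch_att <- lapply(seq_len(nk), function(i) {
    fc1 <- nn_linear(bw, hidden)
    fc2 <- nn_linear(hidden, bw)
    nn_module(
      forward = function(x) ag_sigmoid(fc2$forward(ag_leaky_relu(fc1$forward(ag_gap(x))))),
      modules = list(fc1 = fc1, fc2 = fc2)
    )
  })
  names(ch_att) <- paste0("channel_att", seq_len(nk))
  sp_conv <- nn_conv2d(2L, 1L, 7L)
  forward <- function(x) {
    x <- .ag_wrap(x)
    xi <- lapply(branches, function(b) b$forward(x))
    trunk <- ag_concat(xi)
    cw <- ag_cat_cols(lapply(seq_len(nk), function(i) ch_att[[i]]$forward(xi[[i]])))
    pooled <- ag_concat(list(ag_channel_mean(x), ag_channel_max(x)))
    sw <- ag_sigmoid(sp_conv$forward(pooled))
    ag_attention_mix(trunk, cw, sw)
  }
  nn_module(forward = forward,
            modules = c(branches, ch_att, list(spatial_conv = sp_conv)))
}

# Ablation stand-in for the multi-kernel block: two 3x3 conv-BN-ReLU units
# (the plain U-Net-style decoder unit).
plain_decoder_block <- function(in_ch, out_ch) {
  c1 <- nn_conv_bn_relu(in_ch, out_ch, 3L)
  c2 <- nn_conv_bn_relu(out_ch, out_ch, 3L)
  nn_module(
    forward = function(x) c2$forward(c1$forward(x)),
    modules = list(conv1 = c1, conv2 = c2)
  )
}
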