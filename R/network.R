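# Full network assembly: residual encoder -> deep-supervision mask head ->
# mask-gated skip fusion -> multi-kernel attention decoder -> prediction
# head, with ablation switches for each component.

#' Network architecture configuration
#'
#' @param filters five encoder channel widths (stem, stages 1-4). The
#'   default follows the reference configuration `c(32, 64, 128, 256, 512)`;
#'   pretrained ResNet34 import requires `c(64, 64, 128, 256, 512)`.
#' @param input_size square input resolution in pixels, divisible by 32.
#' @param decoder_widths four decoder channel widths, deepest first.
#' @param mk_kernels kernel sizes of the multi-kernel decoder block.
#' @param mk_reduction channel-attention bottleneck ratio.
#' @param aux_width internal width of the supervision head.
#' @param use_aux_head include the deep-supervision mask head.
#' @param use_skip_fusion include mask-gated skip fusion (off: raw encoder
#'   taps are used as skips).
#' @param use_mk_decoder use multi-kernel attention decoder blocks (off:
#'   plain double-conv blocks, the baseline decoder).
#' @param use_local_loss attach the local Dice loss to the supervision mask
#'   during training.
#' @return a `network_config` list.
#' @export
network_config <- function(filters = c(32L, 64L, 128L, 256L, 512L),
                           input_size = 256L,
                           decoder_widths = c(256L, 128L, 64L, 32L),
                           mk_kernels = c(3L, 5L, 7L, 9L),
                           mk_reduction = 4L,
                           aux_width = 64L,
                           use_aux_head = TRUE,
                           use_skip_fusion = TRUE,
                           use_mk_decoder = TRUE,
                           use_local_loss = TRUE) {
  filters <- as.integer(filters)
  input_size <- as.integer(input_size)
  decoder_widths <- as.integer(decoder_widths)
  if (length(filters) != 5L || any(filters < 1L)) {
    stop("network_config: filters must be five positive channel widths")
  }
  if (input_size < 32L || input_size %% 32L != 0L) {
    stop("network_config: input_size must be a positive multiple of 32")
  }
  if (length(decoder_widths) != 4L) {
    stop("network_config: decoder_widths must have four entries")
  }
  if (use_mk_decoder && any(decoder_widths %% length(mk_kernels) != 0L)) {
    stop("network_config: decoder widths must be divisible by the number of ",
         "parallel kernels (", length(mk_kernels), ")")
  }
  structure(list(
    filters = filters, input_size = input_size,
    decoder_widths = decoder_widths,
    mk_kernels = as.integer(mk_kernels), mk_reduction = as.integer(mk_reduction),
    aux_width = as.integer(aux_width),
    use_aux_head = isTRUE(use_aux_head),
    use_skip_fusion = isTRUE(use_skip_fusion),
    use_mk_decoder = isTRUE(use_mk_decoder),
    use_local_loss = isTRUE(use_local_loss)
  ), class = "network_config")
}

#' Build the segmentation network
#'
#' Constructs all modules with freshly initialised parameters (He-normal
#' convolution weights). Seed the R RNG beforehand for reproducible builds.
#'
#' @param config a [network_config()].
#' @return a `seg_network` object with elements `config`, `module` (the
#'   root `nn_module`) and `parameters` (flat named list).
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  f <- config$filters
  dw <- config$decoder_widths
  encoder <- build_encoder(f)
  mods <- list(encoder = encoder)

  if (config$use_aux_head) {
    mods$aux_head <- supervision_head(f[1], f[5], width = config$aux_width)
  }
  skip_ch <- f[2:5]  # channels of taps e3, e7, e13, e16
  if (config$use_skip_fusion) {
    skips <- lapply(skip_ch, mask_gated_skip)
    names(skips) <- paste0("skip_", c("e3", "e7", "e13", "e16"))
    mods <- c(mods, skips)
  }

  dec_block <- function(in_ch, out_ch) {
    if (config$use_mk_decoder) {
      multi_kernel_block(in_ch, out_ch, config$mk_kernels, config$mk_reduction)
    } else {
      plain_decoder_block(in_ch, out_ch)
    }
  }
  # deepest level consumes the fused e16 tap directly; upper levels
  # concatenate the upsampled decoder state with the fused skip
  mods$dec4 <- dec_block(f[5], dw[1])
  mods$dec3 <- dec_block(dw[1] + f[4], dw[2])
  mods$dec2 <- dec_block(dw[2] + f[3], dw[3])
  mods$dec1 <- dec_block(dw[3] + f[2], dw[4])
  mods$head_refine1 <- nn_conv_bn_relu(dw[4], dw[4], 3L)
  mods$head_refine2 <- nn_conv_bn_relu(dw[4], dw[4], 3L)
  mods$head_out <- nn_conv2d(dw[4], 1L, 1L, pad = 0L)

  forward <- function(x) {
    x <- .ag_wrap(x)
    taps <- encoder$forward(x)
    aux <- NULL
    mask_prob <- NULL
    if (config$use_aux_head) {
      aux <- mods$aux_head$forward(taps$stem, taps$e16)
      mask_prob <- aux$prob
    }
    fuse <- function(which, tap) {
      if (config$use_skip_fusion) {
        mods[[paste0("skip_", which)]]$forward(tap, mask_prob)
      } else {
        tap
      }
    }
    s3 <- fuse("e3", taps$e3)
    s7 <- fuse("e7", taps$e7)
    s13 <- fuse("e13", taps$e13)
    s16 <- fuse("e16", taps$e16)

    up2 <- function(x) {
      d <- dim(.ag_val(x))
      ag_bilinear(x, 2L * d[3], 2L * d[4])
    }
    d4 <- mods$dec4$forward(s16)
    d3 <- mods$dec3$forward(ag_concat(list(up2(d4), s13)))
    d2 <- mods$dec2$forward(ag_concat(list(up2(d3), s7)))
    d1 <- mods$dec1$forward(ag_concat(list(up2(d2), s3)))
    h <- mods$head_refine1$forward(up2(d1))
    h <- mods$head_refine2$forward(up2(h))
    prediction <- ag_sigmoid(mods$head_out$forward(h))
    structure(list(prediction = prediction, aux = aux, taps = taps),
              class = "seg_forward")
  }

  root <- nn_module(forward = forward, modules = mods)
  structure(list(config = config, module = root,
                 parameters = collect_parameters(root)),
            class = "seg_network")
}

#' @export
print.seg_network <- function(x, ...) {
  cfg <- x$config
  cat("<seg_network>\n")
  cat("  filters:       ", paste(cfg$filters, collapse = ", "), "\n")
  cat("  decoder widths:", paste(cfg$decoder_widths, collapse = ", "), "\n")
  cat("  switches:       aux_head=", cfg$use_aux_head,
      " skip_fusion=", cfg$use_skip_fusion,
      " mk_decoder=", cfg$use_mk_decoder,
      " local_loss=", cfg$use_local_loss, "\n", sep = "")
  cat("  parameters:    ", format(sum(parameter_census(x)$parameters), big.mark = ","), "\n")
  invisible(x)
}

#' Run the network forward
#'
#' @param network a `seg_network`.
#' @param images numeric array (N, 3, H, W) in `[0, 1]`, H and W divisible
#'   by 32.
#' @param training logical; TRUE uses batch statistics in normalisation
#'   layers (and requires an open tape to record gradients), FALSE uses
#'   running statistics (inference).
#' @return a `seg_forward` list: `prediction` (node, (N, 1, H, W) in
#'   `(0, 1)`), `aux` (`list(logits, prob)` or NULL), `taps`.
#' @export
forward_pass <- function(network, images, training = FALSE) {
  stopifnot(inherits(network, "seg_network"))
  ag_set_training(training)
  on.exit(ag_set_training(FALSE))
  network$module$forward(images)
}

#' Predict segmentation probability maps
#'
#' Inference-mode forward pass returning a plain array.
#'
#' @inheritParams forward_pass
#' @return numeric array (N, 1, H, W) of foreground probabilities.
#' @export
predict_masks_array <- function(network, images) {
  out <- forward_pass(network, images, training = FALSE)
  out$prediction$value
}

#' Per-module trainable parameter counts
#'
#' @param network a `seg_network`.
#' @return a data.frame with columns `module` and `parameters`, one row per
#'   top-level component, ordered as built.
#' @export
parameter_census <- function(network) {
  stopifnot(inherits(network, "seg_network"))
  mods <- network$module$modules
  data.frame(
    module = names(mods),
    parameters = vapply(mods, n_parameters, numeric(1)),
    row.names = NULL
  )
}
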