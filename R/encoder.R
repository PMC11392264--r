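# Residual encoder: 7x7 stem convolution, stride-2 max pool, then four
# stages of ResNet34 BasicBlocks (3/4/6/3), with feature taps after
# residual blocks 3, 7, 13 and 16 (the end of each stage).
#
# Submodule names follow the torch ResNet34 state-dict convention
# (conv1, bn1, layer1.0.conv1, ..., layerL.i.downsample.0) so that
# pretrained weights can be matched by name.

#' Residual basic block
#'
#' Two 3x3 convolutions (the first optionally strided), each followed by
#' batch normalisation, with rectification after the first and after the
#' residual sum. The shortcut is the identity when the block preserves
#' shape, otherwise a strided 1x1 projection with batch normalisation.
#'
#' @param in_ch,out_ch input and output channel counts.
#' @param stride 1 or 2; the stride of the first convolution.
#' @return an `nn_module` whose `forward(x)` maps (N, in_ch, H, W) to
#'   (N, out_ch, H/stride, W/stride).
#' @keywords internal
residual_block <- function(in_ch, out_ch, stride = 1L) {
  if (!stride %in% c(1L, 2L)) {
    stop("residual_block: stride must be 1 or 2, got ", stride)
  }
  if (in_ch < 1L || out_ch < 1L) {
    stop("residual_block: channel counts must be positive")
  }
  conv1 <- nn_conv2d(in_ch, out_ch, 3L, stride = stride, bias = FALSE)
  bn1 <- nn_batch_norm2d(out_ch)
  conv2 <- nn_conv2d(out_ch, out_ch, 3L, stride = 1L, bias = FALSE)
  bn2 <- nn_batch_norm2d(out_ch)
  modules <- list(conv1 = conv1, bn1 = bn1, conv2 = conv2, bn2 = bn2)
  project <- (stride != 1L) || (in_ch != out_ch)
  if (project) {
    down <- nn_conv2d(in_ch, out_ch, 1L, stride = stride, pad = 0L, bias = FALSE)
    down_bn <- nn_batch_norm2d(out_ch)
    modules$downsample <- nn_module(
      forward = function(x) down_bn$forward(down$forward(x)),
      modules = list(`0` = down, `1` = down_bn)
    )
  }
  forward <- function(x) {
    out <- bn2$forward(conv2$forward(ag_relu(bn1$forward(conv1$forward(x)))))
    shortcut <- if (project) modules$downsample$forward(x) else .ag_wrap(x)
    ag_relu(ag_add(out, shortcut))
  }
  nn_module(forward = forward, modules = modules)
}

.encoder_stage <- function(n_blocks, in_ch, out_ch, first_stride) {
  blocks <- vector("list", n_blocks)
  blocks[[1]] <- residual_block(in_ch, out_ch, stride = first_stride)
  for (i in seq_len(n_blocks - 1L)) {
    blocks[[i + 1L]] <- residual_block(out_ch, out_ch, stride = 1L)
  }
  names(blocks) <- as.character(seq_len(n_blocks) - 1L)
  nn_module(
    forward = function(x) {
      for (b in blocks) x <- b$forward(x)
      x
    },
    modules = blocks
  )
}

#' Build the residual encoder
#'
#' @param filters five channel widths: stem and stages 1-4.
#' @param in_ch input image channels (3 for RGB).
#' @return an `nn_module` whose `forward(image)` returns the tap list
#'   `list(stem, e3, e7, e13, e16)` at strides 2, 4, 8, 16, 32.
#' @keywords internal
build_encoder <- function(filters, in_ch = 3L) {
  stopifnot(length(filters) == 5L)
  conv1 <- nn_conv2d(in_ch, filters[1], 7L, stride = 2L, pad = 3L, bias = FALSE)
  bn1 <- nn_batch_norm2d(filters[1])
  layer1 <- .encoder_stage(3L, filters[1], filters[2], first_stride = 1L)
  layer2 <- .encoder_stage(4L, filters[2], filters[3], first_stride = 2L)
  layer3 <- .encoder_stage(6L, filters[3], filters[4], first_stride = 2L)
  layer4 <- .encoder_stage(3L, filters[4], filters[5], first_stride = 2L)
  forward <- function(x) {
    x <- .ag_wrap(x)
    d <- dim(x$value)
    if (d[3] %% 32L != 0L || d[4] %% 32L != 0L) {
      stop("encoder: input spatial size must be divisible by 32, got ",
           d[3], "x", d[4])
    }
    stem <- ag_relu(bn1$forward(conv1$forward(x)))
    pooled <- ag_maxpool(stem, k = 3L, stride = 2L, pad = 1L)
    e3 <- layer1$forward(pooled)
    e7 <- layer2$forward(e3)
    e13 <- layer3$forward(e7)
    e16 <- layer4$forward(e13)
    list(stem = stem, e3 = e3, e7 = e7, e13 = e13, e16 = e16)
  }
  nn_module(
    forward = forward,
    modules = list(conv1 = conv1, bn1 = bn1,
                   layer1 = layer1, layer2 = layer2,
                   layer3 = layer3, layer4 = layer4)
  )
}

# Count residual blocks in an encoder module tree (sanity/introspection).
encoder_block_count <- function(encoder) {
  sum(vapply(c("layer1", "layer2", "layer3", "layer4"), function(l) {
    length(encoder$modules[[l]]$modules)
  }, numeric(1)))
}

#' Import pretrained ResNet34 encoder weights
#'
#' Copies stem and stage weights from a standard ResNet34 state dict (a
#' named list of arrays using torch naming, e.g. `layer1.0.conv1.weight`,
#' or an RDS file containing one) into the encoder. Requires the encoder
#' to have been built with the standard ResNet34 widths
#' `c(64, 64, 128, 256, 512)`; the default width list starts at 32 and is
#' incompatible with pretrained stems.
#'
#' @param network a `seg_network` (see [build_network()]).
#' @param state_source named list of numeric arrays, or path to an RDS file.
#' @return a list with character vectors `loaded` and `skipped`
#'   (parameter names), returned invisibly is FALSE (the report is the value).
#' @export
load_pretrained <- function(network, state_source) {
  filters <- network$config$filters
  if (!identical(as.numeric(filters), c(64, 64, 128, 256, 512))) {
    stop("load_pretrained: encoder stem width is ", filters[1],
         " but pretrained ResNet34 weights require filters c(64, 64, 128, 256, 512); ",
         "rebuild the network with those widths to import weights")
  }
  if (is.character(state_source)) {
    if (!file.exists(state_source)) {
      stop("load_pretrained: cannot read weight file '", state_source, "'")
    }
    state_source <- readRDS(state_source)
  }
  stopifnot(is.list(state_source), !is.null(names(state_source)))
  params <- collect_parameters(network$module$modules$encoder)
  loaded <- character(0)
  skipped <- character(0)
  for (nm in names(params)) {
    # our batch-norm params are gamma/beta; torch calls them weight/bias
    src_nm <- sub("\\.gamma$", ".weight", sub("\\.beta$", ".bias", nm))
    src <- state_source[[src_nm]]
    if (is.null(src) || length(src) != length(params[[nm]]$value)) {
      skipped <- c(skipped, nm)
      next
    }
    v <- params[[nm]]$value
    params[[nm]]$value <- array(as.numeric(src), dim = .dims(v))
    if (is.null(dim(v))) params[[nm]]$value <- as.numeric(src)
    loaded <- c(loaded, nm)
  }
  list(loaded = loaded, skipped = skipped,
       unused = setdiff(names(state_source),
                        sub("\\.gamma$", ".weight", sub("\\.beta$", ".bias", names(params)))))
}
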