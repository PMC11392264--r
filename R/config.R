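# YAML configuration mirroring train_config / network_config / loss_config.
#
# Layout:
#   network: {filters, input_size, decoder_widths, mk_kernels, mk_reduction,
#             use_aux_head, use_skip_fusion, use_mk_decoder, use_local_loss}
#   loss:    {alpha, lambda_local, epsilon}
#   train:   {batch_size, epochs, initial_lr, min_lr, beta1, seed, max_steps}
#   data:    {images, masks, val_images, val_masks, out}

#' Read a training configuration from YAML
#'
#' Missing keys fall back to the package defaults.
#'
#' @param path YAML file.
#' @return a [train_config()].
#' @export
read_train_config <- function(path) {
  if (!file.exists(path)) stop("read_train_config: no such file '", path, "'")
  y <- yaml::read_yaml(path)
  take <- function(block, defaults) {
    args <- defaults
    for (nm in names(block)) {
      if (!nm %in% names(args)) {
        stop("read_train_config: unknown key '", nm, "' in ", path)
      }
      args[[nm]] <- block[[nm]]
    }
    args
  }
  net_args <- take(y$network, formals(network_config))
  net <- do.call(network_config, lapply(net_args, function(a) {
    if (is.language(a)) eval(a) else a
  }))
  loss_args <- take(y$loss, formals(loss_config))
  loss <- do.call(loss_config, lapply(loss_args, function(a) {
    if (is.language(a)) eval(a) else a
  }))
  tr <- y$train %||% list()
  dat <- y$data %||% list()
  train_config(
    images_dir = dat$images, masks_dir = dat$masks,
    out_dir = dat$out,
    val_images_dir = dat$val_images, val_masks_dir = dat$val_masks,
    batch_size = tr$batch_size %||% 4L,
    epochs = tr$epochs %||% 200L,
    initial_lr = tr$initial_lr %||% 1e-4,
    min_lr = tr$min_lr %||% 1e-5,
    beta1 = tr$beta1 %||% 0.9,
    seed = tr$seed %||% 0L,
    max_steps = tr$max_steps,
    threshold = tr$threshold %||% 0.5,
    loss = loss, network = net
  )
}
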