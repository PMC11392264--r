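# Training loop: Adam with cosine-annealed learning rate, per-epoch
# validation, best/last checkpoints and a CSV history of loss components
# and metrics.

#' Training configuration
#'
#' Defaults follow the reference training protocol: batch size 4, 200
#' epochs, Adam with first-moment decay 0.9, learning rate annealed from
#' 1e-4 to 1e-5.
#'
#' @param images_dir,masks_dir training data directories (paired by stem).
#' @param out_dir output directory for checkpoints and history.
#' @param val_images_dir,val_masks_dir optional validation directories; no
#'   split is made internally.
#' @param batch_size samples per optimisation step (>= 1).
#' @param epochs training epochs.
#' @param initial_lr,min_lr cosine annealing endpoints, `min_lr <= initial_lr`.
#' @param beta1 Adam first-moment decay (the protocol's "momentum").
#' @param beta2,adam_eps remaining Adam constants.
#' @param seed RNG seed for initialisation and batch shuffling.
#' @param max_steps optional cap on total optimisation steps.
#' @param validate_every_epoch run validation after each epoch when
#'   validation data is configured.
#' @param threshold binarisation threshold for metric computation.
#' @param loss a [loss_config()].
#' @param network a [network_config()].
#' @return a `train_config` list.
#' @export
train_config <- function(images_dir = NULL, masks_dir = NULL, out_dir = NULL,
                         val_images_dir = NULL, val_masks_dir = NULL,
                         batch_size = 4L, epochs = 200L,
                         initial_lr = 1e-4, min_lr = 1e-5,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         seed = 0L, max_steps = NULL,
                         validate_every_epoch = TRUE, threshold = 0.5,
                         loss = loss_config(), network = network_config()) {
  if (batch_size < 1L) stop("train_config: batch_size must be >= 1")
  if (min_lr > initial_lr) stop("train_config: min_lr must not exceed initial_lr")
  if (epochs < 1L) stop("train_config: epochs must be >= 1")
  structure(list(
    images_dir = images_dir, masks_dir = masks_dir, out_dir = out_dir,
    val_images_dir = val_images_dir, val_masks_dir = val_masks_dir,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    initial_lr = initial_lr, min_lr = min_lr,
    beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
    seed = as.integer(seed),
    max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
    validate_every_epoch = isTRUE(validate_every_epoch),
    threshold = threshold, loss = loss, network = network
  ), class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Cosine annealing from `initial_lr` at epoch 0 to `min_lr` at the final
#' epoch (`epochs - 1`).
#'
#' @param cfg a [train_config()].
#' @param epoch zero-based epoch index in `[0, epochs)`.
#' @return the learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  if (epoch < 0 || epoch >= cfg$epochs) {
    stop("lr_at_epoch: epoch ", epoch, " outside [0, ", cfg$epochs, ")")
  }
  if (cfg$epochs == 1L) return(cfg$initial_lr)
  frac <- epoch / (cfg$epochs - 1)
  cfg$min_lr + 0.5 * (cfg$initial_lr - cfg$min_lr) * (1 + cos(pi * frac))
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function(params) {
  list(
    m = lapply(params, function(p) p$value * 0),
    v = lapply(params, function(p) p$value * 0),
    t = 0L
  )
}

adam_step <- function(params, st, lr, beta1, beta2, eps) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    p$value <- p$value - lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  st
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- data loading -----------------------------------------------------------

# Load a full (desk-scale) dataset into batch arrays at the network size.
load_dataset_arrays <- function(images_dir, masks_dir, target_size) {
  manifest <- list_pairs(images_dir, masks_dir)
  pairs <- lapply(seq_len(nrow(manifest)), function(i) {
    load_pair(manifest[i, ], target_size)
  })
  stack_pairs(pairs)
}

# ---- training ---------------------------------------------------------------

#' Train the network
#'
#' Seeds all RNG streams from `cfg$seed`, iterates epochs x batches, and
#' per step computes the total double loss, backpropagates and applies an
#' Adam update at the cosine-annealed rate. When validation data is
#' configured, validation runs after each epoch and the checkpoint with
#' the best validation DSC is kept alongside the last one. Loss components
#' and metrics per epoch are logged to stderr and written to
#' `out_dir/history.csv`.
#'
#' @param cfg a [train_config()] with data directories set.
#' @param network optional pre-built `seg_network` (built from
#'   `cfg$network` when omitted).
#' @return invisibly, a list with `network`, `history` (data.frame), and
#'   checkpoint paths `last` / `best` (when `out_dir` is set).
#' @export
train_network <- function(cfg, network = NULL) {
  stopifnot(inherits(cfg, "train_config"))
  set.seed(cfg$seed)
  if (is.null(network)) network <- build_network(cfg$network)
  params <- network$parameters
  st <- adam_state(params)
  size <- cfg$network$input_size
  loss_cfg <- cfg$loss
  if (!cfg$network$use_local_loss) loss_cfg$lambda_local <- 0

  data <- load_dataset_arrays(cfg$images_dir, cfg$masks_dir, size)
  n <- dim(data$x)[1]
  val <- NULL
  if (!is.null(cfg$val_images_dir) && !is.null(cfg$val_masks_dir)) {
    val <- load_dataset_arrays(cfg$val_images_dir, cfg$val_masks_dir, size)
  }

  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  history <- list()
  best_dsc <- -Inf
  paths <- list(last = NULL, best = NULL)
  step <- 0L
  done <- FALSE

  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, epoch - 1L)
    order <- sample.int(n)
    comps <- c(global = 0, local = 0)
    total_sum <- 0
    n_batches <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- order[start:min(start + cfg$batch_size - 1L, n)]
      xb <- data$x[idx, , , , drop = FALSE]
      qb <- data$q[idx, , , , drop = FALSE]
      ag_tape_start()
      out <- forward_pass(network, xb, training = TRUE)
      tl <- total_loss_node(out, qb, loss_cfg)
      if (!is.finite(tl$node$value)) {
        ag_tape_stop()
        stop("train_network: non-finite loss at epoch ", epoch, ", step ",
             step + 1L, " (components: ",
             paste(names(tl$components), round(tl$components, 4),
                   sep = "=", collapse = ", "), ")")
      }
      ag_backward(tl$node)
      ag_tape_stop()
      st <- adam_step(params, st, lr, cfg$beta1, cfg$beta2, cfg$adam_eps)
      zero_grads(params)
      total_sum <- total_sum + tl$node$value
      comps <- comps + tl$components[names(comps)]
      n_batches <- n_batches + 1L
      step <- step + 1L
      if (!is.null(cfg$max_steps) && step >= cfg$max_steps) { done <- TRUE; break }
    }
    comps <- comps / n_batches
    row <- data.frame(epoch = epoch, lr = lr, steps = step,
                      loss = total_sum / n_batches,
                      loss_global = comps[["global"]],
                      loss_local = comps[["local"]],
                      val_dsc = NA_real_)
    if (!is.null(val) && cfg$validate_every_epoch) {
      vm <- .mean_dsc(network, val, cfg$threshold)
      row$val_dsc <- vm
      if (!is.null(cfg$out_dir) && vm > best_dsc) {
        best_dsc <- vm
        paths$best <- file.path(cfg$out_dir, "best.rds")
        save_checkpoint(network, paths$best,
                        extra = list(epoch = epoch, val_dsc = vm))
      }
    }
    history[[epoch]] <- row
    message(sprintf(
      "epoch %3d  lr %.2e  loss %.4f  global %.4f  local %.4f  val_dsc %s",
      epoch, lr, row$loss, row$loss_global, row$loss_local,
      ifelse(is.na(row$val_dsc), "-", sprintf("%.4f", row$val_dsc))))
    if (done) break
  }

  history <- do.call(rbind, history)
  if (!is.null(cfg$out_dir)) {
    paths$last <- file.path(cfg$out_dir, "last.rds")
    save_checkpoint(network, paths$last, extra = list(epoch = nrow(history)))
    utils::write.csv(history, file.path(cfg$out_dir, "history.csv"),
                     row.names = FALSE)
  }
  invisible(list(network = network, history = history,
                 checkpoints = paths))
}

# mean per-image DSC of inference predictions over stacked arrays
.mean_dsc <- function(network, data, threshold, batch = 4L) {
  n <- dim(data$x)[1]
  dscs <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    p <- predict_masks_array(network, data$x[idx, , , , drop = FALSE])
    for (j in seq_along(idx)) {
      dscs[idx[j]] <- evaluate_pair(p[j, 1, , ], data$q[idx[j], 1, , ],
                                    threshold)[["dsc"]]
    }
  }
  mean(dscs)
}

#' Evaluate a checkpoint on a dataset
#'
#' Loads the checkpoint, runs inference over all pairs and writes (when
#' `out_csv` is given) a per-image metrics CSV with a summary row, plus a
#' pooled precision-recall CSV alongside it.
#'
#' @param checkpoint path to a checkpoint file, or a `seg_network`.
#' @param images_dir,masks_dir evaluation data.
#' @param out_csv optional output CSV path.
#' @param threshold binarisation threshold.
#' @param aggregate `"per_image"` or `"pooled"` summary convention.
#' @return a list with `metrics` (data.frame) and `pr` (data.frame).
#' @export
evaluate_checkpoint <- function(checkpoint, images_dir, masks_dir,
                                out_csv = NULL, threshold = 0.5,
                                aggregate = "per_image") {
  network <- if (inherits(checkpoint, "seg_network")) checkpoint else {
    load_checkpoint(checkpoint)
  }
  size <- network$config$input_size
  data <- load_dataset_arrays(images_dir, masks_dir, size)
  n <- dim(data$x)[1]
  p_list <- vector("list", n)
  q_list <- vector("list", n)
  for (start in seq(1L, n, by = 4L)) {
    idx <- start:min(start + 3L, n)
    p <- predict_masks_array(network, data$x[idx, , , , drop = FALSE])
    for (j in seq_along(idx)) {
      p_list[[idx[j]]] <- p[j, 1, , ]
      q_list[[idx[j]]] <- data$q[idx[j], 1, , ]
    }
  }
  metrics <- evaluate_dataset(p_list, q_list, threshold = threshold,
                              aggregate = aggregate, ids = data$ids)
  pr <- pr_curve(p_list, q_list)
  if (!is.null(out_csv)) {
    utils::write.csv(metrics, out_csv, row.names = FALSE)
    utils::write.csv(pr, sub("\\.csv$", "_pr.csv", out_csv), row.names = FALSE)
  }
  list(metrics = metrics, pr = pr)
}

#' Predict masks for a directory of images
#'
#' @param checkpoint path to a checkpoint, or a `seg_network`.
#' @param images_dir directory of input images.
#' @param out_dir output directory for predicted mask PNGs (matching
#'   stems).
#' @param threshold binarisation threshold.
#' @return invisibly, character vector of written paths.
#' @export
predict_masks <- function(checkpoint, images_dir, out_dir, threshold = 0.5) {
  network <- if (inherits(checkpoint, "seg_network")) checkpoint else {
    load_checkpoint(checkpoint)
  }
  size <- network$config$input_size
  files <- sort(list.files(images_dir, pattern = .IMG_EXT, ignore.case = TRUE))
  if (length(files) == 0) stop("predict_masks: no images in '", images_dir, "'")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  for (f in files) {
    arr <- .decode_image(file.path(images_dir, f))
    if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
    if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
    img <- resize_bilinear(aperm(arr, c(3, 1, 2)), size, size)
    x <- array(img, c(1L, dim(img)))
    p <- predict_masks_array(network, x)
    out_path <- file.path(out_dir, paste0(tools::file_path_sans_ext(f), ".png"))
    save_mask(p[1, 1, , ], threshold = threshold, path = out_path)
    written <- c(written, out_path)
  }
  invisible(written)
}
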