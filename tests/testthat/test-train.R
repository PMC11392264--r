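# Training loop: schedule, bookkeeping, determinism, loss-component
# switches, checkpointing, and the evaluate/predict commands. All runs use
# the small architecture on tiny synthetic datasets.

make_tiny_dataset <- function(n = 4, seed = 1L, dir = tempfile()) {
  spec <- synthetic_spec(image_size = 64L, seed = seed)
  generate_dataset(spec, n, dir)
  dir
}

tiny_train_cfg <- function(dir, ...) {
  train_config(
    images_dir = file.path(dir, "images"), masks_dir = file.path(dir, "masks"),
    out_dir = file.path(dir, "run"),
    batch_size = 2L, epochs = 1L, seed = 0L,
    network = tiny_config(), ...
  )
}

test_that("cosine schedule hits the configured endpoints and midpoint", {
  cfg <- train_config(epochs = 201L)
  expect_equal(lr_at_epoch(cfg, 0), 1e-4)
  expect_equal(lr_at_epoch(cfg, 200), 1e-5)
  expect_equal(lr_at_epoch(cfg, 100), (1e-4 + 1e-5) / 2, tolerance = 1e-12)
  expect_error(lr_at_epoch(cfg, 201), "outside")
  expect_error(lr_at_epoch(cfg, -1), "outside")
  expect_error(train_config(min_lr = 1e-3), "min_lr")
  expect_error(train_config(batch_size = 0), "batch_size")
})

test_that("one epoch writes history, logs and checkpoints", {
  dir <- make_tiny_dataset()
  cfg <- tiny_train_cfg(dir)
  msgs <- capture.output(res <- train_network(cfg), type = "message")
  expect_true(any(grepl("epoch", msgs)))
  expect_equal(nrow(res$history), 1L)
  expect_true(file.exists(file.path(dir, "run", "history.csv")))
  expect_true(file.exists(res$checkpoints$last))
  expect_true(all(c("loss", "loss_global", "loss_local") %in% names(res$history)))
  expect_gt(res$history$loss_local[1], 0)
  unlink(dir, recursive = TRUE)
})

test_that("two runs with the same seed agree on the loss trajectory", {
  dir <- make_tiny_dataset()
  cfg <- tiny_train_cfg(dir)
  cfg$epochs <- 2L
  r1 <- suppressMessages(train_network(cfg))
  r2 <- suppressMessages(train_network(cfg))
  expect_equal(r1$history$loss, r2$history$loss, tolerance = 1e-9)
  expect_equal(r1$history$loss_local, r2$history$loss_local, tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})

test_that("the local loss component responds to its switches", {
  dir <- make_tiny_dataset()
  cfg <- tiny_train_cfg(dir)
  cfg$loss <- loss_config(lambda_local = 0)
  r0 <- suppressMessages(train_network(cfg))
  expect_identical(r0$history$loss_local, 0)
  cfg2 <- tiny_train_cfg(dir)
  cfg2$network <- tiny_config(use_local_loss = FALSE)
  r1 <- suppressMessages(train_network(cfg2))
  expect_identical(r1$history$loss_local, 0)
  unlink(dir, recursive = TRUE)
})

test_that("checkpoints restore weights, statistics and predictions exactly", {
  dir <- make_tiny_dataset()
  cfg <- tiny_train_cfg(dir)
  res <- suppressMessages(train_network(cfg))
  x <- rand4(1, 3, 64, 64)
  p_before <- predict_masks_array(res$network, x)
  net2 <- load_checkpoint(res$checkpoints$last)
  expect_equal(predict_masks_array(net2, x), p_before, tolerance = 1e-12)
  expect_error(load_checkpoint(file.path(dir, "nothere.rds")), "no such file")
  unlink(dir, recursive = TRUE)
})

test_that("validation drives the best checkpoint by mean DSC", {
  dir <- make_tiny_dataset(4)
  val <- make_tiny_dataset(2, seed = 2L)
  cfg <- tiny_train_cfg(dir,
                        val_images_dir = file.path(val, "images"),
                        val_masks_dir = file.path(val, "masks"))
  res <- suppressMessages(train_network(cfg))
  expect_false(is.na(res$history$val_dsc[1]))
  expect_true(file.exists(res$checkpoints$best))
  unlink(c(dir, val), recursive = TRUE)
})

test_that("evaluation agrees with the metrics module called directly", {
  dir <- make_tiny_dataset()
  cfg <- tiny_train_cfg(dir)
  res <- suppressMessages(train_network(cfg))
  out_csv <- file.path(dir, "metrics.csv")
  ev <- evaluate_checkpoint(res$network, cfg$images_dir, cfg$masks_dir,
                            out_csv = out_csv)
  expect_true(file.exists(out_csv))
  expect_true(file.exists(file.path(dir, "metrics_pr.csv")))
  # cross-check one row against a direct computation
  data <- ps$load_dataset_arrays(cfg$images_dir, cfg$masks_dir, 64L)
  p <- predict_masks_array(res$network, data$x[1, , , , drop = FALSE])
  direct <- evaluate_pair(p[1, 1, , ], data$q[1, 1, , ])
  expect_equal(unlist(ev$metrics[1, c("dsc", "precision", "recall", "iou")]),
               direct, tolerance = 1e-12, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})

test_that("a perfect-oracle prediction scores 1.0 on every metric", {
  # evaluation harness sanity: feed the reference masks as predictions
  dir <- make_tiny_dataset()
  data <- ps$load_dataset_arrays(file.path(dir, "images"), file.path(dir, "masks"), 64L)
  p_list <- lapply(1:4, function(i) data$q[i, 1, , ])
  q_list <- lapply(1:4, function(i) data$q[i, 1, , ])
  m <- evaluate_dataset(p_list, q_list)
  expect_true(all(m[nrow(m), c("dsc", "precision", "recall", "iou")] == 1))
  unlink(dir, recursive = TRUE)
})

test_that("prediction writes one idempotent mask file per input image", {
  dir <- make_tiny_dataset(3)
  cfg <- tiny_train_cfg(dir)
  res <- suppressMessages(train_network(cfg))
  out1 <- file.path(dir, "pred1")
  out2 <- file.path(dir, "pred2")
  written <- predict_masks(res$checkpoints$last, file.path(dir, "images"), out1)
  expect_length(written, 3L)
  expect_identical(sort(basename(written)),
                   sort(list.files(file.path(dir, "masks"))))
  predict_masks(res$checkpoints$last, file.path(dir, "images"), out2)
  expect_identical(unname(tools::md5sum(list.files(out1, full.names = TRUE))),
                   unname(tools::md5sum(list.files(out2, full.names = TRUE))))
  unlink(dir, recursive = TRUE)
})

test_that("a YAML config round-trips into an equivalent train_config", {
  dir <- make_tiny_dataset()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c(
    "network:",
    "  filters: [8, 16, 16, 16, 16]",
    "  input_size: 64",
    "  decoder_widths: [16, 8, 8, 4]",
    "  aux_width: 8",
    "  use_mk_decoder: false",
    "loss:",
    "  alpha: 0.4",
    "train:",
    "  batch_size: 2",
    "  epochs: 1",
    "  seed: 5",
    paste0("data: {images: ", file.path(dir, "images"),
           ", masks: ", file.path(dir, "masks"),
           ", out: ", file.path(dir, "run"), "}")
  ), yml)
  cfg <- read_train_config(yml)
  expect_s3_class(cfg, "train_config")
  expect_identical(cfg$network$filters, c(8L, 16L, 16L, 16L, 16L))
  expect_false(cfg$network$use_mk_decoder)
  expect_equal(cfg$loss$alpha, 0.4)
  expect_equal(cfg$seed, 5L)
  # unknown keys are refused rather than silently ignored
  writeLines(c("network:", "  filterz: [1,2,3,4,5]"), yml)
  expect_error(read_train_config(yml), "unknown key")
  unlink(dir, recursive = TRUE)
})

test_that("the CLI dispatcher routes synth and rejects unknown subcommands", {
  d <- tempfile()
  cli_main(c("synth", "--out", d, "--n", "2", "--size", "64", "--seed", "1"))
  expect_length(list.files(file.path(d, "images")), 2L)
  expect_error(cli_main(c("segment")), "unknown subcommand")
  unlink(d, recursive = TRUE)
})
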