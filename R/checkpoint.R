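# Checkpoints: a flat map from parameter names to arrays, plus the
# architecture config and normalisation-layer running statistics,
# versioned with a schema tag.

.CKPT_SCHEMA <- "polypseg-checkpoint-1"

#' Save a network checkpoint
#'
#' @param network a `seg_network`.
#' @param path output file (RDS).
#' @param extra optional named list stored alongside (e.g. epoch, metrics).
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(network, path, extra = list()) {
  stopifnot(inherits(network, "seg_network"))
  params <- lapply(network$parameters, function(p) p$value)
  states <- lapply(collect_state(network$module), function(s) {
    list(running_mean = s$running_mean, running_var = s$running_var)
  })
  obj <- list(schema = .CKPT_SCHEMA, config = network$config,
              params = params, states = states, extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a network checkpoint
#'
#' Rebuilds the architecture from the stored config and restores all
#' parameters and running statistics.
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return a `seg_network`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("load_checkpoint: no such file '", path, "'")
  obj <- readRDS(path)
  if (!identical(obj$schema, .CKPT_SCHEMA)) {
    stop("load_checkpoint: unrecognised checkpoint schema '", obj$schema, "'")
  }
  network <- build_network(obj$config)
  for (nm in names(obj$params)) {
    p <- network$parameters[[nm]]
    if (is.null(p)) stop("load_checkpoint: unknown parameter '", nm, "'")
    if (length(p$value) != length(obj$params[[nm]])) {
      stop("load_checkpoint: size mismatch for parameter '", nm, "'")
    }
    p$value <- obj$params[[nm]]
  }
  states <- collect_state(network$module)
  for (nm in names(obj$states)) {
    s <- states[[nm]]
    if (is.null(s)) next
    s$running_mean <- obj$states[[nm]]$running_mean
    s$running_var <- obj$states[[nm]]$running_var
  }
  network
}
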