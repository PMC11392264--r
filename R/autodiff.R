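# Reverse-mode automatic differentiation on dense arrays.
#
# A minimal tape-based engine sized for this package's networks: values are
# plain R arrays in (N, C, H, W) layout (or (N, K) matrices / scalars), nodes
# are environments recorded on a per-pass tape, and the heavy kernels
# (convolution, pooling, interpolation) live in C++.
#
# Usage pattern per optimisation step:
#   ag_tape_start(); out <- model$forward(x); ag_backward(loss); ag_tape_stop()
# Without an open tape the same ops run forward-only (inference).

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$enabled <- FALSE
.ag$training <- FALSE

ag_tape_start <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 512L)
  tape$n <- 0L
  .ag$tape <- tape
  .ag$enabled <- TRUE
  invisible(NULL)
}

ag_tape_stop <- function() {
  .ag$enabled <- FALSE
  .ag$tape <- NULL
  invisible(NULL)
}

ag_set_training <- function(on) {
  .ag$training <- isTRUE(on)
  invisible(NULL)
}

ag_is_node <- function(x) inherits(x, "ag_node")

# Leaf wrapper. Parameters are leaves with requires = TRUE whose grads
# persist across tape lifetimes (zeroed explicitly by the optimiser).
ag_leaf <- function(value, requires = FALSE, name = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$requires <- requires
  node$name <- name
  class(node) <- "ag_node"
  node
}

ag_param <- function(value, name = NULL) ag_leaf(value, requires = TRUE, name = name)

# Internal: build a computed node. `backward` maps the node's grad to a list
# of grads aligned with `parents` (NULL entries allowed).
ag_node <- function(value, parents, backward) {
  requires <- any(vapply(parents, function(p) isTRUE(p$requires), logical(1)))
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$requires <- requires
  class(node) <- "ag_node"
  if (requires && .ag$enabled) {
    node$parents <- parents
    node$backward <- backward
    tape <- .ag$tape
    n <- tape$n + 1L
    if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[n]] <- node
    tape$n <- n
  }
  node
}

.ag_wrap <- function(x) if (ag_is_node(x)) x else ag_leaf(x)
.ag_val <- function(x) if (ag_is_node(x)) x$value else x

.ag_accum <- function(node, g) {
  if (!isTRUE(node$requires)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar loss node
#'
#' Seeds the loss gradient with 1 and sweeps the current tape in reverse
#' creation order, accumulating gradients into every node that requires them
#' (in particular all parameters reached by the forward pass).
#'
#' @param loss an `ag_node` holding a length-1 numeric value.
#' @return invisibly, `NULL`.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(ag_is_node(loss), length(loss$value) == 1L)
  tape <- .ag$tape
  if (is.null(tape)) stop("no open tape: call ag_tape_start() before the forward pass")
  loss$grad <- 1
  for (i in seq(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    gs <- node$backward(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) if (!is.null(gs[[j]])) .ag_accum(ps[[j]], gs[[j]])
    # free intermediate grads/values promptly; parameters live off-tape
    node$grad <- NULL
    node$backward <- NULL
    node$parents <- NULL
  }
  invisible(NULL)
}

.dims <- function(x) {
  d <- dim(x)
  if (is.null(d)) length(x) else d
}

# ---- per-channel reduction helpers on (N, C, H, W) arrays -------------------

# sums over (N, H, W) for each channel -> length-C vector
.ch_sum <- function(x) {
  d <- dim(x)
  s_nc <- rowSums(matrix(x, d[1] * d[2], d[3] * d[4]))
  colSums(matrix(s_nc, d[1], d[2]))
}

# broadcast a length-C vector over (N, C, H, W)
.ch_bcast <- function(v, d) rep(rep(v, each = d[1]), times = d[3] * d[4])

# broadcast an (N, C) matrix over spatial dims
.nc_bcast <- function(m, d) rep(as.vector(m), times = d[3] * d[4])

# per-(n, c) sums over spatial dims -> (N, C) matrix
.nc_sum <- function(x) {
  d <- dim(x)
  matrix(rowSums(matrix(x, d[1] * d[2], d[3] * d[4])), d[1], d[2])
}

# sum over channels -> (N, 1, H, W)
.csum_over_channels <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1], d[2], d[3] * d[4])
  out <- colSums(aperm(m, c(2, 1, 3)))  # (N, HW)
  dim(out) <- c(d[1], 1L, d[3], d[4])
  out
}

# expand an (N, 1, H, W) array over C channels
.sp_bcast <- function(s, C) {
  d <- dim(s)
  out <- s[, rep(1L, C), , , drop = FALSE]
  dim(out) <- c(d[1], C, d[3], d[4])
  out
}

# ---- elementwise ops --------------------------------------------------------

ag_add <- function(x, y) {
  x <- .ag_wrap(x); y <- .ag_wrap(y)
  stopifnot(length(x$value) == length(y$value))
  ag_node(x$value + y$value, list(x, y), function(g) list(g, g))
}

ag_mul <- function(x, y) {
  x <- .ag_wrap(x); y <- .ag_wrap(y)
  xv <- x$value; yv <- y$value
  ag_node(xv * yv, list(x, y), function(g) list(g * yv, g * xv))
}

ag_affine <- function(x, a = 1, b = 0) {
  x <- .ag_wrap(x)
  ag_node(a * x$value + b, list(x), function(g) list(a * g))
}

ag_relu <- function(x) {
  x <- .ag_wrap(x)
  pos <- x$value > 0
  y <- x$value * pos
  ag_node(y, list(x), function(g) list(g * pos))
}

# leaky rectifier: used in the narrow channel-attention bottlenecks, where
# a hard ReLU can leave every hidden unit inactive for a whole batch and
# cut the gradient path to the bottleneck weights entirely
ag_leaky_relu <- function(x, slope = 0.01) {
  x <- .ag_wrap(x)
  pos <- x$value > 0
  scale <- ifelse(pos, 1, slope)
  ag_node(x$value * scale, list(x), function(g) list(g * scale))
}

ag_sigmoid <- function(x) {
  x <- .ag_wrap(x)
  y <- 1 / (1 + exp(-x$value))
  ag_node(y, list(x), function(g) list(g * y * (1 - y)))
}

# ---- structural ops ---------------------------------------------------------

# channel concatenation of (N, C_i, H, W) arrays
ag_concat <- function(xs) {
  xs <- lapply(xs, .ag_wrap)
  ds <- lapply(xs, function(x) dim(x$value))
  N <- ds[[1]][1]; H <- ds[[1]][3]; W <- ds[[1]][4]
  cs <- vapply(ds, `[`, integer(1), 2L)
  Ct <- sum(cs)
  pieces <- lapply(xs, function(x) {
    v <- x$value
    dim(v) <- c(N, dim(x$value)[2], H * W)
    v
  })
  out <- array(0, c(N, Ct, H * W))
  off <- 0L
  for (i in seq_along(pieces)) {
    out[, off + seq_len(cs[i]), ] <- pieces[[i]]
    off <- off + cs[i]
  }
  dim(out) <- c(N, Ct, H, W)
  ag_node(out, xs, function(g) {
    dim(g) <- c(N, Ct, H * W)
    off <- 0L
    gs <- vector("list", length(xs))
    for (i in seq_along(xs)) {
      gi <- g[, off + seq_len(cs[i]), , drop = FALSE]
      dim(gi) <- c(N, cs[i], H, W)
      gs[[i]] <- gi
      off <- off + cs[i]
    }
    gs
  })
}

# column concatenation of (N, K_i) matrices (channel-attention weights)
ag_cat_cols <- function(xs) {
  xs <- lapply(xs, .ag_wrap)
  ks <- vapply(xs, function(x) ncol(x$value), integer(1))
  out <- do.call(cbind, lapply(xs, function(x) x$value))
  ag_node(out, xs, function(g) {
    off <- 0L
    gs <- vector("list", length(xs))
    for (i in seq_along(xs)) {
      gs[[i]] <- g[, off + seq_len(ks[i]), drop = FALSE]
      off <- off + ks[i]
    }
    gs
  })
}

# ---- convolution / pooling / interpolation ---------------------------------

ag_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  x <- .ag_wrap(x); w <- .ag_wrap(w); b <- .ag_wrap(b)
  xv <- x$value; wv <- w$value
  y <- cpp_conv2d_forward(xv, wv, b$value, as.integer(stride), as.integer(pad))
  ag_node(y, list(x, w, b), function(g) {
    gr <- cpp_conv2d_backward(xv, wv, g, as.integer(stride), as.integer(pad))
    list(gr$gx, gr$gw, gr$gb)
  })
}

ag_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  x <- .ag_wrap(x)
  fw <- cpp_maxpool_forward(x$value, as.integer(k), as.integer(stride), as.integer(pad))
  xd <- dim(x$value)
  ag_node(fw$y, list(x), function(g) {
    list(cpp_maxpool_backward(g, fw$argmax, as.integer(xd)))
  })
}

ag_bilinear <- function(x, out_h, out_w) {
  x <- .ag_wrap(x)
  d <- dim(x$value)
  y <- cpp_bilinear_forward(x$value, as.integer(out_h), as.integer(out_w))
  ag_node(y, list(x), function(g) {
    list(cpp_bilinear_backward(g, as.integer(d[3]), as.integer(d[4])))
  })
}

# ---- pooling reductions -----------------------------------------------------

# global average pool: (N, C, H, W) -> (N, C)
ag_gap <- function(x) {
  x <- .ag_wrap(x)
  d <- dim(x$value)
  hw <- d[3] * d[4]
  y <- .nc_sum(x$value) / hw
  ag_node(y, list(x), function(g) {
    gx <- rep(as.vector(g), times = hw) / hw
    dim(gx) <- d
    list(gx)
  })
}

# mean over channels: (N, C, H, W) -> (N, 1, H, W)
ag_channel_mean <- function(x) {
  x <- .ag_wrap(x)
  d <- dim(x$value)
  y <- .csum_over_channels(x$value) / d[2]
  ag_node(y, list(x), function(g) {
    gx <- .sp_bcast(g, d[2]) / d[2]
    list(gx)
  })
}

# max over channels: (N, C, H, W) -> (N, 1, H, W)
ag_channel_max <- function(x) {
  x <- .ag_wrap(x)
  d <- dim(x$value)
  m <- x$value
  dim(m) <- c(d[1], d[2], d[3] * d[4])
  best <- m[, 1L, , drop = FALSE]
  arg <- array(1L, dim(best))
  if (d[2] > 1L) for (cc in 2:d[2]) {
    cur <- m[, cc, , drop = FALSE]
    upd <- cur > best
    best[upd] <- cur[upd]
    arg[upd] <- cc
  }
  y <- best
  dim(y) <- c(d[1], 1L, d[3], d[4])
  ag_node(y, list(x), function(g) {
    gx <- array(0, c(d[1], d[2], d[3] * d[4]))
    gv <- g
    dim(gv) <- c(d[1], 1L, d[3] * d[4])
    idx <- cbind(
      rep(seq_len(d[1]), times = d[3] * d[4]),
      as.vector(arg),
      rep(seq_len(d[3] * d[4]), each = d[1])
    )
    gx[idx] <- as.vector(gv)
    dim(gx) <- d
    list(gx)
  })
}

# ---- broadcasting attention ops --------------------------------------------

# scale each channel of x by an (N, C) weight matrix
ag_scale_channel <- function(x, s) {
  x <- .ag_wrap(x); s <- .ag_wrap(s)
  d <- dim(x$value)
  sb <- .nc_bcast(s$value, d)
  xv <- x$value
  ag_node(xv * sb, list(x, s), function(g) {
    list(g * sb, .nc_sum(g * xv))
  })
}

# mask gate with broadcast residual: y = (x + 1) * m, m is (N, 1, H, W)
# broadcast over channels (i.e. x (.) m + m elementwise).
ag_spatial_gate <- function(x, m) {
  x <- .ag_wrap(x); m <- .ag_wrap(m)
  d <- dim(x$value)
  mb <- .sp_bcast(m$value, d[2])
  xp1 <- x$value + 1
  ag_node(xp1 * mb, list(x, m), function(g) {
    list(g * mb, .csum_over_channels(g * xp1))
  })
}

# y = x * (bcast(ch) + bcast(sp)); ch is (N, C), sp is (N, 1, H, W).
# The combined factor is a sum of two sigmoid outputs, hence in (0, 2).
ag_attention_mix <- function(x, ch, sp) {
  x <- .ag_wrap(x); ch <- .ag_wrap(ch); sp <- .ag_wrap(sp)
  d <- dim(x$value)
  att <- .nc_bcast(ch$value, d) + .sp_bcast(sp$value, d[2])
  xv <- x$value
  y <- xv * att
  dim(y) <- d
  ag_node(y, list(x, ch, sp), function(g) {
    gx <- g * att
    dim(gx) <- d
    gxv <- g * xv
    list(gx, .nc_sum(gxv), .csum_over_channels(gxv))
  })
}

# ---- dense layer on (N, K) matrices ----------------------------------------

ag_linear <- function(x, w, b) {
  x <- .ag_wrap(x); w <- .ag_wrap(w); b <- .ag_wrap(b)
  xv <- x$value; wv <- w$value
  y <- sweep(xv %*% t(wv), 2L, b$value, `+`)
  ag_node(y, list(x, w, b), function(g) {
    list(g %*% wv, t(g) %*% xv, colSums(g))
  })
}

# ---- batch normalisation ----------------------------------------------------

# state: environment with $running_mean, $running_var (length C).
# Training mode (per .ag$training) uses batch statistics over (N, H, W) and
# updates the running estimates; inference mode uses the running estimates.
ag_batch_norm <- function(x, gamma, beta, state, momentum = 0.1, eps = 1e-5) {
  x <- .ag_wrap(x); gamma <- .ag_wrap(gamma); beta <- .ag_wrap(beta)
  d <- dim(x$value)
  m <- d[1] * d[3] * d[4]
  xv <- x$value
  if (.ag$training) {
    mu <- .ch_sum(xv) / m
    xc <- xv - .ch_bcast(mu, d)
    var_b <- .ch_sum(xc * xc) / m
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    var_u <- if (m > 1) var_b * m / (m - 1) else var_b
    state$running_var <- (1 - momentum) * state$running_var + momentum * var_u
  } else {
    mu <- state$running_mean
    var_b <- state$running_var
    xc <- xv - .ch_bcast(mu, d)
  }
  inv_sd <- 1 / sqrt(var_b + eps)
  xhat <- xc * .ch_bcast(inv_sd, d)
  y <- xhat * .ch_bcast(gamma$value, d) + .ch_bcast(beta$value, d)
  dim(y) <- d
  training <- .ag$training
  gv <- gamma$value
  ag_node(y, list(x, gamma, beta), function(g) {
    ggamma <- .ch_sum(g * xhat)
    gbeta <- .ch_sum(g)
    if (training) {
      gx <- (g - .ch_bcast(gbeta / m, d) - xhat * .ch_bcast(ggamma / m, d)) *
        .ch_bcast(gv * inv_sd, d)
    } else {
      gx <- g * .ch_bcast(gv * inv_sd, d)
    }
    dim(gx) <- d
    list(gx, ggamma, gbeta)
  })
}

# ---- loss primitives --------------------------------------------------------

# mean binary cross-entropy over all elements, with probability clamping
ag_bce <- function(p, q, clip = 1e-7) {
  p <- .ag_wrap(p)
  qv <- .ag_val(q)
  pv <- p$value
  pc <- pmin(pmax(pv, clip), 1 - clip)
  n <- length(pv)
  val <- -sum(qv * log(pc) + (1 - qv) * log(1 - pc)) / n
  inside <- (pv > clip) & (pv < 1 - clip)
  ag_node(val, list(p), function(g) {
    gp <- g * (pc - qv) / (pc * (1 - pc)) / n
    gp[!inside] <- 0
    dim(gp) <- .dims(pv)
    list(gp)
  })
}

# soft Dice coefficient (2*sum(pq)+eps) / (sum(p^2)+sum(q^2)+eps)
ag_dice_coef <- function(p, q, eps = 1e-6) {
  p <- .ag_wrap(p)
  qv <- .ag_val(q)
  pv <- p$value
  num <- 2 * sum(pv * qv) + eps
  den <- sum(pv * pv) + sum(qv * qv) + eps
  ag_node(num / den, list(p), function(g) {
    gp <- g * (2 * qv * den - num * 2 * pv) / (den * den)
    dim(gp) <- .dims(pv)
    list(gp)
  })
}
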