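# The double-loss system.
#
# Global loss (driving the full-resolution prediction p against the binary
# label q):   L_global = BCE_Dice(p, q) + DiceLoss(p, q)
# with        BCE_Dice = alpha * BCE + (1 - alpha) * DiceLoss, alpha = 0.5.
# Local loss (driving the deep-supervision mask, upsampled to label
# resolution): L_local = DiceLoss(mask, q).
# Total objective: L_global + lambda_local * L_local.
#
# "Dice" inside every loss means one minus the soft Dice coefficient, the
# only reading under which minimisation improves overlap. The coefficient
# itself is exposed separately.
#
# All user-facing functions take plain numeric arrays; the node variants
# (internal, suffix _node) share the same arithmetic through the autodiff
# engine so training optimises exactly the published quantities.

#' Loss configuration
#'
#' @param alpha BCE-Dice mixing weight in `[0, 1]` (default 0.5).
#' @param lambda_local weight of the local loss in the total objective.
#' @param epsilon Dice smoothing constant added to numerator and
#'   denominator; guards empty-mask batches.
#' @param clip BCE probability clamp bound in `(0, 0.5)`.
#' @return a `loss_config` list.
#' @export
loss_config <- function(alpha = 0.5, lambda_local = 1.0,
                        epsilon = 1e-6, clip = 1e-7) {
  stopifnot(alpha >= 0, alpha <= 1, epsilon > 0, clip > 0, clip < 0.5,
            lambda_local >= 0)
  structure(list(alpha = alpha, lambda_local = lambda_local,
                 epsilon = epsilon, clip = clip),
            class = "loss_config")
}

.check_pq <- function(p, q) {
  if (length(p) != length(q)) {
    stop("loss: prediction and label shapes differ (",
         length(p), " vs ", length(q), " elements)")
  }
}

#' Binary cross-entropy loss
#'
#' Mean over all pixels of `-(q log p + (1-q) log(1-p))`, with `p` clamped
#' to `[clip, 1-clip]` before the logarithms.
#'
#' @param p numeric array of predicted probabilities in `[0, 1]`.
#' @param q numeric array of binary labels, same shape.
#' @param clip clamp bound.
#' @return a scalar.
#' @export
bce_loss <- function(p, q, clip = 1e-7) {
  .check_pq(p, q)
  ag_bce(ag_leaf(p), q, clip = clip)$value
}

#' Soft Dice coefficient
#'
#' `(2 * sum(p*q) + eps) / (sum(p^2) + sum(q^2) + eps)`, computed on soft
#' probabilities without thresholding.
#'
#' @inheritParams bce_loss
#' @param eps smoothing constant.
#' @return a scalar in `[0, 1]` (up to smoothing).
#' @export
dice_coefficient <- function(p, q, eps = 1e-6) {
  .check_pq(p, q)
  ag_dice_coef(ag_leaf(p), q, eps = eps)$value
}

#' Dice loss: one minus the soft Dice coefficient
#' @inheritParams dice_coefficient
#' @return a scalar.
#' @export
dice_loss <- function(p, q, eps = 1e-6) 1 - dice_coefficient(p, q, eps = eps)

#' Combined BCE-Dice loss
#'
#' `alpha * BCE + (1 - alpha) * DiceLoss`.
#'
#' @inheritParams bce_loss
#' @param alpha mixing weight in `[0, 1]`.
#' @param eps Dice smoothing constant.
#' @return a scalar.
#' @export
bce_dice_loss <- function(p, q, alpha = 0.5, eps = 1e-6, clip = 1e-7) {
  stopifnot(alpha >= 0, alpha <= 1)
  alpha * bce_loss(p, q, clip = clip) + (1 - alpha) * dice_loss(p, q, eps = eps)
}

#' Global loss: BCE-Dice plus an additional Dice loss term
#'
#' With the default `alpha = 0.5` this equals `0.5 * BCE + 1.5 * DiceLoss`.
#'
#' @inheritParams bce_dice_loss
#' @return a scalar.
#' @export
global_loss <- function(p, q, alpha = 0.5, eps = 1e-6, clip = 1e-7) {
  bce_dice_loss(p, q, alpha = alpha, eps = eps, clip = clip) +
    dice_loss(p, q, eps = eps)
}

#' Local (deep-supervision) loss
#'
#' Dice loss between the supervision-mask probability, bilinearly upsampled
#' to the label's resolution, and the full-resolution binary label.
#'
#' @param aux_prob numeric array (N, 1, h, w) of mask probabilities.
#' @param q numeric array (N, 1, H, W) of binary labels.
#' @param eps Dice smoothing constant.
#' @return a scalar.
#' @export
local_loss <- function(aux_prob, q, eps = 1e-6) {
  if (is.null(aux_prob)) {
    stop("local_loss: no supervision mask present (aux head ablated); ",
         "the trainer must skip the local term instead")
  }
  dq <- .dims(q)
  up <- cpp_bilinear_forward(aux_prob, as.integer(dq[3]), as.integer(dq[4]))
  dice_loss(up, q, eps = eps)
}

# ---- node variants used by the trainer --------------------------------------

dice_loss_node <- function(p_node, q, eps) {
  ag_affine(ag_dice_coef(p_node, q, eps = eps), a = -1, b = 1)
}

global_loss_node <- function(p_node, q, cfg) {
  bce <- ag_bce(p_node, q, clip = cfg$clip)
  dl <- dice_loss_node(p_node, q, cfg$epsilon)
  # alpha*BCE + (1-alpha)*Dice + Dice  ==  alpha*BCE + (2-alpha)*Dice
  ag_add(ag_affine(bce, a = cfg$alpha), ag_affine(dl, a = 2 - cfg$alpha))
}

local_loss_node <- function(aux_prob_node, q, cfg) {
  dq <- .dims(q)
  dice_loss_node(ag_bilinear(aux_prob_node, dq[3], dq[4]), q, cfg$epsilon)
}

#' Total training objective with component breakdown
#'
#' `global + lambda_local * local` when a supervision mask is present,
#' otherwise the global loss alone.
#'
#' @param out a `seg_forward` result (see [forward_pass()]), or any list
#'   with `prediction` and optional `aux` entries (nodes or arrays).
#' @param q numeric array (N, 1, H, W) of binary labels.
#' @param cfg a [loss_config()].
#' @return list with `total` (scalar) and `components` (named numeric:
#'   global, local, bce, dice).
#' @export
total_loss <- function(out, q, cfg = loss_config()) {
  p <- .ag_val(out$prediction)
  comp <- c(
    global = global_loss(p, q, alpha = cfg$alpha, eps = cfg$epsilon, clip = cfg$clip),
    local = 0,
    bce = bce_loss(p, q, clip = cfg$clip),
    dice = dice_loss(p, q, eps = cfg$epsilon)
  )
  total <- comp[["global"]]
  if (!is.null(out$aux) && cfg$lambda_local > 0) {
    comp[["local"]] <- local_loss(.ag_val(out$aux$prob), q, eps = cfg$epsilon)
    total <- total + cfg$lambda_local * comp[["local"]]
  }
  list(total = total, components = comp)
}

# Differentiable total objective for an optimisation step. Returns the node
# and the numeric component breakdown.
total_loss_node <- function(out, q, cfg) {
  gl <- global_loss_node(out$prediction, q, cfg)
  comp <- c(global = gl$value, local = 0)
  node <- gl
  if (!is.null(out$aux) && cfg$lambda_local > 0) {
    ll <- local_loss_node(out$aux$prob, q, cfg)
    comp[["local"]] <- ll$value
    node <- ag_add(gl, ag_affine(ll, a = cfg$lambda_local))
  }
  list(node = node, components = comp)
}
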