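# Seeded synthetic lesion-image generator.
#
# Emulates the statistical challenges of endoscopic polyp images — low
# foreground/background contrast, blurred lesion boundaries, wide lesion
# size variation, additive noise — on a smooth random-texture background.
# Lesions are randomly rotated ellipses with a low-order trigonometric
# perturbation of the boundary radius, which gives organic-looking blobs
# from a handful of seeded draws. The mask is the exact unblurred union of
# the lesion silhouettes; the boundary blur is applied to the image only.
#
# Every sample is a pure function of (spec, seed, index): the per-sample
# RNG stream is derived from a counter-based mix of the two, and the
# session RNG state is saved and restored around each call.

#' Synthetic dataset specification
#'
#' @param image_size square image side in pixels; at least 32 and a
#'   multiple of 32 (so five stride-2 halvings are exact).
#' @param n_lesions_range inclusive integer interval for the lesion count.
#' @param contrast_delta mean foreground-background intensity offset, in
#'   `(0, 0.5]` on the `[0, 1]` intensity scale.
#' @param boundary_blur_sigma Gaussian blur radius (pixels) applied to the
#'   lesion silhouette before compositing; the mask stays sharp.
#' @param noise_sigma per-pixel Gaussian noise standard deviation.
#' @param lesion_area_fraction_range per-lesion area as a fraction of the
#'   image, in `(0, 0.6)`.
#' @param seed integer RNG seed for the dataset.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(image_size = 256L,
                           n_lesions_range = c(1L, 3L),
                           contrast_delta = 0.15,
                           boundary_blur_sigma = 2,
                           noise_sigma = 0.03,
                           lesion_area_fraction_range = c(0.02, 0.3),
                           seed = 0L) {
  image_size <- as.integer(image_size)
  n_lesions_range <- as.integer(n_lesions_range)
  if (image_size < 32L || image_size %% 32L != 0L) {
    stop("synthetic_spec: image_size must be >= 32 and a multiple of 32")
  }
  if (length(n_lesions_range) != 2L || any(n_lesions_range < 0L) ||
      n_lesions_range[1] > n_lesions_range[2]) {
    stop("synthetic_spec: n_lesions_range must be a nondecreasing pair of ",
         "nonnegative integers")
  }
  if (contrast_delta <= 0 || contrast_delta > 0.5) {
    stop("synthetic_spec: contrast_delta must lie in (0, 0.5]")
  }
  fr <- lesion_area_fraction_range
  if (length(fr) != 2L || fr[1] <= 0 || fr[2] >= 0.6 || fr[1] > fr[2]) {
    stop("synthetic_spec: lesion_area_fraction_range must lie in (0, 0.6)")
  }
  if (boundary_blur_sigma < 0 || noise_sigma < 0) {
    stop("synthetic_spec: blur and noise sigmas must be nonnegative")
  }
  # feasibility: the largest (perturbed) lesion must fit inside the image
  r_max <- sqrt(fr[2] * image_size^2 / pi) * 1.2
  if (r_max >= image_size / 2 - 2) {
    stop("invalid spec: lesion area range cannot fit in a ", image_size,
         "px image (max perturbed radius ", round(r_max, 1), "px)")
  }
  structure(list(
    image_size = image_size, n_lesions_range = n_lesions_range,
    contrast_delta = contrast_delta,
    boundary_blur_sigma = boundary_blur_sigma, noise_sigma = noise_sigma,
    lesion_area_fraction_range = fr, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Run expr under a derived, isolated RNG stream; restores the session RNG.
.with_sample_rng <- function(seed, index, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  mixed <- (as.numeric(seed) * 1000003 + as.numeric(index) * 7919 + 12345) %% 2147483647
  set.seed(as.integer(mixed))
  expr
}

# Rasterise one perturbed-ellipse silhouette into an S x S {0,1} matrix.
.draw_lesion <- function(S, frac_range) {
  frac <- runif(1, frac_range[1], frac_range[2])
  r0 <- sqrt(frac * S^2 / pi)
  # aspect ratio, clamped so the perturbed major axis always fits
  rho2 <- ((S / 2 - 2) / (1.2 * r0))^2
  ratio <- runif(1, 0.6, 1.8)
  ratio <- min(max(ratio, 1 / rho2), rho2)
  a <- r0 * sqrt(ratio)
  b <- r0 / sqrt(ratio)
  phi <- runif(1, 0, pi)
  margin <- max(a, b) * 1.25
  cx <- runif(1, margin, S - margin)
  cy <- runif(1, margin, S - margin)
  nh <- sample(2:5, 1)
  amp_raw <- runif(nh)
  amp <- amp_raw / sum(amp_raw) * runif(1, 0.05, 0.2)
  phase <- runif(nh, 0, 2 * pi)

  h0 <- max(1L, floor(cy - margin)); h1 <- min(S, ceiling(cy + margin))
  w0 <- max(1L, floor(cx - margin)); w1 <- min(S, ceiling(cx + margin))
  hs <- h0:h1; ws <- w0:w1
  dy <- matrix(hs - cy, length(hs), length(ws))
  dx <- matrix(ws - cx, length(hs), length(ws), byrow = TRUE)
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  theta <- atan2(v, u)
  r_pix <- sqrt(u^2 + v^2)
  r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  pert <- 1
  for (h in seq_len(nh)) pert <- pert + amp[h] * cos(h * theta + phase[h])
  inside <- r_pix <= r_ell * pert

  sil <- matrix(0, S, S)
  sil[hs, ws] <- inside * 1
  sil
}

#' Generate one synthetic image/mask pair
#'
#' The background is a smoothed random texture; each lesion silhouette is
#' blurred before compositing (blurred boundaries) while the mask stays
#' binary and sharp. After compositing, the inside/outside mean-intensity
#' difference is balanced to equal `contrast_delta` exactly before noise
#' is added, so the nominal contrast is a calibrated property of every
#' sample rather than a random one.
#'
#' @param spec a [synthetic_spec()].
#' @param index sample index (part of the RNG stream; the same
#'   `(spec, index)` always yields the identical pair).
#' @return a `sample_pair` list: `image` (3, H, W) in `[0, 1]`, `mask`
#'   (H, W) in `{0, 1}`, `id` character.
#' @export
generate_sample <- function(spec, index) {
  stopifnot(inherits(spec, "synthetic_spec"))
  S <- spec$image_size
  .with_sample_rng(spec$seed, index, {
    # smooth background texture: coarse Gaussian field upsampled bilinearly
    k <- max(4L, S %/% 32L)
    field <- array(rnorm(k * k), c(1L, 1L, k, k))
    tex <- cpp_bilinear_forward(field, S, S)[1, 1, , ]
    tex <- tex * (0.05 / max(stats::sd(tex), 1e-8))
    tex <- pmin(pmax(tex, -0.12), 0.12)
    base <- 0.45 + tex

    n_les <- if (spec$n_lesions_range[1] == spec$n_lesions_range[2]) {
      spec$n_lesions_range[1]
    } else {
      sample(spec$n_lesions_range[1]:spec$n_lesions_range[2], 1)
    }
    mask <- matrix(0, S, S)
    if (n_les > 0) {
      for (i in seq_len(n_les)) {
        mask <- pmax(mask, .draw_lesion(S, spec$lesion_area_fraction_range))
      }
    }
    sil <- cpp_gaussian_blur(mask, spec$boundary_blur_sigma)
    gray <- base + spec$contrast_delta * sil
    inside <- mask == 1
    if (any(inside) && any(!inside)) {
      c0 <- mean(gray[inside]) - mean(gray[!inside])
      gray[inside] <- gray[inside] + (spec$contrast_delta - c0)
    }
    tints <- c(0.03, 0, -0.03)
    img <- array(0, c(3L, S, S))
    for (ch in 1:3) {
      plane <- gray + tints[ch]
      if (spec$noise_sigma > 0) plane <- plane + rnorm(S * S, 0, spec$noise_sigma)
      img[ch, , ] <- pmin(pmax(plane, 0), 1)
    }
    structure(list(image = img, mask = mask,
                   id = sprintf("sample_%05d", as.integer(index))),
              class = "sample_pair")
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` RGB image PNGs and `n` grayscale mask PNGs (values 0/255)
#' into `images/` and `masks/` subdirectories of `out_dir`, matched by
#' filename stem, plus a two-column `manifest.tsv` (image path, mask path,
#' relative to `out_dir`).
#'
#' @param spec a [synthetic_spec()].
#' @param n number of samples.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a data.frame manifest with columns `id`, `image`,
#'   `mask` (absolute paths).
#' @export
generate_dataset <- function(spec, n, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"), n >= 0)
  img_dir <- file.path(out_dir, "images")
  msk_dir <- file.path(out_dir, "masks")
  for (d in c(img_dir, msk_dir)) {
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE)) {
      stop("generate_dataset: cannot create directory '", d, "'")
    }
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- generate_sample(spec, i)
    ip <- file.path(img_dir, paste0(sp$id, ".png"))
    mp <- file.path(msk_dir, paste0(sp$id, ".png"))
    tryCatch({
      png::writePNG(aperm(sp$image, c(2, 3, 1)), ip)
      png::writePNG(sp$mask, mp)
    }, error = function(e) {
      stop("generate_dataset: failed writing '", ip, "': ", conditionMessage(e))
    })
    rows[[i]] <- data.frame(id = sp$id, image = ip, mask = mp)
  }
  manifest <- if (n > 0) do.call(rbind, rows) else {
    data.frame(id = character(0), image = character(0), mask = character(0))
  }
  utils::write.table(
    data.frame(image = file.path("images", paste0(manifest$id, ".png")),
               mask = file.path("masks", paste0(manifest$id, ".png"))),
    file.path(out_dir, "manifest.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
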