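# Reading and writing image/mask pairs, resizing to network inputs, and
# writing predicted masks. PNG throughout (JPEG input supported when
# EBImage is installed); masks are 8-bit {0, 255} PNGs thresholded back to
# {0, 1} on read. Coordinates are (row, column) with origin top-left;
# images and masks are co-registered.

.IMG_EXT <- "\\.(png|jpg|jpeg)$"

#' List matched image/mask pairs
#'
#' Pairs files in the two directories by filename stem, sorted
#' lexicographically. Files present on only one side are reported with a
#' warning and excluded.
#'
#' @param images_dir,masks_dir existing directories.
#' @return a data.frame manifest with columns `id`, `image`, `mask`.
#' @export
list_pairs <- function(images_dir, masks_dir) {
  for (d in c(images_dir, masks_dir)) {
    if (!dir.exists(d)) stop("list_pairs: directory '", d, "' does not exist")
  }
  imgs <- sort(list.files(images_dir, pattern = .IMG_EXT, ignore.case = TRUE))
  msks <- sort(list.files(masks_dir, pattern = .IMG_EXT, ignore.case = TRUE))
  istem <- tools::file_path_sans_ext(imgs)
  mstem <- tools::file_path_sans_ext(msks)
  common <- intersect(istem, mstem)
  orphans <- c(setdiff(istem, mstem), setdiff(mstem, istem))
  if (length(orphans) > 0) {
    warning("list_pairs: ", length(orphans), " unmatched file(s) excluded: ",
            paste(utils::head(orphans, 10), collapse = ", "))
  }
  if (length(common) == 0) {
    stop("list_pairs: empty dataset — no image/mask stems in common between '",
         images_dir, "' and '", masks_dir, "'")
  }
  common <- sort(common)
  data.frame(
    id = common,
    image = file.path(images_dir, imgs[match(common, istem)]),
    mask = file.path(masks_dir, msks[match(common, mstem)])
  )
}

# Decode an image file to an (H, W, C) array in [0, 1].
.decode_image <- function(path) {
  if (!file.exists(path)) stop("corrupt-input: file '", path, "' does not exist")
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch({
    if (ext == "png") {
      png::readPNG(path)
    } else if (ext %in% c("jpg", "jpeg")) {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("JPEG input requires the EBImage package")
      }
      # EBImage uses (x, y, c); transpose to (row, col, c)
      a <- EBImage::imageData(EBImage::readImage(path))
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
    } else {
      stop("unsupported image format '.", ext, "'")
    }
  }, error = function(e) {
    stop("corrupt-input: cannot decode '", path, "': ", conditionMessage(e))
  })
  if (is.null(dim(arr))) dim(arr) <- c(length(arr), 1L)
  arr
}

#' Resize an array bilinearly
#'
#' Half-pixel-centre (corner-aligned-off) convention, matching the
#' interpolation used inside the network.
#'
#' @param x matrix (H, W) or array (C, H, W) or (N, C, H, W).
#' @param out_h,out_w target size.
#' @return array of the same rank with new spatial dimensions.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  d <- .dims(x)
  r <- length(d)
  x4 <- x
  if (r == 2L) dim(x4) <- c(1L, 1L, d) else
  if (r == 3L) {
    x4 <- aperm(array(x, c(d, 1L)), c(4, 1, 2, 3))
  } else if (r != 4L) stop("resize_bilinear: rank must be 2, 3 or 4")
  y <- cpp_bilinear_forward(x4, as.integer(out_h), as.integer(out_w))
  if (r == 2L) y <- y[1, 1, , ] else
  if (r == 3L) y <- array(y[1, , , ], dim(y)[2:4])
  y
}

#' Resize an array with nearest-neighbour sampling
#' @inheritParams resize_bilinear
#' @export
resize_nearest <- function(x, out_h, out_w) {
  d <- .dims(x)
  r <- length(d)
  x4 <- x
  if (r == 2L) dim(x4) <- c(1L, 1L, d) else
  if (r == 3L) {
    x4 <- aperm(array(x, c(d, 1L)), c(4, 1, 2, 3))
  } else if (r != 4L) stop("resize_nearest: rank must be 2, 3 or 4")
  y <- cpp_nearest_resize(x4, as.integer(out_h), as.integer(out_w))
  if (r == 2L) y <- y[1, 1, , ] else
  if (r == 3L) y <- array(y[1, , , ], dim(y)[2:4])
  y
}

#' Load one image/mask pair as network input
#'
#' The image is decoded to RGB, bilinearly resized to
#' `target_size x target_size` and kept on the `[0, 1]` scale (optionally
#' standardised per channel); the mask is resized with nearest-neighbour
#' sampling and thresholded at 127/255 back to `{0, 1}`.
#'
#' @param entry one manifest row (or any list with `image`, `mask`, `id`).
#' @param target_size square side in pixels, a multiple of 32.
#' @param normalize `"unit"` (default, plain `[0, 1]`) or `"standardize"`
#'   (subtract `norm_mean`, divide by `norm_sd` per channel, for
#'   pretrained-weight compatibility).
#' @param norm_mean,norm_sd per-channel constants for `"standardize"`.
#' @return a `sample_pair`: `image` (3, H, W), `mask` (H, W), `id`.
#' @export
load_pair <- function(entry, target_size,
                      normalize = c("unit", "standardize"),
                      norm_mean = c(0.485, 0.456, 0.406),
                      norm_sd = c(0.229, 0.224, 0.225)) {
  normalize <- match.arg(normalize)
  if (target_size %% 32L != 0L) {
    stop("load_pair: target_size must be a multiple of 32")
  }
  arr <- .decode_image(as.character(entry$image))
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  img <- aperm(arr, c(3, 1, 2))
  if (any(dim(img)[2:3] != target_size)) {
    img <- resize_bilinear(img, target_size, target_size)
  }
  if (normalize == "standardize") {
    for (ch in 1:3) img[ch, , ] <- (img[ch, , ] - norm_mean[ch]) / norm_sd[ch]
  }
  m <- .decode_image(as.character(entry$mask))
  if (length(dim(m)) == 3L) m <- m[, , 1]
  if (any(dim(m) != target_size)) m <- resize_nearest(m, target_size, target_size)
  m <- (m > 127 / 255) * 1
  structure(list(image = img, mask = m,
                 id = as.character(entry$id %||% tools::file_path_sans_ext(basename(entry$image)))),
            class = "sample_pair")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a predicted mask as an 8-bit PNG
#'
#' Pixels with probability `>= threshold` are written as 255, the rest
#' as 0.
#'
#' @param p numeric matrix (H, W) or array (N, 1, H, W) with one sample,
#'   values in `[0, 1]`.
#' @param threshold binarisation threshold (inclusive `>=`).
#' @param path output PNG path.
#' @export
save_mask <- function(p, threshold = 0.5, path) {
  d <- .dims(p)
  if (length(d) == 4L) {
    stopifnot(d[1] == 1L, d[2] == 1L)
    p <- array(p, d)[1, 1, , ]
  }
  stopifnot(min(p) >= 0, max(p) <= 1)
  bin <- (p >= threshold) * 1
  tryCatch(png::writePNG(bin, path),
           error = function(e) stop("save_mask: failed writing '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

# Stack a list of sample_pairs into network-ready batch arrays.
stack_pairs <- function(pairs) {
  n <- length(pairs)
  S <- dim(pairs[[1]]$image)[2]
  x <- array(0, c(n, 3L, S, S))
  q <- array(0, c(n, 1L, S, S))
  for (i in seq_len(n)) {
    x[i, , , ] <- pairs[[i]]$image
    q[i, 1, , ] <- pairs[[i]]$mask
  }
  list(x = x, q = q, ids = vapply(pairs, `[[`, character(1), "id"))
}
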