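# Image preparation: tissue masking, grid tiling, Reinhard colour-transfer
# stain standardization with tissue-masked statistics, and dihedral
# class-balancing augmentation.

# Saturation channel (HSV S) of an 8-bit RGB array, in [0, 1].
saturation_channel <- function(img) {
  assert_rgb(img)
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  s <- matrix(0, nrow(mx), ncol(mx))
  nz <- mx > 0
  s[nz] <- (mx[nz] - mn[nz]) / mx[nz]
  s
}

# Gaussian blur with the kernel clipped to fit small inputs.
blur_channel <- function(ch, sigma) {
  max_sigma <- (min(dim(ch)) - 1) / 8
  sigma <- min(sigma, max_sigma)
  if (sigma < 0.3) return(ch)
  as.matrix(EBImage::gblur(ch, sigma = sigma))
}

#' Otsu tissue mask
#'
#' Thresholds the saturation channel (after Gaussian blur) with Otsu's
#' method; saturated pixels are tissue, the near-white background is not.
#' A constant saturation channel (no tissue/background bimodality) yields
#' an all-background mask.
#'
#' @param image RGB array (H x W x 3, 0-255).
#' @param blur_sigma Gaussian blur sd in px before thresholding.
#' @return A `tissue_mask`: logical `mask`, `threshold`, `channel`.
#' @export
tissue_mask <- function(image, blur_sigma = 3) {
  if (is.matrix(image) || (is.array(image) && length(dim(image)) == 2))
    stop("grayscale input: `image` must be a 3-channel RGB array")
  assert_rgb(image)
  s <- blur_channel(saturation_channel(image), blur_sigma)
  if (diff(range(s)) < 1e-3) {
    mask <- matrix(FALSE, nrow(s), ncol(s))
    thr <- NA_real_
  } else {
    thr <- EBImage::otsu(s, range = c(0, 1))
    mask <- s > thr
  }
  structure(list(mask = mask, threshold = thr, channel = "saturation"),
            class = "tissue_mask")
}

#' Extract the non-overlapping tile grid of a slide
#'
#' The grid is anchored at pixel (0, 0) with half-open, side x side
#' extents; partial edge tiles are discarded and tiles whose tissue
#' coverage falls below `min_coverage` are excluded. Tiles are returned in
#' row-major order with 0-based grid coordinates.
#'
#' @param image RGB array.
#' @param mask A `tissue_mask` (or logical matrix of matching dims).
#' @param side Tile side in px (default 299).
#' @param min_coverage Minimum tissue fraction for inclusion.
#' @param slide_id Identifier recorded on each tile.
#' @return List of `tile` objects.
#' @export
tile_grid <- function(image, mask, side = 299, min_coverage = 0.5,
                      slide_id = "slide") {
  assert_rgb(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (side > min(H, W))
    stop(sprintf("tile side %d exceeds image dims %d x %d", side, H, W))
  m <- if (inherits(mask, "tissue_mask")) mask$mask else mask
  stopifnot(all(dim(m) == c(H, W)))
  nr <- H %/% side; nc <- W %/% side
  tiles <- list()
  for (r in seq_len(nr) - 1L) for (c in seq_len(nc) - 1L) {
    ys <- r * side + seq_len(side); xs <- c * side + seq_len(side)
    cov <- mean(m[ys, xs])
    if (cov >= min_coverage)
      tiles[[length(tiles) + 1L]] <-
        new_tile(image[ys, xs, , drop = FALSE], slide_id, r, c, cov)
  }
  tiles
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Estimate a stain template from tissue pixels
#'
#' Pools tissue-masked pixels across one or more images, converts to the
#' l-alpha-beta colour-transfer space, and returns per-channel mean and
#' (population) sd. Background pixels never enter the statistics, so
#' adding white border to an image leaves its template unchanged.
#'
#' @param images One RGB array or a list of them.
#' @param masks Matching `tissue_mask` (or logical matrix), or list.
#' @return A `stain_template`: `means`, `sds` (length 3, sds floored at
#'   1e-6), `n_pixels`.
#' @export
estimate_template <- function(images, masks) {
  if (!is.list(images) || is.array(images)) images <- list(images)
  if (!is.list(masks) || is.matrix(masks) || inherits(masks, "tissue_mask"))
    masks <- list(masks)
  stopifnot(length(images) == length(masks))
  px <- do.call(rbind, Map(function(img, m) {
    mm <- if (inherits(m, "tissue_mask")) m$mask else m
    pixel_matrix(img, mm)
  }, images, masks))
  if (nrow(px) < 1000)
    stop(sprintf("too few tissue pixels (%d) to estimate a template; need >= 1000",
                 nrow(px)))
  lab <- rgb_to_lab(px)
  structure(list(means = colMeans(lab),
                 sds = pmax(apply(lab, 2, pop_sd), 1e-6),
                 n_pixels = nrow(px)),
            class = "stain_template")
}

#' Reinhard stain standardization with tissue-masked statistics
#'
#' Z-scores each l-alpha-beta channel using statistics computed over
#' tissue pixels only, rescales and shifts to the target template, and
#' inverts back to RGB. Non-tissue (background) pixels pass through
#' unchanged, so the white slide border never biases the transfer.
#'
#' @param image RGB array.
#' @param mask `tissue_mask` or logical matrix.
#' @param target A `stain_template`.
#' @return RGB array of the same dims, clipped to \[0, 255\].
#' @export
reinhard_normalize <- function(image, mask, target) {
  assert_rgb(image)
  if (!inherits(target, "stain_template")) stop("`target` must be a stain_template")
  m <- if (inherits(mask, "tissue_mask")) mask$mask else mask
  idx <- which(as.logical(m))
  if (length(idx) == 0L) {
    warning("empty tissue mask; returning image unchanged")
    return(image)
  }
  d <- dim(image)
  px <- matrix(image, ncol = 3)[idx, , drop = FALSE]
  lab <- rgb_to_lab(px)
  mu <- colMeans(lab)
  sd0 <- pmax(apply(lab, 2, pop_sd), 1e-6)
  z <- sweep(sweep(lab, 2, mu), 2, sd0, "/")
  out_lab <- sweep(sweep(z, 2, target$sds, "*"), 2, target$means, "+")
  rgb_out <- lab_to_rgb(out_lab)
  res <- matrix(image, ncol = 3)
  res[idx, ] <- rgb_out
  array(res, dim = d)
}

# Dihedral-group transform t in 0..7: t %% 4 clockwise quarter turns,
# preceded by a horizontal flip when t >= 4.
apply_dihedral <- function(pixels, t) {
  stopifnot(t %in% 0:7)
  rot90cw <- function(a) {
    a2 <- aperm(a, c(2, 1, 3))
    a2[, rev(seq_len(dim(a2)[2])), , drop = FALSE]
  }
  out <- pixels
  if (t >= 4) out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
  for (i in seq_len(t %% 4)) out <- rot90cw(out)
  out
}

#' Balance tile counts across classes by dihedral augmentation
#'
#' Upsamples minority classes to the majority count using the eight
#' label-preserving dihedral transforms (quarter-turn rotations and
#' flips). No (tile, transform) pair is reused until every pair for that
#' class has been used once.
#'
#' @param tiles_by_class Named list: class label -> list of `tile`s.
#' @param seed Integer seed for transform sampling.
#' @return Named list of the same shape with equal counts per class.
#' @export
augment_balance <- function(tiles_by_class, seed) {
  counts <- vapply(tiles_by_class, length, integer(1))
  if (any(counts == 0))
    stop(sprintf("class '%s' has no tiles", names(counts)[counts == 0][1]))
  target <- max(counts)
  with_seed(seed, {
    for (cls in names(tiles_by_class)) {
      need <- target - counts[[cls]]
      if (need == 0) next
      orig <- tiles_by_class[[cls]]
      pool <- expand.grid(tile = seq_along(orig), tf = 1:7)
      pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
      picks <- pool[rep(seq_len(nrow(pool)), length.out = need), , drop = FALSE]
      aug <- lapply(seq_len(need), function(i) {
        tl <- orig[[picks$tile[i]]]
        tl$pixels <- apply_dihedral(tl$pixels, picks$tf[i])
        attr(tl, "dihedral") <- picks$tf[i]
        tl
      })
      tiles_by_class[[cls]] <- c(orig, aug)
    }
    tiles_by_class
  })
}
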