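# Pathological signature extraction: 21 colour/texture/morphometry
# features per tile, assembled per slide into a 138-feature candidate
# catalogue (6 class area proportions + 21 features x 6 classes averaged
# over each class's top-K tiles + 6 class-presence flags).

.N_TILE_FEATURES <- 21L
.CATALOGUE_VERSION <- "hs-cat-1"

tile_feature_names <- function() {
  c("r_mean", "g_mean", "b_mean", "r_sd", "g_sd", "b_sd",
    "l_mean", "alpha_mean", "beta_mean", "l_sd", "alpha_sd", "beta_sd",
    "glcm_contrast", "glcm_homogeneity", "glcm_energy", "glcm_correlation",
    "glcm_entropy",
    "blob_density", "blob_area_mean", "blob_area_frac", "blob_ecc_mean")
}

#' Names of the full slide-signature catalogue
#'
#' @return Character vector of 138 feature names: `prop_<class>` area
#'   proportions, `<class>.<feature>` top-tile feature means, and
#'   `present_<class>` flags.
#' @export
signature_names <- function() {
  cls <- hcc_classes()
  c(paste0("prop_", cls),
    unlist(lapply(cls, function(k) paste0(k, ".", tile_feature_names()))),
    paste0("present_", cls))
}

# Symmetric GLCM at one offset; returns the normalized co-occurrence matrix.
glcm_matrix <- function(q, levels, dy, dx) {
  H <- nrow(q); W <- ncol(q)
  ys <- max(1, 1 - dy):min(H, H - dy)
  xs <- max(1, 1 - dx):min(W, W - dx)
  a <- q[ys, xs]
  b <- q[ys + dy, xs + dx]
  cnt <- tabulate((a - 1L) * levels + b, nbins = levels * levels)
  m <- matrix(cnt, levels, levels, byrow = TRUE)
  m <- m + t(m)
  m / sum(m)
}

glcm_stats <- function(p) {
  L <- nrow(p)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p)); sd_j <- sqrt(sum((j - mu_j)^2 * p))
  corr <- if (sd_i < 1e-12 || sd_j < 1e-12) 0 else
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
  nz <- p[p > 0]
  c(glcm_contrast = sum((i - j)^2 * p),
    glcm_homogeneity = sum(p / (1 + (i - j)^2)),
    glcm_energy = sum(p^2),
    glcm_correlation = corr,
    glcm_entropy = -sum(nz * log(nz)))
}

# Eccentricity of labelled components from second central moments.
component_stats <- function(lab) {
  n <- max(lab)
  if (n == 0) return(list(count = 0L, areas = numeric(0), ecc = numeric(0)))
  idx <- which(lab > 0)
  comp <- lab[idx]
  ys <- ((idx - 1L) %% nrow(lab)) + 1L
  xs <- ((idx - 1L) %/% nrow(lab)) + 1L
  areas <- tabulate(comp, nbins = n)
  my <- tapply(ys, comp, mean); mx <- tapply(xs, comp, mean)
  dy <- ys - my[comp]; dx <- xs - mx[comp]
  syy <- tapply(dy^2, comp, mean); sxx <- tapply(dx^2, comp, mean)
  sxy <- tapply(dy * dx, comp, mean)
  tr <- syy + sxx
  det <- syy * sxx - sxy^2
  disc <- sqrt(pmax(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  ecc <- ifelse(l1 < 1e-12, 0, sqrt(pmax(1 - l2 / l1, 0)))
  list(count = n, areas = areas, ecc = as.numeric(ecc))
}

#' Compute the 21 per-tile pathological features
#'
#' Per-channel mean/sd in RGB and l-alpha-beta (12), angle-averaged
#' gray-level co-occurrence statistics at distance 1 over 32 gray levels
#' (contrast, homogeneity, energy, correlation, entropy; 5), and
#' morphometric statistics of Otsu-thresholded dark blobs, a nuclei proxy
#' (count density per 10^4 px^2, mean area, area fraction, mean
#' eccentricity; 4).
#'
#' @param tile A `tile` object or RGB pixel array.
#' @param glcm_levels Gray-level quantization (default 32).
#' @return Named numeric vector of length 21.
#' @export
tile_features <- function(tile, glcm_levels = 32L) {
  px <- if (is.list(tile) && !is.null(tile$pixels)) tile$pixels else tile
  assert_rgb(px, "tile")
  flat <- matrix(px, ncol = 3)
  rgb_mean <- colMeans(flat)
  rgb_sd <- apply(flat, 2, pop_sd)
  lab <- rgb_to_lab(flat)
  lab_mean <- colMeans(lab)
  lab_sd <- apply(lab, 2, pop_sd)

  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  q <- pmin(floor(gray / 256 * glcm_levels), glcm_levels - 1L) + 1L
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  gl <- rowMeans(vapply(offsets, function(o)
    glcm_stats(glcm_matrix(q, glcm_levels, o[1], o[2])), numeric(5)))

  if (diff(range(gray)) < 1e-9) {
    blobs <- c(0, 0, 0, 0)
  } else {
    thr <- EBImage::otsu(gray / 255, range = c(0, 1)) * 255
    fg <- gray < thr
    cs <- component_stats(EBImage::bwlabel(fg))
    blobs <- if (cs$count == 0) c(0, 0, 0, 0) else
      c(cs$count / length(gray) * 1e4, mean(cs$areas),
        sum(cs$areas) / length(gray), mean(cs$ecc))
  }
  stats::setNames(
    c(rgb_mean, rgb_sd, lab_mean, lab_sd, gl, blobs),
    tile_feature_names())
}

# Feature matrix (n x 21) for a list of tiles.
featurize_tiles <- function(tiles, glcm_levels = 32L) {
  t(vapply(tiles, tile_features, numeric(.N_TILE_FEATURES),
           glcm_levels = glcm_levels))
}

#' Assemble the per-slide signature vector
#'
#' Concatenates (a) the six class area proportions over tissue cells of
#' the classification map, (b) for each class the mean of `tile_features`
#' over its top-K representative tiles (zero-imputed when the class is
#' absent), and (c) six class-presence flags.
#'
#' @param map A `classification_map`.
#' @param topk Output of `top_k_tiles` for the same slide.
#' @param tile_accessor Function `(grid_row, grid_col) -> RGB array`
#'   returning the pixels of a grid tile.
#' @return A `signature_vector`: `slide_id`, named `values` (length 138),
#'   `catalogue_version`.
#' @export
slide_signature <- function(map, topk, tile_accessor) {
  stopifnot(inherits(map, "classification_map"))
  if (!identical(map$slide_id, attr(topk, "slide_id")))
    stop(sprintf("slide mismatch: map is '%s', top-k is '%s'",
                 map$slide_id, attr(topk, "slide_id")))
  cls <- hcc_classes()
  labels <- map$labels
  tissue <- !is.na(labels)
  if (!any(tissue)) stop("classification map has no tissue cells")
  props <- vapply(cls, function(k) mean(labels[tissue] == k), numeric(1))

  blocks <- numeric(0)
  flags <- numeric(length(cls))
  for (ci in seq_along(cls)) {
    sel <- topk[[cls[ci]]]
    if (nrow(sel$tiles) == 0) {
      fv <- stats::setNames(numeric(.N_TILE_FEATURES), tile_feature_names())
    } else {
      flags[ci] <- 1
      feats <- t(vapply(seq_len(nrow(sel$tiles)), function(i)
        tile_features(tile_accessor(sel$tiles$grid_row[i], sel$tiles$grid_col[i])),
        numeric(.N_TILE_FEATURES)))
      fv <- colMeans(feats)
    }
    blocks <- c(blocks, stats::setNames(fv, paste0(cls[ci], ".", names(fv))))
  }
  values <- c(stats::setNames(props, paste0("prop_", cls)), blocks,
              stats::setNames(flags, paste0("present_", cls)))
  stopifnot(identical(names(values), signature_names()))
  structure(list(slide_id = map$slide_id, values = values,
                 catalogue_version = .CATALOGUE_VERSION),
            class = "signature_vector")
}
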