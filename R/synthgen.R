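# Synthetic six-class histology generator. Textures are parametric
# (blobs / rings / streaks / amorphous patches on an H&E-like palette) so
# that every downstream stage — masking, tiling, classification, signature
# extraction, survival modelling — can be tested against known ground truth.

#' Construct a texture recipe for one tissue class
#'
#' A recipe fully parameterises the synthetic appearance of one tissue
#' class: a background colour, a structural element colour (the "nucleus"
#' colour), the element density per 10^4 px^2, the element radius
#' distribution, the structural motif and additive per-channel noise.
#'
#' @param class_label One of `hcc_classes()`.
#' @param background_color,nucleus_color RGB triples in \[0, 255\].
#' @param nucleus_density Elements per 10^4 px^2 (>= 0).
#' @param nucleus_radius Length-2 numeric `c(mean, sd)` in px, mean > 0.
#' @param structure One of "blobs", "rings", "streaks", "amorphous".
#' @param noise_sd Per-channel Gaussian noise sd in gray levels.
#' @return A `texture_recipe` object.
#' @export
texture_recipe <- function(class_label, background_color, nucleus_color,
                           nucleus_density, nucleus_radius,
                           structure = c("blobs", "rings", "streaks", "amorphous"),
                           noise_sd = 5) {
  if (!class_label %in% hcc_classes())
    stop(sprintf("unknown class label '%s'; must be one of %s",
                 class_label, paste(hcc_classes(), collapse = ", ")))
  structure <- match.arg(structure)
  stopifnot(length(background_color) == 3, length(nucleus_color) == 3,
            all(background_color >= 0 & background_color <= 255),
            all(nucleus_color >= 0 & nucleus_color <= 255),
            nucleus_density >= 0, length(nucleus_radius) == 2,
            nucleus_radius[1] > 0, nucleus_radius[2] >= 0, noise_sd >= 0)
  structure(list(class_label = class_label,
                 background_color = as.numeric(background_color),
                 nucleus_color = as.numeric(nucleus_color),
                 nucleus_density = nucleus_density,
                 nucleus_radius = as.numeric(nucleus_radius),
                 structure = structure,
                 noise_sd = noise_sd),
            class = "texture_recipe")
}

#' Default recipes for the six tissue classes
#'
#' H&E-like palettes: dense purple nuclei on pink-purple stroma for tumor,
#' sparse nuclei on light pink for normal liver, ringed ducts for portal
#' area, pink streaks for fibrosis, dark amorphous patches on red for
#' hemorrhage/necrosis, and dense small dark nuclei for lymphocyte areas.
#' The palettes are deliberately well separated in mean colour.
#'
#' @return Named list of six `texture_recipe` objects in `hcc_classes()` order.
#' @export
default_recipes <- function() {
  list(
    TR  = texture_recipe("TR",  c(200, 150, 192), c(90, 50, 120),
                         nucleus_density = 60, nucleus_radius = c(3.5, 0.8),
                         structure = "blobs", noise_sd = 6),
    NLT = texture_recipe("NLT", c(242, 178, 196), c(135, 88, 150),
                         nucleus_density = 22, nucleus_radius = c(2.5, 0.5),
                         structure = "blobs", noise_sd = 5),
    PA  = texture_recipe("PA",  c(208, 168, 232), c(110, 72, 140),
                         nucleus_density = 6, nucleus_radius = c(3, 0.6),
                         structure = "rings", noise_sd = 5),
    FI  = texture_recipe("FI",  c(235, 160, 178), c(198, 120, 150),
                         nucleus_density = 9, nucleus_radius = c(2, 0.4),
                         structure = "streaks", noise_sd = 5),
    HNA = texture_recipe("HNA", c(205, 125, 122), c(118, 42, 46),
                         nucleus_density = 10, nucleus_radius = c(3, 0.6),
                         structure = "amorphous", noise_sd = 7),
    LA  = texture_recipe("LA",  c(196, 170, 230), c(70, 45, 110),
                         nucleus_density = 120, nucleus_radius = c(1.8, 0.3),
                         structure = "blobs", noise_sd = 5)
  )
}

# Linear pixel indices of a filled disk, clipped to the image bounds.
disk_idx <- function(cy, cx, r, H, W) {
  ri <- ceiling(r)
  dy <- -ri:ri
  off <- expand.grid(dy = dy, dx = dy)
  off <- off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
  y <- cy + off$dy; x <- cx + off$dx
  ok <- y >= 1 & y <= H & x >= 1 & x <= W
  (x[ok] - 1L) * H + y[ok]
}

# Annulus (ring) indices between radii r_in and r_out.
ring_idx <- function(cy, cx, r_in, r_out, H, W) {
  ri <- ceiling(r_out)
  dy <- -ri:ri
  off <- expand.grid(dy = dy, dx = dy)
  d2 <- off$dy^2 + off$dx^2
  off <- off[d2 <= r_out^2 & d2 >= r_in^2, , drop = FALSE]
  y <- cy + off$dy; x <- cx + off$dx
  ok <- y >= 1 & y <= H & x >= 1 & x <= W
  (x[ok] - 1L) * H + y[ok]
}

# Draw one class's texture into channel matrices over the pixels where
# `region` is TRUE. Consumes RNG draws; callers seed via with_seed().
render_texture <- function(chans, region, recipe) {
  H <- nrow(region); W <- ncol(region)
  idx_region <- which(region)
  area <- length(idx_region)
  if (area == 0L) return(chans)
  for (k in 1:3) chans[[k]][idx_region] <- recipe$background_color[k]

  n_elem <- round(recipe$nucleus_density * area / 1e4)
  if (n_elem > 0) {
    centers <- idx_region[sample.int(area, n_elem, replace = n_elem > area)]
    cy <- ((centers - 1L) %% H) + 1L
    cx <- ((centers - 1L) %/% H) + 1L
    rads <- pmax(0.6, stats::rnorm(n_elem, recipe$nucleus_radius[1],
                                   recipe$nucleus_radius[2]))
    jit <- matrix(stats::rnorm(3 * n_elem, 0, 6), ncol = 3)
    for (e in seq_len(n_elem)) {
      col_e <- clamp(recipe$nucleus_color + jit[e, ], 0, 255)
      idx <- switch(recipe$structure,
        blobs = disk_idx(cy[e], cx[e], rads[e], H, W),
        rings = ring_idx(cy[e], cx[e], 2 * rads[e], 3 * rads[e], H, W),
        streaks = {
          ang <- stats::runif(1, 0, pi)
          len <- 12 * rads[e]
          steps <- seq(-len / 2, len / 2, by = max(1, rads[e] / 2))
          unlist(lapply(steps, function(s)
            disk_idx(round(cy[e] + s * sin(ang)), round(cx[e] + s * cos(ang)),
                     max(1, rads[e] / 2), H, W)))
        },
        amorphous = {
          col_e <- clamp((recipe$nucleus_color + recipe$background_color) / 2 +
                           jit[e, ], 0, 255)
          disk_idx(cy[e], cx[e], 4 * rads[e], H, W)
        })
      idx <- idx[region[idx]]
      if (length(idx)) for (k in 1:3) chans[[k]][idx] <- col_e[k]
    }
  }
  if (recipe$noise_sd > 0) {
    for (k in 1:3) {
      noise <- stats::rnorm(area, 0, recipe$noise_sd)
      chans[[k]][idx_region] <- clamp(chans[[k]][idx_region] + noise, 0, 255)
    }
  }
  chans
}

chans_to_array <- function(chans) {
  H <- nrow(chans[[1]]); W <- ncol(chans[[1]])
  array(c(chans[[1]], chans[[2]], chans[[3]]), dim = c(H, W, 3))
}

#' Render a single square tile of one tissue class
#'
#' @param recipe A `texture_recipe`.
#' @param side Tile side in px (>= 32).
#' @param seed Integer seed; rendering is a pure function of
#'   `(recipe, side, seed)`.
#' @return A `tile` object: `pixels` (side x side x 3, 0-255), `label`,
#'   `slide_id`, `grid_row`, `grid_col`, `coverage`.
#' @export
render_tile <- function(recipe, side, seed) {
  if (!inherits(recipe, "texture_recipe"))
    stop("`recipe` must be a texture_recipe")
  if (side < 32) stop("`side` must be >= 32 px")
  pixels <- with_seed(seed, {
    chans <- replicate(3, matrix(255, side, side), simplify = FALSE)
    chans <- render_texture(chans, matrix(TRUE, side, side), recipe)
    chans_to_array(chans)
  })
  new_tile(pixels, slide_id = NA_character_, grid_row = 0L, grid_col = 0L,
           coverage = 1, label = recipe$class_label)
}

new_tile <- function(pixels, slide_id, grid_row, grid_col, coverage, label = NA) {
  structure(list(pixels = pixels, slide_id = slide_id,
                 grid_row = as.integer(grid_row), grid_col = as.integer(grid_col),
                 coverage = coverage, label = label),
            class = "tile")
}

#' Compose a synthetic slide from a tissue-class composition
#'
#' Lays out seeded Voronoi cells over the slide interior, assigns cells to
#' classes greedily (largest cell first, to the class with the largest
#' remaining area deficit) so realized area fractions track the requested
#' composition, renders each region with its class texture, and frames the
#' tissue with a white border.
#'
#' @param composition Numeric 6-vector of intended class area fractions in
#'   `hcc_classes()` order; non-negative, summing to 1.
#' @param size Image size: scalar (square) or `c(H, W)`.
#' @param seed Integer seed.
#' @param recipes Named list of recipes (default `default_recipes()`).
#' @param n_cells Number of Voronoi cells; default scales with area.
#' @param border White border width in px; default ~1.5% of the short side.
#' @return A `synthetic_slide`: `image` (H x W x 3), `truth_mask` (H x W
#'   integer, 0 = background, 1..6 = class index), `composition`, `seed`.
#' @export
compose_slide <- function(composition, size, seed, recipes = default_recipes(),
                          n_cells = NULL, border = NULL) {
  composition <- as.numeric(composition)
  if (length(composition) != 6 || any(composition < 0))
    stop("`composition` must be 6 non-negative fractions")
  if (abs(sum(composition) - 1) > 1e-6)
    stop("`composition` must sum to 1")
  if (length(size) == 1) size <- c(size, size)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (is.null(border)) border <- max(8L, round(0.04 * min(H, W)))
  present <- which(composition > 0)
  n_present <- length(present)
  iH <- H - 2L * border; iW <- W - 2L * border
  min_interior <- 32L * ceiling(sqrt(n_present))
  if (iH < min_interior || iW < min_interior)
    stop(sprintf(
      "size %dx%d too small for %d classes; minimum size is %dx%d (border %d px)",
      H, W, n_present, min_interior + 2L * border, min_interior + 2L * border,
      border))
  if (is.null(n_cells))
    n_cells <- max(3L * n_present, round(iH * iW / 32768))

  out <- with_seed(seed, {
    sy <- stats::runif(n_cells, 1, iH)
    sx <- stats::runif(n_cells, 1, iW)
    # nearest-seed assignment, running minimum over cells
    best <- matrix(Inf, iH, iW)
    cell <- matrix(0L, iH, iW)
    for (i in seq_len(n_cells)) {
      d <- outer((seq_len(iH) - sy[i])^2, (seq_len(iW) - sx[i])^2, "+")
      upd <- d < best
      best[upd] <- d[upd]
      cell[upd] <- i
    }
    areas <- tabulate(cell, nbins = n_cells)
    total <- sum(areas)
    deficit <- composition * total
    cls_of_cell <- integer(n_cells)
    for (i in order(areas, decreasing = TRUE)) {
      k <- which.max(deficit)
      cls_of_cell[i] <- k
      deficit[k] <- deficit[k] - areas[i]
    }
    interior_mask <- matrix(cls_of_cell[cell], iH, iW)

    truth <- matrix(0L, H, W)
    truth[border + seq_len(iH), border + seq_len(iW)] <- interior_mask
    chans <- replicate(3, matrix(255, H, W), simplify = FALSE)
    for (k in sort(unique(cls_of_cell)))
      chans <- render_texture(chans, truth == k, recipes[[hcc_classes()[k]]])
    list(image = chans_to_array(chans), truth_mask = truth)
  })
  structure(list(image = out$image, truth_mask = out$truth_mask,
                 composition = stats::setNames(composition, hcc_classes()),
                 seed = seed),
            class = "synthetic_slide")
}
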