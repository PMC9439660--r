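# Slide classification maps: per-tile prediction grids, label-grid
# morphology (majority filter + small-component absorption), and top-K
# representative tile selection per class.

new_classification_map <- function(labels, probs, slide_id, side) {
  structure(list(labels = labels, probs = probs, slide_id = slide_id,
                 side = side),
            class = "classification_map")
}

#' Build the classification map of a slide
#'
#' Runs the tile classifier over every grid tile passing the coverage
#' rule; excluded tiles become background (NA label, no probabilities).
#'
#' @param image Slide RGB array.
#' @param mask `tissue_mask` or logical matrix.
#' @param model A `tile_classifier`; its tile side defines the grid.
#' @param min_coverage Minimum tissue fraction per tile.
#' @param slide_id Identifier recorded on the map.
#' @return A `classification_map`: `labels` (nr x nc character, NA =
#'   background), `probs` (nr x nc x 6), `slide_id`, `side`.
#' @export
build_map <- function(image, mask, model, min_coverage = 0.5,
                      slide_id = "slide") {
  assert_rgb(image)
  stopifnot(inherits(model, "tile_classifier"))
  side <- model$side
  H <- dim(image)[1]; W <- dim(image)[2]
  if (side > min(H, W))
    stop(sprintf("model tile side %d does not fit into slide dims %d x %d",
                 side, H, W))
  m <- if (inherits(mask, "tissue_mask")) mask$mask else mask
  nr <- H %/% side; nc <- W %/% side
  labels <- matrix(NA_character_, nr, nc)
  probs <- array(NA_real_, dim = c(nr, nc, 6),
                 dimnames = list(NULL, NULL, hcc_classes()))
  keep <- list(); feats <- list()
  for (r in seq_len(nr) - 1L) for (c in seq_len(nc) - 1L) {
    ys <- r * side + seq_len(side); xs <- c * side + seq_len(side)
    if (mean(m[ys, xs]) >= min_coverage) {
      keep[[length(keep) + 1L]] <- c(r, c)
      feats[[length(feats) + 1L]] <-
        tile_features(image[ys, xs, , drop = FALSE])
    }
  }
  if (length(keep)) {
    p <- predict_proba(model, do.call(rbind, feats))
    for (i in seq_along(keep)) {
      r <- keep[[i]][1] + 1L; c <- keep[[i]][2] + 1L
      probs[r, c, ] <- p[i, ]
      labels[r, c] <- hcc_classes()[which.max(p[i, ])]
    }
  }
  new_classification_map(labels, probs, slide_id, side)
}

# 4-connected components of a label grid; NA cells are background.
# Returns an integer component-id matrix (0 = background).
label_components <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  comp <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (is.na(labels[i, j]) || comp[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), 1)
    comp[i, j] <- cur
    while (nrow(queue)) {
      cell <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        y <- cell[1] + d[1]; x <- cell[2] + d[2]
        if (y >= 1 && y <= nr && x >= 1 && x <= nc && comp[y, x] == 0L &&
            !is.na(labels[y, x]) && labels[y, x] == labels[i, j]) {
          comp[y, x] <- cur
          queue <- rbind(queue, c(y, x))
        }
      }
    }
  }
  comp
}

#' Morphologically smooth a classification map
#'
#' Two passes over the label grid: (1) each tissue cell takes the
#' majority label of its 3x3 neighbourhood (background cells excluded
#' from the vote; ties retain the original label); (2) 4-connected
#' components smaller than `min_region` cells are absorbed into their
#' largest neighbouring component. Probabilities are left untouched.
#'
#' @param map A `classification_map`.
#' @param min_region Minimum component size in cells (default 2).
#' @return A smoothed `classification_map`.
#' @export
smooth_map <- function(map, min_region = 2) {
  stopifnot(inherits(map, "classification_map"))
  labels <- map$labels
  nr <- nrow(labels); nc <- ncol(labels)
  if (nr == 0 || all(is.na(labels))) return(map)

  out <- labels
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(labels[i, j])) next
    nb <- labels[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    votes <- table(nb[!is.na(nb)])
    top <- names(votes)[votes == max(votes)]
    out[i, j] <- if (length(top) == 1) top else labels[i, j]
  }

  # absorb small components; each pass reads only pass-start state, so the
  # result is independent of processing order within a pass
  for (pass in 1:10) {
    comp <- label_components(out)
    sizes <- tabulate(comp)
    small <- which(sizes > 0 & sizes < min_region)
    if (!length(small)) break
    base <- out
    changed <- FALSE
    for (cid in small[order(sizes[small])]) {
      cells <- which(comp == cid, arr.ind = TRUE)
      nb_comp <- integer(0)
      for (r in seq_len(nrow(cells))) {
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          y <- cells[r, 1] + d[1]; x <- cells[r, 2] + d[2]
          if (y >= 1 && y <= nr && x >= 1 && x <= nc &&
              comp[y, x] != 0L && comp[y, x] != cid)
            nb_comp <- c(nb_comp, comp[y, x])
        }
      }
      if (!length(nb_comp)) next
      nb_comp <- unique(nb_comp)
      # largest neighbour; ties -> component whose first cell comes first
      # in row-major order
      first_rm <- vapply(nb_comp, function(id) {
        cc <- which(comp == id, arr.ind = TRUE)
        min((cc[, 1] - 1L) * nc + (cc[, 2] - 1L))
      }, numeric(1))
      best <- nb_comp[order(-sizes[nb_comp], first_rm)][1]
      new_lab <- base[which(comp == best)[1]]
      out[comp == cid] <- new_lab
      changed <- TRUE
    }
    if (!changed) break
  }
  new_classification_map(out, map$probs, map$slide_id, map$side)
}

#' Select the top-K representative tiles per class
#'
#' For each class, returns the k tiles whose (smoothed) label equals that
#' class, ranked by that class's predicted probability descending; ties
#' broken by row-major grid order. Classes with fewer than k tiles return
#' all of them with `flagged_short = TRUE`.
#'
#' @param map A `classification_map`.
#' @param k Number of tiles per class (default 10).
#' @return Named list per class: `tiles` (data.frame grid_row, grid_col,
#'   prob; 0-based coords) and `flagged_short`. Carries the slide id as
#'   an attribute.
#' @export
top_k_tiles <- function(map, k = 10) {
  stopifnot(inherits(map, "classification_map"))
  nc <- ncol(map$labels)
  out <- lapply(seq_along(hcc_classes()), function(ci) {
    cls <- hcc_classes()[ci]
    cells <- which(!is.na(map$labels) & map$labels == cls, arr.ind = TRUE)
    if (nrow(cells) == 0)
      return(list(tiles = data.frame(grid_row = integer(0),
                                     grid_col = integer(0), prob = numeric(0)),
                  flagged_short = TRUE))
    prob <- map$probs[cbind(cells[, 1], cells[, 2], ci)]
    rowmajor <- (cells[, 1] - 1L) * nc + (cells[, 2] - 1L)
    o <- order(-prob, rowmajor)
    take <- o[seq_len(min(k, length(o)))]
    list(tiles = data.frame(grid_row = cells[take, 1] - 1L,
                            grid_col = cells[take, 2] - 1L,
                            prob = prob[take]),
         flagged_short = length(o) < k)
  })
  names(out) <- hcc_classes()
  attr(out, "slide_id") <- map$slide_id
  attr(out, "k") <- k
  out
}
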