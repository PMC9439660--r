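# Plain-text / PNG serialization of the pipeline's artifacts.

#' Write a synthetic slide to disk
#'
#' Writes the RGB image as PNG, the truth mask as a grayscale PNG
#' (pixel value = class index), and a JSON manifest (seed, composition).
#'
#' @param slide A `synthetic_slide`.
#' @param prefix File path prefix; writes `<prefix>.png`,
#'   `<prefix>_mask.png`, `<prefix>.json`.
#' @return Invisibly, the written paths.
#' @export
write_slide <- function(slide, prefix) {
  stopifnot(inherits(slide, "synthetic_slide"))
  paths <- c(image = paste0(prefix, ".png"),
             mask = paste0(prefix, "_mask.png"),
             manifest = paste0(prefix, ".json"))
  png::writePNG(slide$image / 255, paths["image"])
  png::writePNG(slide$truth_mask / 255, paths["mask"])
  jsonlite::write_json(list(seed = slide$seed,
                            composition = as.list(slide$composition)),
                       paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read an RGB image (PNG) as a 0-255 array
#'
#' @param path PNG path.
#' @return H x W x 3 numeric array in \[0, 255\].
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) stop("grayscale input: need a 3-channel RGB image")
  img[, , 1:3, drop = FALSE] * 255
}

#' Save / load a stain template as JSON
#'
#' @param template A `stain_template`.
#' @param path JSON path.
#' @return `load_template` returns a `stain_template`.
#' @export
save_template <- function(template, path) {
  stopifnot(inherits(template, "stain_template"))
  jsonlite::write_json(list(means = template$means, sds = template$sds,
                            n_pixels = template$n_pixels),
                       path, digits = NA)
  invisible(path)
}

#' @rdname save_template
#' @export
load_template <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(means = as.numeric(x$means), sds = as.numeric(x$sds),
                 n_pixels = x$n_pixels),
            class = "stain_template")
}

#' Write a classification map as CSV
#'
#' One row per grid cell: slide_id, grid_row, grid_col, label and the six
#' class probabilities (background cells omitted).
#'
#' @param map A `classification_map`.
#' @param path CSV path.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "classification_map"))
  cells <- which(!is.na(map$labels), arr.ind = TRUE)
  p <- t(vapply(seq_len(nrow(cells)), function(i)
    map$probs[cells[i, 1], cells[i, 2], ], numeric(6)))
  colnames(p) <- paste0("p_", hcc_classes())
  df <- cbind(data.frame(slide_id = map$slide_id,
                         grid_row = cells[, 1] - 1L,
                         grid_col = cells[, 2] - 1L,
                         label = map$labels[cells]), p)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save a LASSO-Cox fit as JSON
#'
#' @param fit A `lasso_cox_fit`.
#' @param path JSON path.
#' @param cutoff Optional cutoff to store alongside.
#' @export
save_fit <- function(fit, path, cutoff = NULL) {
  jsonlite::write_json(list(features = names(fit$beta),
                            beta = as.numeric(fit$beta),
                            lambda = fit$lambda, n_nonzero = fit$n_nonzero,
                            cutoff = cutoff),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Requires columns patient_id, slide_id, time, event; validates
#' time > 0 and event in {0, 1}, reporting offending row numbers. Extra
#' columns are preserved.
#'
#' @param path CSV path.
#' @return A `cohort_table` data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "slide_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("cohort CSV missing column(s): %s", paste(miss, collapse = ", ")))
  bad_t <- which(!is.finite(df$time) | df$time <= 0)
  bad_e <- which(!df$event %in% c(0, 1))
  if (length(bad_t) || length(bad_e))
    stop(sprintf("malformed cohort rows: %s",
                 paste(sort(unique(c(bad_t, bad_e))), collapse = ", ")))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table to CSV
#'
#' @param cohort A `cohort_table` data.frame.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation / discrimination report as JSON
#'
#' @param report A list of metrics (scalars, vectors, data.frames).
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(path)
}
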