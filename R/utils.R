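#' Fixed tissue-class order
#'
#' The six tissue classes recognised throughout the package, in the fixed
#' order used for probability vectors, confusion matrices and signature
#' names: tumor region (TR), normal liver tissue (NLT), portal area (PA),
#' fibrosis (FI), hemorrhage/necrotic area (HNA) and lymphocyte area (LA).
#'
#' @return Character vector of length 6.
#' @export
hcc_classes <- function() c("TR", "NLT", "PA", "FI", "HNA", "LA")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Makes every generator a pure function
# of its seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Validate an H x W x 3 numeric array with values in [0, 255].
assert_rgb <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an RGB array (H x W x 3); got %s",
                 what, paste(dim(img), collapse = " x ")))
  invisible(img)
}

# Derive a reproducible sub-seed for a named RNG stream.
substream_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
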