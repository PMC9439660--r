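# Six-class tile classifier behind a pluggable interface. Both backends
# consume the package's 21 tile features: a probability random forest
# (ranger) and a single-hidden-layer neural network (nnet) whose weight
# decay is selected on the validation split.

#' Bundle labelled tiles into a feature batch
#'
#' @param tiles List of labelled `tile` objects.
#' @param side Tile side in px.
#' @param keep_pixels Keep the raw pixel arrays alongside the features.
#' @return A `tile_batch`: `features` (n x 21), `labels` (factor over
#'   `hcc_classes()`), `side`, optional `tiles`.
#' @export
tile_batch <- function(tiles, side = dim(tiles[[1]]$pixels)[1],
                       keep_pixels = FALSE) {
  labels <- vapply(tiles, function(t) as.character(t$label), character(1))
  bad <- setdiff(unique(labels), hcc_classes())
  if (length(bad)) stop(sprintf("labels outside the six classes: %s",
                                paste(bad, collapse = ", ")))
  structure(list(features = featurize_tiles(tiles),
                 labels = factor(labels, levels = hcc_classes()),
                 side = side,
                 tiles = if (keep_pixels) tiles else NULL),
            class = "tile_batch")
}

#' Render and featurize a synthetic tile benchmark
#'
#' Renders `n_per_class` tiles for each recipe and featurizes them on the
#' fly, so large benchmarks never hold all pixels in memory.
#'
#' @param n_per_class Tiles per class.
#' @param side Tile side in px (default 96).
#' @param seed Integer seed.
#' @param recipes Named list of recipes.
#' @return A `tile_batch`.
#' @export
synth_tile_batch <- function(n_per_class, side = 96, seed = 1,
                             recipes = default_recipes()) {
  feats <- vector("list", length(recipes))
  labels <- character(0)
  for (ci in seq_along(recipes)) {
    cls <- recipes[[ci]]$class_label
    f <- t(vapply(seq_len(n_per_class), function(i) {
      tl <- render_tile(recipes[[ci]], side,
                        substream_seed(seed, ci * 100000L + i))
      tile_features(tl$pixels)
    }, numeric(.N_TILE_FEATURES)))
    feats[[ci]] <- f
    labels <- c(labels, rep(cls, n_per_class))
  }
  structure(list(features = do.call(rbind, feats),
                 labels = factor(labels, levels = hcc_classes()),
                 side = side, tiles = NULL),
            class = "tile_batch")
}

subset_batch <- function(batch, idx) {
  structure(list(features = batch$features[idx, , drop = FALSE],
                 labels = batch$labels[idx],
                 side = batch$side,
                 tiles = if (!is.null(batch$tiles)) batch$tiles[idx] else NULL),
            class = "tile_batch")
}

#' Stratified train/validation/test split
#'
#' @param batch A `tile_batch`.
#' @param ratios Length-3 split weights (default 8:1:1).
#' @param seed Integer seed; splitting is deterministic per seed.
#' @return List `train`, `val`, `test` of disjoint `tile_batch`es whose
#'   union is the input.
#' @export
split_dataset <- function(batch, ratios = c(8, 1, 1), seed = 1) {
  stopifnot(inherits(batch, "tile_batch"), length(ratios) == 3)
  counts <- table(droplevels(batch$labels))
  if (any(counts < 3))
    stop(sprintf("class '%s' has fewer than 3 tiles",
                 names(counts)[counts < 3][1]))
  r <- ratios / sum(ratios)
  idx <- with_seed(seed, {
    tr <- va <- te <- integer(0)
    for (cls in names(counts)) {
      ids <- sample(which(batch$labels == cls))
      n <- length(ids)
      n_te <- floor(n * r[3]); n_va <- floor(n * r[2])
      te <- c(te, ids[seq_len(n_te)])
      va <- c(va, ids[n_te + seq_len(n_va)])
      tr <- c(tr, ids[-seq_len(n_te + n_va)])
    }
    list(train = sort(tr), val = sort(va), test = sort(te))
  })
  lapply(idx, subset_batch, batch = batch)
}

#' Classifier configuration
#'
#' @param backend "ranger" (probability random forest) or "nnet"
#'   (single-hidden-layer network; weight decay picked on validation
#'   accuracy).
#' @param seed Training seed.
#' @param num_trees Forest size for ranger.
#' @param hidden Hidden units for nnet.
#' @param decay_grid Weight-decay candidates for nnet.
#' @param maxit Max nnet iterations.
#' @return Config list.
#' @export
classifier_config <- function(backend = c("ranger", "nnet"), seed = 1,
                              num_trees = 300, hidden = 16,
                              decay_grid = c(1e-3, 1e-2, 1e-1), maxit = 300) {
  list(backend = match.arg(backend), seed = seed, num_trees = num_trees,
       hidden = hidden, decay_grid = decay_grid, maxit = maxit)
}

#' Train the six-class tile classifier
#'
#' @param train,val `tile_batch`es (val must be non-empty; used to select
#'   the nnet weight decay and to report validation accuracy).
#' @param config From `classifier_config()`.
#' @return A `tile_classifier` exposing `predict_proba()`.
#' @export
train_classifier <- function(train, val, config = classifier_config()) {
  stopifnot(inherits(train, "tile_batch"))
  if (is.null(val) || length(val$labels) == 0)
    stop("validation set is empty")
  x <- train$features
  y <- droplevels(train$labels)
  ctr <- colMeans(x)
  scl <- pmax(apply(x, 2, stats::sd), 1e-8)

  if (nlevels(y) == 1L) {
    model <- structure(list(backend = "constant", constant = levels(y),
                            classes = hcc_classes(), side = train$side,
                            center = ctr, scale = scl),
                       class = "tile_classifier")
  } else if (config$backend == "ranger") {
    fit <- ranger::ranger(x = x, y = y, probability = TRUE,
                          num.trees = config$num_trees,
                          seed = config$seed, num.threads = 1)
    model <- structure(list(backend = "ranger", fit = fit,
                            classes = hcc_classes(), side = train$side,
                            center = ctr, scale = scl),
                       class = "tile_classifier")
  } else {
    xs <- scale(x, ctr, scl)
    fits <- with_seed(config$seed, lapply(config$decay_grid, function(d)
      nnet::nnet(xs, nnet::class.ind(y), size = config$hidden, decay = d,
                 maxit = config$maxit, softmax = TRUE, trace = FALSE,
                 MaxNWts = 10000)))
    accs <- vapply(fits, function(f) {
      m <- structure(list(backend = "nnet", fit = f, lev = levels(y),
                          classes = hcc_classes(), side = train$side,
                          center = ctr, scale = scl),
                     class = "tile_classifier")
      mean(predicted_labels(m, val) == as.character(val$labels))
    }, numeric(1))
    best <- which.max(accs)
    model <- structure(list(backend = "nnet", fit = fits[[best]],
                            lev = levels(y), decay = config$decay_grid[best],
                            classes = hcc_classes(), side = train$side,
                            center = ctr, scale = scl),
                       class = "tile_classifier")
  }
  model$val_accuracy <-
    mean(predicted_labels(model, val) == as.character(val$labels))
  model
}

# Coerce various inputs to a feature matrix.
as_feature_matrix <- function(x) {
  if (inherits(x, "tile_batch")) return(x$features)
  if (inherits(x, "tile")) return(featurize_tiles(list(x)))
  if (is.list(x)) return(featurize_tiles(x))
  if (is.array(x) && length(dim(x)) == 3) return(featurize_tiles(list(list(pixels = x))))
  if (is.matrix(x)) return(x)
  stop("cannot interpret input as tiles or features")
}

#' Predict class probabilities for tiles
#'
#' @param model A `tile_classifier`.
#' @param x A `tile_batch`, list of tiles, single RGB array, or a feature
#'   matrix.
#' @return n x 6 matrix of probabilities (columns in `hcc_classes()`
#'   order; rows sum to 1).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "tile_classifier"))
  f <- as_feature_matrix(x)
  if (is.list(x) && !is.null(x$pixels)) f <- featurize_tiles(list(x))
  n <- nrow(f)
  out <- matrix(0, n, 6, dimnames = list(NULL, model$classes))
  if (model$backend == "constant") {
    out[, model$constant] <- 1
  } else if (model$backend == "ranger") {
    p <- stats::predict(model$fit, data = as.data.frame(f),
                        num.threads = 1)$predictions
    out[, colnames(p)] <- p
  } else {
    xs <- scale(f, model$center, model$scale)
    p <- stats::predict(model$fit, xs)
    out[, model$lev] <- p
  }
  out / rowSums(out)
}

predicted_labels <- function(model, x) {
  p <- predict_proba(model, x)
  model$classes[max.col(p, ties.method = "first")]
}

#' Evaluate a classifier on a labelled test batch
#'
#' @param model A `tile_classifier`.
#' @param test Non-empty labelled `tile_batch`.
#' @return An `eval_report`: `overall_accuracy`, row-normalized 6x6
#'   `confusion` (rows with zero support are NA and listed in
#'   `zero_support`), and `per_class_pr` (curve points + trapezoidal AUC
#'   per class, one-vs-rest).
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(test, "tile_batch"), length(test$labels) > 0)
  truth <- as.character(test$labels)
  bad <- setdiff(unique(truth), hcc_classes())
  if (length(bad)) stop(sprintf("labels outside the six classes: %s",
                                paste(bad, collapse = ", ")))
  probs <- predict_proba(model, test)
  pred <- model$classes[max.col(probs, ties.method = "first")]
  cls <- hcc_classes()
  conf_counts <- table(factor(truth, cls), factor(pred, cls))
  support <- rowSums(conf_counts)
  confusion <- sweep(conf_counts, 1, pmax(support, 1), "/")
  confusion[support == 0, ] <- NA_real_
  pr <- lapply(cls, function(k)
    pr_curve(as.integer(truth == k), probs[, k]))
  names(pr) <- cls
  structure(list(overall_accuracy = mean(pred == truth),
                 confusion = as.matrix(unclass(confusion)),
                 zero_support = cls[support == 0],
                 per_class_pr = pr,
                 n = length(truth)),
            class = "eval_report")
}

# Precision-recall curve and trapezoidal AUC over recall, one-vs-rest.
pr_curve <- function(y, score) {
  P <- sum(y)
  if (P == 0) return(list(recall = numeric(0), precision = numeric(0),
                          auc = NA_real_))
  o <- order(score, decreasing = TRUE)
  y <- y[o]; s <- score[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # one point per threshold
  recall <- tp[keep] / P
  precision <- tp[keep] / (tp[keep] + fp[keep])
  r <- c(0, recall); p <- c(precision[1], precision)
  auc <- sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  list(recall = recall, precision = precision, auc = auc)
}
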