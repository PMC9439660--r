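# Shared fixtures, built once per test run.

.fixtures <- new.env()

# Small trained classifier (96 px tiles), cached across test files.
get_test_model <- function() {
  if (is.null(.fixtures$model)) {
    batch <- synth_tile_batch(40, side = 96, seed = 42)
    sp <- split_dataset(batch, seed = 42)
    .fixtures$model <- train_classifier(sp$train, sp$val,
                                        classifier_config(seed = 42))
  }
  .fixtures$model
}

# Small mixed-composition slide with regions larger than one tile.
get_test_slide <- function() {
  if (is.null(.fixtures$slide))
    .fixtures$slide <- compose_slide(c(0.4, 0.3, 0.1, 0.1, 0.05, 0.05),
                                     480, seed = 5, n_cells = 8)
  .fixtures$slide
}

# Random label grid over the six classes with background holes.
random_label_grid <- function(nr, nc, p_bg = 0.1) {
  lab <- matrix(sample(hcc_classes(), nr * nc, replace = TRUE), nr, nc)
  lab[stats::runif(nr * nc) < p_bg] <- NA_character_
  lab
}

# Wrap a label grid as a classification_map with uniform probabilities.
as_map <- function(labels, slide_id = "t") {
  probs <- array(NA_real_, c(nrow(labels), ncol(labels), 6),
                 dimnames = list(NULL, NULL, hcc_classes()))
  for (i in seq_len(nrow(labels))) for (j in seq_len(ncol(labels))) {
    if (is.na(labels[i, j])) next
    p <- rep(0.02, 6)
    p[match(labels[i, j], hcc_classes())] <- 0.9
    probs[i, j, ] <- p / sum(p)
  }
  histoscore:::new_classification_map(labels, probs, slide_id, 96)
}
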