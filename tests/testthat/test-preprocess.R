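mk_rgb <- function(H, W, col) {
  arr <- array(0, c(H, W, 3))
  for (k in 1:3) arr[, , k] <- col[k]
  arr
}

test_that("tissue mask separates bimodal saturation and degenerates safely", {
  # left half saturation 0.1, right half 0.8 (no blur: exact split)
  img <- mk_rgb(64, 64, c(255, 229.5, 229.5))
  img[, 33:64, 2] <- 51; img[, 33:64, 3] <- 51    # sat 0.8
  m <- tissue_mask(img, blur_sigma = 0)
  expect_true(all(m$mask[, 33:64]))
  expect_false(any(m$mask[, 1:32]))

  white <- mk_rgb(48, 48, c(255, 255, 255))
  expect_equal(sum(tissue_mask(white)$mask), 0)

  expect_error(tissue_mask(matrix(0.5, 10, 10)), "RGB")
})

test_that("tissue mask agrees with generator ground truth", {
  sl <- get_test_slide()
  m <- tissue_mask(sl$image)
  truth <- sl$truth_mask > 0
  jac <- sum(m$mask & truth) / sum(m$mask | truth)
  expect_gte(jac, 0.95)
})

test_that("tile grid follows the coverage rule and grid geometry", {
  img <- mk_rgb(598, 598, c(200, 100, 100))
  full <- matrix(TRUE, 598, 598)
  tiles <- tile_grid(img, full, side = 299)
  expect_length(tiles, 4)
  expect_equal(t(vapply(tiles, function(t) c(t$grid_row, t$grid_col),
                        integer(2))),
               rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))

  none <- matrix(FALSE, 598, 598)
  expect_length(tile_grid(img, none, side = 299), 0)

  img2 <- mk_rgb(299, 897, c(200, 100, 100))
  m2 <- matrix(FALSE, 299, 897); m2[, 1:299] <- TRUE
  tiles2 <- tile_grid(img2, m2, side = 299)
  expect_length(tiles2, 1)
  expect_equal(c(tiles2[[1]]$grid_row, tiles2[[1]]$grid_col), c(0L, 0L))

  expect_error(tile_grid(mk_rgb(100, 100, c(1, 1, 1)), matrix(TRUE, 100, 100),
                         side = 299), "exceeds")
})

test_that("tiling partitions the slide without overlap, deterministically", {
  img <- mk_rgb(300, 400, c(180, 90, 120))
  m <- matrix(TRUE, 300, 400)
  tiles <- tile_grid(img, m, side = 100, min_coverage = 0)
  expect_length(tiles, 12)
  origins <- t(vapply(tiles, function(t) c(t$grid_row, t$grid_col), integer(2)))
  expect_equal(nrow(unique(origins)), 12)
  expect_lte(length(tiles) * 100 * 100, 300 * 400)
  tiles_b <- tile_grid(img, m, side = 100, min_coverage = 0)
  expect_identical(origins, t(vapply(tiles_b, function(t)
    c(t$grid_row, t$grid_col), integer(2))))
})

test_that("stain templates pool masked pixels with population statistics", {
  img <- mk_rgb(64, 64, c(180, 120, 140))
  m <- matrix(TRUE, 64, 64)
  tm <- estimate_template(img, m)
  expect_equal(tm$sds, pmax(c(0, 0, 0), 1e-6))
  expect_equal(as.numeric(tm$means),
               as.numeric(rgb_to_lab(matrix(c(180, 120, 140), 1))))

  # pooling idempotence: duplicating the image leaves the template unchanged
  tm2 <- estimate_template(list(img, img), list(m, m))
  expect_equal(tm$means, tm2$means, tolerance = 1e-12)
  expect_equal(tm$sds, tm2$sds, tolerance = 1e-12)

  expect_error(estimate_template(mk_rgb(10, 10, c(1, 2, 3)),
                                 matrix(TRUE, 10, 10)), "too few")
})

test_that("template means shift monotonically with background lightness and ignore white pixels", {
  recs <- default_recipes()
  lighter <- recs
  lighter$TR$background_color <- pmin(recs$TR$background_color * 1.15, 255)
  s1 <- compose_slide(c(1, 0, 0, 0, 0, 0), 256, seed = 6)
  s2 <- compose_slide(c(1, 0, 0, 0, 0, 0), 256, seed = 6, recipes = lighter)
  m1 <- tissue_mask(s1$image); m2 <- tissue_mask(s2$image)
  t1 <- estimate_template(s1$image, m1)
  t2 <- estimate_template(s2$image, m2)
  expect_gt(t2$means[1], t1$means[1])   # l channel tracks lightness

  # adding pure-white background never changes the template
  pad <- array(255, c(nrow(s1$image) + 80, ncol(s1$image), 3))
  pad[seq_len(nrow(s1$image)), , ] <- s1$image
  mpad <- rbind(m1$mask, matrix(FALSE, 80, ncol(s1$image)))
  tpad <- estimate_template(pad, mpad)
  expect_equal(t1$means, tpad$means, tolerance = 1e-12)
  expect_equal(t1$sds, tpad$sds, tolerance = 1e-12)
})

test_that("Reinhard transfer hits the target statistics and is idempotent", {
  slA <- get_test_slide()
  recsB <- default_recipes()
  for (k in seq_along(recsB))
    recsB[[k]]$background_color <- recsB[[k]]$background_color * 0.9
  slB <- compose_slide(c(0.4, 0.3, 0.1, 0.1, 0.05, 0.05), 480, seed = 12,
                       n_cells = 8, recipes = recsB)
  mA <- tissue_mask(slA$image); mB <- tissue_mask(slB$image)
  tmplB <- estimate_template(slB$image, mB)

  normA <- reinhard_normalize(slA$image, mA, tmplB)
  tmplA2 <- estimate_template(normA, mA)
  expect_lt(max(abs(tmplA2$means - tmplB$means) /
                  pmax(abs(tmplB$means), 1e-2)), 0.01)
  expect_lt(max(abs(tmplA2$sds - tmplB$sds) / tmplB$sds), 0.01)

  # self-transfer is the identity within 2 gray levels
  tmplA <- estimate_template(slA$image, mA)
  selfA <- reinhard_normalize(slA$image, mA, tmplA)
  expect_lte(max(abs(selfA - slA$image)[rep(mA$mask, 3)]), 2)

  # idempotence: normalizing twice equals once within 1 gray level
  normA2 <- reinhard_normalize(normA, mA, tmplB)
  expect_lte(max(abs(normA2 - normA)[rep(mA$mask, 3)]), 1)

  # constant-colour tissue maps exactly onto the target means
  cimg <- mk_rgb(64, 64, c(150, 100, 160))
  cm <- matrix(TRUE, 64, 64)
  mapped <- reinhard_normalize(cimg, cm, tmplB)
  expect_equal(as.numeric(mapped[1, 1, ]),
               as.numeric(lab_to_rgb(matrix(tmplB$means, 1))),
               tolerance = 1e-6)

  expect_warning(out <- reinhard_normalize(cimg, matrix(FALSE, 64, 64), tmplB),
                 "empty")
  expect_identical(out, cimg)
})

test_that("dihedral augmentation balances classes without fabricating content", {
  mk_tile <- function(seed) render_tile(default_recipes()$TR, 32, seed)
  tiles <- list(TR = lapply(1:10, mk_tile),
                LA = lapply(11:15, function(s)
                  render_tile(default_recipes()$LA, 32, s)))
  bal <- augment_balance(tiles, seed = 1)
  expect_equal(vapply(bal, length, integer(1)), c(TR = 10L, LA = 10L))

  # every augmented tile is a dihedral transform of an original
  for (i in 6:10) {
    aug <- bal$LA[[i]]$pixels
    match_found <- any(vapply(tiles$LA, function(orig)
      any(vapply(0:7, function(t)
        identical(histoscore:::apply_dihedral(orig$pixels, t), aug),
        logical(1))), logical(1)))
    expect_true(match_found)
  }

  balanced <- list(TR = tiles$TR, LA = tiles$TR)
  expect_identical(augment_balance(balanced, seed = 2), balanced)
  expect_error(augment_balance(list(TR = tiles$TR, LA = list()), seed = 1),
               "LA")
})
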