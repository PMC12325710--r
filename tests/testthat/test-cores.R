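make_test_slide <- function(scores = c(0, 1, 2, 3, 2, 1), seed = 4) {
  lay <- core_layout(2, 3, pitch_um = 320, core_diameter_um = 220)
  list(layout = lay,
       gen = generate_slide(lay, scores, seed = seed, margin_um = 70))
}

test_that("white balance removes a constant color cast and is idempotent", {
  sl <- make_test_slide()$gen$slide
  wb1 <- white_balance(sl)
  # already-white input is left unchanged within one gray level
  wb2 <- white_balance(wb1)
  expect_lt(max(abs(wb2$rgb - wb1$rgb)), 1 / 255)
  # synthetic cast is removed: background returns to white
  cast <- sl
  for (k in 1:3) cast$rgb[, , k] <- clip_cast <- pmax(sl$rgb[, , k] - c(0.1, 0.05, 0)[k], 0)
  wbc <- white_balance(cast)
  bg_band <- wbc$rgb[1:40, 1:40, ]
  expect_lt(max(abs(apply(bg_band, 3, mean) - 1)), 1 / 255)
  # a slide with no clean background block errors
  noisy <- structure(list(rgb = array(stats::runif(200 * 200 * 3, 0, 0.6),
                                      c(200, 200, 3))), class = "slide_image")
  expect_error(white_balance(noisy), "no-background")
})

test_that("tissue bbox finds a dark disk within smoothing tolerance", {
  img <- array(1, c(512, 512, 3))
  ctr <- 256; rad <- 50
  for (y in (ctr - rad):(ctr + rad)) for (x in (ctr - rad):(ctr + rad))
    if ((y - ctr)^2 + (x - ctr)^2 <= rad^2) img[y, x, ] <- 0.3
  bb <- find_tissue_bbox(img, blur_sigma = 3)
  tol <- 3 + 2
  expect_lt(abs(bb$min_x - (ctr - rad - 1)), tol)
  expect_lt(abs(bb$max_x - (ctr + rad)), tol)
  expect_lt(abs(bb$min_y - (ctr - rad - 1)), tol)
  expect_lt(abs(bb$max_y - (ctr + rad)), tol)
  expect_error(find_tissue_bbox(array(1, c(128, 128, 3))), "empty-tissue")
})

test_that("bbox of a slide contains every manifest core center", {
  ts <- make_test_slide()
  wb <- white_balance(ts$gen$slide)
  bb <- find_tissue_bbox(wb)
  man <- ts$gen$manifest$cores
  expect_true(all(man$center_x_um >= bb$min_x & man$center_x_um < bb$max_x))
  expect_true(all(man$center_y_um >= bb$min_y & man$center_y_um < bb$max_y))
})

test_that("grid segmentation partitions the bbox equally", {
  bb <- structure(list(min_x = 0L, min_y = 0L, max_x = 600L, max_y = 400L),
                  class = "tissue_bbox")
  cells <- segment_grid(bb, core_layout(2, 3, 300, 200))
  expect_equal(nrow(cells), 6)
  expect_true(all(cells$x1 - cells$x0 == 200))
  expect_true(all(cells$y1 - cells$y0 == 200))
  expect_equal(cells$grid_row, rep(1:2, each = 3))
  one <- segment_grid(bb, core_layout(1, 1, 300, 200))
  expect_equal(unlist(one[1, c("x0", "y0", "x1", "y1")], use.names = FALSE),
               c(0, 0, 600, 400))
  expect_error(segment_grid(bb, core_layout(100, 100, 300, 200)),
               "cell-too-small")
})

test_that("each core center falls in its own grid cell", {
  ts <- make_test_slide()
  wb <- white_balance(ts$gen$slide)
  bb <- find_tissue_bbox(wb)
  cells <- segment_grid(bb, ts$layout)
  man <- ts$gen$manifest$cores
  for (i in seq_len(nrow(man))) {
    cl <- cells[cells$grid_row == man$grid_row[i] &
                cells$grid_col == man$grid_col[i], ]
    expect_true(man$center_x_um[i] >= cl$x0 && man$center_x_um[i] < cl$x1)
    expect_true(man$center_y_um[i] >= cl$y0 && man$center_y_um[i] < cl$y1)
  }
})

test_that("crop_and_label emits one labeled crop per occupied cell", {
  ts <- make_test_slide()
  wb <- white_balance(ts$gen$slide)
  cells <- segment_grid(find_tissue_bbox(wb), ts$layout)
  crops <- crop_and_label(wb, cells, ts$gen$manifest, repeat_index = 2)
  expect_length(crops, 6)
  for (cr in crops) {
    rec <- ts$gen$manifest$cores
    idx <- which(rec$grid_row == cr$grid_row & rec$grid_col == cr$grid_col)
    expect_equal(cr$her2_score, rec$her2_score[idx])
    expect_equal(cr$repeat_index, 2L)
  }
  # a missing core is skipped without error
  ts2 <- make_test_slide(scores = c(0, 1, NA, 3, 2, 1))
  wb2 <- white_balance(ts2$gen$slide)
  cells2 <- segment_grid(find_tissue_bbox(wb2), ts2$layout)
  expect_length(crop_and_label(wb2, cells2, ts2$gen$manifest), 5)
  # manifest grid larger than the segmented grid
  bad <- ts$gen$manifest
  bad$cores$grid_row[1] <- 4L
  expect_error(crop_and_label(wb, cells, bad), "label-mismatch")
})

test_that("stain statistic is invariant to white-balance offsets", {
  core <- render_core(her2_appearance_params(), 3, 220, 1, seed = 6)
  s0 <- stain_statistic(core)
  cast <- core
  for (k in 1:3) cast[, , k] <- pmax(core[, , k] - c(0.08, 0.04, 0.02)[k], 0)
  expect_lt(abs(stain_statistic(cast) - s0), 0.01)
  expect_gt(s0, 0.05)
})
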