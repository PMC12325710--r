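# Tissue-core extraction: white balance, tissue bounding box, grid
# segmentation against the layout, and labeled per-core crops.

get_rgb <- function(x) {
  if (is.list(x) && !is.null(x$rgb)) x$rgb else as_rgb(x)
}
set_rgb <- function(x, rgb) {
  if (is.list(x) && !is.null(x$rgb)) { x$rgb <- rgb; x } else rgb
}

# brightest low-variance block of the image; NULL when the slide is fully
# covered by tissue. Returns per-channel mean of the sampled region.
find_background_block <- function(img, block = 64L, sd_tol = 0.02) {
  img <- as_rgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  block <- min(block, h, w)
  ys <- seq(1L, h - block + 1L, by = block)
  xs <- seq(1L, w - block + 1L, by = block)
  best <- NULL; best_gray <- -Inf
  for (y in ys) for (x in xs) {
    blk <- img[y:(y + block - 1L), x:(x + block - 1L), , drop = FALSE]
    sds <- apply(blk, 3, stats::sd)
    if (max(sds) > sd_tol) next
    mu <- apply(blk, 3, mean)
    g <- sum(mu * c(0.299, 0.587, 0.114))
    if (g > best_gray) { best_gray <- g; best <- mu }
  }
  best
}

#' White-balance a mosaic against its own background
#'
#' Samples a region devoid of tissue (the brightest low-variance block) and
#' subtracts its offset from pure white from the whole image, ensuring a
#' uniform white background. Values are clipped to \[0, 1\]. Idempotent up
#' to one gray level.
#'
#' @param mosaic RGB array, or any object with an `$rgb` field
#'   (`slide_image`, `mosaic`).
#' @param block background sampling block size in pixels.
#' @param sd_tol maximum per-channel standard deviation for a block to count
#'   as background.
#' @return same type as the input, white-balanced.
#' @export
white_balance <- function(mosaic, block = 64L, sd_tol = 0.02) {
  img <- get_rgb(mosaic)
  bg <- find_background_block(img, block, sd_tol)
  if (is.null(bg))
    stop("no-background: no tissue-free region found to sample", call. = FALSE)
  out <- img
  for (k in 1:3) out[, , k] <- clip01(img[, , k] + (1 - bg[k]))
  set_rgb(mosaic, out)
}

#' Locate the tissue bounding box
#'
#' Grayscale -> global (Otsu) threshold -> Gaussian smoothing of the binary
#' mask -> re-threshold -> clear components touching the border -> bounding
#' box of the union of the remaining components.
#'
#' @param mosaic white-balanced RGB array or object with `$rgb`.
#' @param blur_sigma smoothing sigma in pixels.
#' @param border_margin_px components within this margin of the border are
#'   cleared.
#' @param min_area_px components smaller than this are discarded.
#' @param max_fg_gray if the mean gray of thresholded foreground exceeds
#'   this, the slide is considered tissue-free.
#' @return object of class `tissue_bbox`: `min_x, min_y, max_x, max_y`
#'   (0-based pixel coordinates, half-open).
#' @export
find_tissue_bbox <- function(mosaic, blur_sigma = 3, border_margin_px = 2L,
                             min_area_px = 30L, max_fg_gray = 0.92) {
  img <- get_rgb(mosaic)
  gray <- rgb_to_gray(img)
  thr <- otsu_threshold(gray)
  mask <- gray < thr
  if (!any(mask) || mean(gray[mask]) > max_fg_gray)
    stop("empty-tissue: no foreground found after thresholding", call. = FALSE)
  sm <- gaussian_smooth(mask * 1, blur_sigma)
  mask <- sm > 0.5
  if (!any(mask))
    stop("empty-tissue: no foreground after smoothing", call. = FALSE)
  lab <- label_components(mask)
  h <- nrow(lab); w <- ncol(lab)
  m <- border_margin_px
  border_ids <- unique(c(lab[seq_len(min(m, h)), ], lab[(h - min(m, h) + 1L):h, ],
                         lab[, seq_len(min(m, w))], lab[, (w - min(m, w) + 1L):w]))
  border_ids <- setdiff(border_ids, 0L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- setdiff(which(sizes >= min_area_px), border_ids)
  if (length(keep) == 0L)
    stop("empty-tissue: all components cleared at the border", call. = FALSE)
  sel <- matrix(lab %in% keep, nrow(lab))
  rows <- which(rowSums(sel) > 0L)
  cols <- which(colSums(sel) > 0L)
  structure(list(min_x = min(cols) - 1L, min_y = min(rows) - 1L,
                 max_x = max(cols), max_y = max(rows)),
            class = "tissue_bbox")
}

#' Divide a tissue bounding box into the layout grid
#'
#' The box is partitioned into `n_rows x n_cols` equal rectangles in reading
#' order, mirroring the layout diagram accompanying the array.
#'
#' @param bbox `tissue_bbox`.
#' @param layout `core_layout`.
#' @param min_cell_px error if a cell side falls below this.
#' @return data.frame with `grid_row`, `grid_col`, `x0`, `y0`, `x1`, `y1`
#'   (0-based, half-open).
#' @export
segment_grid <- function(bbox, layout, min_cell_px = 8L) {
  stopifnot(inherits(bbox, "tissue_bbox"), inherits(layout, "core_layout"))
  wx <- bbox$max_x - bbox$min_x
  wy <- bbox$max_y - bbox$min_y
  if (wx / layout$n_cols < min_cell_px || wy / layout$n_rows < min_cell_px)
    stop("cell-too-small: grid cells below the minimum size", call. = FALSE)
  xb <- round(bbox$min_x + wx * (0:layout$n_cols) / layout$n_cols)
  yb <- round(bbox$min_y + wy * (0:layout$n_rows) / layout$n_rows)
  cells <- expand.grid(grid_col = seq_len(layout$n_cols),
                       grid_row = seq_len(layout$n_rows))
  data.frame(grid_row = cells$grid_row, grid_col = cells$grid_col,
             x0 = xb[cells$grid_col], y0 = yb[cells$grid_row],
             x1 = xb[cells$grid_col + 1L], y1 = yb[cells$grid_row + 1L])
}

#' Binary tissue mask
#'
#' Pixels darker than `threshold` in grayscale; intended for white-balanced
#' images where the background sits at 1.0.
#'
#' @param img RGB array or object with `$rgb`.
#' @param threshold gray cutoff; the default sits between the faint tissue
#'   tint (~0.93 after white balance) and the background (1.0), so whole
#'   core disks — not just stained cells — count as tissue.
#' @return logical matrix.
#' @export
tissue_mask <- function(img, threshold = 0.96) {
  rgb_to_gray(get_rgb(img)) < threshold
}

#' Crop and label tissue cores
#'
#' One labeled crop per occupied grid cell; cells whose tissue fraction
#' falls below `min_tissue_frac` are treated as gaps and skipped.
#'
#' @param mosaic white-balanced RGB array or object with `$rgb`.
#' @param cells grid cells from [segment_grid()].
#' @param manifest `tma_manifest` supplying `her2_score` per (grid_row,
#'   grid_col); must cover every occupied cell and must not address grid
#'   positions outside the cell grid.
#' @param repeat_index scan repeat recorded on each crop.
#' @param min_tissue_frac occupancy threshold for a cell to count as a core.
#' @return list of `labeled_core` objects (`core_id`, `rgb`, `her2_score`,
#'   `grid_row`, `grid_col`, `repeat_index`).
#' @export
crop_and_label <- function(mosaic, cells, manifest, repeat_index = 1L,
                           min_tissue_frac = 0.02) {
  img <- get_rgb(mosaic)
  stopifnot(inherits(manifest, "tma_manifest"))
  cores <- manifest$cores
  if (nrow(cores) > 0L &&
      (max(cores$grid_row) > max(cells$grid_row) ||
       max(cores$grid_col) > max(cells$grid_col)))
    stop("label-mismatch: manifest grid exceeds the segmented grid", call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    crop <- img[(cl$y0 + 1L):cl$y1, (cl$x0 + 1L):cl$x1, , drop = FALSE]
    if (mean(tissue_mask(crop)) < min_tissue_frac) next
    hit <- which(cores$grid_row == cl$grid_row & cores$grid_col == cl$grid_col)
    if (length(hit) == 0L)
      stop("label-mismatch: occupied cell (", cl$grid_row, ",", cl$grid_col,
           ") has no manifest record", call. = FALSE)
    rec <- cores[hit[1L], ]
    out[[length(out) + 1L]] <- structure(
      list(core_id = rec$core_id, rgb = crop,
           her2_score = as.integer(rec$her2_score),
           grid_row = rec$grid_row, grid_col = rec$grid_col,
           repeat_index = as.integer(repeat_index)),
      class = "labeled_core")
  }
  out
}

#' Brown-stain statistic
#'
#' The module's quantitative staining readout: after normalizing the image
#' so its sampled background maps to white, the mean over the tissue mask of
#' `max(0, 1 - blue/red)`. DAB brown attenuates blue more than red, so the
#' statistic grows with membrane stain level and completeness; blue
#' (hematoxylin) nuclei are clamped to zero contribution. Because the image
#' is re-normalized internally, the statistic is invariant to white-balance
#' offsets by construction.
#'
#' @param img RGB array or object with `$rgb`.
#' @param mask optional logical tissue mask; computed from the normalized
#'   image by default.
#' @return scalar statistic (0 when no tissue is present).
#' @export
stain_statistic <- function(img, mask = NULL) {
  img <- get_rgb(img)
  bg <- find_background_block(img, block = 32L)  # fits single-core images
  if (!is.null(bg)) for (k in 1:3) img[, , k] <- clip01(img[, , k] + (1 - bg[k]))
  if (is.null(mask)) mask <- tissue_mask(img, 0.97)
  if (!any(mask)) return(0)
  r <- img[, , 1][mask]
  b <- img[, , 3][mask]
  mean(pmax(0, 1 - b / pmax(r, 1e-6)))
}
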