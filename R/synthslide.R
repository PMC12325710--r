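# Synthetic HER2-stained TMA slide generator.
#
# Slides emulate immunohistochemistry appearance at the level the HER2 score
# is defined on: brown (DAB) membrane staining whose intensity and
# circumferential completeness increase with score 0 -> 3+, blue
# (hematoxylin) nuclei, pale near-white background. The rendering is
# stylized (rings + disks), not histologically realistic, but the class
# signal is the clinically meaningful one.

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are pure
#' functions of their (parameters, seed).
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# deterministic 31-bit seed derived from a base seed and arbitrary strings
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (tok in unlist(list(...))) {
    for (v in utf8ToInt(as.character(tok))) s <- (s * 69069 + v) %% 2147483647
  }
  as.integer(s)
}

#' Default HER2 appearance parameters
#'
#' Per-score rendering parameters for scores 0, 1+, 2+, 3+. Membrane stain
#' level (brown darkening, in \[0,1\]) and membrane completeness (fraction of
#' each cell ring that is stained) are strictly increasing in score; cell
#' density and nuclear staining are score-independent.
#'
#' @param membrane_stain_level numeric\[4\], brown attenuation exponent per score.
#' @param membrane_completeness numeric\[4\], stained ring fraction per score.
#' @param cell_density cells per mm^2 (recycled to length 4).
#' @param nucleus_stain_level blue attenuation exponent in \[0,1\].
#' @param background_rgb near-white background triplet (each >= 0.9).
#' @param tissue_tint multiplicative tint of the tissue disk (counterstain haze).
#' @param background_noise_sd slide-level texture noise (fraction of full scale).
#' @return object of class `her2_params`.
#' @export
her2_appearance_params <- function(membrane_stain_level = c(0.06, 0.28, 0.55, 0.85),
                                   membrane_completeness = c(0.10, 0.35, 0.70, 0.95),
                                   cell_density = 2000,
                                   nucleus_stain_level = 0.55,
                                   background_rgb = c(0.97, 0.96, 0.95),
                                   tissue_tint = c(0.93, 0.90, 0.94),
                                   background_noise_sd = 0.003) {
  stopifnot(length(membrane_stain_level) == 4L, length(membrane_completeness) == 4L)
  if (any(membrane_stain_level < 0 | membrane_stain_level > 1) ||
      any(membrane_completeness < 0 | membrane_completeness > 1) ||
      nucleus_stain_level < 0 || nucleus_stain_level > 1)
    stop("stain levels must lie in [0, 1]", call. = FALSE)
  if (any(background_rgb < 0.9))
    stop("background_rgb channels must be >= 0.9", call. = FALSE)
  structure(list(
    membrane_stain_level = membrane_stain_level,
    membrane_completeness = membrane_completeness,
    cell_density = rep_len(cell_density, 4L),
    nucleus_stain_level = nucleus_stain_level,
    background_rgb = background_rgb,
    tissue_tint = tissue_tint,
    background_noise_sd = background_noise_sd,
    # reference chromogen colors (sRGB-ish): DAB brown, hematoxylin blue
    dab_rgb = c(0.45, 0.30, 0.14),
    hematoxylin_rgb = c(0.40, 0.45, 0.80),
    cell_radius_um = 7, nucleus_radius_um = 3.2, membrane_thickness_um = 1.8
  ), class = "her2_params")
}

#' TMA core grid layout
#'
#' @param n_rows,n_cols grid dimensions.
#' @param pitch_um center-to-center spacing; must exceed `core_diameter_um`
#'   so cores stay fully separated in the stitched mosaic.
#' @param core_diameter_um core diameter.
#' @param origin_um length-2 (x, y) position of the top-left core center.
#' @return object of class `core_layout`.
#' @export
core_layout <- function(n_rows, n_cols, pitch_um = 400, core_diameter_um = 260,
                        origin_um = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  if (pitch_um <= core_diameter_um)
    stop("pitch_um must exceed core_diameter_um (cores must be separated)",
         call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pitch_um = pitch_um, core_diameter_um = core_diameter_um,
                 origin_um = origin_um),
            class = "core_layout")
}

#' Render one synthetic tissue core
#'
#' Draws a circular tissue region of the stated diameter: a lightly tinted
#' disk, hematoxylin-blue nuclei, and DAB-brown membrane rings whose
#' darkening and arc completeness follow the appearance parameters for the
#' given score. Staining is applied as multiplicative attenuation by the
#' chromogen color raised to the stain level, so staining only ever darkens
#' and the operation is monotone in the level.
#'
#' @param params `her2_params` object.
#' @param score HER2 score in `{0, 1, 2, 3}`.
#' @param diameter_um core diameter (> 0).
#' @param pixel_size_um microns per pixel.
#' @param seed RNG seed; output is a pure function of arguments.
#' @return RGB array of side `round(diameter_um / pixel_size_um)`.
#' @export
render_core <- function(params, score, diameter_um = 260, pixel_size_um = 1,
                        seed = 1) {
  if (length(score) != 1L || !score %in% 0:3)
    stop("invalid-score: score must be one of 0, 1, 2, 3", call. = FALSE)
  stopifnot(diameter_um > 0, pixel_size_um > 0)
  si <- score + 1L
  n <- max(4L, round(diameter_um / pixel_size_um))
  R <- n / 2
  cx <- (n + 1) / 2
  xg <- matrix(seq_len(n), n, n, byrow = TRUE) - cx   # x offset per pixel
  yg <- matrix(seq_len(n), n, n) - cx
  d2 <- xg^2 + yg^2
  tissue <- d2 <= R^2
  img <- array(rep(params$background_rgb, each = n * n), c(n, n, 3L))
  for (k in 1:3) {
    ch <- img[, , k]
    ch[tissue] <- ch[tissue] * params$tissue_tint[k]
    img[, , k] <- ch
  }
  with_seed(seed, {
    r_cell <- params$cell_radius_um / pixel_size_um
    r_nuc <- params$nucleus_radius_um / pixel_size_um
    half_t <- max(0.75, params$membrane_thickness_um / (2 * pixel_size_um))
    area_mm2 <- pi * (diameter_um / 2000)^2
    n_cells <- max(0L, round(params$cell_density[si] * area_mm2))
    level <- params$membrane_stain_level[si]
    compl <- params$membrane_completeness[si]
    dab <- params$dab_rgb^level
    hem <- params$hematoxylin_rgb^params$nucleus_stain_level
    if (n_cells > 0) {
      # uniform positions inside the disk, cells kept fully inside the tissue
      rr <- (R - r_cell - half_t) * sqrt(stats::runif(n_cells))
      th <- stats::runif(n_cells, 0, 2 * pi)
      cxs <- cx + rr * cos(th)
      cys <- cx + rr * sin(th)
      sizes <- stats::runif(n_cells, 0.85, 1.15)
      arc0 <- stats::runif(n_cells, 0, 2 * pi)
      for (i in seq_len(n_cells)) {
        rc <- r_cell * sizes[i]
        x0 <- max(1L, floor(cxs[i] - rc - half_t - 1))
        x1 <- min(n, ceiling(cxs[i] + rc + half_t + 1))
        y0 <- max(1L, floor(cys[i] - rc - half_t - 1))
        y1 <- min(n, ceiling(cys[i] + rc + half_t + 1))
        lx <- matrix(x0:x1, y1 - y0 + 1L, x1 - x0 + 1L, byrow = TRUE) - cxs[i]
        ly <- matrix(y0:y1, y1 - y0 + 1L, x1 - x0 + 1L) - cys[i]
        ld <- sqrt(lx^2 + ly^2)
        nuc <- ld <= r_nuc * sizes[i]
        memb <- abs(ld - rc) <= half_t
        if (compl < 1 && any(memb)) {
          ang <- (atan2(ly, lx) - arc0[i]) %% (2 * pi)
          memb <- memb & (ang <= compl * 2 * pi)
        } else if (compl == 0) memb[] <- FALSE
        for (k in 1:3) {
          blk <- img[y0:y1, x0:x1, k]
          blk[nuc] <- blk[nuc] * hem[k]
          blk[memb] <- blk[memb] * dab[k]
          img[y0:y1, x0:x1, k] <- blk
        }
      }
    }
    if (params$background_noise_sd > 0) {
      img <- clip01(img + array(stats::rnorm(n * n * 3, 0, params$background_noise_sd),
                                c(n, n, 3L)))
    }
  })
  img
}

#' Generate a synthetic TMA slide and its ground-truth manifest
#'
#' Renders each core at its grid center on a uniform near-white background.
#'
#' @param layout `core_layout` object.
#' @param scores integer vector of length `n_rows * n_cols` in row-major
#'   (reading) order; `NA` marks an absent core (gap).
#' @param params `her2_params` appearance parameters.
#' @param pixel_size_um microns per pixel (default 1, so a 640 x 480 px frame
#'   covers 640 x 480 um).
#' @param seed base RNG seed; each core's seed is derived from it.
#' @param margin_um background margin around the core grid.
#' @param split split tag recorded in the manifest (`"train"` or `"test"`).
#' @param max_pixels guard on raster size; exceeding it is an error.
#' @return list with `slide` (class `slide_image`: `$rgb`, `$pixel_size_um`,
#'   `$background_rgb`) and `manifest` (class `tma_manifest`).
#' @export
generate_slide <- function(layout, scores, params = her2_appearance_params(),
                           pixel_size_um = 1, seed = 1, margin_um = 100,
                           split = "train", max_pixels = 1.2e8) {
  stopifnot(inherits(layout, "core_layout"))
  if (length(scores) != layout$n_rows * layout$n_cols)
    stop("scores must have n_rows * n_cols entries (NA for gaps)", call. = FALSE)
  if (!all(is.na(scores) | scores %in% 0:3))
    stop("invalid-score: scores must be in {0,1,2,3} or NA", call. = FALSE)
  dia <- layout$core_diameter_um
  origin <- layout$origin_um
  if (is.null(origin)) origin <- c(margin_um + dia / 2, margin_um + dia / 2)
  w_um <- origin[1] + (layout$n_cols - 1L) * layout$pitch_um + dia / 2 + margin_um
  h_um <- origin[2] + (layout$n_rows - 1L) * layout$pitch_um + dia / 2 + margin_um
  W <- ceiling(w_um / pixel_size_um); H <- ceiling(h_um / pixel_size_um)
  if (as.double(W) * H > max_pixels)
    stop("size error: layout extent exceeds maximum raster size", call. = FALSE)
  img <- array(rep(params$background_rgb, each = H * W), c(H, W, 3L))
  rec <- list()
  idx <- 0L
  for (r in seq_len(layout$n_rows)) for (cc in seq_len(layout$n_cols)) {
    idx <- idx + 1L
    sc <- scores[idx]
    if (is.na(sc)) next
    cx_um <- origin[1] + (cc - 1L) * layout$pitch_um
    cy_um <- origin[2] + (r - 1L) * layout$pitch_um
    core_id <- sprintf("R%02dC%02d", r, cc)
    core <- render_core(params, sc, dia, pixel_size_um,
                        seed = derive_seed(seed, core_id))
    nside <- dim(core)[1]
    x0 <- round(cx_um / pixel_size_um - nside / 2)
    y0 <- round(cy_um / pixel_size_um - nside / 2)
    img[y0 + seq_len(nside), x0 + seq_len(nside), ] <- core
    rec[[length(rec) + 1L]] <- data.frame(
      core_id = core_id, grid_row = r, grid_col = cc,
      center_x_um = cx_um, center_y_um = cy_um,
      her2_score = as.integer(sc), split = split,
      stringsAsFactors = FALSE)
  }
  cores <- if (length(rec)) do.call(rbind, rec) else
    data.frame(core_id = character(), grid_row = integer(), grid_col = integer(),
               center_x_um = double(), center_y_um = double(),
               her2_score = integer(), split = character(),
               stringsAsFactors = FALSE)
  manifest <- structure(list(cores = cores, scans = NULL), class = "tma_manifest")
  slide <- structure(list(rgb = img, pixel_size_um = pixel_size_um,
                          background_rgb = params$background_rgb),
                     class = "slide_image")
  list(slide = slide, manifest = manifest)
}

#' Add per-repeat scan records to a manifest
#'
#' @param manifest `tma_manifest`.
#' @param n_repeats repeats per core (the scanner protocol uses 3).
#' @return manifest with `$scans` holding one record per (core, repeat).
#' @export
add_scan_records <- function(manifest, n_repeats = 3) {
  stopifnot(inherits(manifest, "tma_manifest"), n_repeats >= 0)
  cores <- manifest$cores
  if (nrow(cores) == 0L || n_repeats == 0L) {
    manifest$scans <- cores[integer(0), ]
    manifest$scans$repeat_index <- integer(0)
    return(manifest)
  }
  scans <- cores[rep(seq_len(nrow(cores)), each = n_repeats), ]
  scans$repeat_index <- rep(seq_len(n_repeats), nrow(cores))
  rownames(scans) <- NULL
  manifest$scans <- scans
  manifest
}

#' Number of scan records in a manifest
#' @param manifest `tma_manifest`.
#' @return integer count (0 if scanning records are absent).
#' @export
n_scan_records <- function(manifest) {
  if (is.null(manifest$scans)) 0L else nrow(manifest$scans)
}

#' Generate a dataset bookkeeping manifest
#'
#' Creates `n_train + n_test` core records with disjoint splits, random
#' scores, and `n_repeats` scan records per core. With the study-scale
#' defaults (1144 training cores, 284 test cores, 3 repeats) this yields
#' 3N = 4284 scan records.
#'
#' @param n_train,n_test core counts per split (>= 0).
#' @param n_repeats scan repeats per core.
#' @param seed RNG seed for the score assignment.
#' @param layout optional `core_layout` used for grid positions; by default
#'   cores are arranged in a near-square grid at 400 um pitch.
#' @return `tma_manifest` with `$cores` and `$scans`.
#' @export
generate_dataset_manifest <- function(n_train = 1144, n_test = 284,
                                      n_repeats = 3, seed = 1, layout = NULL) {
  if (n_train < 0 || n_test < 0 || n_repeats < 0)
    stop("counts must be non-negative", call. = FALSE)
  n <- n_train + n_test
  if (n == 0L) {
    m <- structure(list(cores = data.frame(core_id = character(),
                                           grid_row = integer(), grid_col = integer(),
                                           center_x_um = double(), center_y_um = double(),
                                           her2_score = integer(), split = character(),
                                           stringsAsFactors = FALSE),
                        scans = NULL), class = "tma_manifest")
    return(add_scan_records(m, n_repeats))
  }
  if (is.null(layout)) {
    ncol_g <- ceiling(sqrt(n))
    nrow_g <- ceiling(n / ncol_g)
    layout <- core_layout(nrow_g, ncol_g)
  }
  gi <- seq_len(n) - 1L
  gr <- gi %/% layout$n_cols + 1L
  gc <- gi %% layout$n_cols + 1L
  origin <- layout$origin_um
  if (is.null(origin)) origin <- c(layout$core_diameter_um / 2 + 100,
                                   layout$core_diameter_um / 2 + 100)
  scores <- with_seed(seed, sample(0:3, n, replace = TRUE))
  cores <- data.frame(
    core_id = sprintf("core%05d", seq_len(n)),
    grid_row = gr, grid_col = gc,
    center_x_um = origin[1] + (gc - 1L) * layout$pitch_um,
    center_y_um = origin[2] + (gr - 1L) * layout$pitch_um,
    her2_score = as.integer(scores),
    split = rep(c("train", "test"), c(n_train, n_test)),
    stringsAsFactors = FALSE)
  add_scan_records(structure(list(cores = cores, scans = NULL),
                             class = "tma_manifest"), n_repeats)
}

#' Write / read a ground-truth manifest as CSV
#'
#' Header: `core_id,grid_row,grid_col,center_x_um,center_y_um,her2_score,split`
#' plus `repeat_index` when scan records are present (one row per scan
#' record in that case).
#'
#' @param manifest `tma_manifest`.
#' @param path CSV path.
#' @return `path` invisibly; `read_manifest` returns a `tma_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "tma_manifest"))
  df <- if (!is.null(manifest$scans)) manifest$scans else manifest$cores
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("repeat_index" %in% names(df)) {
    cores <- unique(df[, setdiff(names(df), "repeat_index")])
    rownames(cores) <- NULL
    structure(list(cores = cores, scans = df), class = "tma_manifest")
  } else {
    structure(list(cores = df, scans = NULL), class = "tma_manifest")
  }
}
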