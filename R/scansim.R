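# Continuous zigzag scan simulation.
#
# The stage moves at constant speed s_x along alternating directions while
# the camera records at a fixed frame rate; each exposure of duration T
# smears the image along the scan direction over a distance s_x * T. The
# blurred frame is the crisp frame convolved along x with a 1-D rectangular
# kernel of that width, normalized to unit sum. Rows alternate direction
# (zigzag), so the blur orientation flips row to row.

#' Scan configuration
#'
#' Defaults reproduce the reference instrument geometry: 5000 um/s stage
#' speed, 7.8 ms exposure (blur width 39 um), 30 fps at 640 x 480 pixels,
#' 1 um/px effective pixel size, 0.5 s pauses bracketing each scan line, and
#' a vertical row step of 80% of the frame height (20% row overlap).
#'
#' @param s_x stage speed in um/s (>= 0).
#' @param T exposure (acquisition) time in seconds; must satisfy `T <= 1/fps`.
#' @param fps camera frame rate (1/s).
#' @param fov_px frame width and height in pixels, `c(w, h)`.
#' @param pixel_size_um microns per pixel (isotropic).
#' @param pause_s stage dwell before and after each scan line, seconds.
#' @param row_step_um vertical advance between scan lines; must not exceed
#'   the frame height (no coverage gaps).
#' @param jitter list with numeric fields `ax, fx, ay, fy` (amplitudes in um,
#'   frequencies in Hz) modeling oscillatory stage ringing; all zero by
#'   default (deterministic scan).
#' @return object of class `scan_config`.
#' @export
scan_config <- function(s_x = 5000, T = 0.0078, fps = 30,
                        fov_px = c(640L, 480L), pixel_size_um = 1,
                        pause_s = 0.5, row_step_um = NULL,
                        jitter = list(ax = 0, fx = 0, ay = 0, fy = 0)) {
  if (s_x < 0) stop("invalid-config: s_x must be >= 0", call. = FALSE)
  if (T <= 0 || fps <= 0) stop("invalid-config: T and fps must be positive", call. = FALSE)
  if (T > 1 / fps + 1e-12)
    stop("invalid-config: exposure T cannot exceed the frame interval 1/fps", call. = FALSE)
  if (pixel_size_um <= 0) stop("invalid-config: pixel_size_um must be positive", call. = FALSE)
  fov_um <- fov_px * pixel_size_um
  if (is.null(row_step_um)) row_step_um <- 0.8 * fov_um[2]
  if (row_step_um > fov_um[2])
    stop("coverage-gap: row_step_um exceeds the frame height", call. = FALSE)
  structure(list(s_x = s_x, T = T, fps = fps, fov_px = as.integer(fov_px),
                 pixel_size_um = pixel_size_um, pause_s = pause_s,
                 row_step_um = row_step_um, jitter = jitter),
            class = "scan_config")
}

#' Motion-blur width
#'
#' The physical distance the stage travels during one exposure, `s_x * T`;
#' the support of the rectangular blur kernel. At the default operating
#' point (5000 um/s, 7.8 ms) this is 39 um.
#'
#' @param s_x stage speed in um/s.
#' @param T exposure time in s.
#' @return blur width in um.
#' @export
blur_width <- function(s_x, T) {
  if (s_x < 0) stop("invalid-config: s_x must be >= 0", call. = FALSE)
  if (T <= 0) stop("invalid-config: T must be positive", call. = FALSE)
  s_x * T
}

#' Rectangular blur kernel
#'
#' @param width_um physical blur width `s_x * T` in um.
#' @param pixel_size_um microns per pixel.
#' @param direction `"+x"` (kernel averages forward along x) or `"-x"`.
#' @return object of class `blur_kernel` with `width_um`, `width_px`
#'   (`max(1, round(width_um / pixel_size_um))`) and `direction`; the kernel
#'   weights are the discrete rect of that width normalized to sum 1.
#' @export
blur_kernel <- function(width_um, pixel_size_um = 1, direction = "+x") {
  if (width_um < 0) stop("invalid-kernel: width must be >= 0", call. = FALSE)
  direction <- match.arg(direction, c("+x", "-x"))
  structure(list(width_um = width_um,
                 width_px = max(1L, as.integer(round(width_um / pixel_size_um))),
                 direction = direction),
            class = "blur_kernel")
}

#' Apply directional rectangular motion blur
#'
#' Each image row of each channel is convolved along x with the normalized
#' rect; for direction `"+x"` output pixel x averages input columns
#' `x .. x+w-1` (the content swept during the exposure), mirrored for
#' `"-x"`. Boundaries use replicate-edge padding: frames are windows of a
#' larger slide, so true content exists beyond the edges and callers that
#' care cut windows after blurring the padded region.
#'
#' @param img RGB array or matrix.
#' @param kernel `blur_kernel`.
#' @return blurred raster, same dimensions.
#' @export
motion_blur <- function(img, kernel) {
  stopifnot(inherits(kernel, "blur_kernel"))
  w <- kernel$width_px
  gray <- is.matrix(img)
  if (!gray) img <- as_rgb(img)
  W <- if (gray) ncol(img) else dim(img)[2]
  if (w > W) stop("invalid-kernel: blur width exceeds image width", call. = FALSE)
  if (w == 1L) return(img)
  # windowed mean via cumulative sums: S(x) = (cs[x+w-1] - cs[x-1]) / w
  blur_mat <- function(m) {
    if (kernel$direction == "+x") {
      mp <- cbind(m, m[, rep(ncol(m), w - 1L), drop = FALSE])
    } else {
      mp <- cbind(m[, rep(1L, w - 1L), drop = FALSE], m)
    }
    cs <- t(apply(mp, 1L, cumsum))
    hi <- cs[, (1:W) + (w - 1L), drop = FALSE]
    lo <- cbind(0, cs[, 1:(W - 1L), drop = FALSE])
    (hi - lo) / w
  }
  if (gray) return(blur_mat(img))
  out <- img
  for (k in 1:3) out[, , k] <- blur_mat(img[, , k])
  out
}

#' Plan a zigzag acquisition trace
#'
#' Builds the per-frame stage schedule: each scan line is bracketed by
#' `pause_s` of static frames, moving frames advance `s_x / fps` per frame,
#' and consecutive lines alternate direction (+x, -x, ...) separated
#' vertically by `row_step_um`. The stage dwells one frame-advance before
#' the line start (lead-in), so the first moving frame already covers the
#' line origin and the union of moving-frame footprints covers the slide.
#'
#' @param extent_um slide extent `c(width, height)` in um.
#' @param config `scan_config`.
#' @return data.frame (class `motion_trace`) with columns `frame_index`,
#'   `time_s`, `stage_x_um`, `stage_y_um`, `moving`, `row_index`,
#'   `direction`.
#' @export
plan_zigzag <- function(extent_um, config) {
  stopifnot(inherits(config, "scan_config"), all(extent_um > 0))
  fov_um <- config$fov_px * config$pixel_size_um
  if (config$row_step_um > fov_um[2])
    stop("coverage-gap: row_step_um exceeds the frame height", call. = FALSE)
  dx <- config$s_x / config$fps
  if (dx <= 0) stop("invalid-config: zero stage speed cannot cover the slide", call. = FALSE)
  L <- max(1L, ceiling((extent_um[1] - fov_um[1]) / dx) + 1L)
  n_rows <- max(1L, ceiling((extent_um[2] - fov_um[2]) / config$row_step_um) + 1L)
  n_pause <- round(config$pause_s * config$fps)
  x_end <- (L - 1L) * dx
  rows <- lapply(seq_len(n_rows), function(r) {
    dirp <- if (r %% 2L == 1L) "+x" else "-x"
    if (dirp == "+x") {
      xs <- c(rep(-dx, n_pause), (seq_len(L) - 1L) * dx, rep(x_end, n_pause))
    } else {
      xs <- c(rep(x_end + dx, n_pause), x_end - (seq_len(L) - 1L) * dx, rep(0, n_pause))
    }
    data.frame(stage_x_um = xs,
               stage_y_um = (r - 1L) * config$row_step_um,
               moving = c(rep(FALSE, n_pause), rep(TRUE, L), rep(FALSE, n_pause)),
               row_index = r, direction = dirp, stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, rows)
  tr$frame_index <- seq_len(nrow(tr))
  tr$time_s <- (tr$frame_index - 1L) / config$fps
  tr <- tr[, c("frame_index", "time_s", "stage_x_um", "stage_y_um",
               "moving", "row_index", "direction")]
  class(tr) <- c("motion_trace", "data.frame")
  tr
}

# Pad a slide with its background color so every window in the trace fits.
# Returns list(rgb, pad_left_px, pad_top_px).
pad_slide_for_trace <- function(slide, trace, config) {
  px <- config$pixel_size_um
  fov <- config$fov_px
  H <- dim(slide$rgb)[1]; W <- dim(slide$rgb)[2]
  xs <- round(trace$stage_x_um / px)
  ys <- round(trace$stage_y_um / px)
  pad_l <- max(0L, -min(xs))
  pad_t <- max(0L, -min(ys))
  pad_r <- max(0L, max(xs) + fov[1] - W)
  pad_b <- max(0L, max(ys) + fov[2] - H)
  maxpad <- 2L * max(fov) + ceiling(config$s_x / config$fps / px)
  if (max(pad_l, pad_t, pad_r, pad_b) > maxpad)
    stop("out-of-bounds: trace extends far beyond the slide", call. = FALSE)
  bg <- slide$background_rgb
  if (is.null(bg)) bg <- apply(slide$rgb[c(1, H), , , drop = FALSE], 3, stats::median)
  out <- array(rep(bg, each = (H + pad_t + pad_b) * (W + pad_l + pad_r)),
               c(H + pad_t + pad_b, W + pad_l + pad_r, 3L))
  out[pad_t + seq_len(H), pad_l + seq_len(W), ] <- slide$rgb
  list(rgb = out, pad_left_px = pad_l, pad_top_px = pad_t)
}

#' Simulate the camera frame stream for a planned trace
#'
#' Each frame is the field-of-view-sized window of the slide at the frame's
#' stage position; while the stage moves, the window is taken from the slide
#' pre-blurred with the rectangular kernel in the row's scan direction
#' (windows are cut after blurring the padded slide, so frame edges carry
#' true neighboring content). Static frames are crisp. With zero jitter the
#' output is deterministic.
#'
#' @param slide `slide_image` (from [generate_slide()]).
#' @param trace `motion_trace` (from [plan_zigzag()]).
#' @param config `scan_config`.
#' @param seed seed for the jitter phases (only used if jitter is enabled).
#' @return object of class `frame_seq`: list with `frames` (list of RGB
#'   arrays), `trace`, `config`, and the padding offsets mapping frame
#'   coordinates back to slide coordinates.
#' @export
simulate_scan <- function(slide, trace, config, seed = 1) {
  stopifnot(inherits(slide, "slide_image"), inherits(config, "scan_config"))
  px <- config$pixel_size_um
  fov <- config$fov_px
  jit <- config$jitter
  use_jitter <- any(unlist(jit[c("ax", "ay")]) != 0)
  if (use_jitter) {
    ph <- with_seed(seed, stats::runif(2, 0, 2 * pi))
    trace$stage_x_um <- trace$stage_x_um +
      ifelse(trace$moving, jit$ax * sin(2 * pi * jit$fx * trace$time_s + ph[1]), 0)
    trace$stage_y_um <- trace$stage_y_um +
      ifelse(trace$moving, jit$ay * sin(2 * pi * jit$fy * trace$time_s + ph[2]), 0)
  }
  padded <- pad_slide_for_trace(slide, trace, config)
  wum <- blur_width(config$s_x, config$T)
  blur_p <- motion_blur(padded$rgb, blur_kernel(wum, px, "+x"))
  blur_m <- motion_blur(padded$rgb, blur_kernel(wum, px, "-x"))
  frames <- vector("list", nrow(trace))
  for (i in seq_len(nrow(trace))) {
    c0 <- round(trace$stage_x_um[i] / px) + padded$pad_left_px
    r0 <- round(trace$stage_y_um[i] / px) + padded$pad_top_px
    src <- if (!trace$moving[i]) padded$rgb
           else if (trace$direction[i] == "+x") blur_p else blur_m
    frames[[i]] <- src[r0 + seq_len(fov[2]), c0 + seq_len(fov[1]), , drop = FALSE]
  }
  structure(list(frames = frames, trace = trace, config = config,
                 pad_left_px = padded$pad_left_px,
                 pad_top_px = padded$pad_top_px,
                 padded_dim = dim(padded$rgb)[1:2]),
            class = "frame_seq")
}

#' Areal scanning throughput
#'
#' `(s_x + fov_width_um) * fov_height_um`, in mm^2/s: per second the stage
#' sweeps `s_x` um of fresh width plus one frame width, over the frame
#' height. Defaults give 2.7072 (~2.7) mm^2/s.
#'
#' @param config `scan_config`.
#' @return throughput in mm^2 per second.
#' @export
area_throughput <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  fov_um <- config$fov_px * config$pixel_size_um
  (config$s_x + fov_um[1]) * fov_um[2] / 1e6
}

#' Write a frame sequence to disk
#'
#' Frames as zero-padded numbered PNGs plus the trace as CSV
#' (`frame_index,time_s,stage_x_um,stage_y_um,moving,row_index,direction`).
#'
#' @param fs `frame_seq`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(fs, dir) {
  stopifnot(inherits(fs, "frame_seq"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(fs$frames))
    write_raster(fs$frames[[i]], file.path(dir, sprintf("frame_%05d.png", i)))
  utils::write.csv(as.data.frame(fs$trace), file.path(dir, "trace.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read frames written by [write_frames()]
#'
#' The trace CSV, if present, is attached for oracle tests only; the
#' stitching algorithm never reads it.
#'
#' @param dir directory of `frame_*.png` files.
#' @return list with `frames` and (possibly `NULL`) `trace`.
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  frames <- lapply(files, read_raster)
  tr_path <- file.path(dir, "trace.csv")
  trace <- if (file.exists(tr_path)) utils::read.csv(tr_path, stringsAsFactors = FALSE) else NULL
  list(frames = frames, trace = trace)
}
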