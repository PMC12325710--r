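# Whole-slide stitching from the continuous-scan frame stream.
#
# The algorithm infers timing, not displacement, from the video: consecutive
# frames are near-identical while the stage pauses at line ends and decorrelate
# while it moves. Thresholded correlations give raw moving/static labels; a
# square wave fitted to them corrects errors in featureless regions (and the
# short vertical jump between lines). Displacement then follows from the known
# stage speed, so frames are placed at uniform offsets along each scan line.

#' Consecutive-frame correlation series
#'
#' Pearson correlation (zero-mean, unit-norm) of consecutive
#' grayscale-converted frames, computed on center crops to reduce edge
#' effects. Constant (featureless) frame pairs correlate 1 when identical,
#' 0 otherwise.
#'
#' @param frames list of RGB frames.
#' @param crop_frac central fraction of each frame used (0 < f <= 1).
#' @return numeric vector of length `length(frames) - 1`.
#' @export
frame_correlations <- function(frames, crop_frac = 0.5) {
  if (length(frames) < 2L)
    stop("insufficient-input: need at least 2 frames", call. = FALSE)
  crop_gray <- function(fr) {
    g <- rgb_to_gray(fr)
    h <- nrow(g); w <- ncol(g)
    dh <- floor(h * (1 - crop_frac) / 2); dw <- floor(w * (1 - crop_frac) / 2)
    as.vector(g[(dh + 1L):(h - dh), (dw + 1L):(w - dw)])
  }
  gs <- lapply(frames, crop_gray)
  vapply(seq_len(length(frames) - 1L), function(i) {
    a <- gs[[i]]; b <- gs[[i + 1L]]
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
      if (max(abs(a - b)) < 1e-9) 1 else 0
    } else stats::cor(a, b)
  }, numeric(1))
}

# best circular square wave for binary series s (1 = static/high):
# period p, exactly q consecutive high offsets, phase f; scored by Hamming
# disagreement. Ties: smallest period, then phase, then pause.
# The period grid reaches n/2 but always extends past the longest raw run:
# a shorter cap cannot represent single-line (sub-period) videos and would
# hallucinate extra moving runs.
fit_square_wave <- function(s, p_min = 4L, p_max = NULL) {
  m <- length(s)
  n <- m + 1L                              # frame count
  if (is.null(p_max))
    p_max <- min(m, max(floor(n / 2), max(rle(s)$lengths) + 3L))
  p_max <- max(p_min, p_max)
  total1 <- sum(s)
  best <- list(D = Inf, p = NA, q = NA, f = NA)
  for (p in p_min:p_max) {
    r <- (seq_len(m) - 1L) %% p
    cnt1 <- vapply(0:(p - 1L), function(x) sum(s[r == x]), numeric(1))
    cntn <- tabulate(r + 1L, p)
    a <- cntn - 2 * cnt1                   # cost delta of making a residue "high"
    aa <- c(a, a)
    cs <- c(0, cumsum(aa))
    for (f in 0:(p - 1L)) {
      for (q in 1:(p - 1L)) {
        D <- total1 + (cs[f + q + 1L] - cs[f + 1L])
        if (D < best$D) best <- list(D = D, p = p, q = q, f = f)
      }
    }
  }
  best
}

#' Classify frames as moving or static
#'
#' Raw labels come from thresholding the correlation series at the midpoint
#' of its two 1-D k-means modes (high correlation = static pair). With
#' `fit = TRUE` the best-fitting square wave (exhaustive grid over integer
#' period, pause length and phase, scored by Hamming disagreement with the
#' raw labels) replaces them, correcting isolated errors from featureless
#' regions and from the short vertical jump between lines. Frame `i + 1` is
#' moving iff series element `i` is low; frame 1 inherits frame 2's label
#' (the series cannot distinguish the two).
#'
#' @param series correlation series from [frame_correlations()].
#' @param fit fit the square-wave motion model (default) or keep raw labels.
#' @return object of class `squarewave_model`: `moving` (logical per frame),
#'   `line_period_frames`, `pause_frames`, `phase_frames`, `threshold`,
#'   `raw_high`, `series`.
#' @export
classify_motion <- function(series, fit = TRUE) {
  m <- length(series)
  if (m < 3L || stats::sd(series) < 1e-12)
    stop("no-scan-lines: correlation series is degenerate", call. = FALSE)
  # two-means on 1-D values
  c1 <- min(series); c2 <- max(series)
  for (it in 1:50) {
    assign2 <- abs(series - c2) < abs(series - c1)
    if (!any(assign2) || all(assign2)) break
    c1n <- mean(series[!assign2]); c2n <- mean(series[assign2])
    if (abs(c1n - c1) + abs(c2n - c2) < 1e-12) { c1 <- c1n; c2 <- c2n; break }
    c1 <- c1n; c2 <- c2n
  }
  thr <- (c1 + c2) / 2
  raw_high <- series >= thr
  if (all(raw_high) || !any(raw_high))
    stop("no-scan-lines: no moving/static alternation found", call. = FALSE)
  if (fit) {
    fw <- fit_square_wave(as.numeric(raw_high))
    high <- ((seq_len(m) - 1L - fw$f) %% fw$p) < fw$q
    moving <- c(NA, !high)
    moving[1L] <- moving[2L]
    period <- fw$p; pause <- fw$q; phase <- fw$f
  } else {
    moving <- c(NA, !raw_high)
    moving[1L] <- moving[2L]
    period <- NA_integer_; pause <- NA_integer_; phase <- NA_integer_
  }
  structure(list(moving = moving, line_period_frames = period,
                 pause_frames = pause, phase_frames = phase,
                 threshold = thr, raw_high = raw_high, series = series),
            class = "squarewave_model")
}

#' Extract scan-line segments from a motion model
#'
#' One segment per run of moving frames; directions alternate starting from
#' `first_direction` (the video alone cannot disambiguate it, so it must be
#' supplied or taken from the scan configuration).
#'
#' @param model `squarewave_model`.
#' @param first_direction `"+x"` or `"-x"`.
#' @return data.frame with `start_frame`, `end_frame`, `row_index`,
#'   `direction`.
#' @export
detect_scan_lines <- function(model, first_direction = "+x") {
  stopifnot(inherits(model, "squarewave_model"))
  first_direction <- match.arg(first_direction, c("+x", "-x"))
  mv <- model$moving
  if (!any(mv)) stop("no-scan-lines: no moving run present", call. = FALSE)
  r <- rle(mv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  dirs <- c("+x", "-x")
  if (first_direction == "-x") dirs <- rev(dirs)
  data.frame(start_frame = starts[idx], end_frame = ends[idx],
             row_index = seq_along(idx),
             direction = dirs[(seq_along(idx) - 1L) %% 2L + 1L],
             stringsAsFactors = FALSE)
}

#' Assemble the whole-slide mosaic
#'
#' Within each scan-line segment, frames sit at uniform
#' `per_frame_advance_px` offsets along the segment direction (`-x` rows are
#' flipped into slide coordinates); rows stack at `row_step_px`. Overlaps
#' are resolved by the blend rule (default: the later frame overwrites).
#'
#' @param frames list of RGB frames.
#' @param segments data.frame from [detect_scan_lines()].
#' @param per_frame_advance_px horizontal stage advance per frame, pixels
#'   (`s_x / (fps * pixel_size_um)`).
#' @param row_step_px vertical row separation in pixels.
#' @param blend `"last"` (overwrite) or `"average"`.
#' @param pixel_size_um recorded on the mosaic.
#' @param max_pixels guard on the output size.
#' @return object of class `mosaic`: `rgb`, `pixel_size_um`, `provenance`.
#' @export
assemble_mosaic <- function(frames, segments, per_frame_advance_px,
                            row_step_px, blend = c("last", "average"),
                            pixel_size_um = 1, max_pixels = 2e8) {
  blend <- match.arg(blend)
  stopifnot(per_frame_advance_px > 0, row_step_px > 0, nrow(segments) >= 1)
  fd <- dim(frames[[1L]])
  fh <- fd[1]; fw <- fd[2]
  lens <- segments$end_frame - segments$start_frame + 1L
  Lmax <- max(lens)
  W <- round((Lmax - 1L) * per_frame_advance_px) + fw
  H <- round((nrow(segments) - 1L) * row_step_px) + fh
  if (as.double(W) * H > max_pixels)
    stop("size error: mosaic exceeds the maximum size", call. = FALSE)
  acc <- array(0, c(H, W, 3L))
  cnt <- if (blend == "average") matrix(0L, H, W) else NULL
  for (si in seq_len(nrow(segments))) {
    seg <- segments[si, ]
    y0 <- round((seg$row_index - 1L) * row_step_px)
    js <- seq_len(seg$end_frame - seg$start_frame + 1L)
    for (j in js) {
      x0 <- if (seg$direction == "+x") round((j - 1L) * per_frame_advance_px)
            else round((Lmax - j) * per_frame_advance_px)
      fr <- frames[[seg$start_frame + j - 1L]]
      ry <- y0 + seq_len(fh); rx <- x0 + seq_len(fw)
      if (blend == "last") acc[ry, rx, ] <- fr
      else { acc[ry, rx, ] <- acc[ry, rx, ] + fr; cnt[ry, rx] <- cnt[ry, rx] + 1L }
    }
  }
  if (blend == "average") {
    cnt[cnt == 0L] <- 1L
    for (k in 1:3) acc[, , k] <- acc[, , k] / cnt
  }
  structure(list(rgb = acc, pixel_size_um = pixel_size_um,
                 provenance = list(n_frames = length(frames),
                                   n_segments = nrow(segments),
                                   advance_px = per_frame_advance_px,
                                   row_step_px = row_step_px, blend = blend)),
            class = "mosaic")
}

#' Stitch a frame stream end to end
#'
#' Convenience wrapper: correlations -> motion classification (square-wave
#' fit) -> scan-line segments -> mosaic assembly, with the per-frame advance
#' and row step taken from the scan configuration.
#'
#' @param frames list of RGB frames (e.g. `frame_seq$frames`).
#' @param config `scan_config`.
#' @param first_direction direction of the first scan line.
#' @param blend overlap rule passed to [assemble_mosaic()].
#' @return list with `mosaic`, `model`, `segments`, `series`.
#' @export
stitch_scan <- function(frames, config, first_direction = "+x",
                        blend = "last") {
  stopifnot(inherits(config, "scan_config"))
  series <- frame_correlations(frames)
  model <- classify_motion(series)
  segments <- detect_scan_lines(model, first_direction)
  adv <- config$s_x / (config$fps * config$pixel_size_um)
  step <- config$row_step_um / config$pixel_size_um
  mosaic <- assemble_mosaic(frames, segments, adv, step, blend = blend,
                            pixel_size_um = config$pixel_size_um)
  list(mosaic = mosaic, model = model, segments = segments, series = series)
}
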