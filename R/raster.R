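# Low-level raster helpers shared across modules.
#
# Images are numeric arrays of dimension H x W x 3 with values in [0, 1];
# coordinates follow the package convention: origin at the top-left corner,
# x rightward (columns), y downward (rows), 0-based pixel indices, physical
# positions at pixel centers.

#' Validate and coerce an RGB raster
#'
#' @param img numeric array `H x W x 3` (values in \[0, 1\]) or an `H x W`
#'   matrix, which is expanded to three identical channels.
#' @return numeric array `H x W x 3`.
#' @keywords internal
as_rgb <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  storage.mode(img) <- "double"
  img
}

#' Convert an RGB raster to grayscale
#'
#' Uses the Rec. 601 luma weights (0.299, 0.587, 0.114).
#'
#' @param img RGB array.
#' @return numeric `H x W` matrix.
#' @export
rgb_to_gray <- function(img) {
  img <- as_rgb(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Block-mean (area) downsampling to a square target
#'
#' Area interpolation: the source is partitioned into an `S x S` grid of
#' rectangular bins and each output pixel is the mean of its bin. Mean
#' intensity is preserved up to bin-size rounding.
#'
#' @param img RGB array or matrix.
#' @param S target side length in pixels.
#' @return downsampled raster of size `S x S` (x 3 if RGB).
#' @export
downsample_mean <- function(img, S) {
  if (S <= 0) stop("invalid-size: S must be positive", call. = FALSE)
  one <- function(m) {
    h <- nrow(m); w <- ncol(m)
    ri <- findInterval(seq_len(h) - 1L, seq(0, h, length.out = S + 1L),
                       rightmost.closed = TRUE)
    ci <- findInterval(seq_len(w) - 1L, seq(0, w, length.out = S + 1L),
                       rightmost.closed = TRUE)
    sums <- rowsum(m, ri)                 # S x w
    sums <- t(rowsum(t(sums), ci))        # S x S
    cnt <- tabulate(ri, S) %o% tabulate(ci, S)
    sums / cnt
  }
  if (is.matrix(img)) return(one(img))
  img <- as_rgb(img)
  out <- array(0, c(S, S, 3L))
  for (k in 1:3) out[, , k] <- one(img[, , k])
  out
}

#' Separable Gaussian smoothing of a matrix
#'
#' @param m numeric matrix.
#' @param sigma standard deviation in pixels; the kernel is truncated at
#'   `ceiling(3 * sigma)` and renormalized. `sigma <= 0` returns `m`.
#' @return smoothed matrix of the same size (replicate-edge padding).
#' @export
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  conv_cols <- function(x) {
    xp <- x[pad_idx(nrow(x)), , drop = FALSE]
    out <- 0
    for (i in seq_along(k)) out <- out + k[i] * xp[i:(i + nrow(x) - 1L), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

#' Otsu threshold of a numeric vector
#'
#' Maximizes between-class variance on a 256-bin histogram.
#'
#' @param v numeric values in \[0, 1\].
#' @return scalar threshold.
#' @export
otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  h <- tabulate(pmin(pmax(floor(v * 256) + 1L, 1L), 256L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256L) - 0.5) / 256)
  mu_t <- mu[256L]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  which.max(sb) / 256
}

#' Label 4-connected components of a binary mask
#'
#' Row-run union-find labeling; suitable for whole-slide masks.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same size; 0 = background, components
#'   numbered from 1 in first-encounter order.
#' @export
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  # runs of TRUE within each column-major row scan: work row-wise
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  prev_runs <- NULL  # data.frame(start, end, id) of previous row
  nlab <- 0L
  for (y in seq_len(h)) {
    r <- mask[y, ]
    if (!any(r)) { prev_runs <- NULL; next }
    d <- diff(c(FALSE, r, FALSE))
    starts <- which(d == 1L); ends <- which(d == -1L) - 1L
    ids <- integer(length(starts))
    for (j in seq_along(starts)) {
      id <- 0L
      if (!is.null(prev_runs)) {
        ov <- which(prev_runs$start <= ends[j] & prev_runs$end >= starts[j])
        for (o in ov) {
          pid <- prev_runs$id[o]
          if (id == 0L) id <- pid else unite(id, pid)
        }
      }
      if (id == 0L) { nlab <- nlab + 1L; parent[nlab] <- nlab; id <- nlab }
      ids[j] <- id
      lab[y, starts[j]:ends[j]] <- id
    }
    prev_runs <- data.frame(start = starts, end = ends, id = ids)
  }
  if (nlab == 0L) return(lab)
  roots <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(roots, unique(roots))
  idx <- lab > 0L
  lab[idx] <- remap[lab[idx]]
  lab
}

#' Write an RGB raster to a PNG file
#'
#' @param img RGB array in \[0, 1\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  png::writePNG(clip01(as_rgb(img)), path)
  invisible(path)
}

#' Read an RGB raster from a PNG file
#'
#' @param path PNG file path.
#' @return RGB array in \[0, 1\].
#' @export
read_raster <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) return(as_rgb(img))
  if (dim(img)[3] == 4L) img <- img[, , 1:3]
  as_rgb(img)
}
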