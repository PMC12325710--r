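# Multi-scale input stacks: 1 globally downsampled view + 4 random crops of
# the same side length, channel-stacked into a 15-channel raster.

reflect_pad_to <- function(img, S) {
  h <- dim(img)[1]; w <- dim(img)[2]
  refl <- function(n, target) {
    if (n >= target) return(seq_len(target))
    idx <- seq_len(n)
    mirror <- c(idx, rev(idx)[-1])  # period 2n - 1, reflect without repeating edge
    mirror[((seq_len(target) - 1L) %% length(mirror)) + 1L]
  }
  img[refl(h, max(h, S)), refl(w, max(w, S)), , drop = FALSE]
}

#' Build the 5-image multi-scale patch stack for one core
#'
#' Slot 1 is the full core image area-downsampled to `S x S`; slots
#' 2..`n_crops + 1` are uniform-random `S x S` windows of the
#' original-resolution image (reflect-padded to at least `S` per side if the
#' core is smaller). The slots are concatenated along channels, giving an
#' `S x S x 3(n_crops + 1)` array. The crop offsets are drawn from a seed
#' derived from `(seed, core_id, repeat_index)`, so stacks are deterministic
#' per core and repeat.
#'
#' @param core `labeled_core` (from [crop_and_label()]) or a plain RGB array.
#' @param S side length of each slot (default 512).
#' @param n_crops number of random crops (default 4).
#' @param seed global seed from which the per-core seed is derived.
#' @return `patch_stack`: numeric array `S x S x 3(n_crops+1)` with
#'   attributes `offsets` (n_crops x 2, 0-based y/x), `seed`, `core_id`,
#'   `repeat_index`, `label`.
#' @export
build_stack <- function(core, S = 512L, n_crops = 4L, seed = 1L) {
  if (S <= 0) stop("invalid-size: S must be positive", call. = FALSE)
  is_core <- inherits(core, "labeled_core")
  img <- as_rgb(get_rgb(core))
  core_id <- if (is_core) core$core_id else NA_character_
  rep_idx <- if (is_core) core$repeat_index else 1L
  label <- if (is_core) core$her2_score else NA_integer_
  sseed <- derive_seed(seed, if (is.na(core_id)) "anon" else core_id, rep_idx)
  img <- reflect_pad_to(img, S)
  h <- dim(img)[1]; w <- dim(img)[2]
  stack <- array(0, c(S, S, 3L * (n_crops + 1L)))
  stack[, , 1:3] <- downsample_mean(img, S)
  offs <- matrix(0L, n_crops, 2L, dimnames = list(NULL, c("y", "x")))
  if (n_crops > 0L) {
    with_seed(sseed, {
      for (j in seq_len(n_crops)) {
        oy <- if (h > S) sample.int(h - S + 1L, 1L) - 1L else 0L
        ox <- if (w > S) sample.int(w - S + 1L, 1L) - 1L else 0L
        offs[j, ] <- c(oy, ox)
        stack[, , (3L * j + 1L):(3L * j + 3L)] <-
          img[oy + seq_len(S), ox + seq_len(S), ]
      }
    })
  }
  structure(stack, offsets = offs, seed = sseed, core_id = core_id,
            repeat_index = rep_idx, label = label, class = "patch_stack")
}
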