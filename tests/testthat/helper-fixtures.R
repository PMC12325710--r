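# Shared fixtures, built once per session and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 2-row x 3-column slide, default scan config: used by stitching round-trip
# tests and acceptance criterion 5
scan_fixture <- function() {
  memo("scan2x3", function() {
    lay <- core_layout(2, 3, pitch_um = 400, core_diameter_um = 260)
    gen <- generate_slide(lay, scores = c(0, 1, 2, 3, 2, 1), seed = 11,
                          margin_um = 80)
    cfg <- scan_config()
    extent <- c(dim(gen$slide$rgb)[2], dim(gen$slide$rgb)[1])
    trace <- plan_zigzag(extent, cfg)
    fs <- simulate_scan(gen$slide, trace, cfg)
    st <- stitch_scan(fs$frames, cfg, "+x")
    list(layout = lay, gen = gen, cfg = cfg, trace = trace, fs = fs, st = st)
  })
}

# 4 x 6 TMA full pipeline (criterion 6); shorter pauses keep the frame
# stream small without changing the mechanics under test
tma_fixture <- function() {
  memo("tma4x6", function() {
    lay <- core_layout(4, 6, pitch_um = 400, core_diameter_um = 260)
    scores <- with_seed(31, sample(0:3, 24, replace = TRUE))
    gen <- generate_slide(lay, scores, seed = 21, margin_um = 80)
    cfg <- scan_config(pause_s = 0.2)
    extent <- c(dim(gen$slide$rgb)[2], dim(gen$slide$rgb)[1])
    trace <- plan_zigzag(extent, cfg)
    fs <- simulate_scan(gen$slide, trace, cfg)
    st <- stitch_scan(fs$frames, cfg, "+x")
    list(layout = lay, scores = scores, gen = gen, cfg = cfg, trace = trace,
         fs = fs, st = st)
  })
}

# row-wise directionally blurred ground truth assembled exactly like the
# mosaic (later rows overwrite), restricted to the mosaic extent
mosaic_ground_truth <- function(fx) {
  cfg <- fx$cfg
  pad <- her2scan:::pad_slide_for_trace(fx$gen$slide, fx$trace, cfg)
  wum <- blur_width(cfg$s_x, cfg$T)
  bp <- motion_blur(pad$rgb, blur_kernel(wum, cfg$pixel_size_um, "+x"))
  bm <- motion_blur(pad$rgb, blur_kernel(wum, cfg$pixel_size_um, "-x"))
  mo <- fx$st$mosaic$rgb
  gt <- array(0, dim(mo))
  fov_h <- cfg$fov_px[2]
  step <- cfg$row_step_um / cfg$pixel_size_um
  for (r in seq_len(max(fx$trace$row_index))) {
    y0 <- round((r - 1) * step)
    src <- if (r %% 2 == 1) bp else bm
    gt[y0 + seq_len(fov_h), , ] <-
      src[pad$pad_top_px + y0 + seq_len(fov_h),
          pad$pad_left_px + seq_len(dim(mo)[2]), ]
  }
  gt
}

# small rendered-core training set for classifier tests (balanced classes)
render_stack_set <- function(n_per_class, S = 128L, diameter_um = 180,
                             seed = 1000L) {
  params <- her2_appearance_params()
  labels <- rep(0:3, each = n_per_class)
  stacks <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    core <- render_core(params, labels[i], diameter_um = diameter_um,
                        pixel_size_um = 1, seed = seed + i)
    stacks[[i]] <- build_stack(core, S = S, n_crops = 4L, seed = seed + i)
  }
  list(stacks = stacks, labels = labels)
}
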