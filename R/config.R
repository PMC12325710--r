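# YAML round-trip for scan configurations.

#' Write / read a scan configuration as YAML
#'
#' @param config `scan_config`.
#' @param path YAML file path.
#' @return `path` invisibly; `read_scan_config` returns a `scan_config`.
#' @export
write_scan_config <- function(config, path) {
  stopifnot(inherits(config, "scan_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_scan_config
#' @export
read_scan_config <- function(path) {
  x <- yaml::read_yaml(path)
  scan_config(s_x = x$s_x, T = x$T, fps = x$fps,
              fov_px = as.integer(unlist(x$fov_px)),
              pixel_size_um = x$pixel_size_um, pause_s = x$pause_s,
              row_step_um = x$row_step_um,
              jitter = lapply(x$jitter, as.numeric))
}
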