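#' Write a two-channel SHG stack as a multi-page 16-bit TIFF
#'
#' Pages hold all forward slices first, then all backward slices; a YAML
#' sidecar (`<path>.yaml`) records the channel order, slice count and voxel
#' size so the pair is self-describing. Intensities are stored as 16-bit
#' integers, so values are quantized to the nearest integer on write.
#'
#' @param stack An [shg_stack()].
#' @param path Output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_shg_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "shg_stack"))
  nz <- dim(stack$forward)[3]
  q16 <- function(m) round(m) / 65535   # quantize here; writeTIFF truncates
  pages <- c(lapply(seq_len(nz), function(k) q16(stack$forward[, , k])),
             lapply(seq_len(nz), function(k) q16(stack$backward[, , k])))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  yaml::write_yaml(list(channels = c("forward", "backward"), nz = nz,
                        voxel_size_um = as.numeric(stack$voxel_size)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a two-channel SHG stack written by [write_shg_tiff()]
#'
#' @param path TIFF file path; `<path>.yaml` supplies channel order and
#'   voxel size when present.
#' @param channel_order Page-block order used when no sidecar is found;
#'   default `c("forward", "backward")`.
#' @return An [shg_stack()].
#' @export
read_shg_tiff <- function(path, channel_order = c("forward", "backward")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  voxel <- c(0.24, 0.24, 1)
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    channel_order <- meta$channels %||% channel_order
    voxel <- meta$voxel_size_um %||% voxel
  }
  if (length(pages) %% 2L != 0L) {
    stop("expected an even number of pages (two channels)", call. = FALSE)
  }
  nz <- length(pages) %/% 2L
  d <- dim(pages[[1]])
  to_arr <- function(idx) {
    a <- array(0, c(d[1], d[2], nz))
    for (k in seq_len(nz)) a[, , k] <- pages[[idx[k]]] * 65535
    a
  }
  ch1 <- to_arr(seq_len(nz))
  ch2 <- to_arr(nz + seq_len(nz))
  if (identical(channel_order, c("backward", "forward"))) {
    tmp <- ch1; ch1 <- ch2; ch2 <- tmp
  }
  shg_stack(ch1, ch2, voxel_size = voxel)
}
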