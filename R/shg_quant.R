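#' Adaptive background threshold for one SHG channel
#'
#' Computes the mean and population standard deviation of *all* voxels of a
#' channel (background included) and sets the threshold at `mu + sigma`,
#' the rule used to exclude background emission before measuring collagen
#' signal. The threshold is scale-equivariant: multiplying the channel by
#' `c > 0` multiplies the threshold by `c`, so the above-threshold voxel
#' set is unchanged.
#'
#' @param channel 3D (or any-dimensional) numeric intensity array.
#' @return An object of class `shg_threshold` with fields `mu`, `sigma`
#'   and `threshold` (`= mu + sigma`).
#' @export
compute_threshold <- function(channel) {
  if (length(channel) == 0L) stop("empty channel", call. = FALSE)
  mu <- mean(channel)
  sigma <- pop_sd(channel)
  structure(list(mu = mu, sigma = sigma, threshold = mu + sigma),
            class = "shg_threshold")
}

#' Per-slice and stack-averaged channel metrics
#'
#' For every slice along the z (third) axis: `area` is the number of voxels
#' with intensity strictly above the threshold, `density` the mean intensity
#' of those voxels, and `intensity` their total signal (`area * density`).
#' Ties at the threshold count as background. Slices with zero area
#' contribute area 0 and intensity 0 to the stack averages but are excluded
#' from the density average (density is undefined on an empty set).
#'
#' @param channel 3D numeric intensity array (x, y, z).
#' @param threshold Finite scalar intensity threshold.
#' @return An object of class `channel_metrics` with per-slice vectors
#'   `per_slice_area`, `per_slice_density`, `per_slice_intensity` and stack
#'   means `mean_area`, `mean_density`, `mean_intensity`.
#' @export
channel_metrics <- function(channel, threshold) {
  stopifnot(is.array(channel), length(dim(channel)) == 3L)
  stopifnot_scalar(threshold, "threshold")
  nz <- dim(channel)[3]
  area <- integer(nz)
  density <- rep(NA_real_, nz)
  intensity <- numeric(nz)
  for (k in seq_len(nz)) {
    sl <- channel[, , k]
    above <- sl[sl > threshold]
    area[k] <- length(above)
    if (area[k] > 0L) {
      density[k] <- mean(above)
      intensity[k] <- area[k] * density[k]
    }
  }
  structure(
    list(per_slice_area = area, per_slice_density = density,
         per_slice_intensity = intensity,
         mean_area = mean(area),
         mean_density = if (all(is.na(density))) NaN
                        else mean(density, na.rm = TRUE),
         mean_intensity = mean(intensity)),
    class = "channel_metrics"
  )
}

#' Forward/backward ratios of stack-averaged metrics
#'
#' Each ratio divides the forward stack mean by the backward stack mean for
#' the corresponding metric (area, density, intensity); stacks are averaged
#' first, then the ratio is taken. A higher intensity F/B indicates greater
#' fibril maturity/thickness.
#'
#' @param forward,backward `channel_metrics` for the two channels.
#' @return An object of class `shg_ratios` with fields `fb_area`,
#'   `fb_density`, `fb_intensity`.
#' @export
fb_ratios <- function(forward, backward) {
  stopifnot(inherits(forward, "channel_metrics"),
            inherits(backward, "channel_metrics"))
  denom <- c(area = backward$mean_area,
             density = backward$mean_density,
             intensity = backward$mean_intensity)
  bad <- names(denom)[!is.finite(denom) | denom == 0]
  if (length(bad)) {
    stop("undefined F/B ratio: backward mean ", paste(bad, collapse = ", "),
         " is zero or undefined", call. = FALSE)
  }
  structure(list(fb_area = forward$mean_area / backward$mean_area,
                 fb_density = forward$mean_density / backward$mean_density,
                 fb_intensity = forward$mean_intensity / backward$mean_intensity),
            class = "shg_ratios")
}

#' Full SHG stack analysis
#'
#' Computes a `mu + sigma` threshold independently for each channel (the
#' detectors have different gains), derives per-slice metrics, and returns
#' the three forward/backward ratios together with the full per-channel
#' metrics for audit.
#'
#' @param stack An [shg_stack()].
#' @return An object of class `shg_analysis`: list with `threshold_forward`,
#'   `threshold_backward`, `metrics_forward`, `metrics_backward`, `ratios`.
#' @examples
#' tr <- shg_truth(random_fibril_field(8, c(32, 32, 4), maturity = 0.8))
#' res <- analyse_stack(gen_shg_stack(tr, c(32, 32, 4)))
#' res$ratios$fb_intensity  # ~ 0.8 / 0.2 = 4
#' @export
analyse_stack <- function(stack) {
  stopifnot(inherits(stack, "shg_stack"))
  tf <- compute_threshold(stack$forward)
  tb <- compute_threshold(stack$backward)
  mf <- channel_metrics(stack$forward, tf$threshold)
  mb <- channel_metrics(stack$backward, tb$threshold)
  structure(list(threshold_forward = tf, threshold_backward = tb,
                 metrics_forward = mf, metrics_backward = mb,
                 ratios = fb_ratios(mf, mb)),
            class = "shg_analysis")
}

#' @export
print.shg_analysis <- function(x, ...) {
  cat(sprintf(
    "<shg_analysis> thresholds F=%.3g B=%.3g | F/B area %.3f density %.3f intensity %.3f\n",
    x$threshold_forward$threshold, x$threshold_backward$threshold,
    x$ratios$fb_area, x$ratios$fb_density, x$ratios$fb_intensity))
  invisible(x)
}

#' Random selection of imaging regions on a tile grid
#'
#' Reproduces the acquisition protocol in which a grid (10x10 on whole
#' tissue, 5x5 on decellularized samples) is laid over the section and a
#' fixed number of regions is chosen with a seeded random number generator.
#'
#' @param grid_dims Grid size `c(rows, cols)`.
#' @param n Number of regions to select (`n <= rows * cols`).
#' @param seed Integer seed; the same seed reproduces the same selection.
#' @return An object of class `region_grid` with `grid_dims`, `selected`
#'   (sorted linear cell indices, row-major), `cells` (row/col data frame)
#'   and `seed`.
#' @export
sample_regions <- function(grid_dims, n, seed = 1L) {
  stopifnot(length(grid_dims) == 2L, all(grid_dims >= 1))
  total <- grid_dims[1] * grid_dims[2]
  if (n > total) {
    stop(sprintf("cannot select %d regions from a %dx%d grid",
                 n, grid_dims[1], grid_dims[2]), call. = FALSE)
  }
  sel <- with_local_seed(seed, sort(sample.int(total, n)))
  structure(list(
    grid_dims = grid_dims,
    selected = sel,
    cells = data.frame(row = ((sel - 1L) %/% grid_dims[2]) + 1L,
                       col = ((sel - 1L) %% grid_dims[2]) + 1L),
    seed = as.integer(seed)), class = "region_grid")
}
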