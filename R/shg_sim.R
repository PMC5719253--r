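#' Ground truth for a synthetic two-channel SHG acquisition
#'
#' Describes a field of fibrillar collagen segments whose second-harmonic
#' emission is split between the forward and backward detection channels
#' according to a per-segment maturity parameter `m` in \[0, 1\]: mature,
#' organized fibrils emit predominantly forward, immature/disorganized
#' fibrils predominantly backward. A segment with maturity `m` sends a
#' fraction `m` of its emitted signal to the forward channel and `1 - m`
#' backward, so total emission is independent of maturity.
#'
#' @param segments Data frame of fibril segments with columns
#'   `x0, y0, z0, x1, y1, z1` (end points, voxel units), `radius`
#'   (voxels) and `maturity` (in \[0, 1\]).
#' @param forward_gain,backward_gain Detector gains (arbitrary units, > 0).
#' @param background_level Additive background offset (a.u., >= 0).
#' @param noise_sd Standard deviation of additive Gaussian detector noise
#'   (a.u., >= 0).
#' @param seed Integer seed controlling the noise draw.
#' @return An object of class `shg_truth`.
#' @seealso [gen_shg_stack()], [random_fibril_field()]
#' @export
shg_truth <- function(segments, forward_gain = 1, backward_gain = 1,
                      background_level = 0, noise_sd = 0, seed = 1L) {
  need <- c("x0", "y0", "z0", "x1", "y1", "z1", "radius", "maturity")
  if (!is.data.frame(segments) || !all(need %in% names(segments))) {
    stop("`segments` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(segments) == 0L) stop("at least one segment is required", call. = FALSE)
  if (any(segments$maturity < 0 | segments$maturity > 1)) {
    stop("segment maturity must lie in [0, 1]", call. = FALSE)
  }
  if (any(segments$radius <= 0)) stop("segment radius must be > 0", call. = FALSE)
  len2 <- (segments$x1 - segments$x0)^2 + (segments$y1 - segments$y0)^2 +
    (segments$z1 - segments$z0)^2
  if (any(len2 == 0)) {
    stop("degenerate (zero-length) fibril segment", call. = FALSE)
  }
  stopifnot_scalar(forward_gain, "forward_gain", min = 0, strict_min = TRUE)
  stopifnot_scalar(backward_gain, "backward_gain", min = 0, strict_min = TRUE)
  stopifnot_scalar(background_level, "background_level", min = 0)
  stopifnot_scalar(noise_sd, "noise_sd", min = 0)
  structure(
    list(segments = segments, forward_gain = forward_gain,
         backward_gain = backward_gain, background_level = background_level,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "shg_truth"
  )
}

#' Random fibril field helper
#'
#' Draws `n_segments` straight fibril segments uniformly inside a volume,
#' all with the given maturity (or one maturity per segment).
#'
#' @param n_segments Number of segments.
#' @param shape Volume dimensions `c(nx, ny, nz)` in voxels.
#' @param maturity Maturity value(s) in \[0, 1\], recycled to `n_segments`.
#' @param radius Fibril radius in voxels (recycled).
#' @param seed Integer seed for the geometry draw.
#' @return A data frame of segments suitable for [shg_truth()].
#' @export
random_fibril_field <- function(n_segments, shape, maturity = 0.5,
                                radius = 1.5, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 2))
  with_local_seed(seed, {
    p0 <- cbind(runif(n_segments, 1, shape[1]),
                runif(n_segments, 1, shape[2]),
                runif(n_segments, 1, shape[3]))
    # direction mostly in-plane, as in thin-section acquisitions
    theta <- runif(n_segments, 0, 2 * pi)
    len <- runif(n_segments, 0.3, 0.7) * min(shape[1:2])
    dz <- runif(n_segments, -1, 1)
    p1 <- p0 + cbind(cos(theta) * len, sin(theta) * len, dz)
    p1[, 1] <- pmin(pmax(p1[, 1], 1), shape[1])
    p1[, 2] <- pmin(pmax(p1[, 2], 1), shape[2])
    p1[, 3] <- pmin(pmax(p1[, 3], 1), shape[3])
    data.frame(x0 = p0[, 1], y0 = p0[, 2], z0 = p0[, 3],
               x1 = p1[, 1], y1 = p1[, 2], z1 = p1[, 3],
               radius = rep_len(radius, n_segments),
               maturity = rep_len(maturity, n_segments))
  })
}

# distance from every voxel centre to one 3D segment; vectorized over voxels
segment_distance <- function(px, py, pz, seg) {
  dx <- seg$x1 - seg$x0; dy <- seg$y1 - seg$y0; dz <- seg$z1 - seg$z0
  l2 <- dx^2 + dy^2 + dz^2
  t <- ((px - seg$x0) * dx + (py - seg$y0) * dy + (pz - seg$z0) * dz) / l2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (seg$x0 + t * dx))^2 +
       (py - (seg$y0 + t * dy))^2 +
       (pz - (seg$z0 + t * dz))^2)
}

#' Generate a synthetic two-channel SHG stack
#'
#' Renders the fibril segments of an [shg_truth()] into co-registered
#' forward and backward intensity volumes. Each segment is a hard cylinder
#' with an anti-aliased edge (linear intensity falloff over one voxel of
#' distance beyond the radius). A segment of maturity `m` contributes
#' `forward_gain * m * c(v)` to the forward channel and
#' `backward_gain * (1 - m) * c(v)` backward, where `c(v)` is its geometric
#' coverage of voxel `v`; background and Gaussian noise are then added and
#' both channels are clipped to the 16-bit range \[0, 65535\]. Intensities
#' are kept continuous: detector quantization is not modelled.
#'
#' @param truth An [shg_truth()] object.
#' @param shape Stack dimensions `c(nx, ny, nz)` in voxels.
#' @param voxel_size Voxel pitch `c(x, y, z)` in micrometres (metadata only).
#' @return An object of class `shg_stack`: list with `forward` and
#'   `backward` 3D arrays, `voxel_size`, and `meta`.
#' @examples
#' tr <- shg_truth(random_fibril_field(5, c(32, 32, 4), maturity = 0.8))
#' st <- gen_shg_stack(tr, c(32, 32, 4))
#' @export
gen_shg_stack <- function(truth, shape = c(64, 64, 8),
                          voxel_size = c(0.24, 0.24, 1)) {
  stopifnot(inherits(truth, "shg_truth"))
  if (length(shape) != 3L || any(shape < 1)) {
    stop("`shape` must be positive in all three dimensions", call. = FALSE)
  }
  px <- rep(seq_len(shape[1]), times = shape[2] * shape[3])
  py <- rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3])
  pz <- rep(seq_len(shape[3]), each = shape[1] * shape[2])
  cov_f <- numeric(length(px))
  cov_b <- numeric(length(px))
  for (i in seq_len(nrow(truth$segments))) {
    seg <- truth$segments[i, ]
    d <- segment_distance(px, py, pz, seg)
    contrib <- pmin(pmax(seg$radius + 0.5 - d, 0), 1)
    cov_f <- cov_f + truth$forward_gain * seg$maturity * contrib
    cov_b <- cov_b + truth$backward_gain * (1 - seg$maturity) * contrib
  }
  fwd <- cov_f + truth$background_level
  bwd <- cov_b + truth$background_level
  if (truth$noise_sd > 0) {
    noise <- with_local_seed(truth$seed, {
      list(f = stats::rnorm(length(fwd), 0, truth$noise_sd),
           b = stats::rnorm(length(bwd), 0, truth$noise_sd))
    })
    fwd <- fwd + noise$f
    bwd <- bwd + noise$b
  }
  fwd <- pmin(pmax(fwd, 0), 65535)
  bwd <- pmin(pmax(bwd, 0), 65535)
  shg_stack(array(fwd, shape), array(bwd, shape), voxel_size = voxel_size,
            meta = list(seed = truth$seed))
}

#' Construct an SHG stack container
#'
#' @param forward,backward 3D intensity arrays of equal shape, values in the
#'   16-bit range.
#' @param voxel_size Voxel pitch `c(x, y, z)` in micrometres.
#' @param meta Optional metadata list (magnification, labels, seed).
#' @return An object of class `shg_stack`.
#' @export
shg_stack <- function(forward, backward, voxel_size = c(0.24, 0.24, 1),
                      meta = list()) {
  if (!is.array(forward) || !is.array(backward) ||
      length(dim(forward)) != 3L ||
      !identical(dim(forward), dim(backward))) {
    stop("forward and backward must be 3D arrays of identical shape",
         call. = FALSE)
  }
  if (any(forward < 0) || any(backward < 0)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  structure(list(forward = forward, backward = backward,
                 voxel_size = voxel_size, meta = meta),
            class = "shg_stack")
}

#' @export
print.shg_stack <- function(x, ...) {
  d <- dim(x$forward)
  cat(sprintf("<shg_stack> %d x %d x %d voxels, voxel size %s um\n",
              d[1], d[2], d[3], paste(x$voxel_size, collapse = " x ")))
  invisible(x)
}
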