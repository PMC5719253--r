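#' Ground truth for a synthetic AFM micro-indentation force curve
#'
#' Parameters mirror the acquisition protocol: a sphere-tipped probe of
#' radius 2.5 um, a 10 um ramp, and Poisson's ratio 0.4 for soft tissue.
#' Units follow the package convention E in kPa, lengths in um, force in nN
#' (1 kPa x um^2 = 1 nN, see [hertz_force()]).
#'
#' @param E_true True Young's modulus (kPa, >= 0).
#' @param R Probe radius (um, > 0).
#' @param nu Poisson's ratio (0 <= nu < 0.5).
#' @param contact_point Piezo position of tip-surface contact (um).
#' @param baseline_slope Pre-contact drift slope (nN per um).
#' @param noise_sd Additive force noise s.d. (nN).
#' @param noise_rel Multiplicative noise: s.d. as a fraction of the local
#'   force magnitude (0 = off).
#' @param n_points Number of samples along the ramp (>= 50).
#' @param ramp Ramp size (um, > 0).
#' @param seed Integer seed for the noise draw.
#' @return An object of class `curve_truth`.
#' @export
curve_truth <- function(E_true, R = 2.5, nu = 0.4, contact_point = 2,
                        baseline_slope = 0, noise_sd = 0, noise_rel = 0,
                        n_points = 500L, ramp = 10, seed = 1L) {
  stopifnot_scalar(E_true, "E_true", min = 0)
  stopifnot_scalar(R, "R", min = 0, strict_min = TRUE)
  stopifnot_scalar(nu, "nu", min = 0)
  if (nu >= 0.5) stop("`nu` must be < 0.5", call. = FALSE)
  stopifnot_scalar(ramp, "ramp", min = 0, strict_min = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar(noise_rel, "noise_rel", min = 0)
  if (n_points < 50L) stop("`n_points` must be >= 50", call. = FALSE)
  if (contact_point < 0 || contact_point > ramp) {
    stop("`contact_point` must lie within [0, ramp]", call. = FALSE)
  }
  structure(list(E_true = E_true, R = R, nu = nu,
                 contact_point = contact_point,
                 baseline_slope = baseline_slope, noise_sd = noise_sd,
                 noise_rel = noise_rel, n_points = as.integer(n_points),
                 ramp = ramp, seed = as.integer(seed)),
            class = "curve_truth")
}

#' Generate a synthetic force--indentation curve
#'
#' Before contact the force follows the linear baseline drift; past the
#' contact point the Hertz sphere term
#' `(4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)` is added, with
#' `delta = z - contact_point`. Additive and/or multiplicative Gaussian
#' noise is applied last. With `noise_sd = 0` and `noise_rel = 0` the
#' post-contact force is monotone non-decreasing.
#'
#' @param truth A [curve_truth()].
#' @return An object of class `force_curve`: list with `z` (um, strictly
#'   increasing), `force` (nN), `probe_radius`, `poisson_nu`,
#'   `spring_constant` (pN/nm; metadata, `NA` for synthetic curves), `meta`.
#' @examples
#' fc <- gen_force_curve(curve_truth(E_true = 16.52))
#' fit_hertz(fc)$E
#' @export
gen_force_curve <- function(truth) {
  stopifnot(inherits(truth, "curve_truth"))
  z <- seq(0, truth$ramp, length.out = truth$n_points)
  delta <- pmax(z - truth$contact_point, 0)
  force <- truth$baseline_slope * z +
    hertz_force(delta, truth$E_true, truth$R, truth$nu)
  if (truth$noise_sd > 0 || truth$noise_rel > 0) {
    force <- with_local_seed(truth$seed, {
      f <- force
      if (truth$noise_rel > 0) {
        f <- f * (1 + stats::rnorm(length(f), 0, truth$noise_rel))
      }
      if (truth$noise_sd > 0) {
        f <- f + stats::rnorm(length(f), 0, truth$noise_sd)
      }
      f
    })
  }
  force_curve(z, force, probe_radius = truth$R, poisson_nu = truth$nu,
              meta = list(E_true = truth$E_true,
                          contact_point = truth$contact_point,
                          seed = truth$seed))
}

#' Construct a force-curve container
#'
#' @param z Piezo positions (um), strictly increasing.
#' @param force Forces (nN), finite.
#' @param probe_radius Probe radius R (um).
#' @param poisson_nu Poisson's ratio.
#' @param spring_constant Cantilever spring constant (pN/nm), metadata.
#' @param meta Optional metadata list.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(z, force, probe_radius = 2.5, poisson_nu = 0.4,
                        spring_constant = NA_real_, meta = list()) {
  if (length(z) != length(force)) stop("z and force lengths differ", call. = FALSE)
  if (any(diff(z) <= 0)) stop("z must be strictly increasing", call. = FALSE)
  if (!all(is.finite(force))) stop("forces must be finite", call. = FALSE)
  stopifnot_scalar(probe_radius, "probe_radius", min = 0, strict_min = TRUE)
  if (poisson_nu < 0 || poisson_nu >= 0.5) {
    stop("`poisson_nu` must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(z = z, force = force, probe_radius = probe_radius,
                 poisson_nu = poisson_nu, spring_constant = spring_constant,
                 meta = meta),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d points, z %.2f..%.2f um, R=%.2f um, nu=%.2f\n",
              length(x$z), min(x$z), max(x$z), x$probe_radius, x$poisson_nu))
  invisible(x)
}
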