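#' Hertz sphere-model contact force
#'
#' Force exerted by a rigid sphere of radius `R` indenting an elastic
#' half-space to depth `delta`:
#' `F = (4/3) * (E / (1 - nu^2)) * sqrt(R) * delta^(3/2)`.
#'
#' Unit bridge (fixed package-wide): `E` in kPa, lengths in um, force in nN.
#' 1 kPa x um^2 = 1e3 N m^-2 x 1e-12 m^2 = 1e-9 N = 1 nN, so the formula
#' yields nN directly with no extra constant.
#'
#' @param delta Indentation depth(s) (um, >= 0).
#' @param E Young's modulus (kPa).
#' @param R Sphere radius (um).
#' @param nu Poisson's ratio.
#' @return Force(s) in nN.
#' @examples
#' hertz_force(1, E = 10, R = 2.5, nu = 0.4)  # ~25.10 nN
#' @export
hertz_force <- function(delta, E, R = 2.5, nu = 0.4) {
  if (any(delta < 0)) stop("`delta` must be >= 0", call. = FALSE)
  (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * delta^1.5
}

# linear LS fit of force = a + b*z + C*pmax(z - z0, 0)^1.5 on a point subset;
# C clipped at 0 (E >= 0). Returns coefficients and mean squared residual.
hertz_ls <- function(z, force, z0, frac) {
  delta <- pmax(z - z0, 0)
  keep <- delta <= frac * (max(z) - z0) | delta == 0
  zi <- z[keep]; fi <- force[keep]; di <- delta[keep]
  X <- cbind(1, zi, di^1.5)
  fit <- stats::lm.fit(X, fi)
  cf <- fit$coefficients
  clipped <- FALSE
  if (is.na(cf[3]) || cf[3] < 0) {
    fit <- stats::lm.fit(X[, 1:2, drop = FALSE], fi)
    cf <- c(fit$coefficients, 0)
    clipped <- TRUE
  }
  res <- fi - X %*% cf
  list(coef = cf, mse = mean(res^2), rss = sum(res^2),
       n = length(fi), clipped = clipped)
}

#' Fit the Hertz sphere model to a force curve
#'
#' Jointly estimates the contact point, a linear pre-contact baseline and
#' the Young's modulus by least squares. For a candidate contact point `z0`
#' the model `F(z) = a + b z + C max(z - z0, 0)^(3/2)` is linear in
#' `(a, b, C)`; `z0` is chosen by a coarse grid search minimizing the mean
#' squared residual, then refined by golden-section search. The fit is
#' restricted to indentation depths `delta <= max_indentation_fraction`
#' times the post-contact range, mitigating substrate stiffening on thin
#' sections. `C >= 0` (hence `E >= 0`) is enforced by refitting with the
#' Hertz term removed when the unconstrained coefficient is negative.
#'
#' @param curve A [force_curve()].
#' @param nu Poisson's ratio; defaults to the curve's value.
#' @param R Probe radius (um); defaults to the curve's value.
#' @param max_indentation_fraction Fraction of the post-contact range fitted
#'   (default 0.5).
#' @param n_grid Number of contact-point grid candidates.
#' @param min_post,min_pre Minimum post-/pre-contact samples for a candidate.
#' @param tol Golden-section tolerance on `z0` (um).
#' @return An object of class `hertz_fit`: `E` (kPa), `contact_point` (um),
#'   `baseline` (`c(intercept, slope)`), `rss` (nN^2), `n_fit_points`,
#'   `converged`, `diagnostics`.
#' @export
fit_hertz <- function(curve, nu = NULL, R = NULL,
                      max_indentation_fraction = 0.5, n_grid = 60L,
                      min_post = 20L, min_pre = 5L, tol = 1e-6) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$z; force <- curve$force
  nu <- nu %||% curve$poisson_nu
  R <- R %||% curve$probe_radius
  n <- length(z)
  if (n < min_post + min_pre) {
    stop("curve too short for fitting", call. = FALSE)
  }
  lo <- z[min_pre]
  hi <- z[n - min_post]
  if (hi <= lo) stop("not enough samples to bracket a contact point", call. = FALSE)
  frac <- max_indentation_fraction
  obj <- function(z0) hertz_ls(z, force, z0, frac)$mse
  grid <- seq(lo, hi, length.out = n_grid)
  mse <- vapply(grid, obj, numeric(1))
  k <- which.min(mse)
  a <- grid[max(k - 1L, 1L)]; b <- grid[min(k + 1L, n_grid)]
  # golden-section refinement inside the bracketing grid interval
  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- obj(x1); f2 <- obj(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- obj(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- obj(x2)
    }
  }
  z0 <- (a + b) / 2
  fit <- hertz_ls(z, force, z0, frac)
  E <- 0.75 * fit$coef[3] * (1 - nu^2) / sqrt(R)
  boundary <- k %in% c(1L, n_grid)
  structure(list(
    E = unname(E),
    contact_point = z0,
    baseline = c(intercept = unname(fit$coef[1]), slope = unname(fit$coef[2])),
    rss = fit$rss,
    n_fit_points = fit$n,
    converged = !boundary,
    diagnostics = list(grid_mse_min = mse[k], boundary = boundary,
                       hertz_term_clipped = fit$clipped,
                       nu = nu, R = R,
                       max_indentation_fraction = frac)),
    class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E = %.4g kPa, contact point = %.3f um, rss = %.3g nN^2, %s\n",
              x$E, x$contact_point, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Aggregate per-curve moduli into per-group stiffness summaries
#'
#' @param fits Data frame with a numeric `E` column, a logical `converged`
#'   column, and the grouping columns named in `by`.
#' @param by Character vector of grouping column names (e.g. subject,
#'   treatment, area).
#' @return Data frame with one row per group: `n`, `n_failed`, `median_E`,
#'   `q1_E`, `q3_E`. Failed fits are counted, never silently dropped.
#' @export
aggregate_stiffness <- function(fits, by = "treatment") {
  stopifnot(all(c("E", "converged", by) %in% names(fits)))
  key <- interaction(fits[by], drop = TRUE, lex.order = TRUE)
  if (nlevels(key) == 0L) stop("no groups present", call. = FALSE)
  rows <- lapply(levels(key), function(lv) {
    g <- fits[key == lv, , drop = FALSE]
    ok <- g$converged & is.finite(g$E)
    if (!any(ok)) warning("group ", lv, " has no successful fits", call. = FALSE)
    qs <- if (any(ok)) stats::quantile(g$E[ok], c(0.25, 0.5, 0.75), names = FALSE)
          else rep(NA_real_, 3)
    cbind(g[1, by, drop = FALSE],
          data.frame(n = nrow(g), n_failed = sum(!ok),
                     median_E = qs[2], q1_E = qs[1], q3_E = qs[3]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal--Wallis test with Dunn's post-hoc comparisons
#'
#' Global Kruskal--Wallis rank test followed by Dunn's pairwise z tests with
#' tie correction; pairwise p-values are adjusted with the classical
#' Bonferroni family correction over all pairs. Degenerate input in which
#' every observation is equal returns p = 1 throughout rather than failing.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor/character vector of group labels, same length.
#' @param p_adjust Adjustment method for the pairwise family
#'   (default `"bonferroni"`).
#' @return An object of class `kruskal_dunn`: `kw` (list with `statistic`,
#'   `df`, `p_value`) and `pairwise` (data frame with `group1`, `group2`,
#'   `z`, `p_unadjusted`, `p_adjusted`).
#' @export
kruskal_dunn <- function(values, groups, p_adjust = "bonferroni") {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 3L)) stop("each group needs n >= 3", call. = FALSE)
  pairs <- utils::combn(levels(groups), 2)
  if (length(unique(values)) == 1L) {
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     z = 0, p_unadjusted = 1, p_adjusted = 1)
    return(structure(list(kw = list(statistic = 0, df = nlevels(groups) - 1L,
                                    p_value = 1),
                          pairwise = pw), class = "kruskal_dunn"))
  }
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt(s2 * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z[j] <- (rbar[[g1]] - rbar[[g2]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                   p_unadjusted = p,
                   p_adjusted = stats::p.adjust(p, method = p_adjust))
  structure(list(kw = list(statistic = unname(kw$statistic),
                           df = unname(kw$parameter),
                           p_value = kw$p.value),
                 pairwise = pw),
            class = "kruskal_dunn")
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.3g\n",
              x$kw$statistic, x$kw$df, x$kw$p_value))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
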