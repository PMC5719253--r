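# AFM: Hertz formula, curve generation, fitting, aggregation, group tests

test_that("hertz_force matches the closed form and its symmetries", {
  expect_equal(hertz_force(0, 10), 0)
  # hand-evaluated oracle: (4/3) * (10 / (1 - 0.4^2)) * sqrt(2.5) * 1^1.5
  expect_equal(hertz_force(1, 10, 2.5, 0.4), (4 / 3) * (10 / 0.84) * sqrt(2.5))
  expect_equal(hertz_force(1, 10, 2.5, 0.4), 25.0988, tolerance = 1e-4)
  expect_equal(hertz_force(1, 20, 2.5, 0.4), 2 * hertz_force(1, 10, 2.5, 0.4))
  expect_equal(hertz_force(4, 10, 2.5, 0.4), 8 * hertz_force(1, 10, 2.5, 0.4))
  expect_error(hertz_force(-0.1, 10), ">= 0")
})

test_that("generated curves follow baseline + Hertz with seeded noise", {
  tr <- curve_truth(E_true = 0, baseline_slope = 0.5)
  fc <- gen_force_curve(tr)
  expect_equal(fc$force, 0.5 * fc$z)          # pure drift

  tr <- curve_truth(E_true = 10, contact_point = 2)
  fc <- gen_force_curve(tr)
  pre <- fc$z < 2
  expect_true(all(fc$force[pre] == 0))
  delta <- pmax(fc$z - 2, 0)
  expect_equal(fc$force, hertz_force(delta, 10, 2.5, 0.4))
  expect_true(all(diff(fc$force) >= 0))       # monotone when noiseless

  noisy <- curve_truth(E_true = 10, noise_sd = 0.5, seed = 8)
  expect_identical(gen_force_curve(noisy)$force, gen_force_curve(noisy)$force)
  expect_error(curve_truth(E_true = 10, nu = 0.5), "nu")
  expect_error(curve_truth(E_true = 10, n_points = 10), "n_points")
})

test_that("noiseless curves are refit to within 0.1% across the stiffness range", {
  for (E in c(1.96, 10, 16.52, 60)) {
    fc <- gen_force_curve(curve_truth(E_true = E, contact_point = 2))
    fit <- fit_hertz(fc)
    expect_true(fit$converged)
    expect_lt(abs(fit$E - E) / E, 0.001)
    expect_lt(abs(fit$contact_point - 2), diff(fc$z[1:2]))
  }
  # with baseline drift present
  fc <- gen_force_curve(curve_truth(E_true = 16.52, contact_point = 3,
                                    baseline_slope = 0.2))
  fit <- fit_hertz(fc)
  expect_lt(abs(fit$E - 16.52) / 16.52, 0.001)
  expect_equal(unname(fit$baseline["slope"]), 0.2, tolerance = 1e-3)
})

test_that("a pure-baseline curve yields E below 0.05 kPa, never negative", {
  fc <- gen_force_curve(curve_truth(E_true = 0, baseline_slope = 0.3,
                                    noise_sd = 0.02, seed = 4))
  fit <- fit_hertz(fc)
  expect_gte(fit$E, 0)
  expect_lt(fit$E, 0.05)
})

test_that("fit is shift-invariant in z and scales linearly with force", {
  fc <- gen_force_curve(curve_truth(E_true = 12, contact_point = 2,
                                    noise_sd = 0.1, seed = 21))
  fit <- fit_hertz(fc)
  shifted <- force_curve(fc$z + 1.7, fc$force, probe_radius = fc$probe_radius,
                         poisson_nu = fc$poisson_nu)
  fit_s <- fit_hertz(shifted)
  expect_equal(fit_s$E, fit$E, tolerance = 1e-6)
  expect_equal(fit_s$contact_point, fit$contact_point + 1.7, tolerance = 1e-4)

  scaled <- force_curve(fc$z, fc$force * 3, probe_radius = fc$probe_radius,
                        poisson_nu = fc$poisson_nu)
  expect_equal(fit_hertz(scaled)$E, 3 * fit$E, tolerance = 1e-6)
})

test_that("noisy replicates recover the modulus with small bias and no failures", {
  E_true <- 16.52
  fits <- vapply(1:100, function(s) {
    fc <- gen_force_curve(curve_truth(E_true = E_true, contact_point = 2,
                                      noise_rel = 0.01, seed = s))
    fit <- fit_hertz(fc)
    expect_true(fit$converged)
    fit$E
  }, numeric(1))
  expect_lt(abs(median(fits) - E_true) / E_true, 0.05)
  expect_lt(abs(mean(fits) - E_true) / E_true, 0.02)
})

test_that("force curves round-trip through CSV + YAML sidecar", {
  curves <- list(a = gen_force_curve(curve_truth(E_true = 5, seed = 1)),
                 b = gen_force_curve(curve_truth(E_true = 20, noise_sd = 0.3,
                                                 seed = 2)))
  path <- tempfile(fileext = ".csv")
  write_force_curves(curves, path)
  parsed <- parse_force_curves(path)
  expect_named(parsed$curves, c("a", "b"))
  expect_equal(parsed$curves$a$z, curves$a$z)
  expect_equal(parsed$curves$a$force, curves$a$force)
  expect_equal(parsed$curves$b$probe_radius, 2.5)
  expect_equal(nrow(parsed$rejected), 0L)

  # deflection + spring constant form: force = k * deflection / 1000
  tab <- data.frame(z_um = seq(0, 10, length.out = 60),
                    deflection_nm = seq(0, 50, length.out = 60))
  p2 <- tempfile(fileext = ".csv")
  write.csv(tab, p2, row.names = FALSE)
  parsed2 <- parse_force_curves(p2, default_meta = list(spring_constant_pN_nm = 100))
  expect_equal(parsed2$curves$curve1$force, 100 * tab$deflection_nm / 1000)

  # non-monotone z rejected with a reason, not dropped silently
  bad <- data.frame(z_um = c(0, 1, 0.5, 2), force_nN = 1:4)
  p3 <- tempfile(fileext = ".csv")
  write.csv(bad, p3, row.names = FALSE)
  parsed3 <- parse_force_curves(p3)
  expect_length(parsed3$curves, 0L)
  expect_match(parsed3$rejected$reason, "increasing")
})

test_that("per-group stiffness summaries count failures and match a sort oracle", {
  one <- data.frame(E = 7, converged = TRUE, treatment = "ctrl")
  expect_equal(aggregate_stiffness(one)$median_E, 7)
  tri <- data.frame(E = c(1, 2, 3), converged = TRUE, treatment = "ctrl")
  expect_equal(aggregate_stiffness(tri)$median_E, 2)

  # 3 areas x 35 curves per treatment group
  set.seed(12)
  fits <- expand.grid(area = paste0("a", 1:3), i = 1:35,
                      treatment = c("ctrl", "tgfb"))
  fits$E <- rlnorm(nrow(fits), log(ifelse(fits$treatment == "ctrl", 5, 40)), 0.3)
  fits$converged <- TRUE
  agg <- aggregate_stiffness(fits, by = "treatment")
  expect_equal(agg$n, c(105L, 105L))
  for (g in agg$treatment) {
    vals <- sort(fits$E[fits$treatment == g])
    expect_equal(agg$median_E[agg$treatment == g], median(vals))
    expect_equal(agg$q1_E[agg$treatment == g],
                 unname(quantile(vals, 0.25)))
  }
  fits$converged[fits$treatment == "tgfb"][1:5] <- FALSE
  agg <- aggregate_stiffness(fits, by = "treatment")
  expect_equal(agg$n_failed, c(0L, 5L))
  expect_equal(agg$n, c(105L, 105L))   # failures counted, not dropped
})

test_that("Kruskal-Wallis/Dunn separates stiffness groups and handles ties", {
  # identical groups: adjusted p ~ 1
  kd <- kruskal_dunn(rep(c(1, 2, 3, 4), 2), rep(c("a", "b"), each = 4))
  expect_gt(min(kd$pairwise$p_adjusted), 0.85)

  # degenerate all-equal input: p = 1 report, no crash
  kd0 <- kruskal_dunn(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(kd0$kw$p_value, 1)
  expect_true(all(kd0$pairwise$p_adjusted == 1))

  # strongly separated stiffness generators: 2 vs 16 kPa, 5% noise
  E_soft <- vapply(1:100, function(s)
    fit_hertz(gen_force_curve(curve_truth(E_true = 2, noise_rel = 0.05,
                                          seed = s)))$E, numeric(1))
  E_stiff <- vapply(1:100, function(s)
    fit_hertz(gen_force_curve(curve_truth(E_true = 16, noise_rel = 0.05,
                                          seed = 100 + s)))$E, numeric(1))
  kd <- kruskal_dunn(c(E_soft, E_stiff), rep(c("soft", "stiff"), each = 100))
  expect_lt(kd$pairwise$p_adjusted, 1e-4)
  expect_lt(kd$kw$p_value, 1e-4)

  expect_error(kruskal_dunn(1:5, rep("a", 5)), "two groups")
  expect_error(kruskal_dunn(1:4, c("a", "a", "b", "b")), "n >= 3")
})

test_that("asymptotic Kruskal-Wallis p agrees with a permutation oracle", {
  set.seed(5)
  values <- c(rnorm(6, 0), rnorm(6, 1.2), rnorm(6, 0.4))
  groups <- rep(c("a", "b", "c"), each = 6)
  kd <- kruskal_dunn(values, groups)
  p_perm <- oracle_kw_perm(values, groups, n_perm = 4000)
  mc_se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(kd$kw$p_value - p_perm), 4 * mc_se + 0.01)
})
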