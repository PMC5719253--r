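# Cohort statistics: generator, normality gate, correlation, PAF/promax

test_that("cohort generator honours loadings, shifts and the seed", {
  tr <- default_cohort_truth(seed = 7)
  a <- gen_cohort(tr)
  b <- gen_cohort(tr)
  expect_identical(a, b)
  expect_equal(nrow(a), 200L)
  expect_setequal(unique(a$group), c("non-IPF", "IPF"))

  # zero loadings: variables pairwise uncorrelated in expectation
  tr0 <- cohort_truth(matrix(0, 4, 2) + diag(1e-9, 4)[, 1:2],
                      uniqueness = 1, n_per_group = 100, seed = 2)
  tab0 <- gen_cohort(tr0)
  cc <- cor(as.matrix(tab0[, -(1:2)]))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.2)

  expect_error(gen_cohort(default_cohort_truth(), variables = c("x", "y")),
               "loading-matrix rows")
  expect_error(cohort_truth(cbind(c(1, 1), c(2, 2))), "rank")
  expect_error(cohort_truth(diag(2), uniqueness = 0), "uniqueness")
})

test_that("omnibus normality statistics match independently computed values", {
  # frozen oracle values from an independent implementation of the
  # D'Agostino-Pearson omnibus test (scipy.stats.normaltest)
  x1 <- c(0.5, -1.2, 0.3, 2.1, -0.7, 1.5, -0.2, 0.9, -1.8, 0.4,
          1.1, -0.6, 0.8, 2.4, -1.0, 0.1, 0.7, -0.4, 1.9, -2.2)
  r1 <- dagostino_pearson(x1)
  expect_equal(r1$statistic, 0.2594380945, tolerance = 1e-9)
  expect_equal(r1$p_value, 0.8783421689, tolerance = 1e-9)
  expect_equal(r1$z_skewness, -0.2703875590, tolerance = 1e-9)
  expect_equal(r1$z_kurtosis, -0.4316580388, tolerance = 1e-9)

  x2 <- c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4, 12.8, 25.6, 51.2)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$statistic, 13.5010513313, tolerance = 1e-9)
  expect_equal(r2$p_value, 0.0011702643, tolerance = 1e-6)

  expect_error(dagostino_pearson(rnorm(7)), "n >= 8")
})

test_that("two-group test branches on the normality gate", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.8, 2.9, 3.3, 1.7, 2.5)
  r <- two_group_test(x, x)
  expect_gt(r$p_value, 0.99)

  set.seed(10)
  a <- rnorm(20); b <- rnorm(20, 3)
  r <- two_group_test(a, b)
  expect_identical(r$branch, "t")
  expect_lt(r$p_value, 0.001)

  # heavy-tailed data routes to Mann-Whitney
  set.seed(11)
  h1 <- exp(rnorm(30, 0, 1.5)); h2 <- exp(rnorm(30, 1, 1.5))
  r <- two_group_test(h1, h2)
  expect_identical(r$branch, "mann-whitney")
  expect_identical(r$reason, "omnibus normality rejected")
  # the branch is a pure function of the gate outcome
  gate <- c(dagostino_pearson(h1)$p_value, dagostino_pearson(h2)$p_value)
  expect_true(any(gate <= 0.05))

  # below the n >= 8 gate: nonparametric fallback, no omnibus attempted
  r <- two_group_test(c(1, 2, 3, 4, 5, 6, 7), rnorm(20))
  expect_identical(r$branch, "mann-whitney")
  expect_match(r$reason, "n < 8")

  r <- two_group_test(rep(2, 5), rep(2, 5))
  expect_equal(r$p_value, 1)
  expect_error(two_group_test(1:2, 1:5), "n >= 3")
})

test_that("correlation is symmetric with R^2 = r^2 and sane null behaviour", {
  tab <- data.frame(a = 1:20, b = 2 * (1:20))
  r <- correlate(tab, "a", "b")
  expect_equal(r$r, 1)
  expect_equal(r$r_squared, 1)

  set.seed(3)
  tab <- data.frame(a = rnorm(200), b = rnorm(200))
  r <- correlate(tab, "a", "b")
  expect_lt(abs(r$r), 0.2)
  expect_equal(r$r, correlate(tab, "b", "a")$r)
  expect_equal(r$r_squared, r$r^2)

  tab$b[1:5] <- NA            # pairwise-complete handling
  expect_equal(correlate(tab, "a", "b")$n, 195L)
  expect_error(correlate(data.frame(a = rep(1, 5), b = 1:5), "a", "b"),
               "zero variance")
})

test_that("R^2 at n = 15 under rho = 0.87 sits in the reported magnitude regime", {
  rho <- 0.87
  r2 <- vapply(1:1000, function(s) {
    set.seed(s)
    f <- rnorm(15)
    x <- f + rnorm(15) * sqrt(1 / rho^2 - 1)
    cor(f, x)^2
  }, numeric(1))
  # E[R^2] ~ rho^2 plus small finite-sample bias
  expect_equal(mean(r2), rho^2, tolerance = 0.04 / rho^2)
})

test_that("principal axis factoring recovers planted structures", {
  # identity correlation: nothing in common
  fit <- paf(diag(4), 1)
  expect_lt(max(fit$communalities), 1e-4)
  expect_lt(max(abs(fit$loadings)), 0.02)

  # single factor, loadings 0.8: closed-form communality 0.64
  L <- rep(0.8, 6)
  R <- outer(L, L); diag(R) <- 1
  fit <- paf(R, 1)
  expect_equal(unname(fit$loadings[, 1]), L, tolerance = 1e-4)
  expect_equal(unname(fit$communalities), rep(0.64, 6), tolerance = 1e-3)

  expect_error(paf(matrix(c(1, 2, 3, 4), 2), 1), "symmetric")
  expect_error(paf(diag(4), 4), "n_factors")
})

test_that("promax rotation matches stats::promax and leaves simple structure alone", {
  # independent cross-check on a non-trivial loading matrix
  set.seed(15)
  tab <- gen_cohort(cohort_truth(
    rbind(c(0.8, 0), c(0.75, 0.2), c(0.1, 0.8), c(0, 0.7), c(0.4, 0.5)),
    uniqueness = 0.3, n_per_group = 250, seed = 15))
  fit <- paf(cor(as.matrix(tab[, -(1:2)])), 2)
  ours <- promax_rotation(fit$loadings, kappa = 4)
  ref <- stats::promax(fit$loadings, m = 4)
  cg <- factor_congruence(unclass(ref$loadings), ours$pattern)
  expect_gt(cg$min_congruence, 0.9999)

  # already-simple orthogonal structure is a fixed point up to perm/sign
  L <- rbind(c(0.8, 0), c(0.7, 0), c(0, 0.8), c(0, 0.7))
  rot <- promax_rotation(L)
  cg <- factor_congruence(L, rot$pattern)
  expect_gt(cg$min_congruence, 0.999)
  expect_lt(max(abs(rot$factor_correlations[1, 2])), 0.1)

  # kappa = 2 vs 4 preserves the dominant pattern
  r2 <- promax_rotation(fit$loadings, kappa = 2)
  r4 <- promax_rotation(fit$loadings, kappa = 4)
  expect_identical(apply(abs(r2$pattern), 1, which.max),
                   apply(abs(r4$pattern), 1, which.max))

  expect_error(promax_rotation(matrix(0, 4, 2)), "degenerate")
  expect_error(promax_rotation(L[, 1, drop = FALSE]), ">= 2 factors")
})

test_that("correlated planted factors are recovered within tolerance", {
  # factor correlation 0.5, n = 500
  L <- rbind(c(0.8, 0), c(0.7, 0), c(0.75, 0), c(0, 0.8), c(0, 0.7), c(0, 0.75))
  phi <- matrix(c(1, 0.5, 0.5, 1), 2)
  set.seed(77)
  ch <- chol(phi)
  f <- matrix(rnorm(500 * 2), 500, 2) %*% ch
  X <- f %*% t(L) + matrix(rnorm(500 * 6), 500, 6) * sqrt(0.3)
  fit <- paf(cor(X), 2)
  rot <- promax_rotation(fit$loadings)
  expect_lt(abs(abs(rot$factor_correlations[1, 2]) - 0.5), 0.15)
  cg <- factor_congruence(L, rot$pattern)
  expect_gt(cg$min_congruence, 0.95)
})

test_that("Kaiser rule counts eigenvalues at or above one, invariantly", {
  expect_equal(scree_select(c(2.5, 1.3, 0.4, 0.1)), 2)
  expect_equal(scree_select(eigen(diag(5))$values), 5)   # boundary inclusive

  tab <- gen_cohort(default_cohort_truth(seed = 19))
  X <- as.matrix(tab[, -(1:2)])
  ev <- eigen(cor(X), only.values = TRUE)$values
  expect_equal(scree_select(ev), 2)
  # invariant to variable order and sign flips
  Xp <- X[, c(3, 1, 4, 2)]; Xp[, 2] <- -Xp[, 2]
  expect_equal(scree_select(eigen(cor(Xp), only.values = TRUE)$values), 2)
})

test_that("group scores weight z-scored variables by loading strength", {
  tab <- gen_cohort(default_cohort_truth(seed = 23))
  # one factor, equal loadings: score is the plain mean of z-scores
  m1 <- structure(list(pattern = matrix(0.7, 4, 1,
                         dimnames = list(paste0("V", 1:4), "F1")),
                       variables = paste0("V", 1:4), n_factors = 1L),
                  class = "factor_model")
  gs <- group_scores(tab, m1)
  expect_equal(unname(gs$scores$F1),
               unname(rowMeans(scale(as.matrix(tab[, -(1:2)])))))

  # loading vector (1, 0, 0, 0): score is the first standardized variable
  m2 <- m1
  m2$pattern <- matrix(c(1, 0, 0, 0), 4, 1,
                       dimnames = list(paste0("V", 1:4), "F1"))
  gs2 <- group_scores(tab, m2)
  expect_equal(unname(gs2$scores$F1), unname(scale(tab$V1)[, 1]))

  # shifted cohort: separation only on the factor carrying the shift
  fm <- suppressWarnings(factor_model(tab))
  gs3 <- group_scores(tab, fm)
  shifted <- which.max(abs(fm$pattern["V1", ]))   # factor of shifted V1/V2
  other <- setdiff(1:2, shifted)
  expect_lt(gs3$tests[[shifted]]$p_value, 0.01)
  expect_gt(gs3$tests[[other]]$p_value, 0.05)

  # listwise exclusion of incomplete subjects, with a log
  tab$V2[3] <- NA
  expect_message(gs4 <- group_scores(tab, fm), "excluding 1 subject")
  expect_equal(nrow(gs4$scores), 199L)
  expect_identical(as.character(gs4$excluded), tab$subject[3])
})

test_that("factor_model composes the pipeline on the default cohort", {
  tab <- gen_cohort(default_cohort_truth(seed = 7))
  fm <- suppressWarnings(factor_model(tab))
  expect_equal(fm$n_factors, 2L)
  expect_true(all(fm$communalities >= 0 & fm$communalities <= 1))
  expect_equal(fm$eigenvalues, sort(fm$eigenvalues, decreasing = TRUE))
  cg <- factor_congruence(default_cohort_truth()$loading_matrix, fm$pattern)
  expect_gt(cg$min_congruence, 0.95)
})
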