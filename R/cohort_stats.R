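#' D'Agostino--Pearson omnibus normality test
#'
#' Combines the transformed skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983) z statistics into `K2 = z_skew^2 + z_kurt^2`,
#' referred to a chi-squared distribution with 2 df.
#'
#' @param x Numeric vector, `n >= 8`.
#' @return List with `statistic` (K2), `p_value`, `z_skewness`,
#'   `z_kurtosis`, `n`.
#' @references D'Agostino, Belanger & D'Agostino Jr (1990), The American
#'   Statistician 44:316-321.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("omnibus normality test requires n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance", call. = FALSE)
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2
  # skewness z
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  dlt <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  zs <- dlt * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis z
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (g2 - Eb2) / sqrt(Vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xs * sqrt(2 / (A - 4))))^(1 / 3)) *
    sqrt(9 * A / 2)
  K2 <- zs^2 + zk^2
  list(statistic = K2, p_value = stats::pchisq(K2, 2, lower.tail = FALSE),
       z_skewness = zs, z_kurtosis = zk, n = n)
}

#' Normality-gated two-group comparison
#'
#' Tests each group for normality with the D'Agostino--Pearson omnibus test;
#' if both pass (p > `alpha_normality`) the groups are compared with
#' Student's unpaired two-tailed t-test, otherwise with the Mann--Whitney
#' U test. The omnibus test needs `n >= 8` per group; below that the
#' nonparametric branch is taken directly (typical cohort sizes of 7-10 sit
#' at this edge). Two identical constant groups return p = 1.
#'
#' @param x,y Numeric vectors (each `n >= 3`).
#' @param alpha_normality Normality-gate significance level (default 0.05).
#' @return An object of class `two_group_test`: `branch` (`"t"` or
#'   `"mann-whitney"`), `statistic`, `p_value`, `normality` (per-group
#'   omnibus p or `NA` when gated out), `reason`.
#' @export
two_group_test <- function(x, y, alpha_normality = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L) {
    stop("each group needs n >= 3", call. = FALSE)
  }
  if (length(unique(c(x, y))) == 1L) {
    return(structure(list(branch = "degenerate", statistic = 0, p_value = 1,
                          normality = c(x = NA_real_, y = NA_real_),
                          reason = "all observations equal"),
                     class = "two_group_test"))
  }
  small <- length(x) < 8L || length(y) < 8L
  constant <- stats::var(x) == 0 || stats::var(y) == 0
  if (small || constant) {
    norm_p <- c(x = NA_real_, y = NA_real_)
    branch <- "mann-whitney"
    reason <- if (small) "n < 8: normality gate not applicable" else
      "constant group: normality gate not applicable"
  } else {
    norm_p <- c(x = dagostino_pearson(x)$p_value,
                y = dagostino_pearson(y)$p_value)
    normal <- all(norm_p > alpha_normality)
    branch <- if (normal) "t" else "mann-whitney"
    reason <- if (normal) "both groups pass omnibus normality" else
      "omnibus normality rejected"
  }
  if (branch == "t") {
    ht <- stats::t.test(x, y, var.equal = TRUE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
  }
  structure(list(branch = branch, statistic = unname(ht$statistic),
                 p_value = ht$p.value, normality = norm_p, reason = reason),
            class = "two_group_test")
}

#' @export
print.two_group_test <- function(x, ...) {
  cat(sprintf("two-group test [%s branch: %s]: statistic = %.4g, p = %.4g\n",
              x$branch, x$reason, x$statistic, x$p_value))
  invisible(x)
}

#' Pearson correlation between two cohort variables
#'
#' Pairwise-complete Pearson correlation with `R^2 = r^2` and a two-tailed
#' p-value. Cohorts are pooled across groups (the study combines disease
#' and control subjects to span the full remodelling spectrum).
#'
#' @param table Cohort data frame.
#' @param var_a,var_b Column names.
#' @return List with `r`, `r_squared`, `p_value`, `n`.
#' @export
correlate <- function(table, var_a, var_b) {
  stopifnot(all(c(var_a, var_b) %in% names(table)))
  a <- table[[var_a]]; b <- table[[var_b]]
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("undefined correlation: zero variance in ",
         if (stats::var(a) == 0) var_a else var_b, call. = FALSE)
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n = length(a))
}

#' Principal axis factoring of a correlation matrix
#'
#' Iterative common-factor extraction: communalities are initialized with
#' squared multiple correlations, the reduced correlation matrix (diagonal
#' replaced by communalities) is eigen-decomposed, loadings are taken from
#' the top `n_factors` components, and the communalities are updated from
#' the loadings until the largest change falls below `tol`. Heywood cases
#' (communalities above 1) are clipped with a warning. Negative eigenvalues
#' of the reduced matrix are truncated at zero.
#'
#' @param corr Symmetric correlation matrix.
#' @param n_factors Number of factors to extract (>= 1).
#' @param tol Convergence tolerance on the communality change. The default
#'   0.001 follows the convention of mainstream factor-analysis software;
#'   much tighter tolerances are unattainable for factors with only two
#'   indicators, whose loadings are identified only through their product
#'   and whose communalities drift toward the Heywood boundary.
#' @param max_iter Maximum iterations; non-convergence is an error carrying
#'   the communality trace in its `communality_trace` field.
#' @return List with `loadings` (variables x factors, unrotated),
#'   `communalities`, `iterations`.
#' @export
paf <- function(corr, n_factors, tol = 1e-3, max_iter = 1000L) {
  corr <- as.matrix(corr)
  p <- nrow(corr)
  if (p != ncol(corr) || max(abs(corr - t(corr))) > 1e-8) {
    stop("`corr` must be a symmetric matrix", call. = FALSE)
  }
  if (n_factors < 1L || n_factors >= p) {
    stop("`n_factors` must be in [1, p - 1]", call. = FALSE)
  }
  # squared multiple correlations as starting communalities
  inv <- tryCatch(solve(corr), error = function(e) NULL)
  h2 <- if (is.null(inv)) rep(0.5, p) else 1 - 1 / diag(inv)
  h2 <- pmin(pmax(h2, 0), 1)
  trace <- list()
  for (it in seq_len(max_iter)) {
    red <- corr
    diag(red) <- h2
    eg <- eigen(red, symmetric = TRUE)
    lam <- pmax(eg$values[seq_len(n_factors)], 0)
    L <- eg$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(lam), n_factors)
    h2_new <- rowSums(L^2)
    if (any(h2_new > 1)) {
      warning("Heywood case: communality > 1 clipped", call. = FALSE)
      h2_new <- pmin(h2_new, 1)
    }
    delta <- max(abs(h2_new - h2))
    trace[[it]] <- h2_new
    h2 <- h2_new
    if (delta < tol) {
      # orient factors so dominant loadings are positive (sign convention)
      sgn <- sign(colSums(L^3))
      sgn[sgn == 0] <- 1
      L <- L %*% diag(sgn, n_factors)
      rownames(L) <- rownames(corr)
      colnames(L) <- paste0("F", seq_len(n_factors))
      return(list(loadings = L, communalities = h2, iterations = it))
    }
  }
  err <- simpleError(sprintf("PAF did not converge in %d iterations", max_iter))
  err$communality_trace <- trace
  stop(err)
}

#' Promax oblique rotation
#'
#' Varimax pre-rotation followed by the standard promax target transform:
#' varimax loadings are raised (sign-preserving) to power `kappa`, the
#' least-squares transform onto that target is column-normalized, and the
#' resulting oblique pattern matrix and factor intercorrelations are
#' returned.
#'
#' @param loadings Unrotated loadings (variables x factors, >= 2 factors).
#' @param kappa Promax power (default 4, the conventional value).
#' @return List with `pattern` (rotated pattern matrix), `rotmat`, and
#'   `factor_correlations`.
#' @export
promax_rotation <- function(loadings, kappa = 4) {
  loadings <- as.matrix(loadings)
  if (ncol(loadings) < 2L) stop("promax needs >= 2 factors", call. = FALSE)
  if (all(loadings == 0)) stop("degenerate zero loadings", call. = FALSE)
  vm <- stats::varimax(loadings)
  V <- vm$loadings
  class(V) <- NULL
  target <- V * abs(V)^(kappa - 1)
  U <- solve(crossprod(V), crossprod(V, target))
  U <- U %*% diag(sqrt(diag(solve(crossprod(U)))), ncol(U))
  pattern <- V %*% U
  phi <- solve(crossprod(U))
  # harmonize: factors oriented so dominant loadings are positive
  sgn <- sign(colSums(pattern^3))
  sgn[sgn == 0] <- 1
  pattern <- pattern %*% diag(sgn, ncol(pattern))
  phi <- diag(sgn, ncol(phi)) %*% phi %*% diag(sgn, ncol(phi))
  dimnames(pattern) <- dimnames(loadings)
  dimnames(phi) <- list(colnames(loadings), colnames(loadings))
  list(pattern = pattern, rotmat = vm$rotmat %*% U %*% diag(sgn, ncol(U)),
       factor_correlations = phi)
}

#' Kaiser criterion factor count
#'
#' Number of correlation-matrix eigenvalues greater than or equal to 1
#' (boundary inclusive). Invariant to variable order and sign flips, both
#' of which leave the eigenvalue spectrum unchanged.
#'
#' @param eigenvalues Eigenvalues of a correlation matrix (any order).
#' @return Integer factor count.
#' @export
scree_select <- function(eigenvalues) {
  sum(eigenvalues >= 1)
}

#' Fit a factor model to a cohort table
#'
#' Listwise-complete subjects are used to form the Pearson correlation
#' matrix of the variables; the factor count is chosen by the Kaiser
#' (eigenvalue >= 1) rule unless given; principal axis factoring extracts
#' the loadings and promax rotation obliquely rotates them.
#'
#' @param table Cohort data frame (`subject`, `group`, variables), or a
#'   plain numeric data frame of variables.
#' @param variables Variable columns to model; default all numeric columns
#'   except `subject`/`group`.
#' @param n_factors `"auto"` (Kaiser rule) or an integer.
#' @param kappa Promax power.
#' @return An object of class `factor_model`: `eigenvalues`, `n_factors`,
#'   `pattern`, `communalities`, `factor_correlations`, `variables`,
#'   `n_used`.
#' @export
factor_model <- function(table, variables = NULL, n_factors = "auto",
                         kappa = 4) {
  variables <- variables %||%
    setdiff(names(table)[vapply(table, is.numeric, logical(1))],
            c("subject", "group"))
  X <- table[, variables, drop = FALSE]
  complete <- stats::complete.cases(X)
  X <- as.matrix(X[complete, , drop = FALSE])
  if (nrow(X) < length(variables) + 1L) {
    stop("too few listwise-complete subjects", call. = FALSE)
  }
  corr <- stats::cor(X)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  k <- if (identical(n_factors, "auto")) scree_select(ev) else as.integer(n_factors)
  if (k < 1L) stop("Kaiser rule selected zero factors", call. = FALSE)
  fit <- paf(corr, k)
  if (k >= 2L) {
    rot <- promax_rotation(fit$loadings, kappa = kappa)
    pattern <- rot$pattern
    phi <- rot$factor_correlations
  } else {
    pattern <- fit$loadings
    phi <- matrix(1, 1, 1, dimnames = list("F1", "F1"))
  }
  structure(list(eigenvalues = ev, n_factors = k, pattern = pattern,
                 communalities = fit$communalities,
                 factor_correlations = phi, variables = variables,
                 n_used = nrow(X)),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, digits = 3, ...) {
  cat(sprintf("<factor_model> %d factor(s) over %d variables (n = %d)\n",
              x$n_factors, length(x$variables), x$n_used))
  cat("eigenvalues:", paste(round(x$eigenvalues, digits), collapse = ", "), "\n")
  cat("pattern (promax):\n")
  print(round(x$pattern, digits))
  invisible(x)
}

#' Weighted relationship-group scores per subject
#'
#' The strength of each variable's contribution to a factor (its absolute
#' promax pattern loading, normalized to sum to one within the factor)
#' weights the z-scored variables into one score per subject and factor.
#' Only listwise-complete subjects are scored; excluded subjects are
#' reported. Group differences per factor are assessed with
#' [two_group_test()] when exactly two groups are present.
#'
#' @param table Cohort data frame (`subject`, `group`, variables).
#' @param model A [factor_model()] fitted on the same variables.
#' @return An object of class `group_scores`: `scores` (data frame
#'   `subject`, `group`, one column per factor), `weights`
#'   (variables x factors), `excluded` (subjects with missing data),
#'   `tests` (per-factor [two_group_test()], two-group cohorts only),
#'   `group_summary` (per group and factor mean and s.d.).
#' @export
group_scores <- function(table, model) {
  stopifnot(inherits(model, "factor_model"))
  vars <- model$variables
  if (!all(vars %in% names(table))) {
    stop("table lacks the model's variables", call. = FALSE)
  }
  X <- table[, vars, drop = FALSE]
  complete <- stats::complete.cases(X)
  excluded <- table$subject[!complete]
  if (length(excluded)) {
    message("excluding ", length(excluded),
            " subject(s) with missing data: ",
            paste(excluded, collapse = ", "))
  }
  Xc <- scale(as.matrix(X[complete, , drop = FALSE]))
  W <- abs(model$pattern)
  W <- sweep(W, 2, colSums(W), "/")
  sc <- Xc %*% W
  scores <- data.frame(subject = table$subject[complete],
                       group = table$group[complete], sc,
                       check.names = FALSE)
  groups <- unique(scores$group)
  tests <- NULL
  if (length(groups) == 2L) {
    tests <- lapply(colnames(sc), function(f) {
      two_group_test(scores[scores$group == groups[1], f],
                     scores[scores$group == groups[2], f])
    })
    names(tests) <- colnames(sc)
  }
  summ <- do.call(rbind, lapply(groups, function(g) {
    sub <- sc[scores$group == g, , drop = FALSE]
    data.frame(group = g, factor = colnames(sc),
               mean = colMeans(sub), sd = apply(sub, 2, stats::sd),
               n = nrow(sub))
  }))
  rownames(summ) <- NULL
  structure(list(scores = scores, weights = W, excluded = excluded,
                 tests = tests, group_summary = summ),
            class = "group_scores")
}

#' Tucker congruence between two loading matrices
#'
#' Column-wise congruence after resolving the permutation and sign
#' indeterminacy of factor solutions: columns of `B` are greedily matched
#' to columns of `A` by maximal absolute congruence.
#'
#' @param A,B Loading matrices with equal dimensions.
#' @return List with `congruence` (per matched factor, after sign
#'   alignment), `min_congruence`, `permutation`.
#' @export
factor_congruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(identical(dim(A), dim(B)))
  k <- ncol(A)
  cc <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cc[i, j] <- sum(A[, i] * B[, j]) /
      sqrt(sum(A[, i]^2) * sum(B[, j]^2))
  }
  perm <- integer(k)
  avail <- seq_len(k)
  for (i in seq_len(k)) {
    j <- avail[which.max(abs(cc[i, avail]))]
    perm[i] <- j
    avail <- setdiff(avail, j)
  }
  vals <- abs(cc[cbind(seq_len(k), perm)])
  list(congruence = vals, min_congruence = min(vals), permutation = perm)
}
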