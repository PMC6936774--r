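test_that("Pareto scaling centers and divides by sqrt(sd)", {
  sc <- pareto_scale(cbind(a = c(1, 2, 3), b = c(5, 0, 1)))
  expect_equal(sc$X[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_warning(pareto_scale(cbind(a = c(1, 2, 3), z = c(0, 0, 0))),
                 "constant")
  expect_error(pareto_scale(cbind(z = c(2, 2, 2))), "constant")
  # algebraic identity: variance of a pareto-scaled column equals the raw
  # column's standard deviation
  set.seed(5)
  raw <- matrix(rlnorm(20 * 8, 3, 1), 20, 8)
  sc2 <- pareto_scale(raw)
  expect_equal(apply(sc2$X, 2, var), apply(raw, 2, sd),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("NIPALS reproduces the truncated SVD on random matrices", {
  set.seed(31)
  for (rep in 1:3) {
    X <- scale(matrix(rnorm(10 * 50), 10, 50), scale = FALSE)
    A <- 4
    # tight convergence so the comparison probes the algorithm, not the
    # iteration cut-off
    m <- pca_nipals(X, A, tol = 1e-18, max_iter = 5000,
                    compute_q2 = FALSE)
    sv <- svd(X)
    for (a in seq_len(A)) {
      t_or <- sv$u[, a] * sv$d[a]
      diff <- min(sum((m$scores[, a] - t_or)^2),
                  sum((m$scores[, a] + t_or)^2))
      expect_lt(diff / sum(t_or^2), 1e-13)
    }
    expect_equal(m$r2x_per_component, (sv$d[1:A]^2) / sum(sv$d^2),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # loadings columns are unit norm, scores mutually orthogonal
    expect_equal(colSums(m$loadings^2), rep(1, A), tolerance = 1e-9,
                 ignore_attr = TRUE)
    G <- crossprod(m$scores)
    expect_lt(max(abs(G[upper.tri(G)])) /
                sqrt(max(diag(G)) * min(diag(G))), 1e-8)
    expect_true(all(diff(m$r2x_cum) >= -1e-12))
  }
})

test_that("a rank-1 matrix is explained by one component", {
  u <- c(-2, -1, 0, 1, 2); v <- rnorm(12)
  m <- pca_nipals(u %*% t(v), 1, compute_q2 = FALSE)
  expect_equal(m$r2x_cum, 1, tolerance = 1e-12)
})

test_that("deflation conserves total sum of squares", {
  set.seed(17)
  X <- scale(matrix(rnorm(15 * 40), 15, 40), scale = FALSE)
  A <- 5
  m <- pca_nipals(X, A, compute_q2 = FALSE)
  resid <- X - m$scores %*% t(m$loadings)
  lhs <- sum(X^2)
  rhs <- sum(colSums(m$scores^2)) + sum(resid^2)
  expect_lt(abs(lhs - rhs) / lhs, 1e-8)
})

test_that("the Hotelling limit matches the F-table closed form", {
  # n = 20, A = 2: 2*19*21/(20*18) * F_0.95(2,18), F from printed tables
  expect_equal(hotelling_limit(20, 2, 0.05), (798 / 360) * 3.5546,
               tolerance = 1e-3)
  expect_error(hotelling_limit(3, 3), "more samples")
})

test_that("a strongly displaced sample exceeds the T2 limit", {
  set.seed(23)
  X <- matrix(rnorm(20 * 30), 20, 30)
  X[7, ] <- X[7, ] + 10  # 10 sd along the all-ones direction
  rownames(X) <- paste0("s", 1:20)
  m <- pca_nipals(pareto_scale(X + 100), 2, compute_q2 = FALSE)
  out <- hotelling_outliers(m, 0.05)
  expect_true("s7" %in% out)
  # a tight homogeneous cloud yields no outliers at this limit
  set.seed(24)
  Y <- matrix(rnorm(20 * 30, sd = 1e-3), 20, 30) + 50
  m2 <- pca_nipals(pareto_scale(Y), 2, compute_q2 = FALSE)
  expect_length(hotelling_outliers(m2, 0.001), 0)
})

test_that("OPLS-DA with no orthogonal component equals one-component PLS", {
  skip_if_not_installed("mixOmics")
  set.seed(41)
  X <- scale(matrix(rnorm(20 * 30), 20, 30), scale = FALSE)
  y <- rep(c(1, -1), each = 10)
  m <- oplsda_fit(X, y, n_ortho = 0, compute_q2 = FALSE)
  pls <- mixOmics::pls(X, y, ncomp = 1, scale = FALSE,
                       mode = "regression")
  t_or <- pls$variates$X[, 1]
  expect_lt(1 - abs(cor(m$t_p, t_or)), 1e-10)
  w_or <- pls$loadings$X[, 1]
  expect_lt(min(sum((m$w - w_or)^2), sum((m$w + w_or)^2)), 1e-16)
})

test_that("a variable identical to the class drives a perfect model", {
  set.seed(43)
  y <- rep(c(1, -1), each = 8)
  X <- cbind(marker = y, matrix(rnorm(16 * 5, sd = 1e-4), 16, 5))
  m <- oplsda_fit(X, y, n_ortho = 0, compute_q2 = FALSE)
  expect_equal(m$r2y, 1, tolerance = 1e-6)
  st <- splot(m, X)
  expect_equal(abs(st$corr[st$variable == "marker"]), 1,
               tolerance = 1e-6)
})

test_that("predictive and orthogonal scores are orthogonal; variance
           partitions to 100 percent", {
  set.seed(47)
  X <- scale(matrix(rnorm(24 * 60), 24, 60), scale = FALSE)
  y <- rep(c(1, -1), 12)
  m <- oplsda_fit(X, y, n_ortho = 3, compute_q2 = FALSE)
  for (k in seq_len(m$n_ortho)) {
    ip <- abs(sum(m$t_p * m$T_ortho[, k]))
    expect_lt(ip / (sqrt(sum(m$t_p^2)) * sqrt(sum(m$T_ortho[, k]^2))),
              1e-8)
  }
  expect_equal(m$between_group_pct + m$within_group_pct + m$residual_pct,
               100, tolerance = 1e-6)
  expect_equal(sqrt(sum(m$w^2)), 1, tolerance = 1e-12)
  expect_error(oplsda_fit(X, y, n_ortho = 23), "n_ortho")
  expect_error(oplsda_fit(X, rep(1, 24), 1), "classes")
})

test_that("S-plot correlations match the direct correlation oracle", {
  set.seed(53)
  X <- pareto_scale(matrix(rlnorm(23 * 40, 5, 1), 23, 40))
  y <- rep(c(1, -1), length.out = 23)
  m <- oplsda_fit(X, y, n_ortho = 1, compute_q2 = FALSE)
  st <- splot(m, X)
  oracle_corr <- apply(X$X, 2, function(col) cor(col, m$t_p))
  expect_equal(st$corr, oracle_corr, tolerance = 1e-10,
               ignore_attr = TRUE)
  oracle_p <- apply(X$X, 2, function(col) cor.test(col, m$t_p)$p.value)
  expect_equal(st$p_value, oracle_p, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("null-variable S-plot p-values are uniform", {
  set.seed(59)
  n <- 23
  # many variables so one variable's own contribution to the predictive
  # score is negligible and its null p-value is uniform
  p1 <- replicate(200, {
    X <- matrix(rnorm(n * 2000), n, 2000)
    y <- sample(rep(c(1, -1), length.out = n))
    m <- oplsda_fit(scale(X, scale = FALSE), y, n_ortho = 0,
                    compute_q2 = FALSE)
    splot(m, scale(X, scale = FALSE))$p_value[1]
  })
  expect_gt(suppressWarnings(ks.test(p1, "punif"))$p.value, 0.01)
})

test_that("discriminant selection respects side and threshold", {
  st <- tibble::tibble(
    variable = c("a", "b", "c", "d"),
    cov = c(2.0, -1.5, 0.8, 1.2),
    corr = c(0.9, -0.8, 0.5, 0.6),
    p_value = c(0.078, 0.05, 0.20, 0.09))
  sel <- select_discriminating(st, cfg = selection_config(0.10, 1))
  expect_equal(sel$variable, c("a", "d"))  # p<=0.10 on the active side
  # wrong-side variable excluded despite small p; empty selection allowed
  sel2 <- select_discriminating(st, cfg = selection_config(0.01, 1))
  expect_equal(nrow(sel2), 0)
})

test_that("cross-validated Q2 is high for separable classes", {
  set.seed(61)
  y <- rep(c(1, -1), each = 7)
  X <- cbind(matrix(rnorm(14 * 5), 14, 5) + 3 * y,
             matrix(rnorm(14 * 20), 14, 20))
  m <- oplsda_fit(scale(X, scale = FALSE), y, n_ortho = 0)
  expect_gt(m$q2, 0.5)
})
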