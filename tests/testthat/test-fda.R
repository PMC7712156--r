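test_that("one-dimensional FDA reduces to the sign of the mean difference", {
  X <- matrix(c(3, 4, 5, 1, 2, 1.5), ncol = 1,
              dimnames = list(NULL, "m"))
  m <- fit_fda(X, c("ASD", "ASD", "ASD", "TD", "TD", "TD"))
  expect_equal(unname(m$W), 1)
  m2 <- fit_fda(-X + 10, c("ASD", "ASD", "ASD", "TD", "TD", "TD"))
  expect_equal(unname(m2$W), -1)
})

test_that("closed-form weights match the generalized eigenproblem oracle", {
  set.seed(55)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
    X <- rbind(matrix(rnorm(n1 * k, mean = 1), n1, k),
               matrix(rnorm(n2 * k), n2, k))
    colnames(X) <- paste0("m", 1:k)
    lab <- rep(c("ASD", "TD"), c(n1, n2))
    m <- fit_fda(X, lab)
    ev <- eigen(solve(m$S_W) %*% m$S_B)
    v <- Re(ev$vectors[, which.max(Re(ev$values))])
    v <- v / sqrt(sum(v^2))
    expect_lt(min(sum((m$W - v)^2), sum((m$W + v)^2)), 1e-16)
    expect_equal(m$J, max(Re(ev$values)), tolerance = 1e-8)
  }
})

test_that("degenerate class structure is rejected", {
  X <- rbind(matrix(c(1, 2, 1, 2), 2, 2), matrix(c(1, 2, 1, 2), 2, 2))
  expect_error(fit_fda(X, c("ASD", "ASD", "TD", "TD")),
               "degenerate separation")
  expect_error(fit_fda(X, rep("ASD", 4)), "degenerate labels")
})

test_that("FDA is equivariant to affine feature recoding", {
  set.seed(66)
  n1 <- 12; n2 <- 14; k <- 4
  X <- rbind(matrix(rnorm(n1 * k, 1), n1, k), matrix(rnorm(n2 * k), n2, k))
  colnames(X) <- paste0("m", 1:k)
  lab <- rep(c("ASD", "TD"), c(n1, n2))
  scale <- c(2, 0.5, 10, 1); shift <- c(-1, 3, 0, 100)
  Xt <- sweep(sweep(X, 2, scale, "*"), 2, shift, "+")
  m1 <- fit_fda(X, lab); m2 <- fit_fda(Xt, lab)
  s1 <- fda_project(m1, X); s2 <- fda_project(m2, Xt)
  expect_equal(auroc(s1, lab), auroc(s2, lab))
  expect_equal(m1$J, m2$J, tolerance = 1e-10)
})

test_that("projection is the plain inner product with the weight vector", {
  m <- structure(list(W = c(1, 0), metabolites = c("a", "b"),
                      positive = "ASD"), class = "fda_model")
  expect_equal(fda_project(m, matrix(c(3.2, 99), 1,
                                     dimnames = list(NULL, c("a", "b")))),
               3.2)
  X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(fda_project(m, X), drop(X %*% c(1, 0)))
  bad <- matrix(0, 1, 2, dimnames = list(NULL, c("b", "a")))
  expect_error(fda_project(m, bad), "feature misalignment")
  expect_error(fda_project(m, matrix(0, 1, 3)), "feature misalignment")
})

test_that("kernel density integrates to one and tracks the sampling CDF", {
  set.seed(77)
  d <- fit_kde(rnorm(200))
  grid <- density_grid(d, 2048L)
  integral <- sum(diff(grid$score) *
                    (head(grid$pdf, -1) + grid$pdf[-1]) / 2)
  expect_lt(abs(integral - 1), 1e-3)
  expect_true(all(diff(grid$cdf) >= 0))

  big <- fit_kde(rnorm(1e5))
  expect_lt(abs(big$cdf(0) - 0.5), 0.01)

  # bimodal mixture: smoothed CDF close to the empirical CDF
  x <- c(rnorm(5000, -3), rnorm(5000, 3))
  kd <- fit_kde(x)
  at <- seq(-6, 6, length.out = 201)
  expect_lt(max(abs(kd$cdf(at) - ecdf(x)(at))), 0.05)

  expect_error(fit_kde(rep(1, 5)), "degenerate scores")
})

test_that("beta-quantile thresholds invert the smoothed CDF", {
  set.seed(88)
  sc <- rnorm(1e5)
  d <- fit_kde(sc)
  t05 <- threshold_at_beta(d, 0.05)
  expect_lt(abs(t05$threshold - qnorm(0.05)), 0.05)
  expect_lt(abs(d$cdf(t05$threshold) - 0.05), 1e-3)

  sc2 <- rexp(500)
  d2 <- fit_kde(sc2)
  for (b in c(0.01, 0.05, 0.1, 0.2))
    expect_lt(abs(d2$cdf(threshold_at_beta(d2, b)$threshold) - b), 1e-3)
  expect_lt(threshold_at_beta(d2, 0.01)$threshold,
            threshold_at_beta(d2, 0.2)$threshold)
  # beta = 0.5 recovers the smoothed median
  t50 <- threshold_at_beta(d2, 0.5)
  expect_lt(abs(d2$cdf(t50$threshold) - 0.5), 1e-3)
})

test_that("pre-normalization scaling of W leaves threshold classification unchanged", {
  set.seed(99)
  X <- rbind(matrix(rnorm(40, 2), 10, 4), matrix(rnorm(48), 12, 4))
  colnames(X) <- paste0("m", 1:4)
  lab <- rep(c("ASD", "TD"), c(10, 12))
  m <- fit_fda(X, lab)
  sc <- fda_project(m, X)
  thr <- threshold_at_beta(fit_kde(sc[lab == "ASD"]), 0.1)
  # doubling W doubles scores and (refit) thresholds alike
  m2 <- m; m2$W <- 2 * m$W
  sc2 <- fda_project(m2, X)
  thr2 <- threshold_at_beta(fit_kde(sc2[lab == "ASD"]), 0.1)
  expect_equal(sc2 >= thr2$threshold, sc >= thr$threshold)
})
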