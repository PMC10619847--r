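test_that("blocked REML objective with one block equals the dense objective", {
  d <- toy_dataset(n = 60, seed = 21)
  X <- cbind(1, d$x1, d$x2)
  coords <- as.matrix(d[, c("xcoord", "ycoord")])
  part <- single_block(60)
  for (theta in list(c(1, 0.1, 0.3), c(5, 0.01, 1.2), c(0.5, 2, 0.05))) {
    ob <- reml_objective(theta, coords, X, d$y, part, "exponential")
    oracle <- dense_reml(theta, coords, X, d$y, "exponential")
    expect_equal(ob, oracle, tolerance = 1e-8)
  }
  # spherical family too
  ob <- reml_objective(c(2, 0.2, 0.8), coords, X, d$y, part, "spherical")
  expect_equal(ob, dense_reml(c(2, 0.2, 0.8), coords, X, d$y, "spherical"),
               tolerance = 1e-8)
})

test_that("objective is invariant to block relabeling and finite with
           all-zero design columns in a block", {
  d <- toy_dataset(n = 60, seed = 22)
  X <- cbind(1, d$x1, d$x2)
  coords <- as.matrix(d[, c("xcoord", "ycoord")])
  labs <- rep(1:3, each = 20)
  perm <- c(3L, 1L, 2L)
  o1 <- reml_objective(c(1, 0.2, 0.4), coords, X, d$y,
                       manual_partition(labs), "exponential")
  o2 <- reml_objective(c(1, 0.2, 0.4), coords, X, d$y,
                       manual_partition(perm[labs]), "exponential")
  expect_equal(o1, o2, tolerance = 1e-12)

  # dummy covariate present only in block 1: the pooled log-determinant
  # stays finite even though block 2's local design has an all-zero column
  dummy <- as.numeric(seq_len(60) <= 15)
  X2 <- cbind(1, d$x1, dummy)
  o3 <- reml_objective(c(1, 0.2, 0.4), coords, X2, d$y,
                       manual_partition(rep(1:2, each = 30)), "exponential")
  expect_true(is.finite(o3))
})

test_that("invalid covariance parameters get a penalty, not an error", {
  d <- toy_dataset(n = 30, seed = 23)
  X <- cbind(1, d$x1)
  coords <- as.matrix(d[, c("xcoord", "ycoord")])
  part <- single_block(30)
  expect_gte(reml_objective(c(-1, 0.1, 0.5), coords, X, d$y, part), 1e10)
  expect_gte(reml_objective(c(1, -0.1, 0.5), coords, X, d$y, part), 1e10)
})

test_that("pooled fixed effects with one block equal dense GLS", {
  d <- toy_dataset(n = 80, seed = 24)
  theta <- c(2, 0.3, 0.4)
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = theta, partition_index = single_block(80))
  oracle <- dense_gls(theta, as.matrix(d[, 1:2]), cbind(1, d$x1, d$x2), d$y)
  expect_equal(unname(coef(fit)), oracle$beta, tolerance = 1e-8)
  expect_equal(unname(vcov(fit)), unname(oracle$C), tolerance = 1e-8)
})

test_that("pooled estimator reduces to OLS when correlation vanishes", {
  d <- toy_dataset(n = 90, seed = 25)
  # effectively uncorrelated: range far below the minimum site spacing
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = c(1, 0.5, 1e-9),
                  partition = "random", partition_size = 30, seed = 2)
  ols <- coef(lm(y ~ x1 + x2, d))
  expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-6)
})

test_that("the pooled weight matrix satisfies QX = I", {
  d <- toy_dataset(n = 90, seed = 26)
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = c(1.5, 0.2, 0.3), partition_size = 30, seed = 3)
  Q <- dense_Q(fit)
  expect_equal(Q %*% fit$X, diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # and beta = Qy
  expect_equal(drop(Q %*% fit$y), unname(coef(fit)), tolerance = 1e-8)
})

test_that("exact variance equals Q V Q' under the full covariance", {
  d <- toy_dataset(n = 150, seed = 27)
  theta <- c(3, 0.3, 0.5)
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = theta, partition_size = 50, seed = 4,
                  var_method = "exact")
  expect_equal(fit$fe_partition$P, 3L)
  Q <- dense_Q(fit)
  V <- dense_cov(as.matrix(d[, 1:2]), theta)
  expect_equal(unname(fit$Chat), Q %*% V %*% t(Q), tolerance = 1e-8)
})

test_that("cross-block correction vanishes for truly uncorrelated blocks", {
  # three clusters farther apart than the spherical range: V is exactly
  # block diagonal, so the exact variance collapses to Txx^-1
  set.seed(28)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  coords <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(runif(60, 0, 0.5), 30), 2, centers[k, ], "+")))
  d <- data.frame(xcoord = coords[, 1], ycoord = coords[, 2],
                  x1 = rnorm(90), x2 = rnorm(90))
  d$y <- 1 + d$x1 + d$x2 + rnorm(90)
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  family = "spherical", theta = c(2, 0.1, 0.8),
                  partition_index = manual_partition(rep(1:3, each = 30)))
  expect_equal(unname(vcov(fit, "exact")), unname(solve(fit$Txx)),
               tolerance = 1e-10)
})

test_that("empirical variance matches the direct two-block formula", {
  d <- toy_dataset(n = 60, seed = 29)
  fit <- partkrig(y ~ 1, d, coords = c("xcoord", "ycoord"),
                  theta = c(1, 0.5, 0.2),
                  partition_index = manual_partition(rep(1:2, each = 30)))
  # per-block GLS intercepts via the dense oracle
  bi <- sapply(1:2, function(b) {
    ix <- (b - 1) * 30 + 1:30
    dense_gls(c(1, 0.5, 0.2), as.matrix(d[ix, 1:2]),
              matrix(1, 30), d$y[ix])$beta
  })
  m <- unname(coef(fit))
  expect_equal(unname(vcov(fit, "empirical"))[1, 1],
               ((bi[1] - m)^2 + (bi[2] - m)^2) / 2, tolerance = 1e-8)
  # a single block has no empirical spread to use
  fit1 <- partkrig(y ~ 1, d, coords = c("xcoord", "ycoord"),
                   theta = c(1, 0.5, 0.2), partition_index = single_block(60))
  expect_error(vcov(fit1, "empirical"), "at least 2")
})

test_that("empirical variance is zero for a perfectly reproduced signal", {
  d <- toy_dataset(n = 60, seed = 30)
  d$y <- 2 + 3 * d$x1  # exact linear signal, no noise
  fit <- partkrig(y ~ x1, d, coords = c("xcoord", "ycoord"),
                  theta = c(1, 0.5, 1e-9), partition_size = 20, seed = 5)
  expect_equal(max(abs(vcov(fit, "empirical"))), 0, tolerance = 1e-12)
})

test_that("pooled per-block variance obeys its averaging identities", {
  d <- toy_dataset(n = 70, seed = 31)
  theta <- c(2, 0.4, 0.3)
  # P = 1: identical to the dense GLS covariance
  fit1 <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                   theta = theta, partition_index = single_block(70))
  oracle <- dense_gls(theta, as.matrix(d[, 1:2]), cbind(1, d$x1, d$x2), d$y)
  expect_equal(unname(vcov(fit1, "pooled")), unname(oracle$C),
               tolerance = 1e-8)
  # P identical far-separated blocks: (1/P) x single-block variance
  set.seed(31)
  base <- cbind(runif(25, 0, 0.5), runif(25, 0, 0.5))
  coords <- rbind(base, sweep(base, 2, c(50, 0), "+"))
  dd <- data.frame(xcoord = coords[, 1], ycoord = coords[, 2],
                   x1 = rep(rnorm(25), 2))
  dd$y <- 1 + dd$x1 + rnorm(50)
  fit2 <- partkrig(y ~ x1, dd, coords = c("xcoord", "ycoord"),
                   family = "spherical", theta = c(1, 0.2, 0.4),
                   partition_index = manual_partition(rep(1:2, each = 25)))
  single <- dense_gls(c(1, 0.2, 0.4), base, cbind(1, dd$x1[1:25]),
                      dd$y[1:25], family = "spherical")$C
  # information matrices are identical across the two blocks by design
  expect_equal(unname(vcov(fit2, "pooled")), unname(single) / 2,
               tolerance = 1e-8)
  # PSD and symmetric on a generic instance
  fitg <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                   theta = theta, partition_size = 20, seed = 6)
  Cp <- vcov(fitg, "pooled")
  expect_equal(Cp, t(Cp))
  expect_true(all(eigen(Cp, symmetric = TRUE)$values > -1e-12))
})

test_that("wald_table computes normal-reference z and p values", {
  d <- toy_dataset(n = 60, seed = 32)
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = c(1, 0.3, 0.2), partition_size = 30, seed = 7)
  tab <- wald_table(fit)
  expect_equal(tab$se, sqrt(diag(fit$Chat)), ignore_attr = TRUE)
  expect_equal(tab$z, tab$estimate / tab$se)
  expect_equal(tab$p, 2 * pnorm(-abs(tab$z)))
  # reference values: z = 1.645 -> p ~ 0.0999; estimate 0 -> p = 1
  C <- fit$Chat
  fit$beta <- setNames(c(1.645 * sqrt(C[1, 1]), 0, fit$beta[3]),
                       names(fit$beta))
  tab2 <- wald_table(fit)
  expect_equal(tab2$p[1], 0.09992, tolerance = 1e-3)
  expect_equal(tab2$p[2], 1)
  # degenerate zero standard error reports NA
  fit$Chat[2, 2] <- 0
  expect_true(is.na(wald_table(fit)$p[2]))
})

test_that("REML recovers parameters and is seed deterministic", {
  # correct-model check at a small size: exponential truth, exponential fit
  theta <- c(4, 0.5, 0.15)
  est <- sapply(1:6, function(s) {
    d <- sim_expfield(400, theta, seed = 600 + s)
    fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                    partition_size = 50, seed = s)
    fit$theta
  })
  med <- apply(est, 1, median)
  expect_lt(abs(med[["tau2"]] - theta[1]) / theta[1], 0.5)
  expect_lt(abs(med[["rho"]] - theta[3]) / theta[3], 0.6)
  expect_lt(med[["eta2"]], 1.5)

  d <- sim_expfield(200, theta, seed = 99)
  f1 <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                 partition_size = 50, seed = 31)
  # the stored optimum agrees with the standalone objective evaluator
  expect_equal(f1$objective,
               reml_objective(f1$theta, as.matrix(d[, 1:2]),
                              cbind(1, d$x1, d$x2), d$y, f1$partition),
               tolerance = 1e-10)
  f2 <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                 partition_size = 50, seed = 31)
  expect_identical(f1$theta, f2$theta)
  expect_true(f1$converged)
})

test_that("near-pure-nugget data yield a small partial sill and
           mean-reverting predictions", {
  set.seed(33)
  n <- 300
  d <- data.frame(xcoord = runif(n), ycoord = runif(n),
                  x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 1 + d$x1 + d$x2 + rnorm(n)  # spatially unstructured errors
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  partition_size = 50, seed = 8)
  sig2 <- sum(fit$theta[c("tau2", "eta2")])
  # structured variance that decays within the data is limited; predictions
  # at fresh sites revert to the regression mean
  grid <- make_grid(resolution = 5)
  nd <- data.frame(xcoord = grid$xcoord, ycoord = grid$ycoord,
                   x1 = 0, x2 = 0)
  p <- predict(fit, nd, nn = 50)
  expect_lt(max(abs(p$fit - coef(fit)[1])), 1.0)
  expect_gt(min(p$se), 0.8)  # close to sqrt(sigma2) ~ 1
  expect_lt(abs(sig2 - 1) / 1, 0.5)
})

test_that("rank-deficient designs are rejected with column names", {
  d <- toy_dataset(n = 40, seed = 34)
  d$x3 <- d$x1
  expect_error(partkrig(y ~ x1 + x3, d, coords = c("xcoord", "ycoord"),
                        theta = c(1, 0.1, 0.3)), "rank deficient")
})
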