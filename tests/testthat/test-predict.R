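test_that("nearest-neighbour search is exact with index tie-breaks", {
  set.seed(41)
  obs <- cbind(runif(60), runif(60))
  pred <- cbind(runif(9), runif(9))
  nb <- find_neighbors(obs, pred, 7)
  for (j in 1:9) {
    d <- sqrt(colSums((t(obs) - pred[j, ])^2))
    ord <- order(d, seq_along(d))[1:7]
    expect_identical(as.integer(nb$idx[j, ]), ord)
    expect_equal(nb$dist[j, ], d[ord], tolerance = 1e-12)
  }
  # m = n returns everything; coincident site is its own first neighbour
  nb_all <- find_neighbors(obs, pred, 60)
  expect_identical(sort(as.integer(nb_all$idx[1, ])), 1:60)
  nb_c <- find_neighbors(obs, obs[13, , drop = FALSE], 3)
  expect_identical(as.integer(nb_c$idx[1, 1]), 13L)
  expect_error(find_neighbors(obs, pred, 61), "between 1")
})

test_that("global-coefficient predictor with all data and one block equals
           dense universal kriging", {
  d <- toy_dataset(n = 100, seed = 42)
  theta <- c(2, 0.3, 0.4)
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = theta, partition_index = single_block(100))
  set.seed(43)
  s0 <- cbind(runif(12), runif(12))
  nd <- data.frame(xcoord = s0[, 1], ycoord = s0[, 2],
                   x1 = rnorm(12), x2 = rnorm(12))
  p <- predict(fit, nd, nn = 100)
  oracle <- dense_uk(theta, as.matrix(d[, 1:2]), cbind(1, d$x1, d$x2), d$y,
                     s0, cbind(1, nd$x1, nd$x2))
  expect_equal(p$fit, oracle$fit, tolerance = 1e-8)
  expect_equal(p$se^2, oracle$var, tolerance = 1e-8)
})

test_that("zero nugget interpolates observed sites exactly", {
  d <- toy_dataset(n = 50, seed = 44)
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = c(2, 0, 0.4), partition_size = 25, seed = 1)
  nd <- d[7, c("xcoord", "ycoord", "x1", "x2")]
  p <- predict(fit, nd, nn = 20)
  expect_equal(p$fit, d$y[7], tolerance = 1e-8)
  expect_equal(p$se, 0, tolerance = 1e-6)
})

test_that("kriging weights are unbiased and reproduce the prediction", {
  d <- toy_dataset(n = 120, seed = 45)
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = c(1.5, 0.2, 0.3), partition_size = 40, seed = 2)
  set.seed(46)
  for (k in 1:4) {
    nd <- data.frame(xcoord = runif(1), ycoord = runif(1),
                     x1 = rnorm(1), x2 = rnorm(1))
    lam <- lambda_weights(fit, nd, nn = 30)
    expect_equal(drop(lam %*% fit$X), c(1, nd$x1, nd$x2),
                 tolerance = 1e-8, ignore_attr = TRUE)
    p <- predict(fit, nd, nn = 30)
    expect_equal(sum(lam * fit$y), p$fit, tolerance = 1e-10)
  }
})

test_that("purely local predictor with all data equals dense kriging and
           collapses absent covariate columns", {
  d <- toy_dataset(n = 80, seed = 47)
  theta <- c(2, 0.3, 0.4)
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = theta, partition_index = single_block(80))
  set.seed(48)
  s0 <- cbind(runif(6), runif(6))
  nd <- data.frame(xcoord = s0[, 1], ycoord = s0[, 2],
                   x1 = rnorm(6), x2 = rnorm(6))
  p <- predict(fit, nd, nn = 80, beta = "local")
  oracle <- dense_uk(theta, as.matrix(d[, 1:2]), cbind(1, d$x1, d$x2), d$y,
                     s0, cbind(1, nd$x1, nd$x2))
  expect_equal(p$fit, oracle$fit, tolerance = 1e-8)
  expect_equal(p$se^2, oracle$var, tolerance = 1e-8)

  # a level present only far from the prediction site: with a small
  # neighbourhood the local design column is all zeros and is collapsed
  dd <- d
  dd$x2 <- as.numeric(dd$xcoord > 0.75)  # dummy, absent near x = 0.1
  fit2 <- partkrig(y ~ x1 + x2, dd, coords = c("xcoord", "ycoord"),
                   theta = theta, partition_size = 40, seed = 3)
  near <- order(abs(dd$xcoord - 0.1))[1:10]
  expect_true(all(dd$x2[near] == 0))
  nd2 <- data.frame(xcoord = 0.1, ycoord = dd$ycoord[near[1]],
                    x1 = 0.5, x2 = 0)
  p2 <- predict(fit2, nd2, nn = 10, beta = "local")
  expect_true(is.finite(p2$fit) && is.finite(p2$se))
})

test_that("prediction variance is monotone in the coefficient covariance", {
  d <- toy_dataset(n = 100, seed = 49)
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = c(1, 0.2, 0.3), partition_size = 25, seed = 4)
  nd <- data.frame(xcoord = runif(20), ycoord = runif(20),
                   x1 = rnorm(20), x2 = rnorm(20))
  p1 <- predict(fit, nd, nn = 30)
  p2 <- predict(fit, nd, nn = 30, Chat = 4 * fit$Chat)
  expect_true(all(p2$se >= p1$se - 1e-12))
  expect_true(all(p1$se >= 0))
  # surface target drops the nugget from the site variance
  ps <- predict(fit, nd, nn = 30, target = "surface")
  expect_true(all(ps$se^2 <= p1$se^2 + 1e-12))
})

test_that("prediction intervals use the 1.645 multiplier at 90%", {
  d <- toy_dataset(n = 60, seed = 50)
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = c(1, 0.2, 0.3), partition_size = 30, seed = 5)
  nd <- data.frame(xcoord = 0.5, ycoord = 0.5, x1 = 0, x2 = 0)
  p <- predict(fit, nd, nn = 20, interval = "prediction", level = 0.90)
  z <- qnorm(0.95)
  expect_equal(p$lwr, p$fit - z * p$se, tolerance = 1e-12)
  expect_equal(p$upr, p$fit + z * p$se, tolerance = 1e-12)
  expect_equal(z, 1.645, tolerance = 1e-3)
})
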