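test_that("make_grid produces uniform row-major grids", {
  g <- make_grid(resolution = 40)
  expect_equal(nrow(g), 1600)
  expect_equal(sum(g$weight), 1)
  expect_true(all(g$xcoord > 0 & g$xcoord < 1 & g$ycoord > 0 & g$ycoord < 1))
  # x varies fastest; spacing is uniform
  expect_equal(diff(g$xcoord[1:2]), 1 / 40)
  expect_equal(g$ycoord[41] - g$ycoord[40], 1 / 40)

  g1 <- make_grid(resolution = 1)
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$xcoord, g1$ycoord, g1$weight), c(0.5, 0.5, 1))
  for (r in c(3, 7)) expect_equal(sum(make_grid(resolution = r)$weight), 1)
  expect_error(make_grid(bounds = c(0, 0, 0, 1), resolution = 2),
               "degenerate")
})

test_that("areal-mean prediction averages the point predictions and is
           linear in the data", {
  d <- toy_dataset(n = 150, seed = 61)
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = c(2, 0.3, 0.4), partition_size = 50, seed = 1)
  g <- make_grid(resolution = 6)
  set.seed(62)
  nd <- data.frame(g[, c("xcoord", "ycoord")], x1 = rnorm(36),
                   x2 = rnorm(36), weight = g$weight)
  bp <- block_predict(fit, nd, nn = 40)
  pp <- predict(fit, nd, nn = 40)
  expect_equal(bp$fit, mean(pp$fit), tolerance = 1e-10)
  # a*' y reproduces the block prediction; a*' X_o = a' X_u (unbiasedness)
  expect_equal(sum(bp$astar * fit$y), bp$fit, tolerance = 1e-10)
  expect_equal(drop(bp$astar %*% fit$X),
               colMeans(cbind(1, nd$x1, nd$x2)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a single grid point reduces to the point predictor", {
  d <- toy_dataset(n = 90, seed = 63)
  theta <- c(2, 0.3, 0.4)
  # dense settings: one block, all neighbours, consistent Chat
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = theta, partition_index = single_block(90))
  nd <- data.frame(xcoord = 0.37, ycoord = 0.61, x1 = 0.2, x2 = -0.4,
                   weight = 1)
  bp <- block_predict(fit, nd, nn = 90)
  pp <- predict(fit, nd, nn = 90)
  expect_equal(bp$fit, pp$fit, tolerance = 1e-10)
  expect_equal(bp$se, pp$se, tolerance = 1e-8)
})

test_that("streamed block variance equals the dense evaluation", {
  d <- toy_dataset(n = 200, seed = 64)
  theta <- c(1.5, 0.25, 0.35)
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = theta, partition_size = 50, seed = 2)
  g <- make_grid(resolution = 10)
  set.seed(65)
  nd <- data.frame(g[, c("xcoord", "ycoord")], x1 = rnorm(100),
                   x2 = rnorm(100))
  bp <- block_predict(fit, nd, nn = 50)
  obs <- as.matrix(d[, 1:2]); grd <- as.matrix(g[, 1:2])
  a <- rep(1 / 100, 100)
  Voo <- dense_cov(obs, theta)
  Vou <- dense_cross_cov(obs, grd, theta)
  Vuu <- dense_cov(grd, theta)
  dense <- drop(t(bp$astar) %*% Voo %*% bp$astar -
                2 * t(bp$astar) %*% Vou %*% a + t(a) %*% Vuu %*% a)
  expect_equal(bp$se^2, dense, tolerance = 1e-8)
  # averaging over the region beats the average point variance
  pp <- predict(fit, nd, nn = 50)
  expect_lt(bp$se^2, mean(pp$se^2))
})

test_that("observation subsampling engages above the cap and is seeded", {
  d <- toy_dataset(n = 220, seed = 66)
  fit <- partkrig(y ~ x1 + x2, d, coords = c("xcoord", "ycoord"),
                  theta = c(1, 0.2, 0.3), partition_size = 40, seed = 3)
  g <- make_grid(resolution = 4)
  nd <- data.frame(g[, c("xcoord", "ycoord")], x1 = 0, x2 = 0)
  b1 <- block_predict(fit, nd, nn = 30, cap = 150, seed = 9)
  b2 <- block_predict(fit, nd, nn = 30, cap = 150, seed = 9)
  expect_equal(b1$n_used, 150)
  expect_identical(b1$fit, b2$fit)
  expect_identical(b1$se, b2$se)
  full <- block_predict(fit, nd, nn = 30, cap = 5000)
  expect_equal(full$n_used, 220)
  expect_equal(b1$fit, full$fit, tolerance = 0.2)  # close, not identical
})
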