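# Independent dense-matrix oracles, written directly from the classical
# geostatistical formulas with plain solve()/determinant(). They never call
# the package's blocked code paths.

dense_cov <- function(coords, theta, family = "exponential") {
  D <- as.matrix(stats::dist(coords))
  V <- if (family == "exponential") {
    theta[1] * exp(-D / theta[3])
  } else {
    u <- pmin(D / theta[3], 1)
    theta[1] * (1 - 1.5 * u + 0.5 * u^3) * (D < theta[3])
  }
  diag(V) <- theta[1] + theta[2]
  V
}

dense_cross_cov <- function(A, B, theta, family = "exponential") {
  D <- sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2)
  if (family == "exponential") {
    theta[1] * exp(-D / theta[3])
  } else {
    u <- pmin(D / theta[3], 1)
    theta[1] * (1 - 1.5 * u + 0.5 * u^3) * (D < theta[3])
  }
}

# REML deviance (without the additive constant)
dense_reml <- function(theta, coords, X, y, family = "exponential") {
  V <- dense_cov(coords, theta, family)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(determinant(V)$modulus) + drop(t(r) %*% Vi %*% r) +
    as.numeric(determinant(A)$modulus)
}

# generalized least squares with covariance (X'V^-1X)^-1
dense_gls <- function(theta, coords, X, y, family = "exponential") {
  V <- dense_cov(coords, theta, family)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- drop(solve(A, t(X) %*% Vi %*% y))
  list(beta = beta, C = solve(A))
}

# dense universal kriging (EBLUP) at sites s0 with covariates x0
dense_uk <- function(theta, coords, X, y, s0, x0, family = "exponential") {
  V <- dense_cov(coords, theta, family)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- drop(solve(A, t(X) %*% Vi %*% y))
  Ainv <- solve(A)
  sigma2 <- theta[1] + theta[2]
  q <- nrow(s0)
  fit <- var <- numeric(q)
  for (j in seq_len(q)) {
    c0 <- drop(dense_cross_cov(coords, s0[j, , drop = FALSE], theta, family))
    u <- drop(Vi %*% c0)
    g <- x0[j, ] - drop(t(X) %*% u)
    fit[j] <- sum(x0[j, ] * beta) + sum(u * (y - X %*% beta))
    var[j] <- sigma2 - sum(c0 * u) + drop(t(g) %*% Ainv %*% g)
  }
  list(fit = fit, var = var, beta = beta)
}

# exact simulation of a Gaussian random field with exponential covariance
# (for correct-model coverage checks)
sim_expfield <- function(n, theta, beta = c(1, 1, 1), grid_resolution = 0,
                         seed) {
  set.seed(seed)
  ng <- if (grid_resolution >= 1) grid_resolution^2 else 0
  coords <- cbind(runif(n + ng), runif(n + ng))
  if (ng > 0) {
    g <- make_grid(resolution = grid_resolution)
    coords[(n + 1):(n + ng), ] <- as.matrix(g[, 1:2])
  }
  V <- dense_cov(coords, theta, "exponential")
  L <- t(chol(V))
  eps <- drop(L %*% rnorm(n + ng))
  x2 <- drop(L %*% rnorm(n + ng))
  x1 <- rnorm(n + ng)
  data.frame(xcoord = coords[, 1], ycoord = coords[, 2], x1 = x1, x2 = x2,
             eps = eps, y = beta[1] + beta[2] * x1 + beta[3] * x2 + eps,
             site = rep(c("obs", "grid"), c(n, ng)))
}

# assemble the pooled-GLS weight matrix Q = [Txx^-1 X_i' V_ii^-1] from a
# fit's dimensions but with dense algebra on the stored partition
dense_Q <- function(fit) {
  theta <- unname(fit$theta)
  fam <- fit$family
  Tinv <- solve(fit$Txx)
  Q <- matrix(0, fit$p, fit$n)
  for (b in seq_len(fit$fe_partition$P)) {
    ix <- which(fit$fe_partition$labels == b)
    Vi <- solve(dense_cov(fit$coords[ix, , drop = FALSE], theta, fam))
    Q[, ix] <- Tinv %*% t(fit$X[ix, , drop = FALSE]) %*% Vi
  }
  Q
}
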