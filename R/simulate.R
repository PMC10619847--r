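#' Synthetic spatial surfaces for method evaluation
#'
#' Two generators of point-referenced data on the unit square, each
#' producing `n` uniformly random observation sites plus a uniformly spaced
#' `grid_resolution` x `grid_resolution` prediction grid, with spatially
#' correlated errors simulated jointly at all sites (so realized values at
#' prediction sites share the correlation structure of the observations,
#' which honest prediction-error and interval-coverage summaries require).
#'
#' `sim_geostat()` draws the errors exactly from a Gaussian random field
#' with a spherical autocovariance (partial sill `theta[1]`, nugget
#' `theta[2]`, range `theta[3]`) via the Cholesky factor of the joint
#' covariance matrix: `eps = L z` with `V = L L'`. Exact but O(N^3); total
#' sites are guarded at 6000.
#'
#' `sim_sumsine()` sums 100 randomly rotated two-dimensional sine waves with
#' random amplitudes (decreasing in the component index), frequencies
#' (increasing) and phase shifts, standardises the sum to mean zero and
#' variance `var_target` (default 10) over all sites, and adds independent
#' noise of variance `noise_var` (default 0.1), playing the role of a
#' nugget. Cost is linear in the number of sites; no matrix is formed.
#'
#' Both attach covariates and the response
#' \deqn{Y(s) = \beta_0 + \beta_1 x_1(s) + \beta_2 x_2(s) + \epsilon(s)}
#' with `beta = c(1, 1, 1)` by default: `x1` is i.i.d. standard normal and
#' `x2` is an independent realization of the same error-surface generator,
#' so it is spatially patterned.
#'
#' @param n number of observation sites.
#' @param grid_resolution prediction grid points per side (0 for none).
#' @param theta spherical covariance parameters `c(tau2, eta2, rho)` for
#'   the geostatistical generator (default `c(10, 0.1, 0.5)`).
#' @param beta fixed effects `c(beta0, beta1, beta2)`.
#' @param standardize if `TRUE`, the error surface and the spatially
#'   patterned covariate are each standardised to mean zero and variance
#'   one before the response is assembled.
#' @param var_target,noise_var sine-sum surface variance and independent
#'   noise variance.
#' @param seed integer seed (required; the generators are fully seed
#'   deterministic).
#' @return Data frame with columns `xcoord`, `ycoord`, `x1`, `x2`, `eps`,
#'   `y` and `site` (`"obs"` or `"grid"`); the response reconstructs
#'   exactly as `beta0 + beta1*x1 + beta2*x2 + eps`.
#' @examples
#' d <- sim_sumsine(n = 500, grid_resolution = 10, seed = 42)
#' var(d$eps)
#' @name simulators
NULL

sim_sites <- function(n, grid_resolution) {
  obs <- cbind(stats::runif(n), stats::runif(n))
  if (grid_resolution >= 1) {
    g <- make_grid(resolution = grid_resolution)
    coords <- rbind(obs, as.matrix(g[, c("xcoord", "ycoord")]))
    site <- c(rep("obs", n), rep("grid", nrow(g)))
  } else {
    coords <- obs
    site <- rep("obs", n)
  }
  list(coords = coords, site = site)
}

assemble_surface <- function(coords, site, eps, x2, beta, standardize) {
  if (standardize) {
    eps <- drop(scale(eps))
    x2 <- drop(scale(x2))
  }
  x1 <- stats::rnorm(nrow(coords))
  data.frame(xcoord = coords[, 1], ycoord = coords[, 2],
             x1 = x1, x2 = x2, eps = eps,
             y = beta[1] + beta[2] * x1 + beta[3] * x2 + eps,
             site = site)
}

#' @rdname simulators
#' @export
sim_geostat <- function(n, grid_resolution = 40,
                        theta = c(10, 0.1, 0.5), beta = c(1, 1, 1),
                        standardize = FALSE, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  st <- sim_sites(n, grid_resolution)
  N <- nrow(st$coords)
  if (N > 6000) stop("total sites > 6000: too large for exact Cholesky simulation")
  spec <- cov_spec("spherical", theta[1], theta[2], theta[3])
  V <- cov_matrix(spec, st$coords, check = FALSE)
  L <- t(chol(V))
  eps <- drop(L %*% stats::rnorm(N))
  x2 <- drop(L %*% stats::rnorm(N))  # same model, independent realization
  assemble_surface(st$coords, st$site, eps, x2, beta, standardize)
}

# one sum-of-sines error surface at given coordinates (unstandardised)
sumsine_field <- function(coords) {
  eps <- numeric(nrow(coords))
  for (i in 1:100) {
    u <- stats::runif(6)
    th <- u[1] * pi
    s1 <- coords[, 1] * cos(th) + coords[, 2] * sin(th)
    s2 <- -coords[, 1] * sin(th) + coords[, 2] * cos(th)
    amp <- u[2] * (1 - (i - 1) / 100)
    eps <- eps + amp * (sin(i * u[3] * 2 * pi * (s1 + u[4] * pi)) +
                        sin(i * u[5] * 2 * pi * (s2 + u[6] * pi)))
  }
  eps
}

#' @rdname simulators
#' @export
sim_sumsine <- function(n, grid_resolution = 40, beta = c(1, 1, 1),
                        var_target = 10, noise_var = 0.1,
                        standardize = FALSE, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  st <- sim_sites(n, grid_resolution)
  N <- nrow(st$coords)
  smooth <- drop(scale(sumsine_field(st$coords))) * sqrt(var_target)
  eps <- smooth + stats::rnorm(N, sd = sqrt(noise_var))
  smooth2 <- drop(scale(sumsine_field(st$coords))) * sqrt(var_target)
  x2 <- smooth2 + stats::rnorm(N, sd = sqrt(noise_var))
  assemble_surface(st$coords, st$site, eps, x2, beta, standardize)
}

#' Monte-Carlo error and coverage summaries
#'
#' Root-mean-squared error between estimates (or predictions) and their
#' true (or realized) values, and the empirical coverage of nominal
#' `level` intervals `estimate +/- z * se` with `z = qnorm(1 - (1-level)/2)`
#' (1.645 at the default 90%). Applied to coefficient estimates these are
#' the RMSE and CI90 of a simulation study; applied to point predictions
#' they are the RMSPE and PI90.
#'
#' @param estimates,truth aligned numeric vectors.
#' @param se standard errors; if `NULL` only the RMSE is returned.
#' @param level interval level (default 0.90).
#' @return Named vector `c(rmse, cover)` (or just `rmse`).
#' @export
sim_metrics <- function(estimates, truth, se = NULL, level = 0.90) {
  if (length(estimates) != length(truth))
    stop("estimates and truth have different lengths")
  rmse <- sqrt(mean((estimates - truth)^2))
  if (is.null(se)) return(c(rmse = rmse))
  if (length(se) != length(truth)) stop("se has the wrong length")
  zq <- stats::qnorm(1 - (1 - level) / 2)
  cover <- mean(truth > estimates - zq * se & truth < estimates + zq * se)
  c(rmse = rmse, cover = cover)
}
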