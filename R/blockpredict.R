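#' Uniform prediction grid over a rectangle
#'
#' Cell-centred, uniformly spaced `resolution` x `resolution` grid in
#' row-major order, with uniform averaging weights `1/resolution^2`. Used
#' both as the dense approximation set for areal-mean (block) prediction
#' and as the prediction grid of the simulation harness.
#'
#' @param bounds numeric `c(xmin, xmax, ymin, ymax)` (default unit square).
#' @param resolution points per side, `>= 1`.
#' @return Data frame with the two coordinate columns and a `weight`
#'   column summing to one.
#' @export
make_grid <- function(bounds = c(0, 1, 0, 1), resolution = 40) {
  stopifnot(length(bounds) == 4, resolution >= 1)
  if (bounds[2] <= bounds[1] || bounds[4] <= bounds[3])
    stop("degenerate bounds")
  resolution <- as.integer(resolution)
  gx <- bounds[1] + (seq_len(resolution) - 0.5) / resolution *
    (bounds[2] - bounds[1])
  gy <- bounds[3] + (seq_len(resolution) - 0.5) / resolution *
    (bounds[4] - bounds[3])
  # row-major: x varies fastest within each grid row
  g <- data.frame(xcoord = rep(gx, times = resolution),
                  ycoord = rep(gy, each = resolution))
  g$weight <- 1 / resolution^2
  g
}

#' Predict the areal mean of the surface over a gridded region
#'
#' The block (areal-mean) prediction is the average of global-coefficient
#' nearest-neighbour point predictions over the dense grid, which is linear
#' in the observations: \eqn{\hat Y_D = a^{*'} y_o} with
#' \eqn{a^* = W'a}, rows of \eqn{W} the kriging weight vectors
#' \eqn{\lambda_j} and \eqn{a} the uniform grid weights. Its exact
#' prediction variance under the full covariance model,
#' \deqn{a^{*'} V_{oo} a^* - 2 a^{*'} V_{ou} a + a' V_{uu} a,}
#' is evaluated by streaming one covariance row at a time, so no n x n
#' matrix is ever formed. When the number of observations exceeds `cap`
#' (default 5000) a seeded simple random subsample of the observations is
#' used for the whole block computation, as areal means are typically
#' estimated very precisely.
#'
#' @param object a [partkrig()] fit.
#' @param newdata grid sites with coordinates and covariates, e.g. built
#'   from [make_grid()] joined with covariate values; an optional `weight`
#'   column (summing to 1) overrides uniform weights.
#' @param nn number of nearest neighbours per grid site.
#' @param cap observation-count cap above which a random subsample of size
#'   `cap` is used.
#' @param seed seed for the subsample draw.
#' @param Chat optional override of the fixed-effects covariance.
#' @return List with `fit` (scalar block prediction), `se`, `n_grid`, `nn`,
#'   and `n_used` (observations entering the computation).
#' @export
block_predict <- function(object, newdata, nn = 50, cap = 5000,
                          seed = NULL, Chat = NULL) {
  pd <- build_newdata(object, newdata)
  q <- nrow(pd$coords)
  a <- if ("weight" %in% names(newdata)) as.numeric(newdata$weight) else
    rep(1 / q, q)
  if (abs(sum(a) - 1) > 1e-8) stop("grid weights must sum to 1")
  if (is.null(Chat)) Chat <- object$Chat
  if (is.null(Chat)) Chat <- vcov(object)

  ob <- object
  if (object$n > cap) {
    if (!is.null(seed)) set.seed(seed)
    keep <- sort(sample.int(object$n, cap))
    ob <- rebuild_on_subset(object, keep)
  }
  theta <- unname(ob$theta)
  code <- .family_code(ob$family)
  if (is.na(code))
    stop("block prediction with a user-supplied family is not supported")
  sigma2 <- theta[1] + theta[2]
  nb <- find_neighbors(ob$coords, pd$coords, nn)
  out <- nn_predict_cpp(ob$coords, ob$X, ob$y, pd$coords, pd$X, nb$idx,
                        unname(ob$beta), Chat, theta, code, sigma2,
                        TRUE, a)
  fit <- sum(a * drop(out$fit))
  # a* = Q' (sum_j a_j g_j) + local part accumulated in C++
  astar <- Q_transpose_v(ob, drop(out$gsum)) + drop(out$astar_local)
  v <- block_var_cpp(ob$coords, pd$coords, astar, a, theta, code)
  list(fit = fit, se = sqrt(max(v, 0)), n_grid = q, nn = as.integer(nn),
       n_used = ob$n, astar = astar)
}

# Restrict a fit to a subset of observations: keeps theta, beta and Chat
# from the full fit but rebuilds the per-block GLS caches (and hence Q) on
# the subsample so the areal-mean weights remain well defined.
rebuild_on_subset <- function(object, keep) {
  ob <- object
  ob$coords <- object$coords[keep, , drop = FALSE]
  ob$X <- object$X[keep, , drop = FALSE]
  ob$y <- object$y[keep]
  ob$n <- length(keep)
  labs <- object$fe_partition$labels[keep]
  labs <- match(labs, sort(unique(labs)))  # drop emptied blocks
  ob$fe_partition <- new_partition_index(labs, max(labs),
                                         object$fe_partition$method,
                                         object$fe_partition$target_size)
  ds <- list(X = ob$X, y = ob$y, coords = ob$coords)
  ob$cache <- blocked_gls(object$spec, ds, ob$fe_partition)
  ob
}
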