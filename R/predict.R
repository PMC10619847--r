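#' Exact nearest neighbours of prediction sites
#'
#' Brute-force exact k-nearest-neighbour search under Euclidean distance.
#' Ties at equal distance are broken by the lower observation index so that
#' results are reproducible.
#'
#' @param obs_coords,pred_coords two-column coordinate matrices.
#' @param m number of neighbours, `1 <= m <= nrow(obs_coords)`.
#' @return List with `idx` (q x m matrix of 1-based observation indices,
#'   sorted by distance) and `dist` (matching distances).
#' @export
find_neighbors <- function(obs_coords, pred_coords, m) {
  obs_coords <- as_coord_matrix(obs_coords)
  pred_coords <- as_coord_matrix(pred_coords)
  m <- as.integer(m)
  if (m < 1L || m > nrow(obs_coords))
    stop("m must be between 1 and the number of observations")
  knn_cpp(obs_coords, pred_coords, m)
}

#' Predict from a partitioned spatial linear model
#'
#' Nearest-neighbour universal kriging. For each prediction site the `nn`
#' nearest observations form the local data \eqn{y_j} and the predictor is
#' \deqn{\hat Y(s_j) = x_j'\hat\beta + \hat c_j' \hat V_j^{-1} (y_j - X_j
#' \hat\beta)}
#' with, by default (`beta = "global"`), the single pooled estimate
#' \eqn{\hat\beta} from the fit, so all sites share one coherent model. Its
#' prediction variance is
#' \deqn{\hat\sigma^2 - \hat c_j' \hat V_j^{-1} \hat c_j + g_j' \hat C g_j,
#' \quad g_j = x_j - X_j' \hat V_j^{-1} \hat c_j,}
#' where \eqn{\hat C} is the fixed-effects covariance from the fit (exact
#' cross-block estimator unless another was chosen). `beta = "local"`
#' instead re-estimates the coefficients inside every neighbourhood
#' (a varying-coefficient model); all-zero columns of the local design are
#' collapsed before solving.
#'
#' By default \eqn{\hat\sigma^2 = \hat\tau^2 + \hat\eta^2}, i.e. the target
#' is a new noisy observation at the site; `target = "surface"` predicts
#' the noiseless latent surface (\eqn{\hat\sigma^2 = \hat\tau^2}).
#'
#' @param object a [partkrig()] fit.
#' @param newdata data frame with the coordinate columns used at fit time
#'   and all model covariates.
#' @param nn number of nearest neighbours (default 50).
#' @param beta `"global"` (recommended) or `"local"`.
#' @param target `"observation"` (default) or `"surface"`.
#' @param interval `"none"` or `"prediction"` (90% by default, using the
#'   1.645 normal quantile at `level = 0.90`).
#' @param level interval level.
#' @param Chat optional override for the fixed-effects covariance matrix.
#' @param ... unused.
#' @return A data frame with columns `fit`, `se`, and if requested `lwr`,
#'   `upr`.
#' @export
predict.partkrig <- function(object, newdata, nn = 50,
                             beta = c("global", "local"),
                             target = c("observation", "surface"),
                             interval = c("none", "prediction"),
                             level = 0.90, Chat = NULL, ...) {
  beta <- match.arg(beta)
  target <- match.arg(target)
  interval <- match.arg(interval)
  pd <- build_newdata(object, newdata)
  nn <- as.integer(nn)
  if (nn < 1L || nn > object$n)
    stop("nn must be between 1 and the number of observations")
  nb <- find_neighbors(object$coords, pd$coords, nn)
  theta <- unname(object$theta)
  sigma2 <- if (target == "observation") theta[1] + theta[2] else theta[1]
  code <- .family_code(object$family)
  if (is.na(code))
    stop("prediction with a user-supplied covariance family is not supported")
  if (beta == "global") {
    if (is.null(Chat)) Chat <- object$Chat
    if (is.null(Chat)) Chat <- vcov(object)
    out <- nn_predict_cpp(object$coords, object$X, object$y, pd$coords,
                          pd$X, nb$idx, unname(object$beta), Chat, theta,
                          code, sigma2, FALSE, numeric(nrow(pd$coords)))
  } else {
    out <- local_predict_cpp(object$coords, object$X, object$y, pd$coords,
                             pd$X, nb$idx, theta, code, sigma2)
  }
  se <- sqrt(pmax(drop(out$var), 0))
  res <- data.frame(fit = drop(out$fit), se = se)
  if (interval == "prediction") {
    zq <- stats::qnorm(1 - (1 - level) / 2)
    res$lwr <- res$fit - zq * se
    res$upr <- res$fit + zq * se
  }
  res
}

build_newdata <- function(object, newdata) {
  cn <- object$coords_names
  if (!all(cn %in% names(newdata)))
    stop("newdata lacks coordinate columns: ", paste(cn, collapse = ", "))
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail)
  X <- stats::model.matrix(tt, mf)
  if (!identical(colnames(X), colnames(object$X)))
    stop("newdata covariates do not match the fitted design")
  list(coords = as_coord_matrix(newdata[, cn]), X = X)
}

#' Kriging weights over all observations for one prediction site
#'
#' The global-coefficient nearest-neighbour predictor is linear in the full
#' data vector, \eqn{\hat Y(s_j) = \lambda_j' y}, with
#' \deqn{\lambda_j = Q'(x_j - X_j' \hat V_j^{-1} \hat c_j) + N_j' \hat
#' V_j^{-1} \hat c_j,}
#' where \eqn{Q} is the pooled-GLS weight matrix (\eqn{\hat\beta = Qy}) and
#' \eqn{N_j} subsets the data to the neighbourhood. The weights satisfy
#' \eqn{\lambda_j' X = x_j'} (unbiasedness) and reproduce the prediction as
#' \eqn{\lambda_j' y}.
#'
#' @param object a [partkrig()] fit.
#' @param newdata single-row data frame (coordinates + covariates).
#' @param nn number of nearest neighbours.
#' @return Numeric vector of length `n`.
#' @export
lambda_weights <- function(object, newdata, nn = 50) {
  pd <- build_newdata(object, newdata)
  if (nrow(pd$coords) != 1L) stop("newdata must contain exactly one site")
  nb <- find_neighbors(object$coords, pd$coords, nn)
  ix <- drop(nb$idx)
  spec <- object$spec
  Vj <- cov_matrix(spec, object$coords[ix, , drop = FALSE], check = FALSE)
  cj <- drop(cov_matrix(spec, object$coords[ix, , drop = FALSE],
                        pd$coords))
  u <- solve(Vj, cj)
  g <- drop(pd$X) - drop(crossprod(object$X[ix, , drop = FALSE], u))
  lambda <- Q_transpose_v(object, g)
  lambda[ix] <- lambda[ix] + u
  lambda
}

# Q'v for an R-vector v: per fe-block rows (V_ii^{-1} X_i) T_xx^{-1} v
Q_transpose_v <- function(object, v) {
  cache <- object$cache
  w <- solve(cache$Txx, v)
  out <- numeric(object$n)
  for (k in seq_along(cache$blocks))
    out[cache$blocks[[k]]] <- drop(cache$UX[[k]] %*% w)
  out
}
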