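#' Fit a partitioned spatial linear model
#'
#' Fits the geostatistical linear model \eqn{y = X\beta + \epsilon} with
#' spatially correlated errors to point-referenced data by spatial indexing:
#' observations are assigned to blocks, covariance parameters
#' \eqn{\theta = (\tau^2, \eta^2, \rho)} are estimated by restricted maximum
#' likelihood (REML) on the block-diagonal working covariance matrix (only
#' block-sized matrices are ever inverted), and fixed effects by the pooled
#' generalized-least-squares estimator
#' \deqn{\hat\beta = T_{xx}^{-1} t_{xy}, \quad
#'       T_{xx} = \sum_i X_i' V_{ii}^{-1} X_i, \quad
#'       t_{xy} = \sum_i X_i' V_{ii}^{-1} y_i.}
#' Because the blocks of the true covariance matrix are correlated, the
#' covariance matrix of \eqn{\hat\beta} is computed under the full model:
#' the default (`var_method = "exact"`) is
#' \eqn{T_{xx}^{-1} + T_{xx}^{-1} W_{xx} T_{xx}^{-1}} with \eqn{W_{xx}} the
#' symmetrised double sum of \eqn{X_i' V_{ii}^{-1} V_{ij} V_{jj}^{-1} X_j}
#' over block pairs — exact, requiring no extra block inverses. Two faster
#' alternatives use the empirical spread of per-block coefficient estimates
#' (`"empirical"`) or the average of per-block information-matrix inverses
#' (`"pooled"`).
#'
#' @param formula model formula for the fixed effects, e.g. `y ~ x1 + x2`.
#' @param data data frame containing the response, covariates and
#'   coordinates.
#' @param coords coordinate columns: character vector of two column names or
#'   a one-sided formula such as `~ xcoord + ycoord`.
#' @param family `"exponential"` (default), `"spherical"`, or a user
#'   covariance function as in [cov_spec()].
#' @param partition partition scheme for covariance estimation:
#'   `"compact"` (k-means, default), `"random"`, or `"mixed"`; alternatively
#'   pass a ready-made [partition] object via `partition_index`.
#' @param partition_size target observations per block for covariance
#'   estimation (default 50).
#' @param fe_partition,fe_partition_size optional separate scheme/size for
#'   fixed-effects estimation; defaults reuse the covariance partition.
#' @param var_method covariance estimator for the fixed effects:
#'   `"exact"`, `"empirical"`, `"pooled"`, or `"none"`.
#' @param theta optional fixed `c(tau2, eta2, rho)`; skips REML when given.
#' @param init optional REML starting values `c(tau2, eta2, rho)`. Default:
#'   `tau2 = eta2 = var(OLS residuals)/2`, `rho` = 10% of the maximum
#'   pairwise distance.
#' @param control list passed to [stats::optim()] (Nelder--Mead on
#'   log-transformed parameters); defaults `maxit = 1000`, `reltol = 1e-6`.
#' @param frac_reassigned reassignment fraction for mixed partitions.
#' @param partition_index,fe_partition_index explicit [partition] objects
#'   overriding the scheme arguments.
#' @param seed optional integer seed controlling partition randomness.
#' @return An object of class `"partkrig"`; see [predict.partkrig()],
#'   [summary.partkrig()], [vcov.partkrig()], [block_predict()].
#' @examples
#' d <- sim_geostat(n = 300, grid_resolution = 10, seed = 7)
#' obs <- d[d$site == "obs", ]
#' fit <- partkrig(y ~ x1 + x2, obs, coords = c("xcoord", "ycoord"),
#'                 partition_size = 50, seed = 1)
#' summary(fit)
#' @export
partkrig <- function(formula, data, coords = c("x", "y"),
                     family = "exponential",
                     partition = c("compact", "random", "mixed"),
                     partition_size = 50,
                     fe_partition = NULL, fe_partition_size = NULL,
                     var_method = c("exact", "empirical", "pooled", "none"),
                     theta = NULL, init = NULL, control = list(),
                     frac_reassigned = 0.10,
                     partition_index = NULL, fe_partition_index = NULL,
                     seed = NULL) {
  cl <- match.call()
  if (!is.function(family)) family <- match.arg(family,
                                                c("exponential", "spherical"))
  if (is.character(partition)) partition <- match.arg(partition)
  var_method <- match.arg(var_method)

  ds <- build_dataset(formula, data, coords)
  n <- nrow(ds$X)
  if (!is.null(seed)) set.seed(seed)

  cope <- partition_index
  if (is.null(cope))
    cope <- make_partition(partition, ds$coords, partition_size,
                           frac_reassigned)
  check_partition_covers(cope, n)

  fefe <- fe_partition_index
  if (is.null(fefe)) {
    if (is.null(fe_partition) && is.null(fe_partition_size)) {
      fefe <- cope
    } else {
      fefe <- make_partition(if (is.null(fe_partition)) cope$method else
                               fe_partition,
                             ds$coords,
                             if (is.null(fe_partition_size)) cope$target_size
                             else fe_partition_size,
                             frac_reassigned)
    }
  }
  check_partition_covers(fefe, n)

  # --- covariance parameters -------------------------------------------
  if (is.null(theta)) {
    opt <- reml_optimize(ds, cope, family, init, control)
    theta <- opt$theta
    objective <- opt$objective
    converged <- opt$converged
    counts <- opt$counts
  } else {
    theta <- check_theta(theta)
    objective <- reml_objective(theta, ds$coords, ds$X, ds$y, cope, family)
    converged <- NA
    counts <- c(`function` = 0L, gradient = NA_integer_)
  }
  spec <- cov_spec(family, theta[["tau2"]], theta[["eta2"]], theta[["rho"]])

  # --- pooled fixed effects on the fe partition ------------------------
  cache <- blocked_gls(spec, ds, fefe)
  beta <- tryCatch(solve(cache$Txx, cache$txy), error = function(e)
    stop("T_xx is singular; the design matrix is rank deficient: columns ",
         paste(colnames(ds$X), collapse = ", ")))
  beta <- drop(beta)
  names(beta) <- colnames(ds$X)

  fit <- structure(list(
    call = cl, formula = formula, terms = ds$terms,
    coords_names = ds$coords_names, coords = ds$coords,
    X = ds$X, y = ds$y, family = family, spec = spec,
    theta = theta, objective = objective, converged = converged,
    optim_counts = counts, n = n, p = ncol(ds$X),
    partition = cope, fe_partition = fefe,
    beta = beta, Txx = cache$Txx, txy = cache$txy, cache = cache,
    var_method = var_method, Chat = NULL), class = "partkrig")

  if (var_method != "none") fit$Chat <- vcov(fit, method = var_method)
  fit
}

check_theta <- function(theta) {
  theta <- unname(as.numeric(theta))
  if (length(theta) != 3L || theta[1] <= 0 || theta[2] < 0 || theta[3] <= 0)
    stop("theta must be c(tau2 > 0, eta2 >= 0, rho > 0)")
  c(tau2 = theta[1], eta2 = theta[2], rho = theta[3])
}

check_partition_covers <- function(part, n) {
  if (!inherits(part, "partition_index") || length(part$labels) != n)
    stop("partition does not cover the dataset")
  invisible(TRUE)
}

build_dataset <- function(formula, data, coords) {
  if (inherits(coords, "formula")) coords <- all.vars(coords)
  if (!is.character(coords) || length(coords) != 2L)
    stop("coords must name two coordinate columns")
  missing_cols <- setdiff(coords, names(data))
  if (length(missing_cols))
    stop("coordinate columns not found: ", paste(missing_cols, collapse = ", "))
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  cm <- as_coord_matrix(data[, coords])
  if (anyNA(cm)) stop("missing values in coordinate columns")
  if (nrow(cm) != nrow(X))
    stop("rows with missing values are not allowed")
  if (nrow(X) < ncol(X)) stop("more coefficients than observations")
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient: ",
         paste(colnames(X), collapse = ", "))
  list(X = X, y = as.numeric(y), coords = cm, terms = attr(mf, "terms"),
       coords_names = coords)
}

split_blocks <- function(part) {
  split(seq_along(part$labels), part$labels)
}

#' Blocked REML objective
#'
#' Evaluates \eqn{\sum_i \log|V_{ii}| + r' V_{bd}^{-1} r + \log|T_{xx}|}
#' (the REML deviance up to an additive constant), where \eqn{V_{bd}} is the
#' block-diagonal working covariance at `theta`, and \eqn{r = y - X
#' \hat\beta_\theta} uses the blocked GLS coefficients at `theta`. With a
#' single block this is the dense REML objective. Non-positive-definite
#' parameter values return a large penalty (1e10) rather than an error so
#' derivative-free optimizers can recover.
#'
#' Unlike a composite likelihood, the fixed-effects log-determinant pools
#' the per-block information matrices before taking the determinant, so
#' blocks whose design has all-zero columns (e.g. an unrepresented factor
#' level) remain usable.
#'
#' @param theta numeric `c(tau2, eta2, rho)`.
#' @param coords,X,y data pieces (coordinate matrix, design matrix,
#'   response).
#' @param partition a [partition] object covering the data.
#' @param family covariance family as in [partkrig()].
#' @return Scalar objective value.
#' @export
reml_objective <- function(theta, coords, X, y, partition,
                           family = "exponential") {
  theta <- unname(as.numeric(theta))
  coords <- as_coord_matrix(coords)
  X <- as.matrix(X)
  check_partition_covers(partition, nrow(X))
  blocks <- split_blocks(partition)
  code <- .family_code(family)
  if (!is.na(code)) {
    D_list <- lapply(blocks, function(ix)
      cross_dist(coords[ix, , drop = FALSE], coords[ix, , drop = FALSE]))
    X_list <- lapply(blocks, function(ix) X[ix, , drop = FALSE])
    y_list <- lapply(blocks, function(ix) y[ix])
    return(reml_obj_cpp(theta, D_list, X_list, y_list, code))
  }
  reml_objective_r(theta, coords, X, y, blocks, family)
}

# R path for user-supplied covariance families
reml_objective_r <- function(theta, coords, X, y, blocks, family) {
  penalty <- 1e10
  if (theta[1] <= 0 || theta[2] < 0 || theta[3] <= 0) return(penalty)
  spec <- tryCatch(cov_spec(family, theta[1], theta[2], theta[3]),
                   error = function(e) NULL)
  if (is.null(spec)) return(penalty)
  R <- ncol(X)
  Txx <- matrix(0, R, R); txy <- numeric(R)
  logdetV <- 0; yy <- 0
  for (ix in blocks) {
    V <- tryCatch(cov_matrix(spec, coords[ix, , drop = FALSE], check = FALSE),
                  error = function(e) NULL)
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) return(penalty)
    logdetV <- logdetV + 2 * sum(log(diag(U)))
    Z <- forwardsolve(t(U), cbind(X[ix, , drop = FALSE], y[ix]))
    M <- crossprod(Z)
    Txx <- Txx + M[seq_len(R), seq_len(R), drop = FALSE]
    txy <- txy + M[seq_len(R), R + 1]
    yy <- yy + M[R + 1, R + 1]
  }
  beta <- tryCatch(solve(Txx, txy), error = function(e) NULL)
  if (is.null(beta)) return(penalty)
  ldT <- determinant(Txx, logarithm = TRUE)
  if (ldT$sign <= 0) return(penalty)
  obj <- logdetV + yy - 2 * sum(beta * txy) + drop(crossprod(beta, Txx %*% beta)) +
    as.numeric(ldT$modulus)
  if (!is.finite(obj)) penalty else obj
}

# REML by Nelder-Mead simplex on log(tau2), log(eta2), log(rho)
reml_optimize <- function(ds, partition, family, init, control) {
  if (is.null(init)) {
    r <- stats::lm.fit(ds$X, ds$y)$residuals
    v <- stats::var(r)
    init <- c(tau2 = v / 2, eta2 = v / 2, rho = 0.1 * max_pairwise_dist(ds$coords))
  } else {
    init <- check_theta(init)
  }
  control <- utils::modifyList(list(maxit = 1000L, reltol = 1e-6), control)
  blocks <- split_blocks(partition)
  code <- .family_code(family)
  if (!is.na(code)) {
    ord <- unlist(blocks, use.names = FALSE)
    starts <- c(0L, cumsum(lengths(blocks)))
    coords_o <- ds$coords[ord, , drop = FALSE]
    X_o <- ds$X[ord, , drop = FALSE]
    y_o <- ds$y[ord]
    obj <- function(par) reml_obj_flat_cpp(exp(par), coords_o, X_o, y_o,
                                           starts, code)
  } else {
    obj <- function(par) reml_objective_r(exp(par), ds$coords, ds$X, ds$y,
                                          blocks, family)
  }
  opt <- stats::optim(log(unname(init)), obj, method = "Nelder-Mead",
                      control = control)
  theta <- exp(opt$par)
  list(theta = c(tau2 = theta[1], eta2 = theta[2], rho = theta[3]),
       objective = opt$value, converged = opt$convergence == 0L,
       counts = opt$counts)
}

# exact maximum pairwise distance via the convex hull (the diameter is
# attained between hull vertices)
max_pairwise_dist <- function(coords) {
  h <- grDevices::chull(coords)
  max(cross_dist(coords[h, , drop = FALSE], coords[h, , drop = FALSE]))
}

# Per-block GLS caches at fixed theta on a given partition
blocked_gls <- function(spec, ds, partition) {
  blocks <- split_blocks(partition)
  code <- .family_code(spec$family)
  theta <- unname(spec$theta)
  if (!is.na(code)) {
    coords_list <- lapply(blocks, function(ix) ds$coords[ix, , drop = FALSE])
    X_list <- lapply(blocks, function(ix) ds$X[ix, , drop = FALSE])
    y_list <- lapply(blocks, function(ix) ds$y[ix])
    out <- blocked_gls_cpp(theta, coords_list, X_list, y_list, code)
    out$blocks <- blocks
    out$coords_list <- coords_list
    return(out)
  }
  R <- ncol(ds$X)
  Txx <- matrix(0, R, R); txy <- numeric(R)
  UX <- Uy <- A <- b <- vector("list", length(blocks))
  coords_list <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    ix <- blocks[[k]]
    coords_list[[k]] <- ds$coords[ix, , drop = FALSE]
    V <- cov_matrix(spec, coords_list[[k]], check = FALSE)
    Vinv <- solve(V)
    Xb <- ds$X[ix, , drop = FALSE]
    UX[[k]] <- Vinv %*% Xb
    Uy[[k]] <- Vinv %*% ds$y[ix]
    A[[k]] <- crossprod(Xb, UX[[k]])
    b[[k]] <- drop(crossprod(Xb, Uy[[k]]))
    Txx <- Txx + A[[k]]
    txy <- txy + b[[k]]
  }
  list(Txx = Txx, txy = txy, UX = UX, Uy = Uy, A = A, b = b,
       blocks = blocks, coords_list = coords_list)
}
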