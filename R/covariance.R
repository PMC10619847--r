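#' Covariance specification for the spatial linear model
#'
#' Bundles an autocovariance family with its parameter vector
#' \eqn{\theta = (\tau^2, \eta^2, \rho)}: the partial sill (spatially
#' structured variance), the nugget (micro-scale / measurement-error
#' variance) and the range (distance scale of correlation decay). The
#' stationary variance is \eqn{\sigma^2 = \tau^2 + \eta^2}, the value of the
#' covariance function at distance zero on the diagonal.
#'
#' @param family `"exponential"`, `"spherical"`, or a function
#'   `function(d, theta, on_diagonal)` implementing a user-supplied valid
#'   autocovariance (vectorised over `d`; `theta` is the numeric vector
#'   `c(tau2, eta2, rho)`).
#' @param tau2 partial sill, must be `> 0`.
#' @param eta2 nugget, must be `>= 0`.
#' @param rho range parameter, must be `> 0`.
#' @return An object of class `"cov_spec"`.
#' @examples
#' sp <- cov_spec("exponential", tau2 = 10, eta2 = 0.1, rho = 0.5)
#' cov_value(sp, d = 0, on_diagonal = TRUE)  # sigma^2 = 10.1
#' @export
cov_spec <- function(family = c("exponential", "spherical"),
                     tau2, eta2, rho) {
  if (!is.function(family)) family <- match.arg(family)
  stopifnot(is.numeric(tau2), length(tau2) == 1L,
            is.numeric(eta2), length(eta2) == 1L,
            is.numeric(rho), length(rho) == 1L)
  if (!is.finite(tau2) || tau2 <= 0) stop("tau2 (partial sill) must be > 0")
  if (!is.finite(eta2) || eta2 < 0) stop("eta2 (nugget) must be >= 0")
  if (!is.finite(rho) || rho <= 0) stop("rho (range) must be > 0")
  structure(list(family = family, theta = c(tau2 = tau2, eta2 = eta2,
                                            rho = rho)),
            class = "cov_spec")
}

#' @export
print.cov_spec <- function(x, ...) {
  fam <- if (is.function(x$family)) "user-supplied" else x$family
  cat("Covariance:", fam, "\n")
  print(x$theta)
  invisible(x)
}

# integer code used by the compiled kernels; NA for user families
.family_code <- function(family) {
  if (is.function(family)) return(NA_integer_)
  match(family, c("exponential", "spherical")) - 1L
}

#' Evaluate an autocovariance function
#'
#' The exponential model is \eqn{\tau^2 \exp(-d/\rho)}; the spherical model
#' is \eqn{\tau^2 (1 - 3d/(2\rho) + d^3/(2\rho^3))} for \eqn{d < \rho} and
#' exactly zero beyond the range. The nugget \eqn{\eta^2} is added only when
#' `on_diagonal = TRUE`, i.e. for an observation's covariance with itself;
#' pairs of distinct locations at distance zero do not receive it.
#'
#' @param spec a [cov_spec()].
#' @param d vector of non-negative distances.
#' @param on_diagonal logical; add the nugget?
#' @return Covariance values, same length as `d`.
#' @export
cov_value <- function(spec, d, on_diagonal = FALSE) {
  stopifnot(inherits(spec, "cov_spec"))
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  th <- spec$theta
  if (is.function(spec$family)) {
    v <- spec$family(d, unname(th), on_diagonal)
  } else {
    v <- switch(spec$family,
      exponential = th[["tau2"]] * exp(-d / th[["rho"]]),
      spherical = {
        u <- pmin(d / th[["rho"]], 1)
        th[["tau2"]] * (1 - 1.5 * u + 0.5 * u^3) * (d < th[["rho"]])
      })
    if (on_diagonal) v <- v + th[["eta2"]]
  }
  unname(v)
}

#' Build a covariance matrix between two point sets
#'
#' When `coordsB` is omitted, the same-set matrix is built with the nugget
#' on its diagonal; it is symmetric and must be positive definite. Cross
#' matrices (e.g. between prediction sites and data) never include the
#' nugget.
#'
#' @param spec a [cov_spec()].
#' @param coordsA,coordsB two-column coordinate matrices.
#' @param check if `TRUE` (default) a same-set matrix is checked with a
#'   Cholesky factorisation and an informative error names the parameters on
#'   failure.
#' @return A `nrow(coordsA)` by `nrow(coordsB)` covariance matrix.
#' @export
cov_matrix <- function(spec, coordsA, coordsB = NULL, check = TRUE) {
  stopifnot(inherits(spec, "cov_spec"))
  coordsA <- as_coord_matrix(coordsA)
  same <- is.null(coordsB)
  coordsB <- if (same) coordsA else as_coord_matrix(coordsB)
  th <- spec$theta
  code <- .family_code(spec$family)
  if (is.na(code)) {
    # user-supplied family: plain R double loop through cov_value
    D <- cross_dist(coordsA, coordsB)
    V <- matrix(cov_value(spec, as.vector(D)), nrow(coordsA), nrow(coordsB))
    if (same) diag(V) <- cov_value(spec, rep(0, nrow(coordsA)),
                                   on_diagonal = TRUE)
  } else {
    V <- cov_mat_cpp(coordsA, coordsB, code, th[["tau2"]], th[["eta2"]],
                     th[["rho"]], same)
  }
  if (same && check) {
    ok <- tryCatch({ chol(V); TRUE }, error = function(e) FALSE)
    if (!ok)
      stop(sprintf(
        "covariance matrix is numerically degenerate (tau2=%g, eta2=%g, rho=%g)",
        th[["tau2"]], th[["eta2"]], th[["rho"]]))
  }
  V
}

# Euclidean cross-distance matrix (small inputs; used for user families and
# oracles). Coordinates are planar and unprojected.
cross_dist <- function(A, B) {
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || ncol(x) != 2L || nrow(x) < 1L)
    stop("coordinates must be a non-empty two-column numeric matrix")
  storage.mode(x) <- "double"
  unname(x)
}
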