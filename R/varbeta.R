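#' Covariance matrix of the pooled fixed-effects estimator
#'
#' Three estimators of \eqn{\mathrm{var}(\hat\beta)} for a fitted
#' partitioned spatial linear model:
#' \describe{
#'   \item{`"exact"`}{\eqn{T_{xx}^{-1} + T_{xx}^{-1} W_{xx} T_{xx}^{-1}},
#'     computed under the full (unpartitioned) covariance model; the
#'     cross-block correction \eqn{W_{xx}} loops over block pairs and builds
#'     each cross-covariance block on the fly. Identical to
#'     \eqn{Q \hat{V} Q'} for the weight matrix \eqn{Q} with
#'     \eqn{\hat\beta = Qy}. With one block it reduces to
#'     \eqn{(X'V^{-1}X)^{-1}}.}
#'   \item{`"empirical"`}{\eqn{\frac{1}{P(P-1)} \sum_i (\hat\beta_i -
#'     \hat\beta)(\hat\beta_i - \hat\beta)'} from the per-block GLS
#'     estimates; requires at least two blocks. Blocks with a rank-deficient
#'     local design are dropped with a warning.}
#'   \item{`"pooled"`}{\eqn{\frac{1}{P^2} \sum_i (X_i' V_{ii}^{-1}
#'     X_i)^{-1}}; singular block information matrices are skipped with `P`
#'     adjusted and a warning.}
#' }
#'
#' @param object a [partkrig()] fit.
#' @param method `"exact"` (default), `"empirical"`, or `"pooled"`.
#' @param ... unused.
#' @return A symmetric positive semidefinite matrix, `p` by `p`.
#' @export
vcov.partkrig <- function(object,
                          method = c("exact", "empirical", "pooled"), ...) {
  method <- match.arg(method)
  switch(method,
         exact = var_beta_exact(object),
         empirical = var_beta_empirical(object),
         pooled = var_beta_pooled(object))
}

var_beta_exact <- function(object) {
  cache <- object$cache
  Tinv <- solve(cache$Txx)
  P <- length(cache$blocks)
  if (P == 1L) {
    C <- Tinv
  } else {
    code <- .family_code(object$family)
    theta <- unname(object$theta)
    if (!is.na(code)) {
      W <- wxx_cpp(theta, cache$coords_list, cache$UX, code)
    } else {
      R <- object$p
      W <- matrix(0, R, R)
      spec <- object$spec
      for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
        Vij <- cov_matrix(spec, cache$coords_list[[i]],
                          cache$coords_list[[j]])
        M <- crossprod(cache$UX[[i]], Vij %*% cache$UX[[j]])
        W <- W + M + t(M)
      }
    }
    C <- Tinv + Tinv %*% W %*% Tinv
  }
  C <- (C + t(C)) / 2
  dimnames(C) <- list(names(object$beta), names(object$beta))
  C
}

# per-block GLS coefficient estimates beta_i = (X_i'V_ii^-1 X_i)^-1 X_i'V_ii^-1 y_i
block_betas <- function(object) {
  cache <- object$cache
  lapply(seq_along(cache$blocks), function(k)
    tryCatch(drop(solve(cache$A[[k]], cache$b[[k]])),
             error = function(e) NULL))
}

var_beta_empirical <- function(object) {
  P <- length(object$cache$blocks)
  if (P < 2L)
    stop("empirical variance of the pooled estimator needs at least 2 blocks")
  bi <- block_betas(object)
  bad <- vapply(bi, is.null, logical(1))
  if (any(bad))
    warning(sum(bad), " block(s) with rank-deficient design dropped from ",
            "the empirical variance")
  bi <- bi[!bad]
  Pe <- length(bi)
  if (Pe < 2L) stop("fewer than 2 usable blocks for the empirical variance")
  dev <- lapply(bi, function(b) b - object$beta)
  C <- Reduce(`+`, lapply(dev, tcrossprod)) / (P * (P - 1))
  C <- (C + t(C)) / 2
  dimnames(C) <- list(names(object$beta), names(object$beta))
  C
}

var_beta_pooled <- function(object) {
  cache <- object$cache
  P <- length(cache$blocks)
  Ai <- lapply(cache$A, function(A)
    tryCatch(solve(A), error = function(e) NULL))
  bad <- vapply(Ai, is.null, logical(1))
  if (any(bad)) {
    warning(sum(bad), " block(s) with singular information matrix skipped ",
            "in the pooled variance; P adjusted")
    Ai <- Ai[!bad]
  }
  Pe <- length(Ai)
  C <- Reduce(`+`, Ai) / (Pe * Pe)
  C <- (C + t(C)) / 2
  dimnames(C) <- list(names(object$beta), names(object$beta))
  C
}

#' Wald table for fixed effects
#'
#' Estimates, standard errors from the chosen covariance estimator,
#' z-statistics (estimate divided by its standard error) and two-sided
#' p-values from the standard normal reference. A zero standard error
#' yields `NA` for z and p.
#'
#' @param object a [partkrig()] fit.
#' @param Chat optional covariance matrix of the coefficients; defaults to
#'   the one stored in the fit (or the exact estimator if none stored).
#' @return A data frame with columns `estimate`, `se`, `z`, `p`.
#' @export
wald_table <- function(object, Chat = NULL) {
  if (is.null(Chat)) Chat <- object$Chat
  if (is.null(Chat)) Chat <- vcov(object)
  se <- sqrt(pmax(diag(Chat), 0))
  z <- ifelse(se > 0, object$beta / se, NA_real_)
  p <- ifelse(is.na(z), NA_real_, 2 * stats::pnorm(-abs(z)))
  data.frame(estimate = object$beta, se = se, z = z, p = p,
             row.names = names(object$beta))
}

#' @export
coef.partkrig <- function(object, ...) object$beta

#' @export
fitted.partkrig <- function(object, ...) drop(object$X %*% object$beta)

#' @export
residuals.partkrig <- function(object, ...) object$y - fitted(object)

#' @export
print.partkrig <- function(x, digits = 4, ...) {
  cat("Partitioned spatial linear model\n")
  fam <- if (is.function(x$family)) "user-supplied" else x$family
  cat(sprintf("  n = %d, covariance: %s, blocks: %d (%s, target %d)\n",
              x$n, fam, x$partition$P, x$partition$method,
              x$partition$target_size))
  cat("  theta:", paste(sprintf("%s = %.4g", names(x$theta), x$theta),
                        collapse = ", "), "\n")
  cat("  coefficients:\n")
  print(round(x$beta, digits))
  invisible(x)
}

#' Summary of a partitioned spatial linear model fit
#'
#' @param object a [partkrig()] fit.
#' @param var_method which fixed-effects covariance estimator to report;
#'   defaults to the one chosen at fit time.
#' @param ... unused.
#' @return An object of class `"summary.partkrig"`.
#' @export
summary.partkrig <- function(object, var_method = NULL, ...) {
  if (is.null(var_method))
    var_method <- if (object$var_method == "none") "exact" else
      object$var_method
  Chat <- if (!is.null(object$Chat) && var_method == object$var_method)
    object$Chat else vcov(object, method = var_method)
  structure(list(fit = object, var_method = var_method,
                 coefficients = wald_table(object, Chat)),
            class = "summary.partkrig")
}

#' @export
print.summary.partkrig <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  fixed-effects variance: %s estimator\n", x$var_method))
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("  REML objective: %.4f (converged: %s)\n",
              x$fit$objective, x$fit$converged))
  invisible(x)
}

#' @export
plot.partkrig <- function(x, ...) {
  graphics::plot(x$coords, col = x$partition$labels, pch = 16, cex = 0.5,
                 xlab = x$coords_names[1], ylab = x$coords_names[2],
                 main = sprintf("%s partition, P = %d", x$partition$method,
                                x$partition$P), ...)
  invisible(x)
}
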