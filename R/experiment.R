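#' Re-estimate fixed effects of a fit under a different partition
#'
#' Keeps the estimated covariance parameters but rebuilds the blocked GLS
#' caches, the pooled coefficient estimate and (optionally) its covariance
#' under a new fixed-effects partition. Used to cross partition schemes or
#' sizes between covariance and fixed-effects estimation without repeating
#' the REML optimization.
#'
#' @param object a [partkrig()] fit.
#' @param fe_partition partition scheme (`"compact"`, `"random"`,
#'   `"mixed"`) or a ready [partition] object.
#' @param fe_partition_size target block size (ignored when a partition
#'   object is given).
#' @param var_method fixed-effects covariance estimator, as in
#'   [partkrig()].
#' @param frac_reassigned reassignment fraction for mixed partitions.
#' @return The modified `"partkrig"` object.
#' @export
refit_fixed_effects <- function(object, fe_partition = "compact",
                                fe_partition_size = 50,
                                var_method = object$var_method,
                                frac_reassigned = 0.10) {
  if (inherits(fe_partition, "partition_index")) {
    fefe <- fe_partition
  } else {
    fefe <- make_partition(fe_partition, object$coords, fe_partition_size,
                           frac_reassigned)
  }
  check_partition_covers(fefe, object$n)
  ds <- list(X = object$X, y = object$y, coords = object$coords)
  cache <- blocked_gls(object$spec, ds, fefe)
  object$fe_partition <- fefe
  object$cache <- cache
  object$Txx <- cache$Txx
  object$txy <- cache$txy
  beta <- drop(solve(cache$Txx, cache$txy))
  names(beta) <- colnames(object$X)
  object$beta <- beta
  object$var_method <- var_method
  object$Chat <- if (var_method == "none") NULL else
    vcov(object, method = var_method)
  object
}

#' Monte-Carlo evaluation harness for the partitioned spatial model
#'
#' Repeats: simulate a surface ([sim_geostat()] or [sim_sumsine()]), fit an
#' exponential-covariance model by blocked REML on the observation sites,
#' estimate fixed effects under one or more partition configurations and
#' variance estimators, predict the grid sites by nearest-neighbour
#' kriging, and optionally predict the areal (grid) mean. In the `"mixed"`
#' design each replicate draws the generator at random with equal
#' probability: geostatistical with `n ~ U{geostat_n}` and range
#' `rho ~ U(rho)`, or sine-sum with `n ~ U{sumsine_n}` — and the fitted
#' exponential model is thereby deliberately misspecified.
#'
#' @param reps number of replicates.
#' @param seed integer base seed; replicate `r` uses `seed + r`.
#' @param sim `"mixed"`, `"geostat"`, or `"sumsine"`.
#' @param geostat_n,sumsine_n inclusive integer ranges for the per-method
#'   sample-size draw (a single value fixes `n`).
#' @param rho range `c(min, max)` for the uniform draw of the spherical
#'   range parameter, or a single fixed value.
#' @param theta_geostat partial sill and nugget `c(tau2, eta2)` of the
#'   geostatistical generator.
#' @param standardize standardise errors and the patterned covariate
#'   before assembling the response (as in the fixed-`n` comparison
#'   design).
#' @param grid_resolution prediction grid points per side.
#' @param cope_method,cope_size partition scheme and size for covariance
#'   (REML) estimation; a length-2 `cope_size` is an inclusive range drawn
#'   per replicate.
#' @param fefe_methods,fefe_size one or more fixed-effects partition
#'   schemes; `fefe_size` is a single size or an inclusive range
#'   `c(min, max)` drawn per replicate, defaulting to the covariance
#'   partition's (possibly drawn) size.
#' @param var_methods fixed-effects covariance estimators to evaluate
#'   (first one also feeds the prediction variances).
#' @param nn neighbour counts to evaluate.
#' @param predictors subset of `c("global", "local")`.
#' @param block also compute the areal-mean prediction.
#' @param block_nn neighbour counts for the areal-mean prediction (default:
#'   all of `nn`).
#' @param cap observation cap for the block-variance computation.
#' @param progress print a dot per replicate.
#' @return List of data frames `coef`, `pred`, `block` (see
#'   [summarize_experiment()]), plus the call settings as attributes.
#' @export
run_experiment <- function(reps, seed, sim = c("mixed", "geostat", "sumsine"),
                           geostat_n = c(1000, 2000),
                           sumsine_n = c(2000, 10000),
                           rho = c(0, 2), theta_geostat = c(10, 0.1),
                           standardize = FALSE, grid_resolution = 40,
                           cope_method = "compact", cope_size = 50,
                           fefe_methods = "compact", fefe_size = NULL,
                           var_methods = "exact", nn = 50,
                           predictors = "global", block = FALSE,
                           block_nn = NULL, cap = 5000, progress = FALSE) {
  sim <- match.arg(sim)
  stopifnot(reps >= 1)
  # inclusive-range draw that is safe when the range collapses to a point
  draw_int <- function(rng) {
    v <- rng[1]:rng[2]
    v[sample.int(length(v), 1L)]
  }
  coef_rows <- list(); pred_rows <- list(); block_rows <- list()
  beta_true <- c(1, 1, 1)
  for (r in seq_len(reps)) {
    set.seed(seed + r)
    method <- switch(sim, mixed = if (stats::runif(1) < 0.5) "geostat" else
      "sumsine", sim)
    rho_r <- if (length(rho) > 1) stats::runif(1, rho[1], rho[2]) else rho
    csize_r <- if (length(cope_size) > 1) draw_int(cope_size) else cope_size
    fesize_r <- if (is.null(fefe_size)) csize_r else
      if (length(fefe_size) > 1) draw_int(fefe_size) else fefe_size
    sim_seed <- seed + 100000L + r
    if (method == "geostat") {
      n <- if (length(geostat_n) > 1) draw_int(geostat_n) else geostat_n
      d <- sim_geostat(n, grid_resolution,
                       theta = c(theta_geostat[1], theta_geostat[2], rho_r),
                       beta = beta_true, standardize = standardize,
                       seed = sim_seed)
    } else {
      n <- if (length(sumsine_n) > 1) draw_int(sumsine_n) else sumsine_n
      d <- sim_sumsine(n, grid_resolution, beta = beta_true,
                       standardize = standardize, seed = sim_seed)
    }
    obs <- d[d$site == "obs", ]
    grid <- d[d$site == "grid", ]
    fit0 <- partkrig(y ~ x1 + x2, obs, coords = c("xcoord", "ycoord"),
                     family = "exponential", partition = cope_method,
                     partition_size = csize_r, var_method = "none")
    for (fm in fefe_methods) {
      ft <- refit_fixed_effects(fit0, fm, fesize_r, var_method = "none")
      for (vm in var_methods) {
        Chat <- vcov(ft, method = vm)
        se <- sqrt(pmax(diag(Chat), 0))
        for (term in c("x1", "x2")) {
          coef_rows[[length(coef_rows) + 1L]] <- data.frame(
            rep = r, sim = method, n = n, rho = rho_r,
            fefe_method = fm, fefe_size = fesize_r, var_method = vm,
            term = term, estimate = ft$beta[[term]], se = se[[term]],
            true = 1)
        }
        if (fm == fefe_methods[1] && vm == var_methods[1]) {
          fit_main <- ft
          fit_main$Chat <- Chat
          fit_main$var_method <- vm
        }
      }
    }
    if (nrow(grid) > 0 && (length(predictors) > 0 || block)) {
      for (m in nn) {
        for (pr in predictors) {
          pp <- predict(fit_main, grid, nn = m, beta = pr)
          err <- pp$fit - grid$y
          pred_rows[[length(pred_rows) + 1L]] <- data.frame(
            rep = r, sim = method, n = n, nn = m, predictor = pr,
            sspe = sum(err^2), n_pred = nrow(grid),
            n_cover = sum(abs(err) < 1.645 * pp$se))
        }
        if (block && (is.null(block_nn) || m %in% block_nn)) {
          bp <- block_predict(fit_main, grid, nn = m, cap = cap)
          block_rows[[length(block_rows) + 1L]] <- data.frame(
            rep = r, sim = method, n = n, nn = m, fit = bp$fit,
            truth = mean(grid$y), se = bp$se)
        }
      }
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  out <- list(coef = do.call(rbind, coef_rows),
              pred = do.call(rbind, pred_rows),
              block = do.call(rbind, block_rows))
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  out
}

#' Summaries of a Monte-Carlo experiment
#'
#' Aggregates the per-replicate output of [run_experiment()]: coefficient
#' RMSE and 90% confidence-interval coverage per (partition scheme,
#' variance estimator, term); prediction RMSPE and 90% prediction-interval
#' coverage per (neighbour count, predictor), pooled over replicates and
#' grid sites; areal-mean RMSPE and interval coverage per neighbour count.
#'
#' @param res result of [run_experiment()].
#' @return List of data frames `coef`, `pred`, `block`.
#' @export
summarize_experiment <- function(res) {
  out <- list()
  if (!is.null(res$coef)) {
    cf <- res$coef
    key <- interaction(cf$fefe_method, cf$var_method, cf$term, drop = TRUE)
    out$coef <- do.call(rbind, lapply(split(cf, key), function(g) {
      m <- sim_metrics(g$estimate, g$true, g$se)
      data.frame(fefe_method = g$fefe_method[1], var_method = g$var_method[1],
                 term = g$term[1], rmse = m[["rmse"]], ci90 = m[["cover"]])
    }))
    rownames(out$coef) <- NULL
  }
  if (!is.null(res$pred)) {
    pd <- res$pred
    key <- interaction(pd$nn, pd$predictor, drop = TRUE)
    out$pred <- do.call(rbind, lapply(split(pd, key), function(g) {
      data.frame(nn = g$nn[1], predictor = g$predictor[1],
                 rmspe = sqrt(sum(g$sspe) / sum(g$n_pred)),
                 pi90 = sum(g$n_cover) / sum(g$n_pred))
    }))
    rownames(out$pred) <- NULL
  }
  if (!is.null(res$block)) {
    bl <- res$block
    out$block <- do.call(rbind, lapply(split(bl, bl$nn), function(g) {
      m <- sim_metrics(g$fit, g$truth, g$se)
      data.frame(nn = g$nn[1], rmspe = m[["rmse"]], pi90 = m[["cover"]])
    }))
    rownames(out$block) <- NULL
  }
  out
}
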