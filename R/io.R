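#' Read a point-referenced dataset from CSV
#'
#' Reads a header CSV, checks that the declared coordinate, response and
#' covariate columns are present and numeric, and rejects rows with missing
#' values in the used columns (naming the offending rows). Extra columns
#' are ignored with a notice.
#'
#' @param path CSV file path.
#' @param coords names of the two coordinate columns.
#' @param response response column name (`NULL` for prediction-site files).
#' @param covariates covariate column names (default: all remaining
#'   numeric columns are left untouched but unused).
#' @return The validated data frame (used columns only, original order).
#' @export
read_spatial_csv <- function(path, coords = c("x", "y"), response = NULL,
                             covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(d)))
    stop("duplicate header names: ",
         paste(unique(names(d)[duplicated(names(d))]), collapse = ", "))
  used <- c(coords, response, covariates)
  miss <- setdiff(used, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (cl in used)
    if (!is.numeric(d[[cl]]))
      stop("column '", cl, "' is not numeric")
  bad <- which(!stats::complete.cases(d[used]))
  if (length(bad))
    stop("missing values in rows: ", paste(utils::head(bad, 10L),
                                           collapse = ", "))
  extra <- setdiff(names(d), used)
  if (length(extra))
    message("ignoring unused columns: ", paste(extra, collapse = ", "))
  d[used]
}

#' @rdname read_spatial_csv
#' @param data data frame to write.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model to JSON and back
#'
#' `write_fit()` stores the estimated covariance parameters, coefficients
#' and their covariance matrix, convergence status, both partition label
#' vectors and a configuration echo. `read_fit()` rebuilds a working
#' `"partkrig"` object from the JSON plus the original data; because the
#' coefficient solve is deterministic given the stored parameters and
#' labels, reloaded fits reproduce predictions exactly.
#'
#' @param object a [partkrig()] fit.
#' @param path JSON file path.
#' @return `read_fit()` returns a `"partkrig"` object.
#' @export
write_fit <- function(object, path) {
  fam <- if (is.function(object$family)) stop("cannot serialize a fit with ",
    "a user-supplied covariance function") else object$family
  payload <- list(
    formula = deparse(object$formula),
    coords = object$coords_names,
    family = fam,
    theta = as.list(object$theta),
    beta = as.list(object$beta),
    Chat = object$Chat,
    objective = object$objective,
    converged = object$converged,
    var_method = object$var_method,
    n = object$n,
    partition = list(labels = object$partition$labels,
                     method = object$partition$method,
                     target_size = object$partition$target_size),
    fe_partition = list(labels = object$fe_partition$labels,
                        method = object$fe_partition$method,
                        target_size = object$fe_partition$target_size))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @param data the data frame the model was fitted to.
#' @export
read_fit <- function(path, data) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cope <- new_partition_index(p$partition$labels,
                              max(p$partition$labels),
                              p$partition$method, p$partition$target_size)
  fefe <- new_partition_index(p$fe_partition$labels,
                              max(p$fe_partition$labels),
                              p$fe_partition$method,
                              p$fe_partition$target_size)
  fit <- partkrig(stats::as.formula(paste(p$formula, collapse = " ")),
                  data, coords = p$coords, family = p$family,
                  theta = unlist(p$theta), var_method = "none",
                  partition_index = cope, fe_partition_index = fefe)
  fit$Chat <- matrix(unlist(p$Chat), fit$p, fit$p,
                     dimnames = list(names(fit$beta), names(fit$beta)))
  fit$var_method <- p$var_method
  fit$converged <- p$converged
  fit
}

#' Write predictions with 90% intervals to CSV
#'
#' Columns: site id, the two coordinates, `prediction`, `pred_se`,
#' `lower90`, `upper90` with the 1.645 normal multiplier.
#'
#' @param pred data frame from [predict.partkrig()].
#' @param sites the prediction-site data frame (for the coordinates).
#' @param coords coordinate column names in `sites`.
#' @param path output CSV path.
#' @export
write_predictions <- function(pred, sites, path, coords = c("x", "y")) {
  out <- data.frame(site = seq_len(nrow(pred)),
                    sites[, coords, drop = FALSE],
                    prediction = pred$fit, pred_se = pred$se,
                    lower90 = pred$fit - 1.645 * pred$se,
                    upper90 = pred$fit + 1.645 * pred$se)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
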