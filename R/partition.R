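#' Spatial partitions (indexing) of observations into blocks
#'
#' Assign each observation to one of `P = ceiling(n / target_size)` blocks.
#' Three schemes are available: completely random assignment (`"random"`),
#' spatially compact blocks from k-means clustering of the coordinates
#' (`"compact"`), and a mixed scheme that starts from the compact partition
#' and randomly reassigns a fraction of each block's members to other blocks
#' (`"mixed"`). Compact partitions give the blocked estimators the most
#' information about short-range correlation and are the recommended
#' default.
#'
#' @param coords two-column matrix (or data frame) of planar coordinates.
#' @param target_size requested observations per block (`>= 2` unless a
#'   single block covers the data).
#' @param seed optional integer seed; fixed seeds give identical partitions.
#' @param frac_reassigned for `partition_mixed()`: fraction of each block's
#'   members reassigned uniformly to one of the other blocks (default 0.10).
#' @return An object of class `"partition_index"`: list with `labels`
#'   (integer block id per observation), `P`, `method`, `target_size`.
#' @examples
#' xy <- matrix(runif(200), ncol = 2)
#' p <- partition_compact(xy, target_size = 20, seed = 1)
#' table(p$labels)
#' @name partition
NULL

new_partition_index <- function(labels, P, method, target_size) {
  labels <- as.integer(labels)
  if (any(tabulate(labels, P) == 0L)) stop("internal: empty block")
  structure(list(labels = labels, P = as.integer(P), method = method,
                 target_size = as.integer(target_size)),
            class = "partition_index")
}

#' @export
print.partition_index <- function(x, ...) {
  cat(sprintf("Partition (%s): %d observations in %d blocks (target size %d)\n",
              x$method, length(x$labels), x$P, x$target_size))
  invisible(x)
}

check_partition_args <- function(n, target_size) {
  if (target_size > n) stop("target_size exceeds the number of observations")
  if (target_size < 2L && n > 1L) stop("target_size must be at least 2")
  as.integer(ceiling(n / target_size))
}

#' @rdname partition
#' @export
partition_random <- function(coords, target_size, seed = NULL) {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  P <- check_partition_args(n, target_size)
  if (!is.null(seed)) set.seed(seed)
  # permutation-based: block sizes differ by at most one
  labels <- rep_len(seq_len(P), n)[sample.int(n)]
  new_partition_index(labels, P, "random", target_size)
}

# k-means++ style seeding: spread initial centers proportionally to squared
# distance from the chosen set.
kmeanspp_centers <- function(coords, k) {
  n <- nrow(coords)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((coords - coords[rep(centers[1], n), , drop = FALSE])^2)
  if (k > 1L) for (i in 2:k) {
    prob <- d2 / sum(d2)
    centers[i] <- sample.int(n, 1L, prob = prob)
    nd <- rowSums((coords - coords[rep(centers[i], n), , drop = FALSE])^2)
    d2 <- pmin(d2, nd)
  }
  coords[centers, , drop = FALSE]
}

#' @rdname partition
#' @export
partition_compact <- function(coords, target_size, seed = NULL) {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  P <- check_partition_args(n, target_size)
  if (!is.null(seed)) set.seed(seed)
  if (P == 1L) return(new_partition_index(rep(1L, n), 1L, "compact",
                                          target_size))
  centers <- kmeanspp_centers(coords, P)
  centers <- centers + 1e-10 * matrix(stats::rnorm(2 * P), P, 2)  # distinct
  km <- suppressWarnings(stats::kmeans(coords, centers = centers,
                                       iter.max = 100L,
                                       algorithm = "Lloyd"))
  labels <- km$cluster
  # Lloyd can in principle empty a cluster; reassign nearest points if so
  empty <- which(tabulate(labels, P) == 0L)
  for (b in empty) {
    big <- which.max(tabulate(labels, P))
    move <- which(labels == big)[1L]
    labels[move] <- b
  }
  new_partition_index(labels, P, "compact", target_size)
}

#' @rdname partition
#' @export
partition_mixed <- function(coords, target_size, frac_reassigned = 0.10,
                            seed = NULL) {
  stopifnot(frac_reassigned >= 0, frac_reassigned <= 1)
  coords <- as_coord_matrix(coords)
  if (!is.null(seed)) set.seed(seed)
  part <- partition_compact(coords, target_size)
  labels <- part$labels
  P <- part$P
  if (P > 1L && frac_reassigned > 0) {
    for (b in seq_len(P)) {
      members <- which(labels == b)
      k <- floor(frac_reassigned * length(members))
      if (k >= 1L) {
        move <- members[sample.int(length(members), k)]
        others <- (seq_len(P))[-b]
        labels[move] <- others[sample.int(length(others), k, replace = TRUE)]
      }
    }
    # reassignment must not empty a block
    for (b in which(tabulate(labels, P) == 0L)) {
      donor <- which.max(tabulate(labels, P))
      pick <- which(labels == donor)
      labels[pick[sample.int(length(pick), 1L)]] <- b
    }
  }
  new_partition_index(labels, P, "mixed", target_size)
}

# dispatcher used by the fitting function
make_partition <- function(method, coords, target_size,
                           frac_reassigned = 0.10, seed = NULL) {
  switch(method,
    random = partition_random(coords, target_size, seed),
    compact = partition_compact(coords, target_size, seed),
    mixed = partition_mixed(coords, target_size, frac_reassigned, seed),
    stop("unknown partition method: ", method))
}
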