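# small reusable fixtures, built in code

toy_dataset <- function(n = 80, seed = 11, beta = c(1, 1, 1)) {
  set.seed(seed)
  coords <- cbind(runif(n), runif(n))
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  y <- beta[1] + beta[2] * x1 + beta[3] * x2 + rnorm(n)
  data.frame(xcoord = coords[, 1], ycoord = coords[, 2],
             x1 = x1, x2 = x2, y = y)
}

single_block <- function(n) {
  new_part <- getFromNamespace("new_partition_index", "partkrig")
  new_part(rep(1L, n), 1L, "compact", n)
}

manual_partition <- function(labels, target_size = 50, method = "compact") {
  new_part <- getFromNamespace("new_partition_index", "partkrig")
  new_part(labels, max(labels), method, target_size)
}
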