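# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Upper-triangle index pairs (i < j), column-major order; deterministic.
.upperTri <- function(n) {
  idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

.maxEdges <- function(n) n * (n - 1) / 2

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Largest component size among supra-threshold edges via union-find.
# ei, ej: integer endpoint vectors; weight: per-edge contribution
# (1 for the extent statistic, |t| - t_crit for intensity).
.maxComponent <- function(ei, ej, weight = NULL) {
  m <- length(ei)
  if (m == 0L) return(0)
  if (is.null(weight)) weight <- rep(1, m)
  parent <- seq_len(max(c(ei, ej)))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(m)) {
    ri <- find(ei[k]); rj <- find(ej[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(ei, find, integer(1))
  max(vapply(split(weight, roots), sum, numeric(1)))
}

# Pooled two-sample t statistics for every column of Y, given a logical
# group-1 indicator. Zero-variance columns yield NA.
.colTStats <- function(Y, z) {
  n1 <- sum(z); n2 <- sum(!z); n <- n1 + n2
  S  <- colSums(Y);  S2  <- colSums(Y * Y)
  S1 <- colSums(Y[z, , drop = FALSE])
  S21 <- colSums(Y[z, , drop = FALSE]^2)
  m1 <- S1 / n1; m2 <- (S - S1) / n2
  ss1 <- S21 - n1 * m1 * m1
  ss2 <- (S2 - S21) - n2 * m2 * m2
  sp2 <- (ss1 + ss2) / (n - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  # zero pooled variance: infinite separation when the means differ,
  # no information when they coincide
  bad <- !is.finite(t)
  md <- m1 - m2
  t[bad & md != 0] <- sign(md[bad & md != 0]) * Inf
  t[bad & md == 0] <- NA_real_
  t
}
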