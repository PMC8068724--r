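# Independent brute-force implementations used as oracles.  These share
# no code with the package: distances by Floyd-Warshall, betweenness by
# explicit simple-path enumeration, clustering by triangle counting,
# modularity by direct formula and exhaustive partition search.

o_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

o_global_eff <- function(A) {
  D <- o_dist(A); n <- nrow(A)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
  s / (n * (n - 1))
}

o_nodal_eff <- function(A) {
  D <- o_dist(A); n <- nrow(A)
  sapply(seq_len(n), function(i) {
    v <- D[i, -i]
    sum(1 / v[is.finite(v) & v > 0]) / (n - 1)
  })
}

o_char_path <- function(A) {
  D <- o_dist(A)
  v <- D[upper.tri(D)]
  v <- v[is.finite(v) & v > 0]
  mean(v)
}

o_clustering_mean <- function(A) {
  n <- nrow(A)
  cc <- sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  })
  mean(cc)
}

# local efficiency: global efficiency of each neighborhood subgraph
o_local_eff <- function(A) {
  n <- nrow(A)
  mean(sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    o_global_eff(A[nb, nb, drop = FALSE])
  }))
}

# all simple paths i -> j as list of vertex sequences (small n only)
.o_paths <- function(A, from, to) {
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == to) { out[[length(out) + 1L]] <<- path; return() }
    for (nxt in which(A[last, ] > 0))
      if (!nxt %in% path) walk(c(path, nxt))
  }
  walk(from)
  out
}

o_betweenness <- function(A) {
  n <- nrow(A)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- .o_paths(A, s, t)
    if (length(paths) == 0L) next
    lens <- sapply(paths, length)
    short <- paths[lens == min(lens)]
    np <- length(short)
    for (p in short) {
      inner <- p[-c(1, length(p))]
      bc[inner] <- bc[inner] + 1 / np
    }
  }
  bc
}

o_modularity_Q <- function(A, mem) {
  m2 <- sum(A)                      # 2m
  if (m2 == 0) return(NA_real_)
  Q <- 0
  for (c in unique(mem)) {
    idx <- mem == c
    ecc <- sum(A[idx, idx]) / m2
    ac <- sum(A[idx, ]) / m2
    Q <- Q + ecc - ac^2
  }
  Q
}

# every set partition of n elements (restricted growth strings)
o_all_partitions <- function(n) {
  out <- list()
  rec <- function(s, mx) {
    if (length(s) == n) { out[[length(out) + 1L]] <<- s; return() }
    for (v in seq_len(mx + 1)) rec(c(s, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

o_best_partition <- function(A) {
  parts <- o_all_partitions(nrow(A))
  qs <- sapply(parts, function(p) o_modularity_Q(A, p))
  list(membership = parts[[which.max(qs)]], Q = max(qs))
}

o_phi <- function(A, k) {
  deg <- rowSums(A)
  qual <- which(deg > k)
  if (length(qual) < 2) return(NA_real_)
  sum(A[qual, qual]) / 2 / (length(qual) * (length(qual) - 1) / 2)
}
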