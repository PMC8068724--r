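# Fixtures built in code.

# random connected-ish Erdos-Renyi adjacency (0/1 symmetric, zero diag)
rAdj <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  A + t(A)
}

mat2bg <- function(A, ids = NULL) {
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(A)))
  g <- sparsityBinarize(
    ConnectomeMatrix(A * 1, nodeIds = ids), sum(A) / 2 / (nrow(A) *
                                                            (nrow(A) - 1) / 2))
  g
}

# direct construction of a BinaryGraph from an adjacency without
# round-tripping through the thresholder
adj2bg <- function(A, ids = NULL) {
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(A)))
  methods::new("BinaryGraph", adjacency = A * 1,
               sparsity = sum(A) / 2 / (nrow(A) * (nrow(A) - 1) / 2),
               nodeIds = as.character(ids), sourceSubject = "fixture")
}

rWeighted <- function(n, density = 0.5) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  w <- ifelse(runif(sum(ut)) < density, rlnorm(sum(ut), 2, 1), 0)
  W[ut] <- w
  W <- W + t(W)
  ConnectomeMatrix(W)
}

pathGraph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

completeGraph <- function(n) {
  A <- matrix(1, n, n); diag(A) <- 0; A
}

starGraph <- function(nLeaves) {
  A <- matrix(0, nLeaves + 1, nLeaves + 1)
  A[1, -1] <- A[-1, 1] <- 1
  A
}

twoCliques <- function(k) {
  A <- matrix(0, 2 * k, 2 * k)
  A[1:k, 1:k] <- 1
  A[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1
  diag(A) <- 0
  A
}
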