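## Independent brute-force oracles used to validate the implementation.
## These deliberately share no code with the package: plain dynamic
## programming, ECDF scans and the raw step-up formula.

.oracleBlosum <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

## Needleman-Wunsch, affine gaps (gap of length L costs open + L * ext),
## end gaps penalized.  Returns the optimal raw score.
oracleGlobalScore <- function(a, b, open = 11, ext = 1) {
  S <- .oracleBlosum()
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (A consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (B consumed)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- S[A[i], B[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## Smith-Waterman, affine gaps; returns the optimal raw local score (>= 0).
oracleLocalScore <- function(a, b, open = 11, ext = 1) {
  S <- .oracleBlosum()
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      H[i + 1, j + 1] <- max(0, S[A[i], B[j]] +
                               max(H[i, j], X[i, j], Y[i, j]))
      best <- max(best, H[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best
}

## Exact two-sample KS statistic by scanning the pooled points.
oracleKsD <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
}

## Direct Benjamini-Hochberg step-up evaluation.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (r in seq_len(m)) {
    i <- o[r]
    q[i] <- min(vapply(r:m, function(j) p[o[j]] * m / j, 0), 1)
  }
  q
}

## Dense-matrix MCL iteration (independent of the package's sparse code);
## returns the attractor-based partition as a list of sorted member sets.
oracleMcl <- function(nodes, edges, inflation = 2, iter = 200) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    A[edges$a[k], edges$b[k]] <- edges$weight[k]
    A[edges$b[k], edges$a[k]] <- edges$weight[k]
  }
  diag(A) <- pmax(apply(A, 1, max), 1e-12)
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(iter)) {
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
    M[M < 1e-12] <- 0
    M <- sweep(M, 2, colSums(M), "/")
  }
  attr_of <- apply(M, 2, which.max)
  unname(lapply(split(nodes, nodes[attr_of]), sort))
}

## Random amino-acid sequence for oracle comparisons.
oracleRandSeq <- function(len) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}
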