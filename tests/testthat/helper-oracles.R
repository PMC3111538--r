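# Independent brute-force oracles used across the suite. These deliberately
# use explicit matrix inversion via solve() and path-walking on the edge
# matrix, i.e. none of the package's factorized code paths.

# BM covariance by explicit root-to-MRCA path sums
oracle_bm_cov <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_of <- integer(ntip + tree$Nnode)
  elen_of <- numeric(ntip + tree$Nnode)
  for (r in seq_len(nrow(tree$edge))) {
    parent_of[tree$edge[r, 2L]] <- tree$edge[r, 1L]
    elen_of[tree$edge[r, 2L]] <- tree$edge.length[r]
  }
  path_to_root <- function(node) {
    path <- integer(0)
    while (node != root) {
      path <- c(path, node)
      node <- parent_of[node]
    }
    path
  }
  V <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(ntip), path_to_root)
  for (i in seq_len(ntip)) {
    for (j in seq_len(ntip)) {
      shared <- intersect(paths[[i]], paths[[j]])
      V[i, j] <- sum(elen_of[shared])
    }
  }
  V
}

# K and its four ingredient formulas via explicit solve()
oracle_blomberg_k <- function(y, V) {
  n <- length(y)
  Vi <- solve(V)
  one <- rep(1, n)
  a <- drop(t(one) %*% Vi %*% y) / drop(t(one) %*% Vi %*% one)
  e <- y - a
  mse0 <- sum(e^2) / (n - 1)
  mse <- drop(t(e) %*% Vi %*% e) / (n - 1)
  er <- (sum(diag(V)) - n / drop(t(one) %*% Vi %*% one)) / (n - 1)
  list(K = (mse0 / mse) / er, mse0 = mse0, mse = mse, expected_ratio = er)
}

# GLS estimates and ML log-likelihood via explicit normal equations
oracle_gls <- function(y, X, V) {
  n <- length(y)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  e <- y - X %*% beta
  q <- drop(t(e) %*% Vi %*% e)
  s2 <- q / n
  lnL <- -(n / 2) * (log(2 * pi) + log(s2) + 1) -
    0.5 * determinant(V, logarithm = TRUE)$modulus
  list(beta = drop(beta), lnL = as.numeric(lnL), sigma2_ml = s2)
}

# slope of the regression through the origin on independent contrasts
oracle_pic_slope <- function(tree, x, y) {
  px <- ape::pic(x[tree$tip.label], tree)
  py <- ape::pic(y[tree$tip.label], tree)
  sum(px * py) / sum(px * px)
}

# small deterministic fixture: 4-tip balanced tree with unit lengths
fixture_tree4 <- function() {
  phyloregress::parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
}

# random binary tree with random lengths, reproducible
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 2)
  tr
}
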