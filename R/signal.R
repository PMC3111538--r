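# Internal core shared by blomberg_k / signal_test. Works from a Cholesky
# factor so the covariance is factored once per call even across thousands
# of permutations.
signal_core <- function(y, V) {
  n <- length(y)
  if (n < 3L) stop("phylogenetic signal needs at least 3 tips")
  if (stats::var(y) == 0)
    stop("trait is constant across tips; phylogenetic signal is undefined")
  R <- chol_psd(V)
  one <- rep(1, n)
  w1 <- backsolve(R, one, transpose = TRUE)   # R^-T 1
  sum_vinv <- sum(w1^2)                       # 1' V^-1 1
  trV <- sum(diag(V))
  expected_ratio <- (trV - n / sum_vinv) / (n - 1)

  mse_pair <- function(yy) {
    wy <- backsolve(R, yy, transpose = TRUE)
    a <- sum(w1 * wy) / sum_vinv               # GLS phylogenetic mean
    e <- yy - a
    mse0 <- sum(e * e) / (n - 1)
    we <- wy - a * w1
    mse <- sum(we * we) / (n - 1)              # e' V^-1 e / (n - 1)
    c(mse0 = mse0, mse = mse)
  }
  list(n = n, R = R, expected_ratio = expected_ratio, mse_pair = mse_pair)
}

new_signal_result <- function(K, mse0, mse, expected_ratio,
                              p_value = NA_real_, n_perm = 0L) {
  structure(list(K = K, mse0 = mse0, mse = mse,
                 expected_ratio = expected_ratio,
                 p_value = p_value, n_perm = n_perm),
            class = "signal_result")
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' Measures how strongly related species resemble each other relative to
#' the Brownian-motion expectation on a given tree. With `V` the tree's BM
#' covariance, the GLS phylogenetic mean is
#' `a = (1'V^-1 1)^-1 1'V^-1 y`; the observed ratio of the identity-metric
#' mean squared error `mse0 = (y-a)'(y-a)/(n-1)` to the GLS-metric
#' `mse = (y-a)'V^-1(y-a)/(n-1)` is scaled by its Brownian-motion
#' expectation `(tr(V) - n/(1'V^-1 1))/(n-1)`, giving
#' `K = (mse0/mse) / expected_ratio`. K near 0 indicates no signal, K = 1
#' matches the Brownian-motion expectation, and K > 1 means relatives are
#' more similar than Brownian motion predicts. On a star phylogeny K is
#' identically 1 for any non-constant trait.
#'
#' @param y Named numeric trait vector, or an `"aligned_dataset"` with an
#'   intercept-only design (its response is used).
#' @param V Tip covariance matrix aligned to `y` (taken from the dataset if
#'   `y` is an `"aligned_dataset"`).
#' @return A `"signal_result"` with elements `K`, `mse0`, `mse`,
#'   `expected_ratio` (and `p_value = NA` until [signal_test()] is run).
#' @references Blomberg, Garland & Ives (2003) Evolution 57:717-745.
#' @export
blomberg_k <- function(y, V = NULL) {
  if (inherits(y, "aligned_dataset")) {
    if (is.null(V)) V <- y$V
    y <- y$y
  }
  if (is.null(V)) stop("'V' is required when 'y' is a plain vector")
  if (!is.null(names(y)) && !is.null(colnames(V))) {
    if (!all(names(y) %in% colnames(V))) stop("tip names of 'y' not all in 'V'")
    V <- V[names(y), names(y), drop = FALSE]
  }
  core <- signal_core(y, V)
  m <- core$mse_pair(y)
  K <- (m["mse0"] / m["mse"]) / core$expected_ratio
  new_signal_result(unname(K), unname(m["mse0"]), unname(m["mse"]),
                    core$expected_ratio)
}

#' Randomization test of phylogenetic signal
#'
#' Tests for phylogenetic signal by permuting trait values across the tips:
#' each permutation destroys any trait-tree association while preserving
#' the trait's multiset of values, and the GLS-metric mean squared error is
#' recomputed. Observed MSE smaller than expected under permutation means
#' relatives are more similar than chance — the one-sided alternative. The
#' p-value uses the add-one convention
#' `p = (1 + #\{mse_perm <= mse_obs\}) / (n_perm + 1)`, so its smallest
#' attainable value is `1/(n_perm + 1)` (999 permutations resolve
#' p = 0.001).
#'
#' @inheritParams blomberg_k
#' @param n_perm Number of permutations (default 999; at least 99).
#' @param seed Optional integer seed for the permutations.
#' @return A `"signal_result"` with `K` and the permutation `p_value`.
#' @export
signal_test <- function(y, V = NULL, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("'n_perm' must be at least 99")
  if (inherits(y, "aligned_dataset")) {
    if (is.null(V)) V <- y$V
    y <- y$y
  }
  if (is.null(V)) stop("'V' is required when 'y' is a plain vector")
  if (!is.null(names(y)) && !is.null(colnames(V)))
    V <- V[names(y), names(y), drop = FALSE]
  core <- signal_core(y, V)
  m <- core$mse_pair(y)
  K <- unname((m["mse0"] / m["mse"]) / core$expected_ratio)
  if (!is.null(seed)) set.seed(seed)
  yv <- as.numeric(y)
  count <- 0L
  for (i in seq_len(n_perm)) {
    mp <- core$mse_pair(yv[sample.int(core$n)])
    if (mp["mse"] <= m["mse"]) count <- count + 1L
  }
  p <- (1 + count) / (n_perm + 1)
  new_signal_result(K, unname(m["mse0"]), unname(m["mse"]),
                    core$expected_ratio, p_value = p, n_perm = as.integer(n_perm))
}

#' Phylogenetic signal in regression residuals
#'
#' The model-choice diagnostic for phylogenetic versus nonphylogenetic
#' regression: signal in a model's residuals is evidence that the response
#' did not evolve so fast as to erase phylogenetic structure, so a
#' phylogenetic model is warranted. Uses the *response-scale* residuals
#' `y - X beta_hat` (not GLS-whitened residuals, in which signal is removed
#' by construction) against the Brownian-motion covariance of the supplied
#' tree.
#'
#' @param fit A `"gls_fit"` with tip-space residuals (any model).
#' @param tree The phylogeny on which to test (pruned to the residual tips
#'   if needed).
#' @param n_perm,seed Passed to [signal_test()].
#' @return A `"signal_result"`.
#' @export
residual_signal <- function(fit, tree, n_perm = 999, seed = NULL) {
  stopifnot(inherits(fit, "gls_fit"))
  e <- fit$residuals
  if (is.null(names(e))) stop("fit carries unnamed residuals")
  if (!all(names(e) %in% tree$tip.label))
    stop("residual tips not all present in tree")
  if (length(setdiff(tree$tip.label, names(e))))
    tree <- ape::keep.tip(tree, names(e))
  V <- bm_covariance(tree)
  signal_test(e[colnames(V)], V, n_perm = n_perm, seed = seed)
}

#' @export
print.signal_result <- function(x, digits = 3, ...) {
  cat("Phylogenetic signal (Blomberg's K, MSE randomization)\n")
  cat("  K =", format(x$K, digits = digits))
  if (!is.na(x$p_value))
    cat(",  P = ", format(x$p_value, digits = digits),
        " (", x$n_perm, " permutations, one-sided)", sep = "")
  cat("\n  observed MSE0/MSE =", format(x$mse0 / x$mse, digits = digits),
      "; BM expectation =", format(x$expected_ratio, digits = digits), "\n")
  invisible(x)
}
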