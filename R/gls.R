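# Shared GLS engine. All solves go through one Cholesky factor of V; the
# whitened design is handled by QR. Explicit matrix inverses appear only in
# the test oracles.
gls_engine <- function(y, X, V, model) {
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need n > p (got n = ", n, ", p = ", p, ")")
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n)
    stop("dimension mismatch between y, X and V")
  sym_err <- max(abs(V - t(V)))
  if (sym_err > 1e-10 * max(mean(diag(V)), 1))
    stop("covariance matrix is not symmetric (max asymmetry ", format(sym_err), ")")
  V <- (V + t(V)) / 2
  R <- chol_psd(V)
  logdetV <- 2 * sum(log(diag(R)))

  ty <- backsolve(R, y, transpose = TRUE)
  tX <- backsolve(R, X, transpose = TRUE)
  colnames(tX) <- colnames(X)
  qrX <- qr(tX)
  if (qrX$rank < p) stop("design matrix is singular in the GLS metric")
  beta <- qr.coef(qrX, ty)
  names(beta) <- colnames(X)
  resid_w <- ty - tX %*% beta
  q <- sum(resid_w^2)                       # e' V^-1 e
  e <- drop(y - X %*% beta)
  names(e) <- if (!is.null(rownames(X))) rownames(X) else names(y)
  e_w <- drop(resid_w)          # GLS-whitened residuals, iid under the model
  names(e_w) <- names(e)

  sigma2_ml <- q / n
  sigma2_unb <- q / (n - p)
  lnL <- -(n / 2) * (log(2 * pi) + log(sigma2_ml) + 1) - logdetV / 2

  XtVX_inv <- chol2inv(qr.R(qrX))           # (X' V^-1 X)^-1 (qr not pivoted: p small, full rank)
  se <- sqrt(sigma2_unb * diag(XtVX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  coef_table <- data.frame(estimate = beta, se = se, t = tval, p = pval,
                           row.names = colnames(X))

  # GLS-metric r^2 against the intercept-only (phylogenetic-mean) model
  r2 <- NA_real_
  if (p > 1L) {
    t1 <- backsolve(R, rep(1, n), transpose = TRUE)
    a <- sum(t1 * ty) / sum(t1^2)
    q0 <- sum((ty - a * t1)^2)
    r2 <- if (q0 > 0) 1 - q / q0 else NA_real_
  }

  slope_row <- if (p > 1L) 2L else NA_integer_
  structure(list(
    model = model, beta = beta, se = se, coef_table = coef_table,
    t = if (p > 1L) unname(tval[slope_row]) else NA_real_,
    p_regression = if (p > 1L) unname(pval[slope_row]) else NA_real_,
    r2 = r2, lnL_ML = lnL, sigma2_ml = sigma2_ml, sigma2 = sigma2_unb,
    residuals = e, residuals_whitened = e_w,
    fitted = drop(X %*% beta), n = n, p = p,
    logdetV = logdetV, d_hat = NA_real_),
    class = "gls_fit")
}

#' Generalized least-squares regression with a given tip covariance
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma^2 V)` by GLS:
#' `beta_hat = (X'V^-1 X)^-1 X'V^-1 y`. The reported log-likelihood is the
#' ML profile likelihood
#' `lnL = -(n/2)[ln(2 pi) + ln(sigma2_ML) + 1] - ln|V|/2` with
#' `sigma2_ML = e'V^-1 e / n`, so likelihoods are directly comparable across
#' OLS, PGLS and RegOU fits of the same data. Coefficient standard errors
#' use the unbiased `e'V^-1 e/(n-p)`; slope inference uses the t
#' distribution with `n - p` degrees of freedom. `r2` is the GLS-metric
#' proportion of variance relative to the phylogenetic-mean model; r-squared
#' values are not directly comparable across different covariance models.
#'
#' @param dataset An `"aligned_dataset"` (see [align()]).
#' @param V Tip covariance; defaults to the dataset's own `V`.
#' @param model Label stored on the fit (`"PGLS"` by default).
#' @return A `"gls_fit"`: coefficients and tests, `r2`, `lnL_ML`,
#'   `sigma2`, tip-space `residuals`, and dimensions.
#' @export
fit_gls <- function(dataset, V = NULL, model = "PGLS") {
  stopifnot(inherits(dataset, "aligned_dataset"))
  if (is.null(V)) V <- dataset$V
  if (!is.null(colnames(V)) && !identical(colnames(V), dataset$tips)) {
    if (!all(dataset$tips %in% colnames(V)))
      stop("covariance tips do not cover the dataset")
    V <- V[dataset$tips, dataset$tips, drop = FALSE]
  }
  gls_engine(dataset$y, dataset$X, V, model)
}

#' Ordinary least squares as a star-phylogeny GLS
#'
#' Identical arithmetic to [fit_gls()] with `V` the identity matrix: the
#' covariance structure of a star phylogeny with unit depth. Its `lnL_ML`
#' shares the constant convention of every other fit in the package, which
#' is what makes cross-model likelihood columns meaningful.
#'
#' @param dataset An `"aligned_dataset"`.
#' @return A `"gls_fit"` with `model = "OLS"`.
#' @export
fit_ols <- function(dataset) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  I <- diag(dataset$n)
  dimnames(I) <- list(dataset$tips, dataset$tips)
  gls_engine(dataset$y, dataset$X, I, "OLS")
}

#' Phylogenetic GLS under Brownian motion
#'
#' GLS with `V` the Brownian-motion covariance of the tree; numerically
#' equivalent to regression through the origin on phylogenetically
#' independent contrasts.
#'
#' @param dataset An `"aligned_dataset"`.
#' @param tree Optional tree; defaults to the dataset's pruned tree.
#' @return A `"gls_fit"` with `model = "PGLS"`.
#' @export
fit_pgls <- function(dataset, tree = NULL) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  V <- if (is.null(tree)) {
    if (identical(dataset$cov_model, "bm")) dataset$V
    else bm_covariance(dataset$tree)
  } else bm_covariance(ape::keep.tip(tree, dataset$tips))
  fit_gls(dataset, V, model = "PGLS")
}

# negative restricted log-likelihood profile in d (up to the constant term,
# which is included so reported REML values are absolute)
neg_remll <- function(d, y, X, S) {
  V <- ou_transform(S, d)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  n <- length(y); p <- ncol(X)
  ty <- backsolve(R, y, transpose = TRUE)
  tX <- backsolve(R, X, transpose = TRUE)
  qrX <- qr(tX)
  if (qrX$rank < p) return(1e10)
  q <- sum(qr.resid(qrX, ty)^2)
  s2r <- q / (n - p)
  logdetV <- 2 * sum(log(diag(R)))
  logdetX <- 2 * sum(log(abs(diag(qr.R(qrX)))))
  0.5 * ((n - p) * log(s2r) + logdetV + logdetX + (n - p) * (1 + log(2 * pi)))
}

neg_mll <- function(d, y, X, S) {
  V <- ou_transform(S, d)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  n <- length(y)
  ty <- backsolve(R, y, transpose = TRUE)
  tX <- backsolve(R, X, transpose = TRUE)
  qrX <- qr(tX)
  if (qrX$rank < ncol(X)) return(1e10)
  q <- sum(qr.resid(qrX, ty)^2)
  (n / 2) * (log(2 * pi) + log(q / n) + 1) + sum(log(diag(R)))
}

#' Regression with Ornstein-Uhlenbeck residual covariance (RegOU)
#'
#' Fits the GLS regression whose residual covariance is the one-parameter
#' OU family `V(d)` of [ou_covariance()]: `d = 1` is Brownian motion (PGLS),
#' `d = 0` the star phylogeny (OLS), `d > 1` stronger-than-BM similarity.
#' By default `d` is estimated by REML — maximizing
#' `lnL_R(d) = -1/2[(n-p) ln sigma2_R(d) + ln|V(d)| + ln|X'V(d)^-1 X| +
#' (n-p)(1 + ln 2 pi)]` — by bounded scalar search (tolerance 1e-6) from
#' three starts (0.01, 1, 3, clipped to `d_bounds`), ties resolved toward
#' smaller `d`. The reported `lnL_ML` is the *ML* log-likelihood evaluated
#' at `d_hat`, so it is comparable with [fit_ols()] and [fit_pgls()];
#' coefficient inference conditions on `d_hat`. Estimates landing on a
#' bound of `d_bounds` are flagged via `boundary`.
#'
#' @param dataset An `"aligned_dataset"`.
#' @param tree Optional tree; defaults to the dataset's pruned tree.
#' @param d_bounds Search interval for `d` (default `c(0, 5)`). Setting both
#'   ends equal forces that value of `d` (e.g. `c(0, 0)` gives the OLS
#'   structure with RegOU bookkeeping).
#' @param reml If `FALSE`, estimate `d` by ML instead of REML.
#' @return A `"gls_fit"` with `model = "RegOU"`, plus `d_hat`, `lnL_REML`
#'   (when `reml = TRUE`) and `boundary`.
#' @export
fit_regou <- function(dataset, tree = NULL, d_bounds = c(0, 5), reml = TRUE) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  if (length(d_bounds) != 2L || any(d_bounds < 0) || d_bounds[1] > d_bounds[2])
    stop("'d_bounds' must be an ordered non-negative interval")
  tr <- if (is.null(tree)) dataset$tree else ape::keep.tip(tree, dataset$tips)
  S <- bm_covariance(tr)[dataset$tips, dataset$tips, drop = FALSE]
  y <- dataset$y; X <- dataset$X

  obj <- if (reml) function(d) neg_remll(d, y, X, S)
         else function(d) neg_mll(d, y, X, S)

  if (d_bounds[1] == d_bounds[2]) {
    d_hat <- d_bounds[1]
    obj_val <- obj(d_hat)
    conv <- TRUE
  } else {
    starts <- pmin(pmax(c(0.01, 1, 3), d_bounds[1]), d_bounds[2])
    best <- NULL
    conv <- FALSE
    for (st in unique(starts)) {
      o <- tryCatch(
        stats::optim(st, obj, method = "L-BFGS-B",
                     lower = d_bounds[1], upper = d_bounds[2],
                     control = list(factr = 1e7, pgtol = 1e-6)),
        error = function(e) NULL)
      if (is.null(o)) next
      conv <- conv || o$convergence == 0
      if (is.null(best) || o$value < best$value - 1e-8 ||
          (abs(o$value - best$value) <= 1e-8 && o$par < best$par)) best <- o
    }
    if (is.null(best)) stop("RegOU optimizer failed from every start")
    if (!conv) stop("RegOU optimizer did not converge from any start")
    d_hat <- best$par
    obj_val <- best$value
  }

  fit <- gls_engine(y, X, ou_transform(S, d_hat), "RegOU")
  fit$d_hat <- d_hat
  if (reml) fit$lnL_REML <- -obj_val
  fit$boundary <- d_bounds[1] != d_bounds[2] &&
    (d_hat <= d_bounds[1] + 1e-6 || d_hat >= d_bounds[2] - 1e-6)
  fit
}

#' Phylogenetic ANCOVA (GLS with a two-level group term)
#'
#' Fits `y = intercept + x + group (+ x:group)` by GLS, the phylogenetic
#' equivalent of ANCOVA, used e.g. to test threshold effects by splitting
#' species into low/high classes of a covariate. Alongside the fit it
#' returns a balance report: per-group counts, with an imbalance warning
#' when the smaller group has fewer than 5 members — highly unbalanced
#' designs do not support confident ANCOVA inference, phylogenetic or not.
#' A group with fewer than 2 members makes the fit unidentifiable; the
#' function then refuses to fit and returns the counts only.
#'
#' @param dataset An `"aligned_dataset"` built with a `group` column (see
#'   [align()]); the group must have exactly 2 levels.
#' @param V Tip covariance (defaults to the dataset's).
#' @param interaction Include the `x:group` interaction term?
#' @return A list of class `"ancova_fit"`: `fit` (a `"gls_fit"`, or `NULL`
#'   if refused), `balance` (counts, imbalance flag, message), and
#'   `group_test` (the group coefficient row of the coefficient table).
#' @export
ancova_fit <- function(dataset, V = NULL, interaction = FALSE) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  if (is.null(dataset$group)) stop("dataset has no group column; see align(group=)")
  g <- droplevels(dataset$group)
  if (nlevels(g) != 2L) stop("ANCOVA requires exactly 2 groups, got ", nlevels(g))
  counts <- table(g)
  balance <- list(counts = counts,
                  imbalanced = min(counts) < 5L,
                  message = NULL)
  if (balance$imbalanced)
    balance$message <- paste0("unbalanced design: group sizes ",
                              paste(counts, collapse = "/"),
                              "; ANCOVA inference is unreliable")
  if (min(counts) < 2L) {
    warning("group '", names(counts)[which.min(counts)],
            "' has fewer than 2 members; refusing to fit, reporting counts only")
    return(structure(list(fit = NULL, balance = balance, group_test = NULL),
                     class = "ancova_fit"))
  }
  if (balance$imbalanced) warning(balance$message)
  ind <- as.numeric(g == levels(g)[2L])
  gname <- paste0("group", levels(g)[2L])
  X <- cbind(dataset$X, ind)
  colnames(X) <- c(colnames(dataset$X), gname)
  if (interaction) {
    if (ncol(dataset$X) < 2L) stop("interaction requires a covariate")
    xname <- colnames(dataset$X)[2L]
    X <- cbind(X, dataset$X[, 2L] * ind)
    colnames(X)[ncol(X)] <- paste0(xname, ":", gname)
  }
  if (is.null(V)) V <- dataset$V
  fit <- gls_engine(dataset$y, X, V, "ANCOVA")
  structure(list(fit = fit, balance = balance,
                 group_test = fit$coef_table[gname, ]),
            class = "ancova_fit")
}

#' @export
print.gls_fit <- function(x, digits = 4, ...) {
  cat(x$model, "regression fit: n =", x$n, ", p =", x$p, "\n")
  print(round(x$coef_table, digits))
  cat("r2 =", format(x$r2, digits = digits),
      " (GLS metric; not comparable across covariance models)\n")
  cat("lnL (ML) =", format(x$lnL_ML, digits = digits + 2))
  if (!is.na(x$d_hat)) {
    cat(",  d_hat =", format(x$d_hat, digits = digits))
    if (isTRUE(x$boundary)) cat(" [at search bound]")
  }
  cat("\n")
  invisible(x)
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat("Phylogenetic ANCOVA\n")
  cat("  group sizes:", paste(names(x$balance$counts), x$balance$counts,
                              sep = "=", collapse = ", "), "\n")
  if (!is.null(x$balance$message)) cat("  WARNING:", x$balance$message, "\n")
  if (is.null(x$fit)) {
    cat("  fit refused (a group has < 2 members)\n")
  } else {
    print(x$fit, ...)
  }
  invisible(x)
}
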