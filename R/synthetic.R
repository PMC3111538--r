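#' Balanced tree with unit branch lengths
#'
#' Fully balanced bifurcating tree (tip count a power of 2) with every
#' branch length 1 — the workhorse tree for calibration simulations, where
#' its depth of `log2(n)` gives strong, well-identified phylogenetic
#' structure.
#'
#' @param n_tips Number of tips, a power of 2.
#' @param branch_length Common branch length (default 1).
#' @return A `"phylo"` object with tips `t1 ... tn`.
#' @export
balanced_tree <- function(n_tips, branch_length = 1) {
  if (n_tips < 2 || bitwAnd(n_tips, n_tips - 1L) != 0L)
    stop("'n_tips' must be a power of 2, >= 2")
  tr <- ape::stree(n_tips, "balanced")
  tr$edge.length <- rep(branch_length, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

#' Random pure-birth (Yule) tree rescaled to unit depth
#'
#' Simulates a pure-birth tree and rescales its total depth to 1 so the OU
#' transformation parameter `d` is comparable across replicate trees.
#'
#' @param n_tips Number of tips.
#' @param seed Optional integer seed.
#' @param depth Total root-to-tip depth after rescaling (default 1).
#' @return An ultrametric `"phylo"` object.
#' @export
pure_birth_tree <- function(n_tips, seed = NULL, depth = 1) {
  if (n_tips < 3) stop("'n_tips' must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length * depth /
    max(ape::node.depth.edgelength(tr))
  tr
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Draws replicate traits from the multivariate normal distribution with
#' mean 0 (the root state, absorbed downstream by regression intercepts) and
#' covariance `sigma2 * bm_covariance(tree)`, via a Cholesky factor of the
#' tree covariance.
#'
#' @param tree A fully lengthed `"phylo"` object.
#' @param sigma2 Brownian-motion rate (variance per unit branch length),
#'   `>= 0`; 0 gives identical tip values equal to the root state.
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @param n_reps Number of independent replicate traits.
#' @return An `n_reps` x `n_tips` matrix, columns named by tip label.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, seed = NULL, n_reps = 1) {
  if (!is.numeric(sigma2) || sigma2 < 0) stop("'sigma2' must be >= 0")
  V <- bm_covariance(tree)
  n <- nrow(V)
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(stats::rnorm(n_reps * n), n_reps, n)
  out <- if (sigma2 == 0) matrix(0, n_reps, n) else {
    R <- chol_psd(V)
    sqrt(sigma2) * Z %*% R
  }
  colnames(out) <- colnames(V)
  out
}

#' Simulation configuration for regression datasets
#'
#' Bundles the ingredients of a synthetic comparative regression study:
#' tree, linear relationship, and phylogenetically autocorrelated residuals.
#' The defaults emulate the geometry of a comparative genome-size analysis
#' on the log10 scale: about 29 taxa, a steep negative slope, residual
#' standard deviation below the trait spread, and Brownian-motion residuals
#' (`residual_d = 1`).
#'
#' @param tree A `"phylo"` object, or `NULL` to draw a pure-birth tree of
#'   `n_tips` tips (depth rescaled to 1).
#' @param n_tips Tip count when `tree` is `NULL`.
#' @param slope,intercept True regression coefficients on the analysis scale.
#' @param sigma Residual standard deviation (> 0).
#' @param residual_d OU parameter of the residual covariance: 1 = Brownian
#'   motion, 0 = i.i.d. residuals (the star/OLS case).
#' @param x_mode How the predictor is generated: `"bm"` (Brownian motion on
#'   the tree, so the predictor itself carries phylogenetic signal, as
#'   comparative predictors typically do), `"uniform"`, or `"supplied"`.
#' @param x_values Predictor values when `x_mode = "supplied"` (named by tip
#'   or in tip order).
#' @param x_sigma2 BM rate for `x_mode = "bm"`; range is `x_range` for
#'   `"uniform"`.
#' @param x_range Length-2 numeric range for `x_mode = "uniform"`.
#' @param n_reps Number of replicate datasets.
#' @param seed Integer seed; all randomness in [simulate_regression_dataset()]
#'   derives from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(tree = NULL, n_tips = 29, slope = -1.17,
                       intercept = 0.4, sigma = 0.9, residual_d = 1,
                       x_mode = c("bm", "uniform", "supplied"),
                       x_values = NULL, x_sigma2 = 1, x_range = c(-3, -1),
                       n_reps = 1, seed = NULL) {
  x_mode <- match.arg(x_mode)
  if (!is.numeric(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  if (n_reps < 1) stop("'n_reps' must be >= 1")
  if (!is.null(tree)) validate_phylogeny(tree)
  if (x_mode == "supplied" && is.null(x_values))
    stop("x_mode 'supplied' requires 'x_values'")
  structure(list(tree = tree, n_tips = n_tips, slope = slope,
                 intercept = intercept, sigma = sigma,
                 residual_d = residual_d, x_mode = x_mode,
                 x_values = x_values, x_sigma2 = x_sigma2, x_range = x_range,
                 n_reps = n_reps, seed = seed),
            class = "sim_config")
}

#' Simulate regression datasets with phylogenetically correlated residuals
#'
#' Generates `y = a + b x + e` on a tree, with `e` multivariate normal with
#' covariance `sigma^2 * ou_covariance(tree, d)` (via a Cholesky factor),
#' and returns analysis-ready datasets together with the true parameters.
#' With `residual_d = 1` and `slope = 0` this is the null model under which
#' ordinary least squares is anti-conservative while PGLS is calibrated;
#' with `residual_d = 0` the residuals are i.i.d. and OLS is the correctly
#' specified model.
#'
#' @param config A [sim_config()] object.
#' @return If `n_reps == 1`, a list of class `"sim_dataset"` with elements
#'   `dataset` (an `"aligned_dataset"` whose `V` is the tree's BM
#'   covariance, i.e. what an analyst would use), `truth` (true parameters),
#'   `table` (species x trait data frame) and `tree`. If `n_reps > 1`, a
#'   list of such objects sharing one tree.
#' @export
simulate_regression_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tree <- config$tree
  if (is.null(tree)) tree <- pure_birth_tree(config$n_tips)
  S <- bm_covariance(tree)
  n <- nrow(S)
  tips <- colnames(S)
  Vd <- ou_transform(S, config$residual_d)
  Rd <- chol_psd(Vd)
  Rx <- if (config$x_mode == "bm") chol_psd(S) else NULL

  one <- function() {
    x <- switch(config$x_mode,
      bm = drop(crossprod(Rx, stats::rnorm(n))) * sqrt(config$x_sigma2),
      uniform = stats::runif(n, config$x_range[1], config$x_range[2]),
      supplied = {
        xv <- config$x_values
        if (!is.null(names(xv))) xv <- xv[tips]
        as.numeric(xv)
      })
    eps <- config$sigma * drop(crossprod(Rd, stats::rnorm(n)))
    y <- config$intercept + config$slope * x + eps
    table <- data.frame(species = tips, x = x, y = y,
                        stringsAsFactors = FALSE)
    ds <- align(tree, table, response = "y", predictors = "x",
                log10 = FALSE, cov_model = "bm")
    truth <- list(slope = config$slope, intercept = config$intercept,
                  sigma = config$sigma, residual_d = config$residual_d,
                  x_mode = config$x_mode, seed = config$seed)
    structure(list(dataset = ds, truth = truth, table = table, tree = tree),
              class = "sim_dataset")
  }
  if (config$n_reps == 1L) one() else replicate(config$n_reps, one(),
                                                simplify = FALSE)
}

#' Permute trait values across tips
#'
#' The null-generation primitive of the mean-squared-error randomization
#' test: values are shuffled across tips, so the multiset of values (and
#' hence mean and variance) is preserved exactly while any association with
#' the phylogeny is destroyed.
#'
#' @param trait Numeric vector (optionally named by tip).
#' @param seed Optional integer seed.
#' @return The permuted vector; names, if any, stay in their original order
#'   so the values move across tips.
#' @export
permute_tip_values <- function(trait, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- trait[sample.int(length(trait))]
  names(out) <- names(trait)
  out
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the CSV + Newick pair that [read_trait_table()] and
#' [parse_newick()] consume, plus a JSON record of the true parameters,
#' seed, and package version, so a simulation is reproducible from files
#' alone. Identical seeds give byte-identical outputs.
#'
#' @param sim A `"sim_dataset"` from [simulate_regression_dataset()], or a
#'   list of them (written to numbered subdirectories `rep001`, ...).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!inherits(sim, "sim_dataset")) {
    paths <- character()
    for (i in seq_along(sim)) {
      sub <- file.path(dir, sprintf("rep%03d", i))
      paths <- c(paths, write_simulation(sim[[i]], sub))
    }
    return(invisible(paths))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "traits.csv")
  nwk <- file.path(dir, "tree.nwk")
  tru <- file.path(dir, "truth.json")
  utils::write.csv(sim$table, csv, row.names = FALSE, quote = FALSE)
  writeLines(write_newick(sim$tree), nwk)
  rec <- c(sim$truth,
           list(package_version = as.character(utils::packageVersion("phyloregress")),
                n = nrow(sim$table)))
  jsonlite::write_json(rec, tru, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv, nwk, tru))
}
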