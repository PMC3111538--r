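make_dataset <- function(tree, x, y, group = NULL) {
  table <- data.frame(species = tree$tip.label, x = x, y = y,
                      stringsAsFactors = FALSE)
  if (!is.null(group)) table$grp <- group
  align(tree, table, response = "y", predictors = "x", log10 = FALSE,
        group = if (is.null(group)) NULL else "grp")
}

test_that("GLS estimates match the explicit normal-equations oracle", {
  tree <- fixture_tree4()
  ds <- make_dataset(tree, x = c(1, 2, 3, 5), y = c(2, 3, 9, 11))
  V <- bm_covariance(tree)
  fit <- fit_gls(ds, V)
  want <- oracle_gls(unname(ds$y), ds$X, V)
  expect_equal(unname(fit$beta), unname(want$beta), tolerance = 1e-10)
  expect_equal(fit$lnL_ML, want$lnL, tolerance = 1e-10)
  expect_equal(fit$sigma2_ml, want$sigma2_ml, tolerance = 1e-10)

  tr3 <- parse_newick("((A:1,B:1):1,C:2);")
  ds3 <- align(tr3, data.frame(species = c("A", "B", "C"),
                               x = c(1, 4, 2), y = c(3, 1, 5)),
               response = "y", predictors = "x", log10 = FALSE)
  w3 <- oracle_gls(unname(ds3$y), ds3$X, ds3$V)
  expect_equal(unname(fit_pgls(ds3)$beta), unname(w3$beta), tolerance = 1e-10)
  expect_equal(fit_pgls(ds3)$lnL_ML, w3$lnL, tolerance = 1e-10)
})

test_that("GLS with identity covariance is OLS, bit for bit and versus lm", {
  tree <- balanced_tree(16)
  set.seed(61)
  ds <- make_dataset(tree, x = rnorm(16), y = rnorm(16))
  I <- diag(16); dimnames(I) <- list(ds$tips, ds$tips)
  a <- fit_gls(ds, I)
  b <- fit_ols(ds)
  expect_identical(a$beta, b$beta)
  expect_identical(a$lnL_ML, b$lnL_ML)
  expect_identical(a$residuals, b$residuals)

  lmfit <- stats::lm(unname(ds$y) ~ unname(ds$X[, "x"]))
  expect_equal(unname(b$beta), unname(stats::coef(lmfit)), tolerance = 1e-10)
  sm <- summary(lmfit)
  expect_equal(unname(b$se), unname(sm$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(b$p_regression, sm$coefficients[2, 4], tolerance = 1e-10)
  expect_equal(b$r2, sm$r.squared, tolerance = 1e-10)
  expect_equal(b$lnL_ML, as.numeric(stats::logLik(lmfit)), tolerance = 1e-10)

  # PGLS on a unit-depth star tree is OLS exactly
  st <- star_tree(paste0("t", 1:16), depth = 1)
  ds_star <- make_dataset(st, x = unname(ds$X[, "x"]), y = unname(ds$y))
  expect_equal(unname(fit_pgls(ds_star)$beta), unname(b$beta),
               tolerance = 1e-12)
  expect_equal(fit_pgls(ds_star)$lnL_ML, b$lnL_ML, tolerance = 1e-12)
})

test_that("PGLS slope equals the independent-contrasts through-origin slope", {
  for (seed in 1:50) {
    tr <- random_tree(sample(5:15, 1), seed)
    n <- length(tr$tip.label)
    x <- stats::setNames(rnorm(n), tr$tip.label)
    y <- stats::setNames(rnorm(n), tr$tip.label)
    ds <- make_dataset(tr, x = x[tr$tip.label], y = y[tr$tip.label])
    expect_equal(unname(fit_pgls(ds)$beta["x"]), oracle_pic_slope(tr, x, y),
                 tolerance = 1e-8)
  }
})

test_that("PGLS agrees with nlme::gls under a Brownian correlation", {
  skip_if_not_installed("nlme")
  tr <- ape::rcoal(12)
  set.seed(62)
  x <- rnorm(12); y <- 1 - 0.8 * x + rnorm(12)
  ds <- make_dataset(tr, x, y)
  fit <- fit_pgls(ds)
  df <- data.frame(y = unname(ds$y), x = unname(ds$X[, "x"]),
                   sp = ds$tips)
  ref <- nlme::gls(y ~ x, data = df,
                   correlation = ape::corBrownian(1, tr, form = ~sp),
                   method = "ML")
  expect_equal(unname(fit$beta), unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(fit$p_regression,
               summary(ref)$tTable["x", "p-value"], tolerance = 1e-6)
})

test_that("reported statistics are invariant to tip order and equivariant in x", {
  tr <- random_tree(10, 77)
  set.seed(78)
  x <- rnorm(10); y <- 2 + x + rnorm(10)
  table <- data.frame(species = tr$tip.label, x = x, y = y)
  ds1 <- align(tr, table, response = "y", predictors = "x", log10 = FALSE)
  ds2 <- align(tr, table[sample(10), ], response = "y", predictors = "x",
               log10 = FALSE)
  f1 <- fit_pgls(ds1); f2 <- fit_pgls(ds2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$lnL_ML, f2$lnL_ML, tolerance = 1e-10)

  # rescaling x by c rescales the slope by 1/c and leaves its p alone
  table_c <- transform(table, x = 10 * x)
  fc <- fit_pgls(align(tr, table_c, response = "y", predictors = "x",
                       log10 = FALSE))
  expect_equal(unname(fc$beta["x"]), unname(f1$beta["x"]) / 10,
               tolerance = 1e-10)
  expect_equal(fc$p_regression, f1$p_regression, tolerance = 1e-10)

  # exact collinearity: r2 = 1 and vanishing p
  ds_col <- make_dataset(balanced_tree(8), x = 1:8, y = 3 - 2 * (1:8))
  f_col <- fit_ols(ds_col)
  expect_equal(f_col$r2, 1, tolerance = 1e-10)
  expect_lt(f_col$p_regression, 1e-12)
})

test_that("RegOU nests its special cases and estimates d sensibly", {
  # forced d = 0 reproduces OLS coefficients and likelihood
  sim <- simulate_regression_dataset(
    sim_config(tree = balanced_tree(16), slope = -1, sigma = 1,
               residual_d = 0, seed = 81))
  ols <- fit_ols(sim$dataset)
  forced0 <- fit_regou(sim$dataset, d_bounds = c(0, 0))
  expect_equal(forced0$lnL_ML, ols$lnL_ML, tolerance = 1e-8)
  expect_equal(unname(forced0$beta), unname(ols$beta), tolerance = 1e-8)

  # free fit on iid data lands near 0 and close to the OLS fit
  free0 <- fit_regou(sim$dataset)
  expect_lt(free0$d_hat, 0.3)
  expect_gte(free0$lnL_ML, ols$lnL_ML - 1e-6)

  # nesting at d = 1: RegOU can only improve on PGLS in ML terms
  sim1 <- simulate_regression_dataset(
    sim_config(tree = balanced_tree(32), slope = -1, sigma = 1,
               residual_d = 1, seed = 82))
  pgls <- fit_pgls(sim1$dataset)
  regou <- fit_regou(sim1$dataset)
  expect_gte(regou$lnL_ML, pgls$lnL_ML - 1e-6)

  # REML profile at the optimum beats nearby d (local optimality)
  S <- bm_covariance(sim1$tree)
  obj <- function(d) phyloregress:::neg_remll(d, sim1$dataset$y,
                                              sim1$dataset$X, S)
  expect_lte(obj(regou$d_hat), obj(regou$d_hat + 0.05) + 1e-6)
  expect_lte(obj(regou$d_hat), obj(max(0, regou$d_hat - 0.05)) + 1e-6)

  # boundary flag
  expect_true(fit_regou(sim$dataset, d_bounds = c(0.5, 5),
                        reml = TRUE)$d_hat >= 0.5)
})

test_that("phylogenetic ANCOVA recovers group offsets and reports imbalance", {
  tree <- balanced_tree(32)
  V <- bm_covariance(tree)
  set.seed(91)
  # balanced groups with a true offset of 1.5
  hits <- 0L
  for (r in 1:60) {
    x <- drop(crossprod(chol(V), rnorm(32)))
    grp <- rep(c("g0", "g1"), each = 16)   # g1 is the second factor level
    eps <- drop(crossprod(chol(V), rnorm(32)))
    y <- 0.5 + 0.8 * x + 1.5 * (grp == "g1") + eps
    ds <- make_dataset(tree, x, y, group = grp)
    an <- ancova_fit(ds)
    ci <- an$group_test$estimate +
      c(-1, 1) * stats::qt(0.975, an$fit$n - an$fit$p) * an$group_test$se
    if (ci[1] <= 1.5 && 1.5 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.9)

  # unbalanced 13/2-style split draws a warning but still fits
  grp <- c(rep("lo", 29), rep("hi", 3))
  ds_u <- make_dataset(tree, rnorm(32), rnorm(32), group = grp)
  expect_warning(an_u <- ancova_fit(ds_u), "unbalanced")
  expect_false(is.null(an_u$fit))
  expect_true(an_u$balance$imbalanced)

  # a singleton group is refused; counts still reported
  grp1 <- c(rep("lo", 31), "hi")
  ds_1 <- make_dataset(tree, rnorm(32), rnorm(32), group = grp1)
  expect_warning(an_1 <- ancova_fit(ds_1), "refusing")
  expect_null(an_1$fit)
  expect_equal(as.integer(an_1$balance$counts), c(1L, 31L))

  # interaction adds the x:group column
  an_i <- ancova_fit(make_dataset(tree, rnorm(32), rnorm(32),
                                  group = rep(c("a", "b"), 16)),
                     interaction = TRUE)
  expect_equal(an_i$fit$p, 4L)
})
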