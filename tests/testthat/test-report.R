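test_that("signal report gives one row per trait with usable Ns", {
  tree <- balanced_tree(32)
  set.seed(131)
  # eight strong-signal traits simulated under BM, plus missingness in one
  traits <- t(simulate_bm_trait(tree, sigma2 = 4, n_reps = 8))
  table <- data.frame(species = rownames(traits), traits)
  names(table)[-1] <- paste0("trait", 1:8)
  table$trait8[1:4] <- NA
  rep <- signal_report(tree, table, traits = paste0("trait", 1:8),
                       log10 = FALSE, n_perm = 199, seed = 132)
  expect_equal(nrow(rep), 8)
  expect_equal(rep$n, c(rep(32, 7), 28))
  expect_true(all(rep$P <= 0.05))
  expect_true(all(rep$n_perm == 199))

  expect_error(signal_report(tree, table, traits = character()),
               "at least one")
  table$bad <- 1           # constant trait: error carries the trait name
  expect_error(signal_report(tree, table, traits = "bad", log10 = FALSE),
               "bad")
})

test_that("grid report separates OLS and best-model residual diagnostics", {
  # misspecified OLS keeps phylogenetic signal in its response-scale
  # residuals in most replicates; the best (phylogenetic) model's whitened
  # residuals stay near the nominal rejection rate
  set.seed(141)
  ols_rej <- best_rej <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    sim <- simulate_regression_dataset(
      sim_config(tree = balanced_tree(64), slope = -0.8, sigma = 1,
                 residual_d = 1))
    rep <- grid_report(sim$table, topologies = list(main = sim$tree),
                       schemes = list(all_one = "all_one"),
                       models = c("ols", "pgls"),
                       response = "y", predictors = "x", log10 = FALSE,
                       n_perm = 99)
    expect_equal(rep$best$row$model, "PGLS")
    if (rep$residual_signal_ols$p_value <= 0.05) ols_rej <- ols_rej + 1L
    if (rep$residual_signal_best$p_value <= 0.05) best_rej <- best_rej + 1L
  }
  expect_gte(ols_rej / n_rep, 0.75)
  expect_lte(best_rej / n_rep, 0.25)

  sim <- simulate_regression_dataset(
    sim_config(tree = balanced_tree(64), slope = -0.8, sigma = 1,
               residual_d = 1, seed = 143))
  rep <- grid_report(sim$table, topologies = list(main = sim$tree),
                     schemes = list(all_one = "all_one"),
                     models = c("ols", "pgls"),
                     response = "y", predictors = "x", log10 = FALSE,
                     n_perm = 99, seed = 144)
  expect_s3_class(rep, "grid_report")
  out <- capture.output(print(rep))
  expect_true(any(grepl("Best model", out)))
})

test_that("report writers embed version and seed and round-trip", {
  df <- data.frame(trait = c("a", "b"), K = c(1.2, 0.8), P = c(0.001, 0.2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(df, tsv, seed = 7)
  lines <- readLines(tsv)
  expect_match(lines[1], "phyloregress")
  expect_match(lines[2], "seed: 7")
  back <- utils::read.delim(tsv, comment.char = "#")
  expect_equal(back$K, df$K)

  js <- withr::local_tempfile(fileext = ".json")
  write_report_json(df, js, seed = 7)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$seed, 7)
  expect_equal(parsed$report$K, df$K)

  # identical input produces identical bytes (no timestamps)
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(df, tsv2, seed = 7)
  expect_identical(readLines(tsv), readLines(tsv2))
})

test_that("command-line entry point runs its subcommands end to end", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "phyloregress.R", package = "phyloregress")
  skip_if(cli == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")
  out_dir <- withr::local_tempdir()

  sim_dir <- file.path(out_dir, "sim")
  s1 <- system2(rscript, c(cli, "simulate", "--n-tips", "16", "--seed", "3",
                           "--out", sim_dir), stdout = TRUE, stderr = TRUE)
  expect_equal(attr(s1, "status"), NULL)
  expect_true(file.exists(file.path(sim_dir, "traits.csv")))

  sig <- file.path(out_dir, "signal.tsv")
  s2 <- system2(rscript, c(cli, "signal",
                           "--tree", file.path(sim_dir, "tree.nwk"),
                           "--traits", file.path(sim_dir, "traits.csv"),
                           "--response", "y", "--n-perm", "99",
                           "--seed", "4", "--out", sig),
                stdout = TRUE, stderr = TRUE)
  expect_equal(attr(s2, "status"), NULL)
  expect_true(file.exists(sig))

  grd <- file.path(out_dir, "grid.tsv")
  s3 <- system2(rscript, c(cli, "grid",
                           "--tree", file.path(sim_dir, "tree.nwk"),
                           "--traits", file.path(sim_dir, "traits.csv"),
                           "--response", "y", "--predictor", "x",
                           "--seed", "5", "--out", grd),
                stdout = TRUE, stderr = TRUE)
  expect_equal(attr(s3, "status"), NULL)
  grid_tab <- utils::read.delim(grd, comment.char = "#")
  expect_setequal(unique(grid_tab$model), c("OLS", "PGLS", "RegOU"))

  # input errors exit nonzero
  s4 <- suppressWarnings(
    system2(rscript, c(cli, "signal", "--tree", "/nonexistent.nwk",
                       "--traits", file.path(sim_dir, "traits.csv"),
                       "--response", "y", "--out", sig),
            stdout = TRUE, stderr = TRUE))
  expect_equal(attr(s4, "status"), 2)
})
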