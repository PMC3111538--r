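#' Per-trait phylogenetic signal report
#'
#' One row per trait: species count used (complete cases for that trait),
#' Blomberg's K, and the randomization-test P, on the supplied tree. Traits
#' are log10-transformed by default, matching the usual analysis scale for
#' genomic attributes spanning orders of magnitude.
#'
#' @param tree A fully lengthed `"phylo"` object.
#' @param table Trait `data.frame` (see [read_trait_table()]).
#' @param traits Character vector of trait columns to test (at least one).
#' @param log10 Single logical or named logical over `traits`.
#' @param n_perm,seed Passed to [signal_test()]; the seed for trait `i` is
#'   derived as `seed + i` so traits are independent but reproducible.
#' @param species_col Species column name.
#' @return A `data.frame` with columns `trait`, `n`, `K`, `P`, `n_perm`.
#' @export
signal_report <- function(tree, table, traits, log10 = TRUE, n_perm = 999,
                          seed = NULL, species_col = "species") {
  if (length(traits) < 1L) stop("'traits' must name at least one column")
  if (is.null(names(log10))) {
    log10 <- stats::setNames(rep(log10, length.out = length(traits)), traits)
  }
  rows <- lapply(seq_along(traits), function(i) {
    tr_name <- traits[i]
    res <- tryCatch({
      ds <- align(tree, table, response = tr_name,
                  log10 = isTRUE(log10[[tr_name]]), species_col = species_col)
      st <- signal_test(ds, n_perm = n_perm,
                        seed = if (is.null(seed)) NULL else seed + i)
      data.frame(trait = tr_name, n = ds$n, K = st$K, P = st$p_value,
                 n_perm = st$n_perm, stringsAsFactors = FALSE)
    }, error = function(e) {
      stop("trait '", tr_name, "': ", conditionMessage(e), call. = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}

#' Full model-comparison report with residual-signal diagnostic
#'
#' Runs [run_grid()] and augments it with two residual diagnostics on the
#' first topology under the first scheme. The *model-choice* diagnostic
#' tests the OLS fit's response-scale residuals for phylogenetic signal:
#' signal there is the empirical justification for a phylogenetic model.
#' The *adequacy* diagnostic tests the best-ranked model's GLS-whitened
#' residuals, which are i.i.d. when that model's covariance is correct, so
#' remaining signal indicates the chosen structure is still inadequate.
#' (Response-scale residuals of a correctly specified PGLS retain signal by
#' construction, so they cannot serve as an adequacy check.)
#'
#' @inheritParams run_grid
#' @param n_perm,seed Randomization-test settings for the residual-signal
#'   diagnostics.
#' @return A list of class `"grid_report"`: `grid` (the
#'   `"comparison_grid"`), `best` (from [select_best()]),
#'   `residual_signal_ols` and `residual_signal_best` (each a
#'   `"signal_result"`, or `NULL` when the corresponding fit is absent).
#' @export
grid_report <- function(table, topologies, schemes = list(all_one = "all_one"),
                        models = c("ols", "pgls", "regou"),
                        response, predictors, log10 = TRUE,
                        species_col = "species", d_bounds = c(0, 5),
                        n_perm = 999, seed = NULL) {
  grid <- run_grid(table, topologies, schemes = schemes, models = models,
                   response = response, predictors = predictors,
                   log10 = log10, species_col = species_col,
                   d_bounds = d_bounds)
  best <- select_best(grid)
  if (!is.list(topologies)) topologies <- list(topology = topologies)
  diag_tree <- if (identical(schemes[[1L]], "all_one")) {
    apply_branch_scheme(topologies[[1L]], "all_one")
  } else {
    apply_branch_scheme(topologies[[1L]], "from_file", lengths = schemes[[1L]])
  }
  rs_ols <- if (is.null(grid$fits[["OLS"]])) NULL else
    residual_signal(grid$fits[["OLS"]], diag_tree, n_perm = n_perm,
                    seed = if (is.null(seed)) NULL else seed + 1L)
  rs_best <- if (is.null(best$fit)) NULL else {
    f_w <- best$fit
    f_w$residuals <- f_w$residuals_whitened
    residual_signal(f_w, diag_tree, n_perm = n_perm,
                    seed = if (is.null(seed)) NULL else seed + 2L)
  }
  structure(list(grid = grid, best = best,
                 residual_signal_ols = rs_ols,
                 residual_signal_best = rs_best,
                 seed = seed),
            class = "grid_report")
}

#' @export
print.grid_report <- function(x, ...) {
  print(x$grid, ...)
  cat("\nBest model:", grid_row_id(x$best$row), "(", x$best$rationale, ")\n")
  if (!is.null(x$residual_signal_ols))
    cat("OLS residual signal (response scale):  K =",
        format(x$residual_signal_ols$K, digits = 3),
        ", P =", format(x$residual_signal_ols$p_value, digits = 3), "\n")
  if (!is.null(x$residual_signal_best))
    cat("Best-model whitened-residual signal: K =",
        format(x$residual_signal_best$K, digits = 3),
        ", P =", format(x$residual_signal_best$p_value, digits = 3), "\n")
  invisible(x)
}

#' Write a report table as TSV with a reproducibility header
#'
#' Prepends `#`-comment lines recording the package version, seed, and
#' timestamp-free call summary, so identical inputs give identical files.
#'
#' @param df A `data.frame` (e.g. from [signal_report()] or
#'   `run_grid()$rows`).
#' @param path Output file path.
#' @param seed Seed to record (or `NA`).
#' @return Invisibly, `path`.
#' @export
write_report_tsv <- function(df, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# phyloregress ", utils::packageVersion("phyloregress")),
    paste0("# seed: ", seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a report as JSON with a reproducibility envelope
#'
#' @param x A `data.frame`, `"signal_result"`, or any list-like report.
#' @param path Output file path.
#' @param seed Seed to record (or `NA`).
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(x, path, seed = NA) {
  if (inherits(x, "signal_result")) x <- unclass(x)
  env <- list(package = "phyloregress",
              version = as.character(utils::packageVersion("phyloregress")),
              seed = seed,
              report = x)
  jsonlite::write_json(env, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
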