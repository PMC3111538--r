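#' Likelihood-ratio test between nested GLS models
#'
#' Compares two nested model fits by their ML log-likelihoods:
#' the statistic is `2 (lnL_full - lnL_null)`, referred to the upper tail
#' of a chi-square with `df` degrees of freedom. Used here to compare the
#' RegOU model (one extra parameter, `d`) against OLS (`d = 0`), with
#' `df = 1`. When the null fixes `d` on the boundary of its range the plain
#' chi-square reference is conservative; this convention is retained
#' deliberately.
#'
#' @param lnL_full ML log-likelihood of the richer model.
#' @param lnL_null ML log-likelihood of the nested null model; must not
#'   exceed `lnL_full` by more than a small tolerance (a violation signals a
#'   fitting bug, since the null is a special case of the full model).
#' @param df Degrees of freedom (number of extra parameters), `>= 1`.
#' @return An object of class `"htest"` with `statistic`, `parameter`
#'   (`df`) and `p.value`.
#' @export
#' @examples
#' lr_test(-22.59, -25.53, df = 1)  # statistic 5.88, significant at 0.05
lr_test <- function(lnL_full, lnL_null, df = 1) {
  stopifnot(is.numeric(lnL_full), is.numeric(lnL_null), df >= 1)
  if (lnL_full < lnL_null - 1e-8)
    stop("nesting violated: full-model lnL (", format(lnL_full),
         ") below null lnL (", format(lnL_null),
         ") — the nested fit should never beat the full fit")
  stat <- max(0, 2 * (lnL_full - lnL_null))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = c("X-squared" = stat),
                 parameter = c(df = df),
                 p.value = p,
                 method = "ln maximum likelihood ratio test",
                 data.name = sprintf("lnL_full = %.4f, lnL_null = %.4f",
                                     lnL_full, lnL_null)),
            class = "htest")
}

#' Fit a model grid over topologies and branch-length schemes
#'
#' Runs the full sensitivity grid of a comparative regression: OLS once
#' (it is topology-independent), and PGLS and/or RegOU for every
#' combination of candidate topology and branch-length scheme, all on the
#' identical species set (complete cases of the trait table, required in
#' every topology). Rows are ranked by ML log-likelihood; RegOU rows carry a
#' likelihood-ratio comparison against OLS, and boundary estimates of `d`
#' are flagged. A cell whose fit fails is recorded with its error message
#' and the rest of the grid is still returned.
#'
#' @param table Trait `data.frame` (see [read_trait_table()]).
#' @param topologies Named list of `"phylo"` objects (lengths optional if a
#'   scheme supplies them).
#' @param schemes Named list of branch-length schemes: each element either
#'   the string `"all_one"` or a `lengths` object for
#'   [apply_branch_scheme()] (a lengthed tree or an edge table), or a list
#'   of such objects keyed by topology name when the lengths differ by
#'   topology (as fossil- or substitution-derived lengths do). Names label
#'   the grid rows. A plain character vector is also accepted.
#' @param models Subset of `c("ols", "pgls", "regou")`.
#' @param response,predictors,log10,species_col Passed to [align()].
#' @param d_bounds Search interval for RegOU's `d`.
#' @param subset Optional logical expression on the table's columns,
#'   evaluated like `base::subset()`, restricting the species set (e.g.
#'   `group == "bacteria"`).
#' @return A `"comparison_grid"`: `rows` (a data frame with model,
#'   topology, scheme, lnL, n, b, r2, d, p_slope, lr_p, flags), `fits`
#'   (the underlying `"gls_fit"` objects), ranked by `lnL` descending.
#' @export
run_grid <- function(table, topologies, schemes = list(all_one = "all_one"),
                     models = c("ols", "pgls", "regou"),
                     response, predictors, log10 = TRUE,
                     species_col = "species", d_bounds = c(0, 5),
                     subset = NULL) {
  models <- match.arg(models, c("ols", "pgls", "regou"), several.ok = TRUE)
  if (!is.list(topologies)) topologies <- list(topology = topologies)
  if (is.null(names(topologies)) || any(!nzchar(names(topologies))))
    stop("'topologies' must be a named list")
  if (is.character(schemes)) schemes <- stats::setNames(as.list(schemes), schemes)
  if (is.null(names(schemes)) || any(!nzchar(names(schemes))))
    stop("'schemes' must be named")

  sub_expr <- substitute(subset)
  if (!is.null(sub_expr) && !identical(sub_expr, quote(NULL))) {
    keep <- eval(sub_expr, table, parent.frame())
    keep[is.na(keep)] <- FALSE
    table <- table[keep, , drop = FALSE]
  }

  # common species set: complete cases present in every topology
  vars <- c(response, predictors)
  sp <- trimws(as.character(table[[species_col]]))
  ok <- stats::complete.cases(table[vars])
  for (tp in topologies) ok <- ok & sp %in% tp$tip.label
  table <- table[ok, , drop = FALSE]
  if (nrow(table) < 3L) stop("fewer than 3 complete cases shared by all topologies")

  rows <- list(); fits <- list()
  add_row <- function(model, topo, scheme, fit, err = NA_character_) {
    id <- paste(c(model, topo, scheme)[!is.na(c(model, topo, scheme))],
                collapse = " / ")
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model, topology = topo, scheme = scheme,
      lnL = if (is.null(fit)) NA_real_ else fit$lnL_ML,
      n = if (is.null(fit)) NA_integer_ else fit$n,
      b = if (is.null(fit)) NA_real_ else unname(fit$beta[2L]),
      r2 = if (is.null(fit)) NA_real_ else fit$r2,
      d = if (is.null(fit)) NA_real_ else fit$d_hat,
      p_slope = if (is.null(fit)) NA_real_ else fit$p_regression,
      boundary = if (is.null(fit)) NA else isTRUE(fit$boundary),
      error = err, stringsAsFactors = FALSE)
    fits[[id]] <<- fit
  }
  try_fit <- function(expr) tryCatch(expr, error = function(e) e)

  ols_fit <- NULL
  if ("ols" %in% models) {
    base_tree <- apply_branch_scheme(topologies[[1L]], "all_one")
    r <- try_fit({
      ds <- align(base_tree, table, response, predictors, log10 = log10,
                  species_col = species_col)
      fit_ols(ds)
    })
    if (inherits(r, "error")) add_row("OLS", NA_character_, NA_character_,
                                      NULL, conditionMessage(r))
    else { ols_fit <- r; add_row("OLS", NA_character_, NA_character_, r) }
  }

  for (tn in names(topologies)) {
    for (sn in names(schemes)) {
      sch <- schemes[[sn]]
      # a scheme may carry one lengths object per topology
      if (is.list(sch) && !is.data.frame(sch) && !inherits(sch, "phylo") &&
          all(names(topologies) %in% names(sch))) sch <- sch[[tn]]
      r_tree <- try_fit({
        if (identical(sch, "all_one"))
          apply_branch_scheme(topologies[[tn]], "all_one")
        else
          apply_branch_scheme(topologies[[tn]], "from_file", lengths = sch)
      })
      if (inherits(r_tree, "error")) {
        for (m in intersect(models, c("pgls", "regou")))
          add_row(toupper(sub("regou", "RegOU", m)), tn, sn, NULL,
                  conditionMessage(r_tree))
        next
      }
      r_ds <- try_fit(align(r_tree, table, response, predictors,
                            log10 = log10, species_col = species_col))
      for (m in intersect(models, c("pgls", "regou"))) {
        lab <- if (m == "pgls") "PGLS" else "RegOU"
        if (inherits(r_ds, "error")) {
          add_row(lab, tn, sn, NULL, conditionMessage(r_ds)); next
        }
        r <- try_fit(if (m == "pgls") fit_pgls(r_ds)
                     else fit_regou(r_ds, d_bounds = d_bounds))
        if (inherits(r, "error")) add_row(lab, tn, sn, NULL, conditionMessage(r))
        else add_row(lab, tn, sn, r)
      }
    }
  }

  rows <- do.call(rbind, rows)
  # RegOU vs OLS likelihood-ratio comparison (df = 1)
  rows$lr_p <- NA_real_
  if (!is.null(ols_fit)) {
    for (i in which(rows$model == "RegOU" & !is.na(rows$lnL))) {
      if (rows$lnL[i] >= ols_fit$lnL_ML - 1e-8)
        rows$lr_p[i] <- lr_test(rows$lnL[i], ols_fit$lnL_ML, df = 1)$p.value
    }
  }
  ord <- order(-rows$lnL, match(rows$model, c("OLS", "PGLS", "RegOU")),
               rows$topology, rows$scheme, na.last = TRUE)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(rows = rows, fits = fits,
                 response = response, predictors = predictors),
            class = "comparison_grid")
}

# estimated-parameter count used for tie-breaking (regression coefficients
# + sigma^2, + d for RegOU)
n_params <- function(model, p) p + 1L + (model == "RegOU")

#' Select the best-fitting row of a comparison grid
#'
#' Picks the row with the highest ML log-likelihood. Ties (within 1e-8) are
#' broken toward fewer estimated parameters, then toward PGLS over RegOU,
#' and the rationale is recorded.
#'
#' @param grid A `"comparison_grid"` from [run_grid()].
#' @return A list with `row` (the selected row of `grid$rows`), `fit`, and
#'   `rationale`.
#' @export
select_best <- function(grid) {
  stopifnot(inherits(grid, "comparison_grid"))
  rows <- grid$rows[!is.na(grid$rows$lnL), , drop = FALSE]
  if (nrow(rows) == 0L) stop("no successful fits in grid")
  best_lnL <- max(rows$lnL)
  cand <- rows[rows$lnL >= best_lnL - 1e-8, , drop = FALSE]
  rationale <- "highest ln maximum likelihood"
  if (nrow(cand) > 1L) {
    p <- vapply(seq_len(nrow(cand)), function(i) {
      id <- grid_row_id(cand[i, ])
      grid$fits[[id]]$p
    }, integer(1))
    np <- n_params(cand$model, p)
    cand <- cand[np == min(np), , drop = FALSE]
    rationale <- paste(rationale, "; tie broken toward fewer parameters")
    if (nrow(cand) > 1L && any(cand$model == "PGLS")) {
      cand <- cand[cand$model == "PGLS", , drop = FALSE]
      rationale <- paste(rationale, "; then PGLS over RegOU")
    }
  }
  row <- cand[1L, , drop = FALSE]
  list(row = row, fit = grid$fits[[grid_row_id(row)]], rationale = rationale)
}

grid_row_id <- function(row) {
  paste(c(row$model, row$topology, row$scheme)[
    !is.na(c(row$model, row$topology, row$scheme))], collapse = " / ")
}

#' @export
print.comparison_grid <- function(x, digits = 3, ...) {
  cat("Comparative regression model grid:", x$response, "~",
      paste(x$predictors, collapse = " + "), "\n")
  df <- x$rows
  df$lnL <- round(df$lnL, digits)
  df$b <- round(df$b, digits)
  df$r2 <- round(df$r2, digits)
  df$d <- round(df$d, digits)
  df$p_slope <- signif(df$p_slope, digits)
  df$sig <- ifelse(!is.na(df$lr_p) & df$lr_p < 0.05, "*", "")
  df$lr_p <- signif(df$lr_p, digits)
  print(df, row.names = FALSE)
  cat("* RegOU fits significantly better than OLS (LR test, P < 0.05)\n")
  invisible(x)
}
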