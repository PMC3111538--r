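#' Read a species-by-trait table from delimited text
#'
#' Reads a CSV or TSV table with one row per species, validates it, and
#' coerces trait columns to numeric. Cells that cannot be parsed as numbers
#' become explicit `NA` with a warning; missingness is handled downstream by
#' complete-case alignment ([align()]), never imputation. Any column whose
#' name contains "fraction" is checked to lie in [0, 1].
#'
#' @param path Path to a delimited text file with a header row.
#' @param species_col Name of the species-label column (default `"species"`).
#' @param sep Field separator; `NULL` (default) picks `"\t"` for `.tsv`/`.txt`
#'   files and `","` otherwise.
#' @param group_cols Character vector of columns to keep as categorical
#'   rather than coerce to numeric (e.g. a prokaryote/eukaryote indicator).
#'   Columns that are non-numeric throughout are kept categorical
#'   automatically.
#' @return A `data.frame` with the species column first, species labels
#'   trimmed of outer whitespace, trait columns numeric.
#' @export
read_trait_table <- function(path, species_col = "species", sep = NULL,
                             group_cols = character()) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), quote = "\"",
                           comment.char = "")
  if (!species_col %in% names(raw))
    stop("species column '", species_col, "' not found in ", path)
  raw[[species_col]] <- trimws(as.character(raw[[species_col]]))
  if (any(!nzchar(raw[[species_col]]) | is.na(raw[[species_col]])))
    stop("empty species label in ", path)
  dup <- raw[[species_col]][duplicated(raw[[species_col]])]
  if (length(dup))
    stop("duplicate species: ", paste(unique(dup), collapse = ", "))
  for (col in setdiff(names(raw), c(species_col, group_cols))) {
    x <- raw[[col]]
    if (is.numeric(x)) next
    num <- suppressWarnings(as.numeric(x))
    new_na <- sum(is.na(num) & !is.na(x))
    if (new_na > 0L) {
      if (new_na == sum(!is.na(x))) next  # fully non-numeric: categorical
      warning(new_na, " unparseable value(s) in column '", col,
              "' set to NA")
    }
    raw[[col]] <- num
  }
  for (col in grep("fraction", names(raw), ignore.case = TRUE, value = TRUE)) {
    x <- raw[[col]]
    if (is.numeric(x) && any(x < 0 | x > 1, na.rm = TRUE))
      stop("column '", col, "' must lie in [0, 1]")
  }
  raw[c(species_col, setdiff(names(raw), species_col))]
}

#' Align a phylogeny and a trait table into an analysis-ready dataset
#'
#' Matches species by exact label (after trimming outer whitespace,
#' case-sensitive), restricts to complete cases for the chosen variables,
#' prunes the tree to the retained species, applies log10 transforms where
#' requested, and builds the residual covariance matrix. Species present in
#' only one of the two inputs are reported in the `"matching"` attribute and
#' in a message, never silently dropped.
#'
#' @param tree A fully lengthed `"phylo"` object.
#' @param table A trait `data.frame` as from [read_trait_table()].
#' @param response Name of the response trait column.
#' @param predictors Character vector of predictor trait columns (may be
#'   empty for an intercept-only dataset, e.g. for signal testing).
#' @param log10 Either a single logical applied to every variable, or a
#'   named logical vector over `c(response, predictors)`. log10 is only ever
#'   applied to strictly positive values; offending species are named in the
#'   error.
#' @param group Optional name of a 2-level categorical column to carry along
#'   for [ancova_fit()]; included in the complete-case requirement.
#' @param cov_model `"bm"` (Brownian motion) or `"ou"` (requires `d`).
#' @param d OU transformation parameter when `cov_model = "ou"`.
#' @param species_col Species column name in `table`.
#' @return An object of class `"aligned_dataset"`: a list with elements
#'   `y` (response vector), `X` (design matrix with intercept column),
#'   `V` (tip covariance), `tips`, `tree` (pruned), `n`, and optionally
#'   `group` (factor).
#' @export
align <- function(tree, table, response, predictors = character(),
                  log10 = TRUE, group = NULL, cov_model = c("bm", "ou"),
                  d = NULL, species_col = "species") {
  cov_model <- match.arg(cov_model)
  validate_phylogeny(tree)
  vars <- c(response, predictors)
  miss <- setdiff(c(vars, group, species_col), names(table))
  if (length(miss)) stop("column(s) not in table: ", paste(miss, collapse = ", "))
  if (is.null(names(log10))) {
    if (length(log10) != 1L)
      stop("'log10' must be a single logical or a named logical vector")
    log10 <- stats::setNames(rep(log10, length(vars)), vars)
  }
  log10 <- ifelse(is.na(log10[vars]), FALSE, log10[vars])
  names(log10) <- vars

  sp <- trimws(as.character(table[[species_col]]))
  tree_only <- setdiff(tree$tip.label, sp)
  table_only <- setdiff(sp, tree$tip.label)
  if (length(tree_only) || length(table_only)) {
    message("species matching: ", length(tree_only), " in tree only, ",
            length(table_only), " in table only")
  }
  keep <- sp %in% tree$tip.label
  cols <- table[keep, vars, drop = FALSE]
  complete <- stats::complete.cases(cols)
  if (!is.null(group)) complete <- complete & !is.na(table[keep, group])
  sp <- sp[keep][complete]
  cols <- cols[complete, , drop = FALSE]
  if (length(sp) < 3L)
    stop("fewer than 3 complete cases after matching (got ", length(sp), ")")

  pruned <- ape::keep.tip(tree, sp)
  ord <- match(pruned$tip.label, sp)
  sp <- sp[ord]
  cols <- cols[ord, , drop = FALSE]

  for (v in vars) {
    if (log10[v]) {
      bad <- sp[cols[[v]] <= 0]
      if (length(bad))
        stop("log10 requested for '", v, "' but non-positive value(s) for: ",
             paste(bad, collapse = ", "))
      cols[[v]] <- base::log10(cols[[v]])
    }
  }

  y <- stats::setNames(cols[[response]], sp)
  X <- cbind("(Intercept)" = rep(1, length(sp)))
  for (v in predictors) X <- cbind(X, cols[[v]])
  colnames(X) <- c("(Intercept)", predictors)
  rownames(X) <- sp

  V <- switch(cov_model,
              bm = bm_covariance(pruned),
              ou = {
                if (is.null(d)) stop("cov_model 'ou' requires 'd'")
                ou_covariance(pruned, d)
              })

  ds <- structure(
    list(y = y, X = X, V = V, tips = sp, tree = pruned, n = length(sp),
         response = response, predictors = predictors,
         log10 = log10, cov_model = cov_model),
    class = "aligned_dataset")
  if (!is.null(group)) {
    g <- factor(table[keep, group][complete][ord])
    names(g) <- sp
    ds$group <- g
  }
  attr(ds, "matching") <- list(tree_only = tree_only, table_only = table_only)
  ds
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("Aligned comparative dataset: n =", x$n, "species\n")
  cat("  response:  ", x$response,
      if (isTRUE(x$log10[x$response])) " (log10)" else "", "\n", sep = "")
  if (length(x$predictors))
    cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  if (!is.null(x$group))
    cat("  group:     ", paste(levels(x$group), collapse = " / "),
        " (", paste(table(x$group), collapse = "/"), ")\n", sep = "")
  cat("  covariance:", x$cov_model, "\n")
  invisible(x)
}

#' Effective population size from heterozygosity
#'
#' Converts expected heterozygosity `H` at a neutral locus into an effective
#' population size estimate under the stepwise/infinite-allele style formula
#' `N_e = ((1 - H)^-2 - 1) / (8 u)` with a per-locus mutation rate `u`.
#' With `u` held constant the ranking of species by `N_e` is identical to
#' the ranking by `N_e * u`, so analyses on either scale agree.
#'
#' @param H Heterozygosity values in `[0, 1)`.
#' @param u Mutation rate per locus per generation (default `1e-5`).
#' @return Numeric vector of `N_e` estimates; strictly increasing in `H`.
#' @export
#' @examples
#' ne_from_heterozygosity(0.1)  # about 2932
ne_from_heterozygosity <- function(H, u = 1e-5) {
  if (any(!is.finite(H) | H < 0 | H >= 1)) stop("'H' must lie in [0, 1)")
  if (!is.numeric(u) || any(u <= 0)) stop("'u' must be positive")
  ((1 - H)^-2 - 1) / (8 * u)
}

#' Export an aligned dataset as a CSV + Newick pair
#'
#' Writes the (back-transformed, analysis-scale) data and the pruned tree so
#' a fit can be reproduced from plain-text files alone.
#'
#' @param dataset An `"aligned_dataset"`.
#' @param basename Path prefix; writes `<basename>.csv` and `<basename>.nwk`.
#' @return Invisibly, the two file paths.
#' @export
export_dataset <- function(dataset, basename) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  df <- data.frame(species = dataset$tips, check.names = FALSE)
  df[[dataset$response]] <- unname(dataset$y)
  for (v in dataset$predictors) df[[v]] <- unname(dataset$X[, v])
  if (!is.null(dataset$group)) df$group <- as.character(dataset$group)
  csv <- paste0(basename, ".csv")
  nwk <- paste0(basename, ".nwk")
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  writeLines(write_newick(dataset$tree), nwk)
  invisible(c(csv, nwk))
}
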