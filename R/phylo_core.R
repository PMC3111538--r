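#' Parse a Newick string into a validated phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the package relies on: unique, non-empty tip labels; finite,
#' non-negative branch lengths; a rooted tree. Trees without branch lengths
#' are accepted (a branch-length scheme can supply them later, see
#' [apply_branch_scheme()]).
#'
#' @param text A Newick string, terminated by `";"`.
#' @return An object of class `"phylo"`.
#' @seealso [write_newick()], [apply_branch_scheme()]
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  # locate unbalanced parentheses before handing to the parser, so the
  # error can carry a character position
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i, " in Newick string")
    }
  }
  if (depth != 0L) stop("unbalanced '(' in Newick string (", depth, " unclosed)")
  if (!grepl(";", text, fixed = TRUE)) stop("Newick string lacks ';' terminator")
  tree <- tryCatch(
    ape::read.tree(text = text),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w)),
    error = function(e) stop("malformed Newick: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("malformed Newick string")
  validate_phylogeny(tree, text = text)
  tree
}

#' Serialize a phylogeny to Newick
#'
#' Inverse of [parse_newick()]: `parse_newick(write_newick(tree))` preserves
#' topology, tip labels and branch lengths.
#'
#' @param tree A `"phylo"` object.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string ending in `";"`.
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

# invariant checks shared by every entry point that accepts a tree
validate_phylogeny <- function(tree, text = NULL) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip label")
  dup <- labs[duplicated(labs)]
  if (length(dup)) {
    pos <- if (!is.null(text)) {
      paste0(" (first repeat near position ",
             regexpr(dup[1L], text, fixed = TRUE), ")")
    } else ""
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "), pos)
  }
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length))) stop("non-finite branch length")
    if (any(tree$edge.length < 0)) {
      bad <- which(tree$edge.length < 0)[1L]
      stop("negative branch length on edge to node ", tree$edge[bad, 2L])
    }
  }
  invisible(tree)
}

has_lengths <- function(tree) {
  !is.null(tree$edge.length) && all(is.finite(tree$edge.length))
}

#' Replace branch lengths according to a named scheme
#'
#' Supports the branch-length schemes used in sensitivity analyses over a
#' fixed topology: `"all_one"` sets every edge to exactly 1 (the arbitrary
#' unit-length scheme); `"from_file"` takes lengths from either a fully
#' lengthed tree with the same topology or a two-column table mapping each
#' edge's child clade to a length.
#'
#' @param tree A `"phylo"` object (lengths optional).
#' @param scheme `"all_one"` or `"from_file"`.
#' @param lengths For `"from_file"`: either a `"phylo"` object carrying the
#'   desired lengths on an identical topology, or a data frame whose first
#'   column identifies an edge by its child clade (a single tip label, or
#'   the tips of the clade joined by `","` or `"|"`) and whose second column
#'   gives the positive length.
#' @return The tree with every edge assigned a positive length; topology and
#'   labels untouched.
#' @export
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' tr1 <- apply_branch_scheme(tr, "all_one")
#' range(tr1$edge.length)
apply_branch_scheme <- function(tree, scheme = c("all_one", "from_file"),
                                lengths = NULL) {
  scheme <- match.arg(scheme)
  validate_phylogeny(tree)
  if (scheme == "all_one") {
    tree$edge.length <- rep(1, nrow(tree$edge))
    return(tree)
  }
  if (is.null(lengths)) stop("scheme 'from_file' requires 'lengths'")
  if (inherits(lengths, "phylo")) {
    tab <- data.frame(clade = edge_clade_ids(lengths),
                      length = lengths$edge.length,
                      stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(lengths)
    if (ncol(tab) < 2L) stop("edge-length table needs two columns: clade, length")
    tab <- data.frame(clade = normalize_clade_id(as.character(tab[[1L]])),
                      length = as.numeric(tab[[2L]]),
                      stringsAsFactors = FALSE)
  }
  ids <- edge_clade_ids(tree)
  m <- match(ids, tab$clade)
  if (anyNA(m)) {
    stop("no length supplied for edge(s) subtending clade(s): ",
         paste(ids[is.na(m)], collapse = "; "))
  }
  len <- tab$length[m]
  if (any(!is.finite(len)) || any(len <= 0)) {
    bad <- ids[!is.finite(len) | len <= 0][1L]
    stop("non-positive or missing length for clade: ", bad)
  }
  tree$edge.length <- len
  tree
}

# one identifier per edge: sorted tip labels of the child clade, "|"-joined
edge_clade_ids <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- descendant_tips(tree)
  vapply(tree$edge[, 2L], function(nd) {
    labs <- if (nd <= ntip) tree$tip.label[nd] else tree$tip.label[kids[[nd]]]
    paste(sort(labs), collapse = "|")
  }, character(1L))
}

normalize_clade_id <- function(x) {
  vapply(strsplit(trimws(x), "[,|;]"), function(parts) {
    paste(sort(trimws(parts)), collapse = "|")
  }, character(1L))
}

# list indexed by node number giving the tip indices below each node
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- vector("list", nnode)
  for (i in seq_len(ntip)) kids[[i]] <- i
  # postorder guarantees children are filled before parents
  ord <- stats::reorder(tree, "postorder")$edge
  for (r in seq_len(nrow(ord))) {
    par <- ord[r, 1L]; ch <- ord[r, 2L]
    kids[[par]] <- c(kids[[par]], kids[[ch]])
  }
  kids
}

#' Build a star phylogeny
#'
#' A single polytomy in which every tip attaches directly to the root with
#' the same branch length. Its Brownian-motion tip covariance is
#' `depth` times the identity matrix — the residual covariance structure
#' implicitly assumed by ordinary (nonphylogenetic) regression.
#'
#' @param labels Character vector of at least two unique tip labels.
#' @param depth Common root-to-tip branch length (default 1).
#' @return A `"phylo"` object.
#' @export
#' @examples
#' bm_covariance(star_tree(c("A", "B", "C")))
star_tree <- function(labels, depth = 1) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("a star tree needs at least 2 tips")
  if (anyDuplicated(labels)) stop("duplicate tip labels")
  if (!is.finite(depth) || depth <= 0) stop("depth must be positive")
  parse_newick(paste0("(", paste0(labels, ":", format(depth, digits = 15),
                                  collapse = ","), ");"))
}

#' Brownian-motion tip covariance of a phylogeny
#'
#' Entry (i, j) is the root-to-MRCA path length shared by tips i and j; the
#' diagonal holds root-to-tip depths. Under Brownian-motion trait evolution
#' with rate sigma^2 the tip values are multivariate normal with covariance
#' sigma^2 times this matrix.
#'
#' @param tree A fully lengthed `"phylo"` object.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames, rows/columns in `tree$tip.label` order.
#' @seealso [ou_covariance()] for the Ornstein-Uhlenbeck transformed family.
#' @export
bm_covariance <- function(tree) {
  validate_phylogeny(tree)
  if (!has_lengths(tree)) stop("tree has no branch lengths; apply a scheme first")
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Root-to-tip depths
#'
#' @param tree A fully lengthed `"phylo"` object.
#' @return Named numeric vector of root-to-tip path lengths in tip order.
#' @export
tip_depths <- function(tree) {
  diag(bm_covariance(tree))
}

is_ultrametric_depths <- function(depths, tol = 1e-8) {
  diff(range(depths)) <= tol * max(mean(depths), .Machine$double.eps)
}

#' Ornstein-Uhlenbeck transformed tip covariance
#'
#' One-parameter family of residual covariance matrices connecting the star
#' structure to Brownian motion and beyond. With `d = exp(-2 * alpha)` for
#' OU restraining force `alpha`, shared root-to-MRCA depth `s_ij` and tip
#' depths `t_i`, the entries are
#' \deqn{V_{ij}(d) = d^{(t_i + t_j)/2 - s_{ij}} \frac{1 - d^{s_{ij}}}{1 - d}}
#' with the analytic limits at the two special points: `d = 1` recovers
#' [bm_covariance()] exactly, and `d = 0` the identity-structured (diagonal)
#' matrix of a star phylogeny. Values `d > 1` make relatives *more* similar
#' than Brownian motion predicts.
#'
#' For non-ultrametric trees the generalized exponent
#' `(t_i + t_j)/2 - s_ij` is used and a warning notes that the `d = 0` limit
#' is a unit-diagonal matrix rather than the tree's own star covariance.
#'
#' @param tree A fully lengthed `"phylo"` object.
#' @param d Non-negative scalar transformation parameter.
#' @return A symmetric covariance matrix with tip labels as dimnames.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ou_covariance(tr, 0.5)["A", "B"]  # 0.5
ou_covariance <- function(tree, d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 0)
    stop("'d' must be a single non-negative finite number")
  S <- bm_covariance(tree)
  depths <- diag(S)
  if (!is_ultrametric_depths(depths)) {
    warning("tree is not ultrametric: the d = 0 limit of the OU transform ",
            "is a unit-diagonal matrix, not the tree's star covariance")
  }
  ou_transform(S, d)
}

# core transform on a precomputed BM matrix; reused by the REML profile so
# the tree is traversed once per fit, not once per objective evaluation
ou_transform <- function(S, d) {
  if (abs(d - 1) < 1e-10) return(S)
  n <- nrow(S)
  if (d < 1e-12) {
    V <- diag(n)
    dimnames(V) <- dimnames(S)
    return(V)
  }
  depths <- diag(S)
  E <- outer(depths, depths, "+") / 2 - S
  ld <- log(d)
  # (1 - d^s)/(1 - d) via expm1 for stability near d = 1
  V <- exp(E * ld) * (expm1(S * ld) / expm1(ld))
  dimnames(V) <- dimnames(S)
  (V + t(V)) / 2
}

# Cholesky with one round of diagonal jitter repair; the jitter is bounded
# by 1e-10 * mean(diag) so it cannot mask a genuinely indefinite matrix
chol_psd <- function(V) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    jit <- 1e-10 * mean(diag(V))
    warning("covariance not numerically positive definite; added diagonal ",
            "jitter ", format(jit))
    R <- tryCatch(chol(V + diag(jit, nrow(V))), error = function(e) NULL)
    if (is.null(R)) stop("covariance matrix is not positive definite")
  }
  R
}
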