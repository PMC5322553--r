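#' Read and validate a newick phylogeny
#'
#' Reads a single rooted tree with branch lengths, either from a file or from
#' a newick string.  The tree is the source of the correlation structure used
#' by [fit_gee()]: its branch lengths must all be present and non-negative,
#' and tip labels must be unique, because downstream tables are joined to the
#' tree by label.
#'
#' @param x Path to a newick file containing one tree, or a newick string
#'   (recognized by the presence of a `(` character or a terminal `;`).
#' @param impute_lengths If `TRUE`, edges with missing branch lengths are
#'   assigned length 0 instead of being rejected.  Default `FALSE`: missing
#'   lengths are an error, since they silently distort the phylogenetic
#'   covariance.
#' @return An object of class `"phylo"` (see [ape::read.tree()]) whose tip
#'   order is the newick left-to-right order.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @seealso [vcv_from_tree()], [phylo_df()]
#' @export
read_newick <- function(x, impute_lengths = FALSE) {
  stopifnot(is.character(x), length(x) == 1L)
  text <- if (grepl("(", x, fixed = TRUE) || grepl(";\\s*$", x)) {
    x
  } else {
    if (!file.exists(x)) stop("tree file not found: ", x)
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  .check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse newick string")
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected a single tree, found ", length(tree))
    tree <- tree[[1L]]
  }
  validate_phylogeny(tree, impute = impute_lengths)
}

# Cheap syntax scan so parse failures report a character position; ape's
# parser is permissive and its errors are positionless.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unmatched ')' at character ", i)
    }
  }
  if (depth > 0L)
    stop("malformed newick: ", depth, " unclosed '(' at character ",
         length(chars))
  if (!grepl(";", text, fixed = TRUE))
    stop("malformed newick: missing terminating ';' at character ",
         nchar(text))
  invisible(TRUE)
}

#' Validate phylogeny invariants
#'
#' Checks tip-label uniqueness, presence and non-negativity of all branch
#' lengths, and that the tree is rooted with at least one positive-length
#' edge.  Called by [read_newick()]; exported so programmatically built
#' trees (e.g. from [simulate_tree()]) can be checked with the same rules.
#'
#' @param tree A `"phylo"` object.
#' @param impute If `TRUE`, missing edge lengths become 0.
#' @return The validated (possibly imputed) tree, invisibly classed `"phylo"`.
#' @export
validate_phylogeny <- function(tree, impute = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  tips <- tree$tip.label
  if (any(!nzchar(tips))) stop("empty tip label")
  dup <- unique(tips[duplicated(tips)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  n_edge <- nrow(tree$edge)
  el <- tree$edge.length
  if (is.null(el)) el <- rep(NA_real_, n_edge)
  if (anyNA(el) | any(is.nan(el))) {
    if (impute) {
      el[!is.finite(el)] <- 0
      tree$edge.length <- el
    } else {
      stop("missing branch length on ", sum(!is.finite(el)), " edge(s); ",
           "set impute_lengths = TRUE to treat them as 0")
    }
  }
  if (length(el) != n_edge) stop("branch length count does not match edges")
  if (any(el < 0)) stop("negative branch length")
  if (sum(el) <= 0) stop("degenerate tree: total branch length is 0")
  # exactly one root node (basal multifurcations are fine)
  roots <- unique(tree$edge[!(tree$edge[, 1] %in% tree$edge[, 2]), 1])
  if (length(roots) != 1L) stop("tree must have exactly one root")
  tree
}

#' Phylogenetic covariance and correlation from a tree
#'
#' The phylogenetic covariance between two tips is the summed branch length
#' from the root to their most recent common ancestor (the expected shared
#' drift under Brownian motion); the diagonal holds root-to-tip distances.
#' The correlation matrix rescales it to unit diagonal,
#' `R[i,j] = V[i,j] / sqrt(V[i,i] * V[j,j])`.  Trees are not assumed
#' ultrametric: maximum-likelihood rRNA trees are not clock-like, so tips may
#' have different root-to-tip distances and standardization is done per pair.
#'
#' @param tree A `"phylo"` object passing [validate_phylogeny()].
#' @return An object of class `"phylo_vcv"`: a list with `labels` (tip order
#'   of the tree), `V` (covariance) and `R` (correlation).
#' @examples
#' pv <- vcv_from_tree(read_newick("((A:1,B:1):1,C:2);"))
#' pv$V
#' pv$R
#' @export
vcv_from_tree <- function(tree) {
  tree <- validate_phylogeny(tree)
  V <- ape::vcv(tree)
  ord <- match(tree$tip.label, rownames(V))
  V <- V[ord, ord, drop = FALSE]
  d <- diag(V)
  if (any(d <= 0))
    stop("zero root-to-tip distance for tip(s) ",
         paste(tree$tip.label[d <= 0], collapse = ", "),
         ": correlation undefined")
  R <- V / sqrt(outer(d, d))
  diag(R) <- 1
  structure(list(labels = tree$tip.label, V = V, R = R),
            class = "phylo_vcv")
}

#' @export
print.phylo_vcv <- function(x, ...) {
  cat("Phylogenetic covariance structure:", length(x$labels), "tips\n")
  cat("  root-to-tip distances:",
      paste(format(range(diag(x$V)), digits = 4), collapse = " - "), "\n")
  invisible(x)
}

#' Phylogenetic degrees of freedom
#'
#' Effective sample size used as the reference-distribution degrees of
#' freedom for Wald tests in [fit_gee()].  Implements the comparative-GEE
#' correction
#' \deqn{dfP = n \sum_e \ell_e / \sum_i V_{ii},}
#' the total branch length of the tree divided by the mean root-to-tip
#' distance.  For a star tree with equal branches this equals `n`
#' (independent tips); as tips become more correlated (long shared internal
#' edges, short terminal edges) it shrinks toward the number of effectively
#' independent lineages.
#'
#' @param tree A `"phylo"` object.
#' @return A single positive real, at most `n` only when correlation is
#'   absent; typically between 2 and `n`.
#' @examples
#' phylo_df(read_newick("(A:1,B:1,C:1,D:1);"))  # 4: independent tips
#' @export
phylo_df <- function(tree) {
  tree <- validate_phylogeny(tree)
  n <- length(tree$tip.label)
  V <- ape::vcv(tree)
  sum(tree$edge.length) * n / sum(diag(V))
}

#' Write / read a labeled square matrix as TSV
#'
#' Plain-text exchange format for covariance, correlation, identity and
#' divergence matrices: a header row of labels and a leading label column.
#'
#' @param m Square numeric matrix with identical row and column names.
#' @param path Output file.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            identical(rownames(m), colnames(m)))
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (!identical(rownames(m), colnames(m)))
    stop("matrix row and column labels differ")
  m
}
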