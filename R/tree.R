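#' Read a rooted phylogeny with branch lengths
#'
#' Thin, validating wrapper over [ape::read.tree()]. The phylogenetic
#' turnover statistics (betaMNTD, Faith PD) are undefined without branch
#' lengths, so by default every edge must carry one; `strict = FALSE`
#' replaces missing lengths with zero instead.
#'
#' @param path path to a newick file.
#' @param strict error on missing branch lengths (default `TRUE`).
#' @return A rooted `phylo` object with uniquely labelled tips.
#' @export
read_tree <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  validate_tree(tree, strict = strict)
}

#' Validate a phylogeny for use in this package
#' @param tree a `phylo` object.
#' @param strict error on missing branch lengths rather than zero-filling.
#' @return The (possibly length-filled) tree.
#' @export
validate_tree <- function(tree, strict = TRUE) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("tree has unlabeled tips")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (strict) stop("tree has edges without branch lengths (strict mode)")
    if (is.null(tree$edge.length)) tree$edge.length <- numeric(nrow(tree$edge))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Write a phylogeny as newick
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Tip-to-tip cophenetic distances
#'
#' Sum of branch lengths along the path between every pair of tips; the
#' substrate for betaMNTD and betaNTI.
#'
#' @param tree validated `phylo`.
#' @return Symmetric numeric matrix with tip labels as dimnames and zero
#'   diagonal.
#' @export
cophenetic_distances <- function(tree) {
  tree <- validate_tree(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Read or write a square distance matrix as TSV
#'
#' @param path file path.
#' @return `read_distance_matrix` returns a validated symmetric matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, quote = "")
  validate_distance_matrix(as.matrix(df))
}

#' @rdname read_distance_matrix
#' @param d symmetric matrix with ids as dimnames.
#' @export
write_distance_matrix <- function(d, path) {
  d <- validate_distance_matrix(d)
  df <- data.frame(id = rownames(d), d, check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_distance_matrix <- function(d, tol = 1e-8) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("distance matrix needs identical row/column ids")
  if (anyNA(d) || any(!is.finite(d))) stop("non-finite distances")
  if (any(d < -tol)) stop("negative distances")
  if (max(abs(d - t(d))) > tol) stop("distance matrix not symmetric")
  if (max(abs(diag(d))) > tol) stop("distance matrix diagonal not zero")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}
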