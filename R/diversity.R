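#' Per-sample alpha diversity: richness, Shannon, Faith PD
#'
#' Richness counts OTUs with positive reads; Shannon entropy uses natural
#' logarithms (nats); Faith PD sums the branch lengths spanned by the
#' sample's OTUs, including the path to the tree root (so the PD of the full
#' tip set equals the total branch length of the tree).
#'
#' @param table an [otu_table()].
#' @param tree a rooted `phylo`; every OTU with positive count must be a tip.
#' @return A tibble with columns `sample_id`, `richness`, `shannon`, `pd`.
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' tab <- otu_table(matrix(c(5L, 5L, 0L, 0L), ncol = 1,
#'                         dimnames = list(c("A", "B", "C", "D"), "s1")))
#' alpha_diversity(tab, tree)
#' @export
alpha_diversity <- function(table, tree) {
  stopifnot(is_otu_table(table))
  tree <- validate_tree(tree)
  present <- rownames(table)[rowSums(table) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("OTU(s) absent from the tree: ", paste(missing, collapse = ", "))
  rel <- relative_abundance(table)
  shannon <- apply(rel, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  tibble::tibble(sample_id = colnames(table),
                 richness = colSums(table > 0),
                 shannon = as.numeric(shannon),
                 pd = faith_pd(table, tree))
}

#' Faith phylogenetic diversity (root-inclusive)
#'
#' @param table an [otu_table()].
#' @param tree a rooted `phylo` containing every present OTU as a tip.
#' @return Numeric vector of PD values, one per sample.
#' @export
faith_pd <- function(table, tree) {
  tree <- validate_tree(tree)
  n_tip <- length(tree$tip.label)
  # parent edge index of every node (0 = root, has none)
  parent_edge <- integer(n_tip + tree$Nnode)
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  # edge path from each tip up to the root
  paths <- lapply(seq_len(n_tip), function(tip) {
    p <- integer(0)
    node <- tip
    while (parent_edge[node] != 0L) {
      e <- parent_edge[node]
      p <- c(p, e)
      node <- tree$edge[e, 1L]
    }
    p
  })
  names(paths) <- tree$tip.label
  vapply(seq_len(ncol(table)), function(j) {
    tips <- rownames(table)[table[, j] > 0]
    if (!length(tips)) return(0)
    sum(tree$edge.length[unique(unlist(paths[tips], use.names = FALSE))])
  }, numeric(1))
}

#' Pairwise beta diversity
#'
#' Bray-Curtis on counts (`sum |x - y| / sum (x + y)`) or Jaccard on
#' presence/absence (`1 - shared / union`), computed with [vegan::vegdist()].
#'
#' @param table an [otu_table()] with at least two samples and no all-zero
#'   sample.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return Square symmetric distance matrix with sample ids as dimnames.
#' @export
beta_distance <- function(table, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  stopifnot(is_otu_table(table))
  if (ncol(table) < 2L) stop("need at least 2 samples")
  if (any(colSums(table) == 0)) stop("all-zero sample(s) present")
  comm <- t(unclass(table))
  d <- switch(metric,
              bray_curtis = vegan::vegdist(comm, method = "bray"),
              jaccard = vegan::vegdist(comm, method = "jaccard", binary = TRUE))
  validate_distance_matrix(as.matrix(d))
}

#' Shared-OTU fractions across environments
#'
#' For every non-empty subset of environments, the fraction of all detected
#' OTUs present in exactly that subset (the Venn-region proportions of the
#' environment pools).
#'
#' @param presence logical matrix OTUs x environments (`TRUE` = detected), or
#'   a named list of [otu_table()]s / abundance vectors per environment over
#'   a common OTU set.
#' @return A tibble with `members` (environment subset, "+"-joined),
#'   `n_otus`, `fraction`; fractions sum to 1 over detected OTUs. The
#'   attribute `"unique_fraction"` gives the total fraction unique to a
#'   single environment.
#' @export
shared_otu_fractions <- function(presence) {
  if (is.list(presence)) {
    pres_vec <- lapply(presence, function(x) {
      if (is_otu_table(x) || is.matrix(x)) rowSums(as.matrix(x)) > 0 else x > 0
    })
    ids <- rownames(if (is.matrix(presence[[1]]) || is_otu_table(presence[[1]]))
      presence[[1]] else as.matrix(presence[[1]]))
    presence <- do.call(cbind, pres_vec)
    if (!is.null(ids)) rownames(presence) <- ids
  }
  storage.mode(presence) <- "logical"
  if (ncol(presence) < 2L) stop("need at least 2 environments")
  envs <- colnames(presence) %||% LETTERS[seq_len(ncol(presence))]
  detected <- presence[rowSums(presence) > 0, , drop = FALSE]
  n_total <- nrow(detected)
  if (n_total == 0L) stop("no OTU detected in any environment")
  key <- apply(detected, 1L, function(r) paste(envs[r], collapse = "+"))
  subsets <- unlist(lapply(seq_along(envs), function(k)
    utils::combn(envs, k, paste, collapse = "+")))
  counts <- table(factor(key, levels = subsets))
  out <- tibble::tibble(members = subsets,
                        n_otus = as.integer(counts),
                        fraction = as.numeric(counts) / n_total)
  attr(out, "unique_fraction") <- sum(out$fraction[out$members %in% envs])
  out
}

#' Rao quadratic entropy
#'
#' Expected dissimilarity between two randomly drawn individuals:
#' `Q = sum_i sum_j p_i p_j d_ij`. With the species-neutral dissimilarity
#' `d_ij = 1(i != j)` this reduces to Gini-Simpson diversity.
#'
#' @param abundances relative-abundance vector (sums to 1).
#' @param d symmetric dissimilarity matrix with zero diagonal, aligned with
#'   `abundances` (by names when both are named).
#' @return Rao Q (scalar).
#' @export
rao_quadratic_entropy <- function(abundances, d) {
  if (!is.null(names(abundances)) && !is.null(rownames(d))) {
    if (!all(names(abundances) %in% rownames(d)))
      stop("abundance names missing from dissimilarity matrix")
    d <- d[names(abundances), names(abundances), drop = FALSE]
  }
  if (length(abundances) != nrow(d)) stop("dimension mismatch")
  if (abs(sum(abundances) - 1) > 1e-8) stop("abundances must sum to 1")
  drop(crossprod(abundances, d %*% abundances))
}

# species-neutral dissimilarity 1(i != j)
neutral_dissimilarity <- function(ids) {
  d <- 1 - diag(length(ids))
  dimnames(d) <- list(ids, ids)
  d
}

#' Additive Rao partition of metacommunity diversity
#'
#' Decomposes ecosystem diversity (gamma) into the mean diversity of local
#' communities (alpha), the mean turnover within habitats (beta intra) and
#' the turnover between the water and gut habitats (beta inter), using Rao
#' quadratic entropy at every scale:
#' `gamma = alpha_local + beta_intra_habitats + beta_inter_habitats`.
#'
#' Habitats contribute with equal weight regardless of sample counts, and
#' pooled communities are means of their member relative-abundance vectors.
#' By default each Rao value is transformed to its equivalent number
#' `1 / (1 - Q)` before partitioning (Jost correction), which keeps every
#' beta component non-negative; `correction = FALSE` partitions raw Q.
#'
#' @param table an [otu_table()].
#' @param metadata validated metadata covering the table's samples.
#' @param d OTU dissimilarity matrix; defaults to species-neutral
#'   `1(i != j)`. Supply rescaled cophenetic distances for a phylogenetic
#'   partition.
#' @param scope `"all"` or a tank id to restrict the metacommunity.
#' @param correction apply the equivalent-numbers transform (default `TRUE`).
#' @return A tibble of class `"diversity_partition"` with the scope, the
#'   gamma/alpha/beta components and their fractions of gamma.
#' @export
partition_diversity <- function(table, metadata, d = NULL, scope = "all",
                                correction = TRUE) {
  stopifnot(is_otu_table(table))
  metadata <- tibble::as_tibble(metadata)
  keep <- if (identical(scope, "all")) metadata$sample_id
          else metadata$sample_id[metadata$tank == scope]
  keep <- intersect(colnames(table), keep)
  if (!length(keep)) stop("no samples in scope ", scope)
  meta <- metadata[match(keep, metadata$sample_id), ]
  habs <- c("water", "gut")
  if (!all(habs %in% meta$habitat))
    stop("scope '", scope, "' lacks habitat(s): ",
         paste(setdiff(habs, meta$habitat), collapse = ", "))
  rel <- relative_abundance(table)[, keep, drop = FALSE]
  if (is.null(d)) d <- neutral_dissimilarity(rownames(table))
  d <- validate_distance_matrix(d)[rownames(table), rownames(table)]
  q_raw <- function(p) drop(crossprod(p, d %*% p))
  # equivalent-numbers transform applied to the mean raw Q at each scale;
  # raw Rao is concave in p, so each level mean dominates the one below and
  # both beta terms stay non-negative under the monotone transform
  tf <- if (correction) function(v) 1 / (1 - v) else identity
  q_sample <- apply(rel, 2L, q_raw)
  alpha_h <- vapply(habs, function(h)
    mean(q_sample[meta$habitat == h]), numeric(1))
  pooled_h <- vapply(habs, function(h)
    rowMeans(rel[, meta$habitat == h, drop = FALSE]), numeric(nrow(rel)))
  gamma_h <- apply(pooled_h, 2L, q_raw)
  gamma_eco <- tf(q_raw(rowMeans(pooled_h)))
  alpha_local <- tf(mean(alpha_h))
  beta_intra <- tf(mean(gamma_h)) - alpha_local
  beta_inter <- gamma_eco - tf(mean(gamma_h))
  out <- tibble::tibble(scope = scope,
                        gamma_ecosystem = gamma_eco,
                        alpha_local = alpha_local,
                        beta_intra_habitats = beta_intra,
                        beta_inter_habitats = beta_inter,
                        frac_alpha = alpha_local / gamma_eco,
                        frac_beta_intra = beta_intra / gamma_eco,
                        frac_beta_inter = beta_inter / gamma_eco)
  class(out) <- c("diversity_partition", class(out))
  out
}
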