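#' Null-model configuration for the assembly-process analyses
#'
#' @param n_null number of null replicates (default 999, the convention of
#'   the betaNTI/Raup-Crick framework).
#' @param seed integer seed; each sample pair derives its own stream from
#'   `(seed, pair id)` so results are independent of iteration order.
#' @param bnti_threshold |betaNTI| beyond which turnover is attributed to
#'   selection (default 2).
#' @param rc_threshold |RC-bray| beyond which turnover is attributed to
#'   dispersal (default 0.95).
#' @return A list of class `"null_model_config"`.
#' @export
null_model_config <- function(n_null = 999L, seed = 1L,
                              bnti_threshold = 2, rc_threshold = 0.95) {
  if (n_null < 1L) stop("n_null must be at least 1")
  if (bnti_threshold <= 0 || rc_threshold <= 0) stop("thresholds must be positive")
  structure(list(n_null = as.integer(n_null), seed = as.integer(seed),
                 bnti_threshold = bnti_threshold, rc_threshold = rc_threshold),
            class = "null_model_config")
}

# align a (possibly named) abundance vector with distance-matrix ids and
# return 0-based present indices plus normalized weights
community_index <- function(x, ids) {
  if (!is.null(names(x))) x <- x[ids]
  if (length(x) != length(ids)) stop("community vector does not match OTU ids")
  x[is.na(x)] <- 0
  present <- which(x > 0)
  if (!length(present)) stop("empty community")
  list(idx = present - 1L, w = x[present] / sum(x[present]))
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' For each OTU in one community, the cophenetic distance to its nearest
#' relative in the other community, weighted by relative abundance and
#' averaged over both directions:
#' `0.5 * (sum_i x_i min_j d_ij + sum_j y_j min_i d_ij)`.
#' OTUs shared by both communities contribute distance zero.
#'
#' @param x,y abundance vectors (any non-negative scale; weights are
#'   normalized internally), named by OTU or aligned with `d`.
#' @param d cophenetic distance matrix covering all present OTUs.
#' @return betaMNTD in branch-length units.
#' @export
bmntd <- function(x, y, d) {
  d <- validate_distance_matrix(d)
  a <- community_index(x, rownames(d))
  b <- community_index(y, rownames(d))
  cpp_bmntd(a$idx, a$w, b$idx, b$w, d)
}

#' Beta nearest taxon index for one community pair
#'
#' z-score of the observed betaMNTD against a null distribution obtained by
#' shuffling taxa across the tips of the phylogeny (jointly permuting rows
#' and columns of the cophenetic matrix) while keeping abundances fixed.
#' betaNTI < -2 indicates less phylogenetic turnover than expected
#' (homogeneous selection), betaNTI > 2 more (heterogeneous selection).
#'
#' @param x,y abundance vectors named by OTU.
#' @param tree rooted phylogeny (ignored when `d` is given).
#' @param config a [null_model_config()].
#' @param d optional precomputed cophenetic matrix.
#' @param pair_label optional character id of the pair used to derive the
#'   null RNG stream; defaults to a hash-friendly canonical label built from
#'   the vectors' sample attribute or `"x::y"`.
#' @return A list with `bmntd_obs`, `bnti`, `null_mean`, `null_sd`.
#' @export
bnti <- function(x, y, tree = NULL, config = null_model_config(), d = NULL,
                 pair_label = "x::y") {
  if (config$n_null < 2L) stop("n_null must be >= 2 for a defined null sd")
  if (is.null(d)) d <- cophenetic_distances(tree)
  d <- validate_distance_matrix(d)
  a <- community_index(x, rownames(d))
  b <- community_index(y, rownames(d))
  obs <- cpp_bmntd(a$idx, a$w, b$idx, b$w, d)
  n <- nrow(d)
  P <- with_seed(derive_seed(config$seed, "bnti", pair_label), {
    m <- matrix(0L, config$n_null, n)
    for (r in seq_len(config$n_null)) m[r, ] <- sample.int(n) - 1L
    m
  })
  nulls <- cpp_bmntd_null(a$idx, a$w, b$idx, b$w, d, P)
  s <- stats::sd(nulls)
  if (!is.finite(s) || s == 0)
    stop("degenerate betaMNTD null (sd = 0); tip shuffle cannot randomize ",
         "this pair (e.g. identical communities or a star tree)")
  list(bmntd_obs = obs, bnti = (obs - mean(nulls)) / s,
       null_mean = mean(nulls), null_sd = s)
}

# one richness- and abundance-constrained null community: draw the observed
# richness without replacement with probability ~ occupancy, seed each drawn
# OTU with one read, then allocate the remaining reads ~ metacommunity
# relative abundance (uses the current RNG stream)
null_community <- function(n_otus, richness, reads, occ_freq, meta_p) {
  if (richness > sum(occ_freq > 0)) stop("richness exceeds available pool")
  idx <- sample.int(n_otus, richness, prob = occ_freq)
  out <- numeric(n_otus)
  out[idx] <- 1
  extra <- reads - richness
  if (extra > 0) {
    p <- meta_p[idx]
    if (sum(p) <= 0) p <- rep(1, length(idx))
    out[idx] <- out[idx] + stats::rmultinom(1L, extra, p)[, 1L]
  }
  out
}

#' Bray-Curtis-based Raup-Crick for one sample pair
#'
#' Compares the observed Bray-Curtis dissimilarity with a null distribution
#' in which each community is reassembled preserving its richness and read
#' total: membership is drawn without replacement with probability
#' proportional to OTU occupancy across the metacommunity table, and reads
#' are allocated proportional to metacommunity relative abundance. The
#' fraction of null values below the observed (ties half-weighted) is
#' rescaled to `[-1, 1]`; RC > 0.95 flags dispersal limitation, RC < -0.95
#' homogenizing dispersal.
#'
#' @param x,y count vectors named by OTU (or aligned with `table` rows).
#' @param table metacommunity [otu_table()] supplying occupancy and
#'   abundance weights.
#' @param config a [null_model_config()].
#' @param pair_label canonical pair id for the null RNG stream.
#' @return A list with `bc_obs` and `rc_bray`.
#' @export
rc_bray <- function(x, y, table, config = null_model_config(),
                    pair_label = "x::y") {
  stopifnot(is_otu_table(table))
  ids <- rownames(table)
  align <- function(v) {
    if (!is.null(names(v))) v <- v[ids]
    v[is.na(v)] <- 0
    as.numeric(v)
  }
  x <- align(x); y <- align(y)
  if (sum(x) <= 0 || sum(y) <= 0) stop("empty community")
  occ_freq <- rowSums(unclass(table) > 0)
  meta_p <- rowSums(unclass(table)); meta_p <- meta_p / sum(meta_p)
  bc_obs <- cpp_bray(x, y)
  kx <- sum(x > 0); ky <- sum(y > 0)
  nx <- round(sum(x)); ny <- round(sum(y))
  n <- length(ids)
  res <- with_seed(derive_seed(config$seed, "rc", pair_label), {
    lt <- 0; eq <- 0
    for (r in seq_len(config$n_null)) {
      bx <- null_community(n, kx, nx, occ_freq, meta_p)
      by <- null_community(n, ky, ny, occ_freq, meta_p)
      b <- cpp_bray(bx, by)
      if (b < bc_obs - 1e-12) lt <- lt + 1
      else if (abs(b - bc_obs) <= 1e-12) eq <- eq + 1
    }
    c(lt = lt, eq = eq)
  })
  rc <- 2 * ((res[["lt"]] + 0.5 * res[["eq"]]) / config$n_null) - 1
  list(bc_obs = bc_obs, rc_bray = rc)
}

#' Classify the assembly process of a community pair
#'
#' Hierarchical rule set: selection first (betaNTI beyond +/- the betaNTI
#' threshold gives heterogeneous/homogeneous selection), then dispersal
#' (RC-bray beyond +/- the RC threshold gives dispersal limitation /
#' homogenizing dispersal), otherwise undominated (weak selection, weak
#' dispersal, diversification, drift).
#'
#' @param bnti numeric vector of betaNTI z-scores.
#' @param rc numeric vector of RC-bray values in `[-1, 1]`.
#' @param config a [null_model_config()] supplying the thresholds.
#' @return Factor with levels `heterogeneous_selection`,
#'   `homogeneous_selection`, `dispersal_limitation`,
#'   `homogenizing_dispersal`, `undominated`.
#' @export
classify_process <- function(bnti, rc, config = null_model_config()) {
  if (anyNA(bnti) || anyNA(rc)) stop("NaN/NA betaNTI or RC input")
  if (any(rc < -1 - 1e-9 | rc > 1 + 1e-9)) stop("RC values must lie in [-1, 1]")
  t <- config$bnti_threshold; rt <- config$rc_threshold
  out <- ifelse(bnti > t, "heterogeneous_selection",
         ifelse(bnti < -t, "homogeneous_selection",
         ifelse(rc > rt, "dispersal_limitation",
         ifelse(rc < -rt, "homogenizing_dispersal", "undominated"))))
  factor(out, levels = process_levels())
}

process_levels <- function() c("heterogeneous_selection", "homogeneous_selection",
                               "dispersal_limitation", "homogenizing_dispersal",
                               "undominated")

#' Pairwise turnover table: betaMNTD, betaNTI, Bray-Curtis, RC-bray, process
#'
#' Runs the full pairwise inference for every within-group sample pair
#' (default grouping: developmental stage; gut samples only, pooled across
#' tanks and cages). Each pair's null streams derive from
#' `(seed, canonical pair id)`.
#'
#' @param table rarefied [otu_table()] (the analysis metacommunity).
#' @param tree rooted phylogeny covering the table's OTUs.
#' @param metadata validated metadata; pairs are formed within levels of
#'   `group_by` among samples with `habitat == "gut"` (set
#'   `habitat = NULL` to use all samples).
#' @param group_by metadata column defining the pairing universe
#'   (default `"stage"`).
#' @param config a [null_model_config()].
#' @param habitat habitat filter (default `"gut"`).
#' @return A tibble with one row per pair: `sample_a`, `sample_b`, `group`,
#'   `bmntd_obs`, `bnti`, `bc_obs`, `rc_bray`, `process`.
#' @export
pairwise_turnover <- function(table, tree, metadata, group_by = "stage",
                              config = null_model_config(), habitat = "gut") {
  stopifnot(is_otu_table(table))
  metadata <- tibble::as_tibble(metadata)
  meta <- metadata[metadata$sample_id %in% colnames(table), ]
  if (!is.null(habitat)) meta <- meta[meta$habitat %in% habitat, ]
  if (!group_by %in% names(meta)) stop("unknown grouping column: ", group_by)
  d <- cophenetic_distances(tree)[rownames(table), rownames(table)]
  groups <- split(meta$sample_id, meta[[group_by]])
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  if (!length(groups)) stop("no group with at least 2 samples")
  rows <- list()
  for (g in names(groups)) {
    ss <- sort(groups[[g]])
    for (i in seq_len(length(ss) - 1L)) for (j in (i + 1L):length(ss)) {
      a <- ss[i]; b <- ss[j]
      pid <- pair_id(a, b)
      bn <- bnti(table[, a], table[, b], config = config, d = d,
                 pair_label = pid)
      rcv <- rc_bray(table[, a], table[, b], table, config = config,
                     pair_label = pid)
      rows[[pid]] <- tibble::tibble(sample_a = a, sample_b = b, group = g,
                                    bmntd_obs = bn$bmntd_obs, bnti = bn$bnti,
                                    bc_obs = rcv$bc_obs, rc_bray = rcv$rc_bray)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$process <- classify_process(out$bnti, out$rc_bray, config)
  out
}

#' Per-group assembly-process profile
#'
#' Fraction of sample pairs assigned to each of the five processes within
#' each group (the per-stage process bars of the succession analysis).
#'
#' @param turnovers output of [pairwise_turnover()] (needs columns `group`
#'   and `process`).
#' @return A tibble with `group`, `process`, `n_pairs`, `fraction`;
#'   fractions sum to 1 within each group.
#' @export
process_profile <- function(turnovers) {
  if (!all(c("group", "process") %in% names(turnovers)))
    stop("turnovers must have 'group' and 'process' columns")
  if (!nrow(turnovers)) stop("empty turnover table")
  tab <- table(turnovers$group,
               factor(turnovers$process, levels = process_levels()))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "process", "n_pairs")
  totals <- stats::ave(out$n_pairs, out$group, FUN = sum)
  if (any(totals == 0)) stop("empty group in turnover table")
  out$fraction <- out$n_pairs / totals
  tibble::as_tibble(out[order(out$group, match(out$process, process_levels())), ])
}
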