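# distinct permutations helper: all n! orderings (used when exhaustive
# enumeration is cheaper than sampling)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance for a single grouping
#' factor: `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, and
#' `pseudo-F = (SS_between / (g - 1)) / (SS_within / (n - g))`. Significance
#' is assessed by permuting sample labels; when `n!` does not exceed
#' `n_perm` all distinct permutations are enumerated and the p-value is
#' exact, otherwise `n_perm` random permutations are drawn and the p-value
#' carries the +1 correction (so it is never 0).
#'
#' @param d square distance matrix with sample ids.
#' @param labels grouping vector aligned with `d` (or named by sample id).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return A list of class `"permanova_result"`: `factor_label`, `pseudo_F`,
#'   `p_value`, `n_perm`, `exhaustive`, `df`.
#' @export
permanova <- function(d, labels, n_perm = 999L, seed = 1L) {
  d <- validate_distance_matrix(d)
  if (!is.null(names(labels))) labels <- labels[rownames(d)]
  labels <- as.character(labels)
  n <- nrow(d)
  if (length(labels) != n) stop("labels must match the distance matrix")
  grp <- factor(labels)
  g <- nlevels(grp)
  if (g < 2L) stop("need at least 2 groups")
  if (any(table(grp) < 2L)) stop("every group needs at least 2 samples")
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  if (ss_total <= 1e-12) stop("degenerate input: all samples identical (SS_total = 0)")
  f_stat <- function(gl) {
    ss_w <- 0
    for (lev in levels(gl)) {
      idx <- which(gl == lev)
      ss_w <- ss_w + sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }
    ss_b <- ss_total - ss_w
    if (ss_w <= 1e-12) return(Inf)
    (ss_b / (g - 1)) / (ss_w / (n - g))
  }
  f_obs <- f_stat(grp)
  exhaustive <- factorial(n) <= n_perm
  if (is.infinite(f_obs)) {
    p <- 1 / (1 + n_perm)
    return(structure(list(factor_label = deparse(substitute(labels)),
                          pseudo_F = Inf, p_value = p, n_perm = n_perm,
                          exhaustive = FALSE, df = c(g - 1L, n - g),
                          note = "SS_within = 0; minimum attainable p reported"),
                     class = "permanova_result"))
  }
  if (exhaustive) {
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1L, function(o) f_stat(grp[o]))
    p <- mean(f_perm >= f_obs - 1e-12)
  } else {
    f_perm <- with_seed(derive_seed(seed, "permanova"), {
      vapply(seq_len(n_perm), function(r) f_stat(grp[sample.int(n)]), numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  }
  structure(list(factor_label = NA_character_, pseudo_F = f_obs, p_value = p,
                 n_perm = n_perm, exhaustive = exhaustive,
                 df = c(g - 1L, n - g)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), p = %.4g%s\n",
              x$pseudo_F, x$df[1], x$df[2], x$p_value,
              if (x$exhaustive) " [exhaustive]" else ""))
  invisible(x)
}

lower_vec <- function(m) m[lower.tri(m)]

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the off-diagonal pairs, with one-sided
#' significance (`r_perm >= r_obs`) from permuting the ids of the first
#' matrix. Exhaustive over all `n!` permutations when that is no more work
#' than `n_perm` random draws (exact p); otherwise +1-corrected.
#'
#' @param a,b square distance matrices over the same ids (aligned by
#'   dimnames when present).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return A list of class `"mantel_result"`: `statistic` (r), `p_value`,
#'   `n_perm`, `exhaustive`, `controlled` (NA for the plain test).
#' @export
mantel <- function(a, b, n_perm = 999L, seed = 1L) {
  a <- validate_distance_matrix(a)
  b <- align_to(a, b)
  va <- lower_vec(a); vb <- lower_vec(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance in a distance matrix")
  r_obs <- stats::cor(va, vb)
  n <- nrow(a)
  r_perm_fun <- function(o) stats::cor(lower_vec(a[o, o]), vb)
  res <- perm_pvalue(r_perm_fun, r_obs, n, n_perm, derive_seed(seed, "mantel"))
  structure(list(statistic = r_obs, p_value = res$p, n_perm = n_perm,
                 exhaustive = res$exhaustive, controlled = NA_character_),
            class = "mantel_result")
}

#' Partial Mantel test
#'
#' Correlation between `a` and `b` controlling for `c`:
#' `r(AB.C) = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))`,
#' with significance from permuting the ids of `a` (recomputing `r_AB` and
#' `r_AC` each time).
#'
#' @param a,b,c square distance matrices over the same ids.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return A `"mantel_result"` with `controlled = "c"`.
#' @export
partial_mantel <- function(a, b, c, n_perm = 999L, seed = 1L) {
  a <- validate_distance_matrix(a)
  b <- align_to(a, b)
  c <- align_to(a, c)
  vb <- lower_vec(b); vc <- lower_vec(c)
  partial_r <- function(va) {
    r_ab <- stats::cor(va, vb); r_ac <- stats::cor(va, vc)
    r_bc <- stats::cor(vb, vc)
    den <- sqrt((1 - r_ac^2) * (1 - r_bc^2))
    num <- r_ab - r_ac * r_bc
    if (den < 1e-12) {
      # b == c collapses both numerator and denominator; the limit is 0
      if (abs(num) < 1e-12) return(0)
      stop("undefined partial correlation: |r_AC| or |r_BC| = 1")
    }
    num / den
  }
  r_obs <- partial_r(lower_vec(a))
  n <- nrow(a)
  res <- perm_pvalue(function(o) partial_r(lower_vec(a[o, o])), r_obs, n,
                     n_perm, derive_seed(seed, "partial_mantel"))
  structure(list(statistic = r_obs, p_value = res$p, n_perm = n_perm,
                 exhaustive = res$exhaustive, controlled = "c"),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  lab <- if (is.na(x$controlled)) "Mantel" else "Partial Mantel"
  cat(sprintf("%s: r = %.4f, p = %.4g%s\n", lab, x$statistic, x$p_value,
              if (x$exhaustive) " [exhaustive]" else ""))
  invisible(x)
}

align_to <- function(a, b) {
  b <- validate_distance_matrix(b)
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!setequal(rownames(a), rownames(b))) stop("matrices cover different ids")
    b <- b[rownames(a), rownames(a)]
  } else if (nrow(a) != nrow(b)) stop("matrices differ in size")
  b
}

perm_pvalue <- function(stat_fun, obs, n, n_perm, seed) {
  if (factorial(n) <= n_perm) {
    perms <- all_permutations(n)
    vals <- apply(perms, 1L, stat_fun)
    list(p = mean(vals >= obs - 1e-12), exhaustive = TRUE)
  } else {
    vals <- with_seed(seed, vapply(seq_len(n_perm),
                                   function(r) stat_fun(sample.int(n)),
                                   numeric(1)))
    list(p = (1 + sum(vals >= obs - 1e-12)) / (1 + n_perm), exhaustive = FALSE)
  }
}

#' One-way ANOVA with LSD letters
#'
#' Fisher's least-significant-difference comparison after a one-way ANOVA:
#' pairwise t-tests on the pooled mean squared error, deliberately
#' unadjusted for multiplicity (that is what LSD is), summarised as a
#' compact letter display in which groups sharing a letter do not differ
#' significantly at `alpha`.
#'
#' @param values numeric response vector.
#' @param groups grouping vector (>= 2 groups, each with >= 2 observations).
#' @param alpha significance level for the LSD comparisons (default 0.05).
#' @return A list of class `"anova_lsd"`: `anova` (F, df, p), `means`
#'   (tibble with group, n, mean, se, letters), `alpha`.
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  grp <- factor(groups)
  if (nlevels(grp) < 2L) stop("need at least 2 groups")
  if (any(table(grp) < 2L)) stop("every group needs at least 2 observations")
  fit <- stats::aov(values ~ grp)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  means <- tapply(values, grp, mean)
  ns <- tapply(values, grp, length)
  ord <- order(means, decreasing = TRUE)
  levs <- levels(grp)[ord]
  m <- means[ord]; nn <- ns[ord]
  k <- length(levs)
  nonsig <- matrix(TRUE, k, k, dimnames = list(levs, levs))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (mse <= 0) { nonsig[i, j] <- nonsig[j, i] <- TRUE; next }
    tval <- abs(m[i] - m[j]) / sqrt(mse * (1 / nn[i] + 1 / nn[j]))
    p <- 2 * stats::pt(tval, df_err, lower.tail = FALSE)
    nonsig[i, j] <- nonsig[j, i] <- p > alpha
  }
  # letters from maximal runs of mutually non-significant, mean-ordered groups
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(nonsig[i:(j + 1L), i:(j + 1L)])) j <- j + 1L
    runs[[length(runs) + 1L]] <- i:j
  }
  keep <- !vapply(seq_along(runs), function(r) any(vapply(seq_along(runs),
    function(s) s != r && all(runs[[r]] %in% runs[[s]]), logical(1))),
    logical(1))
  runs <- runs[keep]
  letters_by_group <- stats::setNames(rep("", k), levs)
  for (r in seq_along(runs))
    for (i in runs[[r]])
      letters_by_group[i] <- paste0(letters_by_group[i], letters[r])
  se <- sqrt(tapply(values, grp, stats::var) / ns)[ord]
  structure(list(anova = list(F = an["grp", "F value"],
                              df = c(an["grp", "Df"], df_err),
                              p_value = an["grp", "Pr(>F)"]),
                 means = tibble::tibble(group = levs, n = as.integer(nn),
                                        mean = as.numeric(m),
                                        se = as.numeric(se),
                                        letters = unname(letters_by_group)),
                 alpha = alpha),
            class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g; LSD at alpha = %g\n",
              x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p_value, x$alpha))
  print(x$means)
  invisible(x)
}

#' Variance explained and hierarchical partitioning for alpha diversity
#'
#' Fits ordinary least squares on dummy-coded categorical factors and
#' reports, per factor, the marginal R-squared (single-factor model) and the
#' hierarchical-partitioning independent contribution (Chevan-Sutherland:
#' the increase in R-squared from adding the factor, averaged over all
#' subsets of the remaining factors within each subset size and then across
#' sizes). Independent contributions sum to the full-model R-squared; they
#' are also reported as percentages of that total.
#'
#' @param alpha output of [alpha_diversity()] (or any data frame with
#'   `sample_id` and the response column).
#' @param metadata metadata supplying the factor columns.
#' @param response one of `"pd"`, `"richness"`, `"shannon"` (or any numeric
#'   column of `alpha`).
#' @param factors metadata columns to partition over (default stage,
#'   rearing environment, transition, food).
#' @return A tibble with `factor_label`, `r2_marginal`, `independent`,
#'   `joint`, `independent_pct`; attribute `"r2_full"` carries the
#'   full-model R-squared.
#' @export
variance_partition <- function(alpha, metadata,
                               response = c("pd", "richness", "shannon"),
                               factors = c("stage", "rear_env", "transition",
                                           "food")) {
  response <- if (length(response) > 1L) match.arg(response) else response
  df <- merge(as.data.frame(alpha), as.data.frame(metadata), by = "sample_id")
  if (!response %in% names(df)) stop("response column not found: ", response)
  for (f in factors) {
    if (!f %in% names(df)) stop("factor column not found: ", f)
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2L)
      stop("factor has fewer than 2 levels in these samples: ", f)
  }
  df <- df[stats::complete.cases(df[, c(response, factors)]), ]
  r2 <- function(vars) {
    if (!length(vars)) return(0)
    fit <- stats::lm(stats::reformulate(vars, response), data = df)
    if (anyNA(stats::coef(fit)[-1]))
      stop("aliased/collinear factor levels among: ", paste(vars, collapse = ", "))
    summary(fit)$r.squared
  }
  k <- length(factors)
  subsets <- lapply(0:(2^k - 1), function(m) factors[bitwAnd(m, 2^(0:(k - 1))) > 0])
  r2_cache <- stats::setNames(vapply(subsets, r2, numeric(1)),
                              vapply(subsets, function(v)
                                paste0("S:", paste(sort(v), collapse = "+")),
                                character(1)))
  r2_of <- function(v) r2_cache[[paste0("S:", paste(sort(v), collapse = "+"))]]
  indep <- vapply(factors, function(f) {
    others <- setdiff(factors, f)
    by_size <- vapply(0:length(others), function(sz) {
      combs <- if (sz == 0) list(character(0)) else
        utils::combn(others, sz, simplify = FALSE)
      mean(vapply(combs, function(S) r2_of(c(S, f)) - r2_of(S), numeric(1)))
    }, numeric(1))
    mean(by_size)
  }, numeric(1))
  marginal <- vapply(factors, function(f) r2_of(f), numeric(1))
  full <- r2_of(factors)
  out <- tibble::tibble(factor_label = factors,
                        r2_marginal = as.numeric(marginal),
                        independent = as.numeric(indep),
                        joint = as.numeric(marginal - indep),
                        independent_pct = 100 * as.numeric(indep) / sum(indep))
  attr(out, "r2_full") <- full
  attr(out, "response") <- response
  out
}
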