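# shared fixtures, all built in code

# the 4-tip worked example used throughout: ((A:1,B:1):1,(C:1,D:1):1);
example_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# small random OTU table with positive column sums
random_table <- function(n_otus, n_samples, seed, lambda = 5) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_otus * n_samples, lambda), n_otus, n_samples,
                dimnames = list(sprintf("OTU%03d", seq_len(n_otus)),
                                sprintf("s%02d", seq_len(n_samples))))
    m[, colSums(m) == 0] <- m[, colSums(m) == 0] + 1L
    otu_table(m)
  })
}

# random tree whose tips match a table's OTU ids
random_tree_for <- function(table, seed) {
  withr::with_seed(seed, {
    tree <- ape::rtree(nrow(table))
    tree$tip.label <- rownames(table)
    tree
  })
}

# canonical pair label matching the package's null-stream derivation
pair_id_for_test <- function(a, b) paste(sort(c(a, b)), collapse = "::")

# naive double-loop betaMNTD oracle (independent of the C++ path)
bmntd_oracle <- function(x, y, d) {
  x <- x / sum(x); y <- y / sum(y)
  ix <- which(x > 0); iy <- which(y > 0)
  left <- sum(vapply(ix, function(i) x[i] * min(d[i, iy]), numeric(1)))
  right <- sum(vapply(iy, function(j) y[j] * min(d[ix, j]), numeric(1)))
  0.5 * (left + right)
}

# brute-force tip-to-tip path distance by walking the edge list
path_distance_oracle <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(NA_real_, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (src in seq_len(n)) {
    dist <- rep(Inf, nn); dist[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]; w <- adj[[v]][k, 2]
        if (dist[v] + w < dist[u] - 1e-15) {
          dist[u] <- dist[v] + w
          queue <- c(queue, u)
        }
      }
    }
    d[src, ] <- dist[seq_len(n)]
  }
  d
}

# tiny simulated study used by several structural tests
tiny_study <- function(seed = 7, n_otus = 120, depth = 800, replicates = 1,
                       dph = c(12L, 42L, 98L), ...) {
  simulate_study(simulation_config(n_otus = n_otus, depth = depth,
                                   replicates = replicates,
                                   dph_schedule = dph, seed = seed, ...))
}
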