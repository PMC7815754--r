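#' Configuration for the synthetic metacommunity generator
#'
#' Builds the full parameter set for [simulate_study()], defaulting to the
#' hatch/transition design the package emulates: three water environments
#' (A, B, C) with mostly environment-unique OTU pools, fish hatched in each
#' environment and reared in each environment (3 x 3 cages across 3 tanks),
#' seven sampling ages from 12 to 98 dph grouped into three developmental
#' stages, and stage-dependent host selection acting on a phylogenetically
#' conserved trait so that the betaNTI/RC-bray pipeline can recover the
#' selection gradient.
#'
#' The community model for a gut sample is a colonization-establishment-
#' drift-immigration chain (see [simulate_gut_sample()]): a limited number
#' of lineages (`host_capacity`) colonize the host, with establishment odds
#' sharpened by repeated selective challenges
#' (`((1-s) + s w)^establishment_sharpness` on the Gaussian trait filter
#' `w`); established lineages drift to host-specific abundances
#' (`host_drift_sd`); a small transient fraction (`dispersal_rate` of reads,
#' spread over `immigrant_richness` lineages) arrives from the source pool.
#'
#' Key defaults: the OTU pools reproduce the observed environment overlap
#' (63.7% of OTUs unique to one environment, each shared Venn region within
#' 3-14.5%); per-stage selection strengths (0.3, 0.6, 0.8) encode host
#' selection increasing with development; `depth` matches the 14,666-read
#' library normalisation.
#'
#' @param n_otus number of OTUs in the regional pool.
#' @param pool_unique_frac total fraction of OTUs unique to one environment.
#' @param pool_pair_frac fraction of OTUs shared by exactly one environment
#'   pair (per pair); the remainder is shared by all three.
#' @param pool_lognorm_sd sdlog of the log-normal pool abundances.
#' @param dph_schedule sampled ages, days post-hatching (strictly increasing).
#' @param replicates gut replicates per cage per timepoint.
#' @param depth reads per sample.
#' @param selection_strength_by_stage named numeric, s in `[0,1]` per stage.
#' @param selection_sd width sigma of the Gaussian trait filter (trait units).
#' @param dispersal_rate fraction of gut reads that are transient immigrants
#'   from the source pool.
#' @param immigrant_richness number of distinct lineages in the transient
#'   immigrant fraction of one sample (`Inf` = the whole source pool, the
#'   mass-effects regime).
#' @param host_capacity number of lineages that can establish in one host
#'   (`Inf` disables the colonization bottleneck).
#' @param establishment_sharpness exponent on the selection kernel during
#'   colonization (repeated-challenge establishment).
#' @param colonization_exp exponent on pool abundance during colonization
#'   (< 1: establishment is less abundance-dependent than residence).
#' @param abundance_exp exponent flattening the selection-kernel weights
#'   when allocating resident abundances.
#' @param host_drift_sd sdlog of the host-to-host log-normal drift of
#'   resident abundances.
#' @param trait_rate Brownian-motion rate of the within-clade trait wiggle.
#' @param niche_separation spacing of the (equally spaced) deep-clade niche
#'   centers on the trait axis; stage optima sit at these centers.
#' @param crown_depth depth of the three deep clades relative to total tree
#'   depth 1 (stems have length `1 - crown_depth`).
#' @param water_jitter_sd sdlog of the per-timepoint log-normal jitter
#'   applied to water pools.
#' @param env_pool_mode `"distinct"` for environment-specific pools,
#'   `"shared"` for a single well-mixed pool in all environments.
#' @param cage_pool_frac fraction of pool OTUs available to each cage
#'   (1 = fully connected; < 1 imposes between-cage dispersal limitation).
#' @param seed integer seed; every stochastic stage derives its stream from it.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_otus = 600L,
                              pool_unique_frac = 0.637,
                              pool_pair_frac = 0.073,
                              pool_lognorm_sd = 1.5,
                              dph_schedule = c(12L, 20L, 27L, 42L, 56L, 70L, 98L),
                              replicates = 3L,
                              depth = 14666L,
                              selection_strength_by_stage = c(S1 = 0.3, S2 = 0.6, S3 = 0.8),
                              selection_sd = 0.8,
                              dispersal_rate = 0.05,
                              immigrant_richness = 10,
                              host_capacity = 25,
                              establishment_sharpness = 4,
                              colonization_exp = 0.25,
                              abundance_exp = 0.5,
                              host_drift_sd = 0.8,
                              trait_rate = 1,
                              niche_separation = 2,
                              crown_depth = 0.2,
                              water_jitter_sd = 0.3,
                              env_pool_mode = c("distinct", "shared"),
                              cage_pool_frac = 1,
                              seed = 1L) {
  env_pool_mode <- match.arg(env_pool_mode)
  cfg <- list(n_otus = as.integer(n_otus),
              pool_unique_frac = pool_unique_frac,
              pool_pair_frac = pool_pair_frac,
              pool_lognorm_sd = pool_lognorm_sd,
              dph_schedule = as.integer(dph_schedule),
              tanks = c("A", "B", "C"), cages_per_tank = 3L,
              replicates = as.integer(replicates),
              depth = as.integer(depth),
              selection_strength_by_stage = selection_strength_by_stage,
              selection_sd = selection_sd,
              dispersal_rate = dispersal_rate,
              immigrant_richness = immigrant_richness,
              host_capacity = host_capacity,
              establishment_sharpness = establishment_sharpness,
              colonization_exp = colonization_exp,
              abundance_exp = abundance_exp,
              host_drift_sd = host_drift_sd,
              trait_rate = trait_rate,
              niche_separation = niche_separation,
              crown_depth = crown_depth,
              water_jitter_sd = water_jitter_sd,
              env_pool_mode = env_pool_mode,
              cage_pool_frac = cage_pool_frac,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  props <- c(cfg$pool_unique_frac, cfg$pool_pair_frac, cfg$dispersal_rate,
             cfg$cage_pool_frac)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (cfg$pool_unique_frac + 3 * cfg$pool_pair_frac > 1 + 1e-12)
    stop("pool_unique_frac + 3 * pool_pair_frac must not exceed 1")
  if (is.unsorted(cfg$dph_schedule, strictly = TRUE))
    stop("dph_schedule must be strictly increasing")
  stages <- unique(stage_from_dph(cfg$dph_schedule))
  s <- cfg$selection_strength_by_stage
  if (is.null(names(s)) || !all(stages %in% names(s)))
    stop("selection_strength_by_stage needs one named value per sampled stage")
  if (any(s < 0 | s > 1)) stop("selection strengths must lie in [0, 1]")
  if (cfg$selection_sd <= 0) stop("selection_sd must be positive")
  if (cfg$trait_rate <= 0) stop("trait_rate must be positive")
  if (cfg$n_otus < 3L) stop("n_otus must be at least 3")
  if (cfg$depth < 1L) stop("depth must be positive")
  if (cfg$crown_depth <= 0 || cfg$crown_depth >= 1)
    stop("crown_depth must lie in (0, 1)")
  if (cfg$host_capacity < 1) stop("host_capacity must be at least 1")
  class(cfg) <- "simulation_config"
  cfg
}

# balanced rooted topology for any number of tips (recursive halving)
balanced_newick <- function(m, prefix) {
  if (m == 1L) return(prefix())
  paste0("(", balanced_newick(m %/% 2L, prefix), ",",
         balanced_newick(m - m %/% 2L, prefix), ")")
}

#' Simulate the reference phylogeny: three deep clades
#'
#' Builds an ultrametric tree (total depth 1) with three equally sized,
#' identically shaped balanced clades joined by long stems, mimicking the
#' deep clade structure of real 16S phylogenies (few ancient lineages
#' separated by long internal branches, many shallow divergences within).
#' The deep clades are the substrate of the stage-specific host niches: a
#' Brownian trait on this tree is far more similar within than between
#' clades, which is what the betaNTI null model detects. The topology is a
#' deterministic function of `n_otus`; `seed` is accepted for interface
#' symmetry with the other generator stages.
#'
#' @param n_otus number of tips (>= 3).
#' @param seed integer seed (the topology does not consume randomness).
#' @param clades number of deep clades (default 3, one per developmental
#'   stage).
#' @param crown_depth depth of each clade relative to total depth 1.
#' @return A rooted ultrametric `phylo` with tips `OTU_0001`, ... grouped by
#'   clade in label order.
#' @export
simulate_phylogeny <- function(n_otus, seed = 1L, clades = 3L,
                               crown_depth = 0.2) {
  if (n_otus < 3L) stop("n_otus must be at least 3")
  if (clades < 2L || clades > n_otus) stop("invalid number of clades")
  sizes <- diff(round(seq(0, n_otus, length.out = clades + 1L)))
  counter <- local({ i <- 0L; function() { i <<- i + 1L; sprintf("OTU_%04d", i) } })
  stem <- 1 - crown_depth
  sub <- vapply(sizes, function(m) {
    nwk <- balanced_newick(m, counter)
    if (m == 1L) return(paste0(nwk, ":1"))  # single tip: whole depth on stem
    st <- ape::read.tree(text = paste0(nwk, ";"))
    st <- ape::compute.brlen(st, method = "Grafen")  # ultrametric crown
    st$edge.length <- st$edge.length * crown_depth /
      max(ape::node.depth.edgelength(st))
    paste0(sub(";$", "", ape::write.tree(st)), ":", format(stem, digits = 15))
  }, character(1))
  # nest clades under zero-length internal edges so the root is binary
  # (ape treats a basal multichotomy as unrooted) while keeping all
  # inter-clade distances equal
  nwk <- sub[length(sub)]
  for (i in (length(sub) - 1L):1L)
    nwk <- paste0("(", sub[i], ",", nwk, "):0")
  nwk <- sub(":0$", ";", nwk)
  tree <- ape::read.tree(text = nwk)
  # absorb newick text rounding so total depth is exactly 1
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  validate_tree(tree)
}

#' Simulate a Brownian trait on a phylogeny
#'
#' One continuous, heritable trait per OTU (think: suitability for the gut
#' environment) evolved by Brownian motion from a root value of 0, so close
#' relatives carry similar values.
#'
#' @param tree a `phylo`.
#' @param rate Brownian rate (variance per unit branch length, > 0).
#' @param seed integer seed.
#' @return Named numeric vector of tip trait values.
#' @export
simulate_traits <- function(tree, rate = 1, seed = 1L) {
  if (rate <= 0) stop("rate must be positive")
  tree <- validate_tree(tree)
  tr <- with_seed(derive_seed(seed, "traits"),
                  phytools::fastBM(tree, sig2 = rate, a = 0))
  tr[tree$tip.label]
}

# tips of each deep clade: subtrees hanging off the zero-depth backbone
# (the backbone joins the clade stems with zero-length internal edges)
root_clades <- function(tree) {
  nd <- ape::node.depth.edgelength(tree)
  stems <- which(nd[tree$edge[, 1L]] < 1e-12 & tree$edge.length > 1e-12)
  kids <- tree$edge[stems, 2L]
  lapply(kids[order(kids)], function(k) {
    if (k <= length(tree$tip.label)) return(tree$tip.label[k])
    ape::extract.clade(tree, k)$tip.label
  })
}

# study trait: Brownian wiggle recentered on equally spaced deep-clade niche
# centers (clade k center = (k - (K+1)/2) * separation)
niche_trait <- function(tree, rate, niche_separation, seed) {
  bm <- simulate_traits(tree, rate, seed)
  clades <- root_clades(tree)
  k <- length(clades)
  centers <- (seq_len(k) - (k + 1) / 2) * niche_separation
  tr <- bm
  for (i in seq_len(k)) {
    tips <- clades[[i]]
    tr[tips] <- centers[i] + (bm[tips] - mean(bm[tips]))
  }
  list(trait = tr, centers = centers, clades = clades)
}

#' Simulate the three environment source pools
#'
#' Assigns every OTU to a Venn region of the three environments (unique to
#' one, shared by a pair, shared by all) according to the configured
#' fractions, then gives each environment log-normal relative abundances on
#' its member set. With `env_pool_mode = "shared"` all environments receive
#' one identical well-mixed pool.
#'
#' @param config a [simulation_config()].
#' @param tree phylogeny supplying OTU ids (its tip labels).
#' @param seed integer seed (defaults to the config seed).
#' @return Numeric matrix `n_otus x 3` (columns A, B, C); columns sum to 1,
#'   zeros mark non-members.
#' @export
simulate_water_pools <- function(config, tree, seed = config$seed) {
  config <- validate_simulation_config(unclass(config))
  ids <- tree$tip.label
  n <- length(ids)
  envs <- c("A", "B", "C")
  pools <- matrix(0, n, 3L, dimnames = list(ids, envs))
  if (config$env_pool_mode == "shared") {
    ab <- with_seed(derive_seed(seed, "pools", "shared"),
                    stats::rlnorm(n, 0, config$pool_lognorm_sd))
    for (e in envs) pools[, e] <- ab / sum(ab)
    return(pools)
  }
  n_u <- round(config$pool_unique_frac * n / 3)
  n_p <- round(config$pool_pair_frac * n)
  n_all <- n - 3L * n_u - 3L * n_p
  if (n_all < 0L) stop("pool fractions leave no OTUs for the all-shared region")
  regions <- list("A", "B", "C", c("A", "B"), c("A", "C"), c("B", "C"), envs)
  sizes <- c(n_u, n_u, n_u, n_p, n_p, n_p, n_all)
  ord <- with_seed(derive_seed(seed, "pools", "membership"), sample.int(n))
  idx <- split(ord, factor(rep(seq_along(sizes), sizes),
                           levels = seq_along(sizes)))
  member <- matrix(FALSE, n, 3L, dimnames = list(ids, envs))
  for (r in seq_along(sizes))
    if (length(idx[[r]])) member[idx[[r]], regions[[r]]] <- TRUE
  for (e in envs) {
    m <- member[, e]
    ab <- with_seed(derive_seed(seed, "pools", "abund", e),
                    stats::rlnorm(sum(m), 0, config$pool_lognorm_sd))
    pools[m, e] <- ab / sum(ab)
  }
  pools
}

#' Draw one gut community under a Gaussian host filter
#'
#' The selection kernel is a Gaussian filter on the heritable trait centred
#' at the stage optimum, mixed with the unfiltered pool in proportion
#' `1 - s`:
#' `p_sel  propto  (1 - s) pool + s pool exp(-(trait - optimum)^2 / (2 sigma^2))`.
#' With the default arguments the sample is a single multinomial draw of
#' `depth` reads from `p_sel` (drift enters as multinomial noise).
#'
#' The optional arguments turn on the full host-assembly chain used by
#' [simulate_study()]: only `capacity` lineages colonize, drawn without
#' replacement with probability
#' `pool^colonization_exp * ((1 - s) + s w)^establishment_sharpness`
#' (establishment odds compound over repeated colonization challenges);
#' resident abundances are `p_sel^abundance_exp` times host-specific
#' log-normal drift; and a transient immigrant fraction `dispersal_rate` of
#' reads is spread over `immigrant_richness` pool lineages.
#'
#' @param pool relative-abundance vector over the OTU set (zeros allowed).
#' @param traits named trait vector aligned with `pool`.
#' @param stage_optimum trait value favoured at this developmental stage.
#' @param s selection strength in `[0, 1]`.
#' @param sigma width of the trait filter (> 0).
#' @param depth reads to draw.
#' @param seed integer seed.
#' @param capacity colonization bottleneck (`Inf` = none).
#' @param establishment_sharpness,colonization_exp,abundance_exp,host_drift_sd
#'   host-assembly parameters, see [simulation_config()].
#' @param dispersal_rate,immigrant_richness transient immigration, see
#'   [simulation_config()].
#' @return Integer count vector summing to `depth`.
#' @export
simulate_gut_sample <- function(pool, traits, stage_optimum, s, sigma, depth,
                                seed = 1L, capacity = Inf,
                                establishment_sharpness = 3,
                                colonization_exp = 0.25,
                                abundance_exp = 1,
                                host_drift_sd = 0,
                                dispersal_rate = 0,
                                immigrant_richness = Inf) {
  if (s < 0 || s > 1) stop("s must lie in [0, 1]")
  if (sigma <= 0) stop("sigma must be positive")
  if (depth < 1) stop("depth must be positive")
  if (sum(pool) <= 0) stop("empty source pool")
  pool <- pool / sum(pool)
  n <- length(pool)
  w <- exp(-(traits - stage_optimum)^2 / (2 * sigma^2))
  p_sel <- (1 - s) * pool + s * pool * w
  if (sum(p_sel) <= 0) p_sel <- pool  # filter annihilated the pool
  counts <- with_seed(derive_seed(seed, "gut_sample"), {
    if (is.finite(capacity) && capacity < sum(pool > 0)) {
      estab <- ifelse(pool > 0, pool^colonization_exp, 0) *
        ((1 - s) + s * w)^establishment_sharpness
      col <- sample.int(n, capacity, prob = estab)
      q <- numeric(n)
      q[col] <- p_sel[col]^abundance_exp *
        stats::rlnorm(length(col), 0, host_drift_sd)
    } else {
      q <- p_sel^abundance_exp
      if (host_drift_sd > 0) q <- q * stats::rlnorm(n, 0, host_drift_sd) * (pool > 0)
    }
    q <- q / sum(q)
    if (dispersal_rate > 0) {
      if (is.finite(immigrant_richness) && immigrant_richness < sum(pool > 0)) {
        imm <- sample.int(n, immigrant_richness, prob = pool)
        qi <- numeric(n); qi[imm] <- pool[imm]
        qi <- qi / sum(qi)
      } else qi <- pool
      q <- (1 - dispersal_rate) * q + dispersal_rate * qi
    }
    stats::rmultinom(1L, as.integer(depth), q)[, 1L]
  })
  stats::setNames(as.integer(counts), names(pool))
}

# log-normal temporal jitter of an environment pool at one timepoint
pool_at_time <- function(pool, env, dph, jitter_sd, seed) {
  if (jitter_sd <= 0) return(pool)
  j <- with_seed(derive_seed(seed, "jitter", env, dph),
                 stats::rlnorm(length(pool), 0, jitter_sd))
  p <- pool * j
  p / sum(p)
}

#' Simulate a full hatch/transition study
#'
#' Generates the complete design: water samples per tank and timepoint
#' (all ages except 20 dph, three replicates) drawn from the tank's jittered
#' pool, and gut samples per tank x cage x timepoint x replicate assembled
#' from the cage's source pool under the stage-specific host filter (see
#' [simulate_gut_sample()]). Fish in each cage hatched in one environment;
#' at 12 dph they sit in their hatching water, afterwards in the rearing
#' tank's water, so transition cages switch source pools after the first
#' sampling age. Under the default schedule this yields 189 gut and 54
#' water samples. Stage optima sit at the (equally spaced) deep-clade niche
#' centers of the trait, so each stage favours a different clade and the
#' dominant lineages turn over across development.
#'
#' @param config a [simulation_config()].
#' @return A list of class `"simulated_study"` with elements `table`
#'   ([otu_table()]), `tree`, `metadata` and `truth` (the generating
#'   parameters, for recovery tests).
#' @export
simulate_study <- function(config) {
  config <- validate_simulation_config(unclass(config))
  seed <- config$seed
  tree <- simulate_phylogeny(config$n_otus, seed,
                             crown_depth = config$crown_depth)
  nt <- niche_trait(tree, config$trait_rate, config$niche_separation, seed)
  traits <- nt$trait
  pools <- simulate_water_pools(config, tree, seed)
  envs <- config$tanks
  stages <- sort(unique(stage_from_dph(config$dph_schedule)))
  centers <- nt$centers
  optima <- stats::setNames(centers[pmin(seq_along(stages), length(centers))],
                            stages)

  cage_mask <- list()
  for (tk in seq_along(envs)) for (cg in 1:config$cages_per_tank) {
    cage_no <- (tk - 1L) * config$cages_per_tank + cg
    if (config$cage_pool_frac >= 1) {
      cage_mask[[cage_no]] <- rep(TRUE, config$n_otus)
    } else {
      k <- max(3L, round(config$cage_pool_frac * config$n_otus))
      keep <- with_seed(derive_seed(seed, "cage_mask", cage_no),
                        sample.int(config$n_otus, k))
      m <- rep(FALSE, config$n_otus)
      m[keep] <- TRUE
      cage_mask[[cage_no]] <- m
    }
  }

  counts <- list()
  meta <- list()
  water_dph <- setdiff(config$dph_schedule, 20L)
  for (tk in seq_along(envs)) {
    env <- envs[tk]
    for (t in water_dph) {
      p <- pool_at_time(pools[, env], env, t, config$water_jitter_sd, seed)
      for (r in 1:3) {
        sid <- sprintf("W_T%s_d%03d_r%d", env, t, r)
        counts[[sid]] <- with_seed(derive_seed(seed, "water", sid),
                                   stats::rmultinom(1L, config$depth, p))[, 1L]
        meta[[sid]] <- tibble::tibble(sample_id = sid, habitat = "water",
                                      tank = paste0("T", env), cage = NA_character_,
                                      hatch_env = NA_character_, rear_env = env,
                                      dph = t, stage = stage_from_dph(t),
                                      transition = FALSE, food = NA_character_)
      }
    }
  }
  for (tk in seq_along(envs)) {
    rear <- envs[tk]
    for (cg in 1:config$cages_per_tank) {
      hatch <- envs[cg]
      cage_no <- (tk - 1L) * config$cages_per_tank + cg
      mask <- cage_mask[[cage_no]]
      for (t in config$dph_schedule) {
        src_env <- if (t <= 12L) hatch else rear
        src <- pool_at_time(pools[, src_env], src_env, t,
                            config$water_jitter_sd, seed)
        src <- src * mask
        if (sum(src) <= 0) stop("cage pool restriction emptied a source pool")
        src <- src / sum(src)
        st <- stage_from_dph(t)
        s <- config$selection_strength_by_stage[[st]]
        for (r in 1:config$replicates) {
          sid <- sprintf("G_T%s_c%d_d%03d_r%d", rear, cage_no, t, r)
          counts[[sid]] <- simulate_gut_sample(
            src, traits, optima[[st]], s, config$selection_sd, config$depth,
            seed = derive_seed(seed, "gut", sid),
            capacity = config$host_capacity,
            establishment_sharpness = config$establishment_sharpness,
            colonization_exp = config$colonization_exp,
            abundance_exp = config$abundance_exp,
            host_drift_sd = config$host_drift_sd,
            dispersal_rate = config$dispersal_rate,
            immigrant_richness = config$immigrant_richness)
          meta[[sid]] <- tibble::tibble(sample_id = sid, habitat = "gut",
                                        tank = paste0("T", rear),
                                        cage = paste0("c", cage_no),
                                        hatch_env = hatch, rear_env = rear,
                                        dph = t, stage = st,
                                        transition = hatch != rear,
                                        food = if (t < 20L) "live" else "dry")
        }
      }
    }
  }
  mat <- do.call(cbind, counts)
  rownames(mat) <- tree$tip.label
  study <- list(table = otu_table(mat), tree = tree,
                metadata = validate_metadata(dplyr::bind_rows(meta)),
                truth = list(selection_strength_by_stage = config$selection_strength_by_stage,
                             dispersal_rate = config$dispersal_rate,
                             selection_sd = config$selection_sd,
                             optima = optima, traits = traits,
                             config = config))
  class(study) <- "simulated_study"
  study
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated metacommunity study\n")
  cat(sprintf("  %d OTUs x %d samples (%d gut, %d water)\n",
              nrow(x$table), ncol(x$table),
              sum(x$metadata$habitat == "gut"),
              sum(x$metadata$habitat == "water")))
  cat(sprintf("  selection by stage: %s\n",
              paste(sprintf("%s=%.2f", names(x$truth$selection_strength_by_stage),
                            x$truth$selection_strength_by_stage), collapse = ", ")))
  invisible(x)
}
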