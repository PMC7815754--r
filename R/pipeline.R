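#' Configuration for the end-to-end pipeline
#'
#' Either supply paths to an OTU table, newick tree and metadata TSV, or a
#' [simulation_config()] (or list of its arguments) to generate the study.
#'
#' @param table,tree,metadata input file paths (all three or none).
#' @param simulation a [simulation_config()] or argument list for one.
#' @param rarefaction_depth reads per sample after rarefaction
#'   (default 14666).
#' @param null_config a [null_model_config()].
#' @param out_dir output directory for the written intermediates.
#' @param seed global seed; fans out to every stochastic stage through
#'   [derive_seed()], so adding a stage never perturbs earlier streams.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(table = NULL, tree = NULL, metadata = NULL,
                            simulation = NULL, rarefaction_depth = 14666L,
                            null_config = NULL, out_dir = tempfile("pipeline_"),
                            seed = 1L) {
  have_paths <- !is.null(table) && !is.null(tree) && !is.null(metadata)
  if (!have_paths && is.null(simulation))
    stop("provide input paths (table, tree, metadata) or a simulation block")
  if (have_paths && !is.null(simulation))
    stop("provide either input paths or a simulation block, not both")
  if (!is.null(simulation) && !inherits(simulation, "simulation_config")) {
    simulation$seed <- simulation$seed %||% derive_seed(seed, "simulate")
    simulation <- do.call(simulation_config, simulation)
  }
  structure(list(table = table, tree = tree, metadata = metadata,
                 simulation = simulation,
                 rarefaction_depth = as.integer(rarefaction_depth),
                 null_config = null_config %||%
                   null_model_config(seed = derive_seed(seed, "null_models")),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()]; a `simulation:` mapping holds
#' [simulation_config()] fields and a `null_model:` mapping holds
#' [null_model_config()] fields.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  seed <- seed %||% y$seed %||% 1L
  nm <- y$null_model %||% list()
  nm$seed <- nm$seed %||% derive_seed(seed, "null_models")
  pipeline_config(table = y$table, tree = y$tree, metadata = y$metadata,
                  simulation = y$simulation,
                  rarefaction_depth = y$rarefaction_depth %||% 14666L,
                  null_config = do.call(null_model_config, nm),
                  out_dir = y$out_dir %||% tempfile("pipeline_"),
                  seed = seed)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Run the full succession-analysis pipeline
#'
#' Orchestrates simulate (or load) -> rarefy -> alpha/beta diversity ->
#' Rao diversity partition (per tank and overall) -> pairwise betaNTI /
#' RC-bray process classification per developmental stage -> selection
#' strength -> PERMANOVA (pairwise stage contrasts) and Mantel tests.
#' Every intermediate table is written to `config$out_dir` as TSV plus one
#' JSON summary; identical config and seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `"run_report"` with the tables described above.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_name <- "input"
  run_stage <- function(name, expr) {
    stage_name <<- name
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(config$simulation)) {
    study <- run_stage("simulate", simulate_study(config$simulation))
    table <- study$table; tree <- study$tree; metadata <- study$metadata
    write_otu_table(table, file.path(config$out_dir, "otu_table.tsv"))
    write_tree(tree, file.path(config$out_dir, "tree.nwk"))
    write_metadata(metadata, file.path(config$out_dir, "metadata.tsv"))
    jsonlite::write_json(
      list(selection_strength_by_stage =
             as.list(study$truth$selection_strength_by_stage),
           dispersal_rate = study$truth$dispersal_rate,
           selection_sd = study$truth$selection_sd),
      file.path(config$out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    table <- run_stage("read_table", read_otu_table(config$table))
    tree <- run_stage("read_tree", read_tree(config$tree))
    metadata <- run_stage("read_metadata", read_metadata(config$metadata))
  }
  table <- run_stage("rarefy",
                     rarefy(table, config$rarefaction_depth,
                            seed = derive_seed(config$seed, "rarefy_stage")))
  metadata <- metadata[metadata$sample_id %in% colnames(table), ]

  alpha <- run_stage("alpha_diversity", alpha_diversity(table, tree))
  write_tsv_plain(alpha, file.path(config$out_dir, "alpha.tsv"))
  bc <- run_stage("beta_diversity", beta_distance(table, "bray_curtis"))
  write_distance_matrix(bc, file.path(config$out_dir, "beta_bray_curtis.tsv"))

  tanks <- sort(unique(metadata$tank))
  partitions <- run_stage("diversity_partition", dplyr::bind_rows(c(
    lapply(tanks, function(tk) partition_diversity(table, metadata, scope = tk)),
    list(partition_diversity(table, metadata, scope = "all")))))
  write_tsv_plain(partitions, file.path(config$out_dir, "partition.tsv"))

  turnovers <- run_stage("pairwise_turnover",
                         pairwise_turnover(table, tree, metadata,
                                           config = config$null_config))
  write_tsv_plain(turnovers, file.path(config$out_dir, "pairwise_turnover.tsv"))
  profile <- run_stage("process_profile", process_profile(turnovers))
  write_tsv_plain(profile, file.path(config$out_dir, "process_profile.tsv"))

  sel <- run_stage("selection_strength",
                   selection_strength(table, metadata,
                                      config = config$null_config))
  write_tsv_plain(sel, file.path(config$out_dir, "selection_strength.tsv"))

  gut_meta <- metadata[metadata$habitat == "gut", ]
  stages <- sort(unique(gut_meta$stage))
  perm_rows <- list()
  if (length(stages) >= 2L) {
    for (i in seq_len(length(stages) - 1L)) for (j in (i + 1L):length(stages)) {
      ss <- gut_meta$sample_id[gut_meta$stage %in% stages[c(i, j)]]
      pr <- run_stage("permanova",
                      permanova(bc[ss, ss],
                                stats::setNames(gut_meta$stage[match(ss, gut_meta$sample_id)], ss),
                                n_perm = 999L,
                                seed = derive_seed(config$seed, "permanova",
                                                   stages[i], stages[j])))
      perm_rows[[paste(stages[i], stages[j])]] <-
        tibble::tibble(contrast = paste(stages[i], "vs", stages[j]),
                       pseudo_F = pr$pseudo_F, p_value = pr$p_value)
    }
  }
  permanova_tbl <- dplyr::bind_rows(perm_rows)
  write_tsv_plain(permanova_tbl, file.path(config$out_dir, "permanova.tsv"))

  gut_ids <- gut_meta$sample_id
  stage_d <- outer(gut_meta$stage, gut_meta$stage, `!=`) * 1
  dimnames(stage_d) <- list(gut_ids, gut_ids)
  mt <- run_stage("mantel", mantel(bc[gut_ids, gut_ids], stage_d,
                                   seed = derive_seed(config$seed, "mantel")))
  mantel_tbl <- tibble::tibble(test = "mantel_stage_bray", r = mt$statistic,
                               p_value = mt$p_value)
  write_tsv_plain(mantel_tbl, file.path(config$out_dir, "mantel.tsv"))

  summary <- list(n_samples = ncol(table), n_otus = nrow(table),
                  n_gut = sum(metadata$habitat == "gut"),
                  n_water = sum(metadata$habitat == "water"),
                  rarefaction_depth = config$rarefaction_depth,
                  n_null = config$null_config$n_null, seed = config$seed)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(alpha = alpha, partitions = partitions, turnovers = turnovers,
                 process_profile = profile, selection_strength = sel,
                 permanova = permanova_tbl, mantel = mantel_tbl,
                 summary = summary, out_dir = config$out_dir),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run:", x$summary$n_otus, "OTUs x", x$summary$n_samples,
      "samples; outputs in", x$out_dir, "\n")
  cat("Process profile (fractions by stage):\n")
  print(x$process_profile)
  invisible(x)
}
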