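# End-to-end orchestration: simulate-or-load -> pair -> strip/filter ->
# activity -> diversity -> inference -> report bundle, reproducible from one
# master seed.

#' Build a pipeline configuration
#'
#' Exactly one of `inputs` (paths to DNA/RNA/metadata tables, optional taxa)
#' or `simulation` (a [simulation_config]) must be given.
#'
#' @param inputs named list with `dna`, `rna`, `metadata` and optionally
#'   `taxa` paths.
#' @param simulation a [simulation_config].
#' @param level functional table level.
#' @param min_prevalence prevalence filter fraction (default 0.2).
#' @param min_rna_species contributional-richness display filter (default 2).
#' @param n_perm PERMANOVA/PERMDISP permutations (default 999).
#' @param master_seed master seed; per-stage seeds derive from it via
#'   [child_seed].
#' @param out_dir output directory (NULL: nothing written).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = NULL, simulation = NULL,
                            level = "pathway", min_prevalence = 0.2,
                            min_rna_species = 2, n_perm = 999,
                            master_seed = 1L, out_dir = NULL) {
  if (is.null(inputs) == is.null(simulation)) {
    stop_format("exactly one of 'inputs' or 'simulation' must be given")
  }
  if (!is.null(inputs)) {
    req <- c("dna", "rna", "metadata")
    missing_f <- setdiff(req, names(inputs))
    if (length(missing_f)) stop_format("inputs missing: %s", paste(missing_f, collapse = ", "))
    for (p in unlist(inputs)) {
      if (!file.exists(p)) stop_format("input file not found: %s", p)
    }
  }
  structure(list(inputs = inputs, simulation = simulation, level = level,
                 min_prevalence = min_prevalence,
                 min_rna_species = min_rna_species, n_perm = n_perm,
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Mirrors [pipeline_config]; a `simulation:` block is passed to
#' [simulation_config].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) do.call(simulation_config, y$simulation)
  pipeline_config(
    inputs = y$inputs, simulation = sim,
    level = y$level %||% "pathway",
    min_prevalence = y$min_prevalence %||% 0.2,
    min_rna_species = y$min_rna_species %||% 2,
    n_perm = y$n_perm %||% 999,
    master_seed = y$master_seed %||% 1L,
    out_dir = y$out_dir
  )
}

#' Run the full activity-analysis pipeline
#'
#' Stages: (1) simulate or load the paired dataset; (2) taxonomic alpha/beta
#' diversity with Kruskal-Wallis and subject-restricted PERMANOVA (Aitchison
#' distance on species composition); (3) community-level log10(RNA/DNA)
#' activity with prevalence filtering, ratio beta diversity (shifted weighted
#' Jaccard), PCoA with Shepard check, and PERMANOVA on site and status;
#' (4) differential species abundance (Dirichlet-CLR, plaque disease vs
#' health) and differential pathway activity (log-linear subject model);
#' (5) report bundle (tables, run manifest, plain-text summary) under
#' `out_dir` when set.
#'
#' @param config a `pipeline_config` or path to a YAML file.
#' @return (invisibly) a list with the dataset, activity tables, diversity,
#'   ordinations, test tables, planted effects (simulation runs) and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- vapply(0:9, function(s) child_seed(config$master_seed, s), 1L)

  # stage 1: data
  effects <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- seeds[1]
    gen <- generate_study(sim)
    paired <- gen$dataset
    effects <- gen$effects
  } else {
    dna <- read_stratified_profile(config$inputs$dna, level = config$level)
    rna <- read_stratified_profile(config$inputs$rna, level = config$level)
    md <- read_sample_metadata(config$inputs$metadata)
    taxa <- if (!is.null(config$inputs$taxa)) read_taxonomic_profile(config$inputs$taxa)
    paired <- pair_profiles(dna, rna, md, taxa = taxa)
  }
  md <- paired$metadata

  # stage 2: taxonomic diversity
  taxa_res <- NULL
  if (!is.null(paired$taxa)) {
    tm <- paired$taxa$abundance
    tm <- sweep(tm, 2, pmax(colSums(tm), 1e-12), "/")
    alpha_tax <- alpha_diversity(tm)
    kw_site <- kruskal_wallis_groups(alpha_tax$shannon, md$site)
    kw_status <- kruskal_wallis_groups(alpha_tax$shannon, md$status)
    d_ait <- aitchison_distance(tm)
    perm_site <- permanova_restricted(d_ait, md$site, strata = md$subject_id,
                                      n_perm = config$n_perm, seed = seeds[2],
                                      term = "site")
    perm_status <- permanova_restricted(d_ait, md$status, strata = md$subject_id,
                                        n_perm = config$n_perm, seed = seeds[3],
                                        term = "status")
    disp_site <- permdisp(d_ait, md$site, n_perm = config$n_perm, seed = seeds[4])
    ord_tax <- pcoa_with_shepard(d_ait, k = 2)
    taxa_res <- list(alpha = alpha_tax, kw_site = kw_site, kw_status = kw_status,
                     dist = d_ait, permanova_site = perm_site,
                     permanova_status = perm_status, permdisp_site = disp_site,
                     ordination = ord_tax)
  }

  # stage 3: activity + ratio beta diversity
  act <- compute_activity_table(paired, level = "community_feature")
  prev_ok <- rowSums(act$detected) >= ceiling(config$min_prevalence * length(act$samples))
  act_f <- act
  act_f$value <- act$value[prev_ok, , drop = FALSE]
  act_f$mask <- act$mask[prev_ok, , drop = FALSE]
  act_f$detected <- act$detected[prev_ok, , drop = FALSE]
  act_f$feature <- act$feature[prev_ok]
  act_f$stratum <- act$stratum[prev_ok]
  d_ratio <- ratio_beta_diversity(act_f)
  ord_ratio <- pcoa_with_shepard(d_ratio, k = 2)
  perm_ratio_site <- permanova_restricted(d_ratio, md$site, strata = md$subject_id,
                                          n_perm = config$n_perm, seed = seeds[5],
                                          term = "site")
  perm_ratio_status <- permanova_restricted(d_ratio, md$status, strata = md$subject_id,
                                            n_perm = config$n_perm, seed = seeds[6],
                                            term = "status")
  overall <- overall_sample_activity(act_f)
  kw_overall_site <- kruskal_wallis_groups(overall, md$site)

  # stage 4: differential tests
  species_test <- NULL
  if (!is.null(paired$taxa)) {
    plaque <- md$site == "plaque"
    counts <- round(paired$taxa$abundance[, plaque, drop = FALSE] * 1e4)
    grp <- md$status[plaque]
    if (length(unique(grp)) == 2) {
      species_test <- clr_dirichlet_test(counts, grp, seed = seeds[7])
    }
  }
  # linear modeling keeps the UNMAPPED/UNINTEGRATED mass (diversity does not)
  act_lm <- compute_activity_table(paired, level = "community_feature",
                                   keep_special = TRUE)
  ratio_vals <- act_lm$value
  ratio_vals[!act_lm$mask] <- NA_real_
  pathway_test <- loglinear_differential(ratio_vals, md,
                                         fixed_terms = c("status", "site"),
                                         subject_random = TRUE,
                                         min_prevalence = config$min_prevalence,
                                         transform = "ratio")

  result <- list(
    config = config, dataset = paired, effects = effects,
    activity = act_f, overall_activity = overall,
    taxa = taxa_res,
    ratio_dist = d_ratio, ratio_ordination = ord_ratio,
    permanova_ratio_site = perm_ratio_site,
    permanova_ratio_status = perm_ratio_status,
    kw_overall_site = kw_overall_site,
    species_test = species_test, pathway_test = pathway_test
  )
  result$manifest <- list(
    package = "oralactivity",
    version = as.character(utils::packageVersion("oralactivity")),
    master_seed = config$master_seed,
    stage_seeds = as.integer(seeds),
    level = config$level,
    n_samples = length(paired$samples),
    min_prevalence = config$min_prevalence,
    n_perm = config$n_perm,
    simulated = !is.null(config$simulation),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  if (!is.null(config$out_dir)) write_report_bundle(result, config$out_dir)
  invisible(result)
}

write_dist_tsv <- function(d, path) {
  m <- as.matrix(d)
  utils::write.table(data.frame(sample = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(activity_long(result$activity), "activity_community.tsv")
  wt(data.frame(sample = names(result$overall_activity),
                mean_log10_ratio = result$overall_activity),
     "overall_activity.tsv")
  if (!is.null(result$taxa)) {
    wt(result$taxa$alpha, "alpha_diversity_taxa.tsv")
    write_dist_tsv(result$taxa$dist, file.path(out_dir, "dist_aitchison_taxa.tsv"))
    perm <- do.call(rbind, lapply(
      list(result$taxa$permanova_site, result$taxa$permanova_status,
           result$permanova_ratio_site, result$permanova_ratio_status),
      function(p) data.frame(term = p$term, scheme = p$strata, pseudo_F = p$pseudo_F,
                             R2 = p$R2, p = p$p_value, n_perm = p$n_permutations)))
    perm$table <- c("taxa_aitchison", "taxa_aitchison", "activity_jaccard", "activity_jaccard")
    wt(perm, "permanova.tsv")
  }
  write_dist_tsv(result$ratio_dist, file.path(out_dir, "dist_jaccard_activity.tsv"))
  ordd <- data.frame(sample = rownames(result$ratio_ordination$points),
                     result$ratio_ordination$points)
  wt(ordd, "ordination_activity.tsv")
  if (!is.null(result$species_test)) wt(result$species_test, "species_differential.tsv")
  wt(result$pathway_test, "pathway_activity_differential.tsv")
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(pipeline_summary_text(result), file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

pipeline_summary_text <- function(result) {
  md <- result$dataset$metadata
  lines <- c(
    "oralactivity pipeline summary",
    sprintf("samples: %d (%s)", nrow(md),
            paste(sprintf("%s=%d", names(table(md$site)), table(md$site)), collapse = ", ")),
    sprintf("subjects: %d (%s)", length(unique(md$subject_id)),
            paste(sprintf("%s=%d", names(table(md$status[!duplicated(md$subject_id)])),
                          table(md$status[!duplicated(md$subject_id)])), collapse = ", ")),
    sprintf("activity features after prevalence filter: %d", nrow(result$activity$value)),
    sprintf("PERMANOVA activity ~ site: R2 = %.3f, p = %.4g",
            result$permanova_ratio_site$R2, result$permanova_ratio_site$p_value),
    sprintf("PERMANOVA activity ~ status: R2 = %.3f, p = %.4g",
            result$permanova_ratio_status$R2, result$permanova_ratio_status$p_value),
    sprintf("differential activity (status, q < 0.05): %d pathways",
            sum(result$pathway_test$q < 0.05 &
                  grepl("^status", result$pathway_test$term), na.rm = TRUE))
  )
  if (!is.null(result$taxa)) {
    lines <- c(lines,
      sprintf("PERMANOVA taxa ~ site: R2 = %.3f, p = %.4g",
              result$taxa$permanova_site$R2, result$taxa$permanova_site$p_value),
      sprintf("PERMANOVA taxa ~ status: R2 = %.3f, p = %.4g",
              result$taxa$permanova_status$R2, result$taxa$permanova_status$p_value))
  }
  lines
}
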