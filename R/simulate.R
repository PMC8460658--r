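# Synthetic paired metagenome/metatranscriptome generator emulating a
# repeated-measures oral study: two subject groups (healthy, periodontitis),
# three sites per subject (plaque, tongue, saliva), site-structured species
# composition, plaque-weighted "pathogen" enrichment in disease, and a planted
# reduction of activity (log10 RNA/DNA) on a set of target pathways.

#' Simulation configuration
#'
#' Defaults encode the emulated study design: 11 subjects per group sampled at
#' three oral sites (66 paired samples), 60 species, 200 pathways of which 10
#' carry a disease-reduced activity shift of -0.5 log10 units, 8
#' plaque-weighted pathogen species elevated in disease.
#'
#' @param n_subjects_per_group subjects per health-status group (default 11).
#' @param sites sampled sites (default plaque, tongue, saliva).
#' @param n_species number of species (default 60).
#' @param n_pathways number of pathways (default 200).
#' @param pathogen_set indices of disease-elevated species (default 1:8).
#' @param target_pathways indices of pathways with disease-shifted activity
#'   (default 1:10).
#' @param activity_effect planted delta log10(RNA/DNA) in disease on target
#'   pathways (default -0.5).
#' @param pathogen_shift named per-site log-abundance increase of pathogen
#'   species in disease; largest in plaque, then saliva, smallest in tongue.
#' @param site_pref_sd sd of per-species site log-preference offsets.
#' @param subject_sd sd of per-subject species log-abundance effects.
#' @param sample_sd residual per-sample species log noise.
#' @param activity_sd Gaussian noise sd on the log10 activity scale (default 0.2).
#' @param dna_depth,rna_depth expected reads per sample (defaults 1e5 / 2e5).
#' @param dispersion Dirichlet-multinomial overdispersion (1/concentration)
#'   applied over the full stratified cell vector; default 1e-6, a mild
#'   counting-layer overdispersion — the biological variance is carried by the
#'   hierarchical species/subject/activity layers. `0` gives plain
#'   multinomial sampling.
#' @param dropout probability that a truly present species stratum is
#'   unobserved in a given sample (default 0.05).
#' @param unmapped_mean mean of the Beta-distributed per-sample UNMAPPED
#'   fraction (default 0.2).
#' @param seed integer RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_subjects_per_group = 11,
                              sites = ORAL_SITES,
                              n_species = 60,
                              n_pathways = 200,
                              pathogen_set = 1:8,
                              target_pathways = 1:10,
                              activity_effect = -0.5,
                              pathogen_shift = c(plaque = 1.5, tongue = 0.5, saliva = 1.0),
                              site_pref_sd = 1.0,
                              subject_sd = 0.4,
                              sample_sd = 0.2,
                              activity_sd = 0.2,
                              dna_depth = 1e5,
                              rna_depth = 2e5,
                              dispersion = 1e-6,
                              dropout = 0.05,
                              unmapped_mean = 0.2,
                              seed = 1L) {
  cfg <- list(n_subjects_per_group = n_subjects_per_group, sites = sites,
              n_species = n_species, n_pathways = n_pathways,
              pathogen_set = pathogen_set, target_pathways = target_pathways,
              activity_effect = activity_effect, pathogen_shift = pathogen_shift,
              site_pref_sd = site_pref_sd, subject_sd = subject_sd,
              sample_sd = sample_sd, activity_sd = activity_sd,
              dna_depth = dna_depth, rna_depth = rna_depth,
              dispersion = dispersion, dropout = dropout,
              unmapped_mean = unmapped_mean, seed = as.integer(seed))
  stopifnot(cfg$n_subjects_per_group >= 1, cfg$n_species >= 1, cfg$n_pathways >= 1,
            is.finite(cfg$activity_effect), cfg$dropout >= 0, cfg$dropout <= 1,
            cfg$dna_depth > 0, cfg$rna_depth > 0, cfg$dispersion >= 0,
            all(cfg$sites %in% ORAL_SITES),
            all(cfg$pathogen_set %in% seq_len(cfg$n_species)),
            all(cfg$target_pathways %in% seq_len(cfg$n_pathways)))
  structure(cfg, class = "simulation_config")
}

#' A configuration with every planted effect removed
#'
#' Same design and noise structure as `config`, but zero pathogen shift and
#' zero activity shift: downstream tests should attain their nominal type-I
#' error / FDR on data generated from it.
#'
#' @param config a [simulation_config] (default the package default).
#' @return a [simulation_config].
#' @export
null_config <- function(config = simulation_config()) {
  config$activity_effect <- 0
  config$pathogen_shift[] <- 0
  config
}

#' Dirichlet-multinomial count sampling
#'
#' Expected counts are proportional to `mean_composition`; `dispersion > 0`
#' adds Dirichlet overdispersion with concentration `1/dispersion`
#' (`dispersion = 0` is plain multinomial). True-zero proportions always yield
#' zero counts.
#'
#' @param mean_composition proportion vector summing to 1.
#' @param depth expected total reads.
#' @param dispersion overdispersion parameter (1/concentration), `>= 0`.
#' @param seed optional integer seed.
#' @return nonnegative integer count vector of the same length.
#' @export
sample_counts <- function(mean_composition, depth, dispersion = 0, seed = NULL) {
  p <- as.numeric(mean_composition)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop_format("mean_composition must be a simplex vector (sum 1, nonnegative)")
  }
  stopifnot(depth > 0, dispersion >= 0)
  if (!is.null(seed)) set.seed(seed)
  q <- if (dispersion > 0) {
    g <- numeric(length(p))
    nz <- p > 0
    g[nz] <- stats::rgamma(sum(nz), shape = p[nz] / dispersion)
    if (sum(g) == 0) g[nz] <- p[nz]  # degenerate draw at tiny depth/concentration
    g / sum(g)
  } else p
  as.integer(stats::rmultinom(1, size = round(depth), prob = q))
}

#' Generate a full synthetic paired study
#'
#' DNA species composition is drawn hierarchically (species baseline + site
#' preference + subject effect + pathogen shift in disease, softmax on the log
#' scale). A fixed sparse species-pathway incidence matrix (every pathway
#' contributed by at least two species) converts species abundance into
#' stratified DNA pathway means. RNA stratum means redistribute each pathway's
#' transcription across its species according to the species activity
#' baselines (plus cell-level noise), while the pathway-level total obeys
#' `RNA = DNA * 10^(pathway baseline + disease shift on targets + noise)`
#' exactly — so the planted community-level activity shift of every
#' non-target pathway is zero by construction. Counts are drawn by
#' Dirichlet-multinomial at the configured depths (including a Beta-distributed
#' UNMAPPED fraction) and converted to relative abundances.
#'
#' @param config a [simulation_config].
#' @return list with elements `dataset` (a [pair_profiles] result) and
#'   `effects` (a `planted_effects` record: `true_species_lfc` species x site
#'   matrix, `true_activity_shift` per pathway, `site_centroids`,
#'   `target_pathways`, `pathogen_species`).
#' @export
generate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  S <- config$n_species; P <- config$n_pathways
  sites <- config$sites
  n_subj <- 2L * config$n_subjects_per_group

  genus <- sprintf("Genus%02d", ceiling(seq_len(S) / 3))
  species <- sprintf("%s_sp%03d", genus, seq_len(S))     # taxonomic leaf form
  species_canon <- gsub("_", " ", species)               # functional stratum form
  pathways <- sprintf("PWY%04d", seq_len(P))

  subjects <- sprintf("S%02d", seq_len(n_subj))
  status <- rep(HEALTH_STATUS, each = config$n_subjects_per_group)
  smoking <- ifelse(stats::runif(n_subj) < 0.3, "yes", "no")
  metadata <- data.frame(
    sample_id = as.vector(outer(subjects, sites, paste, sep = "_")),
    subject_id = rep(subjects, times = length(sites)),
    site = rep(sites, each = n_subj),
    status = rep(status, times = length(sites)),
    smoking = rep(smoking, times = length(sites)),
    stringsAsFactors = FALSE
  )
  metadata <- metadata[order(metadata$subject_id, match(metadata$site, sites)), ]
  rownames(metadata) <- NULL
  n_samp <- nrow(metadata)

  # species generative parameters
  base_log <- stats::rnorm(S, 0, 1)
  site_pref <- matrix(stats::rnorm(S * length(sites), 0, config$site_pref_sd),
                      S, length(sites), dimnames = list(species, sites))
  subj_eff <- matrix(stats::rnorm(n_subj * S, 0, config$subject_sd),
                     n_subj, S, dimnames = list(subjects, species))
  is_pathogen <- seq_len(S) %in% config$pathogen_set

  # species-pathway incidence: >= 2 species per pathway, lognormal weights
  inc_species <- vector("list", P)
  inc_weight <- vector("list", P)
  for (f in seq_len(P)) {
    k <- min(S, 2 + stats::rpois(1, 2.5))
    inc_species[[f]] <- sort(sample.int(S, k))
    inc_weight[[f]] <- stats::rlnorm(k, 0, 0.5)
  }
  sp_act <- stats::rnorm(S, 0, 0.3)    # species activity baseline
  pw_act <- stats::rnorm(P, 0, 0.3)    # pathway activity baseline

  row_feature <- c(rep(pathways, lengths(inc_species)), pathways)
  row_stratum <- c(species_canon[unlist(inc_species)], rep("unclassified", P))
  row_species_idx <- c(unlist(inc_species), rep(NA_integer_, P))
  row_pw_idx <- c(rep(seq_len(P), lengths(inc_species)), seq_len(P))
  row_w <- c(unlist(inc_weight), rep(NA_real_, P))
  n_rows <- length(row_feature)

  shift_vec <- config$pathogen_shift[sites]
  is_target_pw <- seq_len(P) %in% config$target_pathways
  beta_shape1 <- 10 * config$unmapped_mean
  beta_shape2 <- 10 * (1 - config$unmapped_mean)

  taxa_rel <- matrix(0, S, n_samp, dimnames = list(species, metadata$sample_id))
  dna_rel <- matrix(0, n_rows + 1L, n_samp)  # +1: UNMAPPED
  rna_rel <- matrix(0, n_rows + 1L, n_samp)

  for (j in seq_len(n_samp)) {
    subj <- metadata$subject_id[j]
    site <- metadata$site[j]
    diseased <- metadata$status[j] == "periodontitis"
    lg <- base_log + site_pref[, site] + subj_eff[subj, ] +
      stats::rnorm(S, 0, config$sample_sd)
    if (diseased) lg <- lg + is_pathogen * shift_vec[site]
    sp_prop <- exp(lg - max(lg)); sp_prop <- sp_prop / sum(sp_prop)

    taxa_counts <- sample_counts(sp_prop, config$dna_depth, config$dispersion)
    taxa_rel[, j] <- taxa_counts / sum(taxa_counts)

    dna_raw <- numeric(n_rows)
    named <- !is.na(row_species_idx)
    dna_raw[named] <- sp_prop[row_species_idx[named]] * row_w[named]
    if (config$dropout > 0) {
      dna_raw[named] <- dna_raw[named] *
        (stats::runif(sum(named)) >= config$dropout)
    }
    # unclassified stratum: 5% of the named mass of its pathway
    pw_sum <- rowsum(dna_raw[named], row_pw_idx[named])
    uncl <- numeric(P)
    uncl[as.integer(rownames(pw_sum))] <- 0.05 * pw_sum[, 1]
    dna_raw[!named] <- uncl[row_pw_idx[!named]]

    # within-pathway transcription shares: species baseline + cell noise
    act_sp <- sp_act[row_species_idx]; act_sp[!named] <- 0
    rna_raw <- dna_raw * 10^(act_sp + stats::rnorm(n_rows, 0, config$activity_sd))
    # pathway-level activity is set exactly by the pathway term, so that the
    # community log10(RNA/DNA) of a pathway is independent of which species
    # carry it (non-target pathways carry exactly zero disease shift)
    pw_act_j <- pw_act + stats::rnorm(P, 0, config$activity_sd)
    if (diseased) pw_act_j <- pw_act_j + is_target_pw * config$activity_effect
    pw_dna <- rowsum(dna_raw, row_pw_idx)[, 1]
    pw_rna <- rowsum(rna_raw, row_pw_idx)[, 1]
    pw_idx_present <- as.integer(names(pw_dna))
    scale_f <- rep(0, P)
    ok_pw <- pw_rna > 0
    scale_f[pw_idx_present[ok_pw]] <-
      (pw_dna[ok_pw] * 10^pw_act_j[pw_idx_present[ok_pw]]) / pw_rna[ok_pw]
    rna_raw <- rna_raw * scale_f[row_pw_idx]

    un_dna <- stats::rbeta(1, beta_shape1, beta_shape2)
    un_rna <- stats::rbeta(1, beta_shape1, beta_shape2)
    dna_mean <- c(dna_raw / sum(dna_raw) * (1 - un_dna), un_dna)
    rna_mean <- c(rna_raw / sum(rna_raw) * (1 - un_rna), un_rna)

    dcounts <- sample_counts(dna_mean, config$dna_depth, config$dispersion)
    rcounts <- sample_counts(rna_mean, config$rna_depth, config$dispersion)
    if (sum(dcounts) == 0 || sum(rcounts) == 0) {
      warning("sequencing depth too low to populate any stratum", call. = FALSE)
    }
    dna_rel[, j] <- dcounts / max(sum(dcounts), 1)
    rna_rel[, j] <- rcounts / max(sum(rcounts), 1)
  }

  colnames(dna_rel) <- colnames(rna_rel) <- metadata$sample_id
  feat_all <- c(row_feature, "UNMAPPED")
  strat_all <- c(row_stratum, NA_character_)
  dna <- stratified_profile(feat_all, strat_all, dna_rel, level = "pathway")
  rna <- stratified_profile(feat_all, strat_all, rna_rel, level = "pathway")
  taxa <- taxonomic_profile(taxa_rel, species = species,
                            clade = paste0("k__Bacteria|g__", genus, "|s__", species))

  dataset <- pair_profiles(dna, rna, metadata, taxa = taxa)

  true_lfc <- matrix(0, S, length(sites), dimnames = list(species, sites))
  true_lfc[config$pathogen_set, ] <- rep(shift_vec, each = length(config$pathogen_set))
  shift <- numeric(P); names(shift) <- pathways
  shift[config$target_pathways] <- config$activity_effect
  centroids <- vapply(sites, function(s) {
    e <- exp(base_log + site_pref[, s]); e / sum(e)
  }, numeric(S))
  rownames(centroids) <- species

  effects <- structure(list(
    true_species_lfc = true_lfc,
    true_activity_shift = shift,
    site_centroids = centroids,
    target_pathways = pathways[config$target_pathways],
    pathogen_species = species[config$pathogen_set]
  ), class = "planted_effects")

  list(dataset = dataset, effects = effects)
}

#' Write a generated study as on-disk fixture files
#'
#' Emits the MetaPhlAn-dialect taxonomic table, HUMAnN2-dialect DNA and RNA
#' stratified tables (with their UNMAPPED rows) and the metadata TSV, all
#' re-readable by the profile readers.
#'
#' @param dataset a `paired_omics` object (e.g. from [generate_study]).
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
emit_fixture <- function(dataset, dir) {
  stopifnot(inherits(dataset, "paired_omics"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) stop_format("cannot write to directory: %s", dir)
  paths <- c(
    dna = file.path(dir, "dna_pathabundance.tsv"),
    rna = file.path(dir, "rna_pathabundance.tsv"),
    taxa = file.path(dir, "taxa_metaphlan.tsv"),
    metadata = file.path(dir, "metadata.tsv")
  )
  write_stratified_profile(dataset$dna, paths[["dna"]])
  write_stratified_profile(dataset$rna, paths[["rna"]])
  if (!is.null(dataset$taxa)) write_taxonomic_profile(dataset$taxa, paths[["taxa"]])
  write_sample_metadata(dataset$metadata, paths[["metadata"]])
  paths
}
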