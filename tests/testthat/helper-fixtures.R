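# Small in-code fixtures shared across test files.

# A 2-feature x 3-stratum x 4-sample stratified profile with an UNMAPPED row.
tiny_stratified <- function(level = "pathway") {
  feature <- c("PWY1", "PWY1", "PWY1", "PWY2", "PWY2", "UNMAPPED")
  stratum <- c("Rothia dentocariosa", "Streptococcus oralis", "unclassified",
               "Rothia dentocariosa", "Tannerella forsythia", NA)
  ab <- matrix(c(
    0.10, 0.20, 0.05, 0.30, 0.15, 0.20,
    0.25, 0.10, 0.00, 0.20, 0.25, 0.20,
    0.05, 0.15, 0.10, 0.10, 0.40, 0.20,
    0.30, 0.05, 0.05, 0.25, 0.15, 0.20
  ), nrow = 6, ncol = 4,
  dimnames = list(NULL, paste0("S", 1:4)))
  stratified_profile(feature, stratum, ab, level = level)
}

tiny_metadata <- function(samples = paste0("S", 1:4)) {
  data.frame(
    sample_id = samples,
    subject_id = c("A", "A", "B", "B")[seq_along(samples)],
    site = c("plaque", "tongue", "plaque", "tongue")[seq_along(samples)],
    status = c("healthy", "healthy", "periodontitis", "periodontitis")[seq_along(samples)],
    smoking = "no",
    stringsAsFactors = FALSE
  )
}

tiny_paired <- function() {
  dna <- tiny_stratified()
  rna <- tiny_stratified()
  rna$abundance <- rna$abundance * matrix(c(2, 1, 0.5, 1, 1, 1), 6, 4)
  pair_profiles(dna, rna, tiny_metadata())
}

# Fast small simulation for structural tests.
small_config <- function(...) {
  simulation_config(n_subjects_per_group = 4, n_species = 20, n_pathways = 40,
                    pathogen_set = 1:4, target_pathways = 1:5,
                    dna_depth = 2e4, rna_depth = 4e4, ...)
}
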