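# Readers, writers and transformations for the table formats the pipeline
# consumes: MetaPhlAn merged taxonomic tables, HUMAnN2-style stratified
# functional tables (pathways / EC / KO / gene families) and the sample
# metadata sheet.

PROFILE_LEVELS <- c("pathway", "EC", "KO", "gene_family")

# ---------------------------------------------------------------------------
# Taxonomic profiles

#' Construct a taxonomic profile
#'
#' Species-by-sample relative abundances. Input tables are percent-scale
#' (MetaPhlAn convention, columns summing to at most 100); internally all
#' abundances are proportions in `[0, 1]`. Per-sample sums may fall short of 1
#' because unclassified mass is not carried.
#'
#' @param abundance numeric matrix, species x samples, proportions.
#' @param species character species labels (unique); default rownames.
#' @param clade optional full clade strings (`k__...|s__...`) per species.
#' @return an object of class `taxonomic_profile`.
#' @export
taxonomic_profile <- function(abundance, species = rownames(abundance), clade = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(species)) stop_format("species labels are required")
  if (anyDuplicated(species)) {
    stop_format("duplicate species labels: %s",
                paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  if (length(species) != nrow(abundance)) stop_format("species/abundance dimension mismatch")
  assert_matrix_nonneg(abundance, "taxonomic abundance")
  cs <- colSums(abundance)
  if (any(cs > 1 + 0.001)) {
    stop_format("per-sample abundance sums exceed 100%% (max %.4f)", max(cs) * 100)
  }
  rownames(abundance) <- species
  structure(list(
    abundance = abundance,
    species = species,
    clade = clade,
    samples = colnames(abundance)
  ), class = "taxonomic_profile")
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat(sprintf("<taxonomic_profile> %d species x %d samples\n",
              length(x$species), length(x$samples)))
  invisible(x)
}

#' Read a MetaPhlAn-style merged taxonomic table
#'
#' Keeps species-level rows only (`|s__` present, no `|t__` strain suffix),
#' extracts the species leaf from the clade string, and converts percent-scale
#' abundances to proportions.
#'
#' @param path path to a TSV with a clade-name first column and one numeric
#'   column per sample; lines starting with `#` are comments (a commented
#'   `#clade_name` header is accepted).
#' @return a [taxonomic_profile].
#' @export
read_taxonomic_profile <- function(path) {
  tab <- read_profile_tsv(path)
  clade <- tab[[1]]
  is_species <- grepl("\\|s__", clade) & !grepl("\\|t__", clade)
  if (!any(is_species)) stop_format("no species-level rows (|s__) in %s", path)
  tab <- tab[is_species, , drop = FALSE]
  clade <- clade[is_species]
  species <- sub(".*\\|s__", "", clade)
  if (anyDuplicated(species)) {
    stop_format("duplicate species label in %s: %s", path,
                paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  abund <- numeric_matrix(tab, path)
  taxonomic_profile(abund / 100, species = species, clade = clade)
}

#' Write a taxonomic profile in MetaPhlAn merged-table dialect
#'
#' @param x a [taxonomic_profile].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxonomic_profile <- function(x, path) {
  clade <- x$clade %||% paste0("k__Bacteria|s__", x$species)
  write_tsv_matrix(x$abundance * 100, clade, "clade_name", path)
}

# ---------------------------------------------------------------------------
# Stratified functional profiles

#' Construct a stratified functional profile
#'
#' The common currency of DNA and RNA functional data: per-feature abundance
#' decomposed into contributing-species strata plus an `"unclassified"`
#' stratum. Rows with `stratum = NA` carry community-only information (either
#' special bookkeeping features or features read without stratification).
#' Community totals are always regenerated from the strata
#' (see [community_totals]); totals carried in input files are used only to
#' record the rounding discrepancy of the upstream tool.
#'
#' @param feature character vector, one entry per row.
#' @param stratum character vector: canonical `"Genus species"`,
#'   `"unclassified"`, or `NA` for community-only rows.
#' @param abundance numeric row x sample matrix, nonnegative.
#' @param level one of `"pathway"`, `"EC"`, `"KO"`, `"gene_family"`.
#' @param input_total_discrepancy max |input community total - stratum sum|
#'   observed at read time.
#' @return an object of class `stratified_profile`.
#' @export
stratified_profile <- function(feature, stratum, abundance, level,
                               input_total_discrepancy = 0) {
  level <- match.arg(level, PROFILE_LEVELS)
  abundance <- as.matrix(abundance)
  stopifnot(length(feature) == nrow(abundance), length(stratum) == nrow(abundance))
  assert_matrix_nonneg(abundance, "stratified abundance")
  key <- paste(feature, ifelse(is.na(stratum), "<community>", stratum), sep = "\r")
  if (anyDuplicated(key)) {
    stop_format("duplicate (feature, stratum) rows: %s",
                gsub("\r", " | ", paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  structure(list(
    feature = as.character(feature),
    stratum = as.character(stratum),
    abundance = abundance,
    level = level,
    samples = colnames(abundance),
    special = intersect(unique(feature), SPECIAL_FEATURES),
    input_total_discrepancy = input_total_discrepancy
  ), class = "stratified_profile")
}

#' @export
print.stratified_profile <- function(x, ...) {
  cat(sprintf("<stratified_profile level=%s> %d features (%d special), %d rows x %d samples\n",
              x$level, length(unique(x$feature)), length(x$special),
              nrow(x$abundance), length(x$samples)))
  invisible(x)
}

#' Community-level feature totals, regenerated from strata
#'
#' For features with stratified rows the total is the exact stratum sum; for
#' community-only rows (specials, unstratified inputs) the row itself.
#'
#' @param x a [stratified_profile].
#' @param keep_special keep UNMAPPED/UNINTEGRATED rows (default TRUE).
#' @return feature x sample numeric matrix.
#' @export
community_totals <- function(x, keep_special = TRUE) {
  tot <- rowsum(x$abundance, group = x$feature)
  if (!keep_special && length(x$special)) {
    tot <- tot[!rownames(tot) %in% x$special, , drop = FALSE]
  }
  tot
}

#' Species-stratum rows of a stratified profile
#'
#' @param x a [stratified_profile].
#' @param drop_unclassified drop the `"unclassified"` stratum (default FALSE).
#' @return list with `feature`, `stratum`, and row x sample `abundance`.
#' @export
stratum_rows <- function(x, drop_unclassified = FALSE) {
  keep <- !is.na(x$stratum)
  if (drop_unclassified) keep <- keep & x$stratum != "unclassified"
  list(feature = x$feature[keep], stratum = x$stratum[keep],
       abundance = x$abundance[keep, , drop = FALSE])
}

# Canonicalize a HUMAnN2 stratum string. Accepts "g__X.s__X_y" and
# "g__X|s__X_y" dialects as well as a bare "s__X_y"; returns "Genus species"
# (underscores in the species epithet become spaces) or "unclassified".
canonical_stratum <- function(s) {
  out <- rep(NA_character_, length(s))
  uncl <- !is.na(s) & s == "unclassified"
  out[uncl] <- "unclassified"
  rest <- !uncl & !is.na(s)
  sp <- sub(".*s__", "", s[rest])
  out[rest] <- gsub("_", " ", sp)
  out
}

# Inverse of canonical_stratum for writing: "Genus species" -> "g__Genus.s__Genus_species".
humann_stratum <- function(s) {
  ifelse(s == "unclassified", "unclassified", {
    us <- gsub(" ", "_", s)
    genus <- sub("_.*", "", us)
    paste0("g__", genus, ".s__", us)
  })
}

#' Read a HUMAnN2-style stratified functional table
#'
#' First column holds `feature`, `feature|g__Genus.s__Genus_species` (or the
#' `|g__Genus|s__...` dialect), or `feature|unclassified`; `UNMAPPED` and
#' `UNINTEGRATED` rows are flagged special. Community rows that coexist with
#' stratum rows are dropped after recording the maximum rounding discrepancy
#' against the stratum sum; totals are regenerated exactly from strata.
#'
#' @param path input TSV; a `# Pathway` / `# Gene Family` header is accepted.
#' @param level table level, see [stratified_profile].
#' @return a [stratified_profile].
#' @export
read_stratified_profile <- function(path, level = "pathway") {
  tab <- read_profile_tsv(path)
  if (nrow(tab) == 0) stop_format("no data rows in %s", path)
  key <- tab[[1]]
  abund <- numeric_matrix(tab, path)
  if (any(abund < 0)) {
    bad <- which(abund < 0, arr.ind = TRUE)[1, ]
    stop_format("negative abundance in %s at row %d, column %d", path, bad[1], bad[2])
  }
  pipe_at <- regexpr("|", key, fixed = TRUE)
  feature <- ifelse(pipe_at > 0, substr(key, 1, pipe_at - 1), key)
  strat_raw <- ifelse(pipe_at > 0, substr(key, pipe_at + 1, nchar(key)), NA_character_)
  stratum <- ifelse(is.na(strat_raw), NA_character_, canonical_stratum(strat_raw))
  stratum[feature %in% SPECIAL_FEATURES] <- NA_character_

  # features having both a community row and stratum rows: record discrepancy,
  # drop the community row (totals are regenerated from strata).
  has_strata <- unique(feature[!is.na(stratum)])
  is_comm <- is.na(stratum)
  redundant <- is_comm & feature %in% has_strata
  discrepancy <- 0
  if (any(redundant)) {
    ssum <- rowsum(abund[!is.na(stratum), , drop = FALSE], feature[!is.na(stratum)])
    comm <- abund[redundant, , drop = FALSE]
    rownames(comm) <- feature[redundant]
    shared <- intersect(rownames(comm), rownames(ssum))
    discrepancy <- max(abs(comm[shared, , drop = FALSE] - ssum[shared, , drop = FALSE]), 0)
    feature <- feature[!redundant]
    stratum <- stratum[!redundant]
    abund <- abund[!redundant, , drop = FALSE]
  }
  stratified_profile(feature, stratum, abund, level = level,
                     input_total_discrepancy = discrepancy)
}

#' Write a stratified profile in HUMAnN2 dialect
#'
#' Emits, per feature, a community row (regenerated stratum sum) followed by
#' its stratum rows; special rows written bare. Header is `# Pathway` or
#' `# Gene Family` depending on level.
#'
#' @param x a [stratified_profile].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_stratified_profile <- function(x, path) {
  header <- if (x$level == "pathway") "# Pathway" else "# Gene Family"
  feats <- setdiff(unique(x$feature), x$special)
  tot <- community_totals(x)
  keys <- character(0)
  rows <- list()
  for (f in feats) {
    keys <- c(keys, f)
    rows[[length(rows) + 1L]] <- tot[f, ]
    idx <- which(x$feature == f & !is.na(x$stratum))
    if (length(idx)) {
      keys <- c(keys, paste0(f, "|", humann_stratum(x$stratum[idx])))
      for (i in idx) rows[[length(rows) + 1L]] <- x$abundance[i, ]
    }
  }
  for (f in intersect(x$special, unique(x$feature))) {
    keys <- c(keys, f)
    rows[[length(rows) + 1L]] <- tot[f, ]
  }
  m <- do.call(rbind, rows)
  colnames(m) <- x$samples
  write_tsv_matrix(m, keys, header, path)
}

# ---------------------------------------------------------------------------
# Metadata and pairing

#' Read the sample metadata sheet
#'
#' @param path CSV or TSV with columns `sample_id`, `subject_id`, `site`,
#'   `status`, `smoking` (delimiter sniffed from the header line).
#' @return a validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  md <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  required <- c("sample_id", "subject_id", "site", "status", "smoking")
  missing <- setdiff(required, names(md))
  if (length(missing)) stop_format("metadata missing required column(s): %s",
                                   paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop_format("duplicate sample_id in metadata")
  bad_site <- setdiff(unique(md$site), ORAL_SITES)
  if (length(bad_site)) stop_format("unknown site value(s): %s", paste(bad_site, collapse = ", "))
  bad_status <- setdiff(unique(md$status), HEALTH_STATUS)
  if (length(bad_status)) stop_format("unknown status value(s): %s", paste(bad_status, collapse = ", "))
  if (anyDuplicated(md[, c("subject_id", "site")])) {
    stop_format("metadata has a repeated (subject, site) pair")
  }
  md
}

#' Write the sample metadata sheet (TSV)
#' @param md metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pair DNA and RNA profiles with sample metadata
#'
#' Intersects the sample sets of the DNA layer, the RNA layer, the metadata
#' (and the optional taxonomic profile) and reorders every layer identically.
#' Samples missing from any input are dropped with a warning naming them.
#'
#' @param dna,rna [stratified_profile]s at the same level.
#' @param metadata metadata data.frame (see [read_sample_metadata]).
#' @param taxa optional [taxonomic_profile].
#' @return an object of class `paired_omics` with elements `dna`, `rna`,
#'   `taxa`, `metadata`, `samples`.
#' @export
pair_profiles <- function(dna, rna, metadata, taxa = NULL) {
  stopifnot(inherits(dna, "stratified_profile"), inherits(rna, "stratified_profile"))
  if (dna$level != rna$level) {
    stop_format("DNA level (%s) and RNA level (%s) differ", dna$level, rna$level)
  }
  metadata <- validate_metadata(metadata)
  sets <- list(dna = dna$samples, rna = rna$samples, metadata = metadata$sample_id)
  if (!is.null(taxa)) sets$taxa <- taxa$samples
  common <- Reduce(intersect, sets)
  if (length(common) == 0) stop_format("no samples shared by DNA, RNA and metadata")
  dropped <- setdiff(unique(unlist(sets)), common)
  if (length(dropped)) {
    warning(sprintf("dropping %d sample(s) absent from at least one layer: %s",
                    length(dropped), paste(sort(dropped), collapse = ", ")),
            call. = FALSE)
  }
  common <- sets$metadata[sets$metadata %in% common]  # metadata order is canonical
  subset_samples <- function(p, keep) {
    p$abundance <- p$abundance[, keep, drop = FALSE]
    p$samples <- keep
    p
  }
  out <- list(
    dna = subset_samples(dna, common),
    rna = subset_samples(rna, common),
    taxa = if (!is.null(taxa)) subset_samples(taxa, common),
    metadata = metadata[match(common, metadata$sample_id), , drop = FALSE],
    samples = common
  )
  rownames(out$metadata) <- NULL
  structure(out, class = "paired_omics")
}

#' @export
print.paired_omics <- function(x, ...) {
  cat(sprintf("<paired_omics level=%s> %d samples, %d subjects\n",
              x$dna$level, length(x$samples), length(unique(x$metadata$subject_id))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Filtering / regrouping

#' Remove UNMAPPED / UNINTEGRATED bookkeeping rows
#'
#' These rows are excluded from alpha/beta-diversity analysis (they are kept
#' for linear modeling, where they damp artificial inflation of housekeeping
#' functions in poorly characterized samples). With `renormalize = TRUE`, each
#' sample's community totals are rescaled to sum to 1.
#'
#' @param profile a [stratified_profile].
#' @param renormalize rescale per-sample totals to 1 after removal.
#' @return a [stratified_profile].
#' @export
strip_special_features <- function(profile, renormalize = FALSE) {
  keep <- !profile$feature %in% SPECIAL_FEATURES
  if (all(keep) && !renormalize) return(profile)
  ab <- profile$abundance[keep, , drop = FALSE]
  fe <- profile$feature[keep]
  st <- profile$stratum[keep]
  if (renormalize) {
    tot <- colSums(rowsum(ab, fe))
    tot[tot == 0] <- 1
    ab <- sweep(ab, 2, tot, "/")
  }
  stratified_profile(fe, st, ab, level = profile$level,
                     input_total_discrepancy = profile$input_total_discrepancy)
}

#' Regroup gene families to broader targets (e.g. EC numbers, KO)
#'
#' Target-group abundance is the sum of mapped source abundances, per stratum
#' per sample; a source mapping to several targets contributes to each.
#' Special rows are never regrouped and are carried through unchanged.
#'
#' @param profile a [stratified_profile].
#' @param mapping data.frame with columns `from` (source feature) and `to`
#'   (target group); many-to-many allowed.
#' @param unmapped_policy `"drop"` (default) or `"keep"` features without a
#'   mapping.
#' @param level level label for the output profile.
#' @return a [stratified_profile].
#' @export
regroup_gene_families <- function(profile, mapping,
                                  unmapped_policy = c("drop", "keep"),
                                  level = "EC") {
  unmapped_policy <- match.arg(unmapped_policy)
  stopifnot(all(c("from", "to") %in% names(mapping)))
  present <- intersect(unique(mapping$from), unique(profile$feature))
  if (length(present) == 0) stop_format("mapping covers no feature present in the profile")

  is_special <- profile$feature %in% SPECIAL_FEATURES
  map_hit <- profile$feature %in% present & !is_special
  pieces_f <- list(); pieces_s <- list(); pieces_a <- list()
  hit_map <- mapping[mapping$from %in% present, , drop = FALSE]
  for (i in seq_len(nrow(hit_map))) {
    idx <- which(profile$feature == hit_map$from[i])
    pieces_f[[i]] <- rep(hit_map$to[i], length(idx))
    pieces_s[[i]] <- profile$stratum[idx]
    pieces_a[[i]] <- profile$abundance[idx, , drop = FALSE]
  }
  fe <- unlist(pieces_f); st <- unlist(pieces_s)
  ab <- do.call(rbind, pieces_a)
  key <- paste(fe, ifelse(is.na(st), "<community>", st), sep = "\r")
  agg <- rowsum(ab, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  fe2 <- vapply(parts, `[`, "", 1)
  st2 <- vapply(parts, function(p) if (p[2] == "<community>") NA_character_ else p[2], "")
  keep_extra <- is_special | (!map_hit & !is_special & unmapped_policy == "keep")
  fe2 <- c(fe2, profile$feature[keep_extra])
  st2 <- c(st2, profile$stratum[keep_extra])
  ab2 <- rbind(agg, profile$abundance[keep_extra, , drop = FALSE])
  colnames(ab2) <- profile$samples
  stratified_profile(fe2, st2, ab2, level = level,
                     input_total_discrepancy = profile$input_total_discrepancy)
}

#' Prevalence filter ("at least 20% of the samples")
#'
#' A feature is retained iff it is nonzero in at least
#' `ceiling(min_fraction * n_samples)` samples; with the study's n = 59 and
#' the default 0.2, the threshold is 12 samples.
#'
#' @param table feature x sample numeric matrix.
#' @param min_fraction minimum fraction of samples, in (0, 1]; default 0.2.
#' @return the filtered matrix (possibly with zero rows, with a warning).
#' @export
filter_prevalence <- function(table, min_fraction = 0.2) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  table <- as.matrix(table)
  need <- ceiling(min_fraction * ncol(table))
  nz <- rowSums(table > 0)
  keep <- nz >= need
  message(sprintf("prevalence filter (>= %d/%d samples): kept %d, dropped %d features",
                  need, ncol(table), sum(keep), sum(!keep)))
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("prevalence filter removed every feature", call. = FALSE)
  out
}

# ---------------------------------------------------------------------------
# Shared low-level TSV helpers

read_profile_tsv <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_format("empty file: %s", path)
  is_comment <- startsWith(lines, "#")
  if (is_comment[1] && sum(!is_comment) > 0) {
    # a commented header ("#clade_name...", "# Pathway...") is the last
    # tab-containing comment preceding the data block; other comments are noise
    lead <- seq_len(which(!is_comment)[1] - 1)
    cand <- lead[grepl("\t", lines[lead])]
    if (length(cand)) {
      header <- sub("^#\\s*", "", lines[max(cand)])
      lines <- c(header, lines[!is_comment])
    } else {
      lines <- lines[!is_comment]
    }
  } else {
    lines <- lines[!is_comment]
  }
  if (length(lines) < 2) stop_format("no data rows in %s", path)
  tab <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           quote = "", comment.char = "", check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop_format("no sample columns in %s", path)
  tab
}

numeric_matrix <- function(tab, path) {
  m <- matrix(NA_real_, nrow(tab), ncol(tab) - 1,
              dimnames = list(NULL, names(tab)[-1]))
  for (j in 2:ncol(tab)) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(is.na(v) & !is.na(tab[[j]]))
    if (length(bad)) {
      stop_format("unparseable numeric value '%s' in %s at data row %d, column '%s'",
                  tab[[j]][bad[1]], path, bad[1], names(tab)[j])
    }
    m[, j - 1] <- v
  }
  m
}

write_tsv_matrix <- function(m, row_keys, first_col_name, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(first_col_name, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(row_keys, body, sep = "\t"), con)
  invisible(path)
}
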