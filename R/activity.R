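# Transcriptional activity: log10(RNA/DNA) at community-feature and
# species-feature resolution, species-level summaries, and contributional
# species diversity of functional features.

#' Compute a log10(RNA/DNA) activity table
#'
#' DNA and RNA layers are stripped of UNMAPPED/UNINTEGRATED rows and
#' renormalized to proportions before the ratio. Positive values mean a
#' feature (or a species' contribution to it) is transcribed above its genomic
#' representation; negative values below it.
#'
#' Zero handling (`pseudocount_policy`):
#' \describe{
#'   \item{half_min_nonzero}{when either side is zero, half the smallest
#'     nonzero proportion of the respective table is added to both numerator
#'     and denominator; cells that are zero in both layers stay undefined.}
#'   \item{fixed}{as above with a fixed pseudocount (`pseudocount`).}
#'   \item{none}{cells with a zero in either layer are masked undefined.}
#' }
#'
#' @param paired a `paired_omics` dataset.
#' @param level `"community_feature"` (per-feature totals) or
#'   `"species_feature"` (per species-stratum rows).
#' @param pseudocount_policy zero-handling policy, see Details.
#' @param pseudocount fixed pseudocount for `policy = "fixed"`.
#' @param keep_special retain UNMAPPED/UNINTEGRATED rows as features instead
#'   of stripping them (default FALSE — strip, as for diversity analysis; use
#'   TRUE for tables feeding linear models, where the bookkeeping mass damps
#'   artificial inflation of well-characterized functions).
#' @return an `activity_table`: `feature`, `stratum` (NA at community level),
#'   `samples`, `value` (log10 ratio matrix), `mask` (TRUE where defined),
#'   `detected` (TRUE where nonzero in both layers), `provenance`.
#' @export
compute_activity_table <- function(paired,
                                   level = c("community_feature", "species_feature"),
                                   pseudocount_policy = c("half_min_nonzero", "fixed", "none"),
                                   pseudocount = 1e-8, keep_special = FALSE) {
  stopifnot(inherits(paired, "paired_omics"))
  level <- match.arg(level)
  policy <- match.arg(pseudocount_policy)
  if (paired$dna$level != paired$rna$level) stop_format("DNA/RNA level mismatch")
  renorm <- function(p) {
    tot <- colSums(rowsum(p$abundance, p$feature))
    tot[tot == 0] <- 1
    p$abundance <- sweep(p$abundance, 2, tot, "/")
    p
  }
  if (keep_special) {
    dna <- renorm(paired$dna)
    rna <- renorm(paired$rna)
  } else {
    dna <- strip_special_features(paired$dna, renormalize = TRUE)
    rna <- strip_special_features(paired$rna, renormalize = TRUE)
  }

  if (level == "community_feature") {
    D <- community_totals(dna); R <- community_totals(rna)
    feats <- sort(union(rownames(D), rownames(R)))
    Dm <- expand_rows(D, feats); Rm <- expand_rows(R, feats)
    feature <- feats; stratum <- rep(NA_character_, length(feats))
  } else {
    sd_ <- stratum_rows(dna); sr <- stratum_rows(rna)
    kd <- paste(sd_$feature, sd_$stratum, sep = "\r")
    kr <- paste(sr$feature, sr$stratum, sep = "\r")
    keys <- sort(union(kd, kr))
    Dm <- expand_rows(`rownames<-`(sd_$abundance, kd), keys)
    Rm <- expand_rows(`rownames<-`(sr$abundance, kr), keys)
    parts <- strsplit(keys, "\r", fixed = TRUE)
    feature <- vapply(parts, `[`, "", 1)
    stratum <- vapply(parts, `[`, "", 2)
  }

  detected <- Dm > 0 & Rm > 0
  both_zero <- Dm == 0 & Rm == 0
  if (policy == "none") {
    mask <- detected
    value <- matrix(NA_real_, nrow(Dm), ncol(Dm))
    value[mask] <- log10(Rm[mask] / Dm[mask])
  } else {
    eps_d <- if (policy == "fixed") pseudocount else 0.5 * min(Dm[Dm > 0])
    eps_r <- if (policy == "fixed") pseudocount else 0.5 * min(Rm[Rm > 0])
    mask <- !both_zero
    D2 <- Dm; R2 <- Rm
    needs <- (Dm == 0 | Rm == 0) & mask
    D2[needs] <- Dm[needs] + eps_d
    R2[needs] <- Rm[needs] + eps_r
    value <- matrix(NA_real_, nrow(Dm), ncol(Dm))
    value[mask] <- log10(R2[mask] / D2[mask])
  }
  dimnames(value) <- dimnames(mask) <- dimnames(detected) <-
    list(rownames(Dm), paired$samples)
  structure(list(
    level = level, feature = feature, stratum = stratum,
    samples = paired$samples, value = value, mask = mask, detected = detected,
    provenance = list(pseudocount_policy = policy,
                      pseudocount = if (policy == "fixed") pseudocount)
  ), class = "activity_table")
}

expand_rows <- function(m, keys) {
  out <- matrix(0, length(keys), ncol(m), dimnames = list(keys, colnames(m)))
  hit <- intersect(keys, rownames(m))
  out[hit, ] <- m[hit, , drop = FALSE]
  out
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("<activity_table level=%s policy=%s> %d rows x %d samples (%.1f%% defined)\n",
              x$level, x$provenance$pseudocount_policy, nrow(x$value),
              length(x$samples), 100 * mean(x$mask)))
  invisible(x)
}

#' Per-species mean activity within samples
#'
#' For each species and sample, the arithmetic mean of log10(RNA/DNA) over the
#' features where that species' stratum is detected (nonzero) in both the
#' metagenome and the metatranscriptome; species with no qualifying feature in
#' a sample are undefined.
#'
#' @param stratified_activity an `activity_table` at `species_feature` level.
#' @return list with species x sample matrices `mean_activity` and
#'   `n_pathways_used`.
#' @export
summarize_species_activity <- function(stratified_activity) {
  x <- stratified_activity
  stopifnot(inherits(x, "activity_table"))
  if (x$level != "species_feature") stop_format("species_feature-level activity required")
  keep <- x$stratum != "unclassified"
  sp <- x$stratum[keep]
  use <- x$detected[keep, , drop = FALSE] & x$mask[keep, , drop = FALSE]
  v <- x$value[keep, , drop = FALSE]
  v[!use] <- 0
  n <- rowsum(use + 0L, sp)
  s <- rowsum(v, sp)
  mean_act <- s / n
  mean_act[n == 0] <- NA_real_
  colnames(mean_act) <- colnames(n) <- x$samples
  list(mean_activity = mean_act, n_pathways_used = n)
}

#' Contributional species diversity of functional features
#'
#' Per feature: richness = number of named species strata nonzero in at least
#' one sample; Shannon diversity (natural log) of the species-contribution
#' proportions averaged over samples; mean community relative abundance.
#' Features whose richness falls below `min_rna_species` are flagged (kept in
#' the table, excluded from default reporting) — apply to the RNA layer to
#' reproduce the "expressed by at least two species" display filter.
#'
#' @param profile a [stratified_profile] with named species strata.
#' @param min_rna_species flag threshold on contributing species (default 2).
#' @return data.frame: `feature`, `richness`, `shannon`, `mean_abundance`,
#'   `flagged`.
#' @export
contributional_diversity <- function(profile, min_rna_species = 2) {
  stopifnot(inherits(profile, "stratified_profile"))
  sr <- stratum_rows(profile, drop_unclassified = TRUE)
  if (length(sr$feature) == 0) stop_format("profile has no named species strata")
  feats <- unique(sr$feature)
  tot <- community_totals(profile, keep_special = FALSE)
  res <- lapply(feats, function(f) {
    idx <- which(sr$feature == f)
    ab <- sr$abundance[idx, , drop = FALSE]
    richness <- sum(rowSums(ab) > 0)
    fs <- colSums(ab)
    ok <- fs > 0
    shannon <- if (richness <= 1 || !any(ok)) 0 else {
      p <- rowMeans(sweep(ab[, ok, drop = FALSE], 2, fs[ok], "/"))
      p <- p[p > 0] / sum(p)
      -sum(p * log(p))
    }
    data.frame(feature = f, richness = richness, shannon = shannon,
               mean_abundance = mean(tot[f, ]))
  })
  out <- do.call(rbind, res)
  out$flagged <- out$richness < min_rna_species
  rownames(out) <- NULL
  out
}

#' Overall per-sample bacterial activity
#'
#' Mean of the defined community-level log10(RNA/DNA) values within each
#' sample; a sample with no defined cells is NA with a warning.
#'
#' @param activity an `activity_table` at `community_feature` level.
#' @return named numeric vector, one value per sample.
#' @export
overall_sample_activity <- function(activity) {
  stopifnot(inherits(activity, "activity_table"))
  if (activity$level != "community_feature") {
    stop_format("community_feature-level activity required")
  }
  v <- activity$value; v[!activity$mask] <- 0
  n <- colSums(activity$mask)
  out <- colSums(v) / n
  if (any(n == 0)) {
    warning(sprintf("sample(s) with no defined activity: %s",
                    paste(activity$samples[n == 0], collapse = ", ")), call. = FALSE)
    out[n == 0] <- NA_real_
  }
  names(out) <- activity$samples
  out
}

#' Long-format export of an activity table
#'
#' @param x an `activity_table`.
#' @return data.frame: `feature`, `stratum`, `sample`, `log10_ratio`, `defined`.
#' @export
activity_long <- function(x) {
  stopifnot(inherits(x, "activity_table"))
  data.frame(
    feature = rep(x$feature, times = length(x$samples)),
    stratum = rep(x$stratum, times = length(x$samples)),
    sample = rep(x$samples, each = length(x$feature)),
    log10_ratio = as.vector(x$value),
    defined = as.vector(x$mask),
    stringsAsFactors = FALSE
  )
}
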