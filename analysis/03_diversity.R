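#!/usr/bin/env Rscript
# Stage 3 — alpha diversity, Aitchison and ratio beta diversity, PCoA with
# Shepard fidelity, and PERMANOVA / PERMDISP with subject-restricted
# permutations.

library(oralactivity)

in_dir <- "results/simulated_study"
out <- "results/diversity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- as.integer(Sys.getenv("ORALACTIVITY_SEED", "1"))

dna <- read_stratified_profile(file.path(in_dir, "dna_pathabundance.tsv"))
rna <- read_stratified_profile(file.path(in_dir, "rna_pathabundance.tsv"))
taxa <- read_taxonomic_profile(file.path(in_dir, "taxa_metaphlan.tsv"))
md <- read_sample_metadata(file.path(in_dir, "metadata.tsv"))
paired <- pair_profiles(dna, rna, md, taxa = taxa)
md <- paired$metadata

# taxonomic alpha/beta diversity
tm <- sweep(paired$taxa$abundance, 2, colSums(paired$taxa$abundance), "/")
alpha <- alpha_diversity(tm)
write.table(alpha, file.path(out, "alpha_taxa.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
kw <- kruskal_wallis_groups(alpha$shannon, md$site)
d_ait <- aitchison_distance(tm)
perm_site <- permanova_restricted(d_ait, md$site, strata = md$subject_id,
                                  seed = seed, term = "site")
perm_status <- permanova_restricted(d_ait, md$status, strata = md$subject_id,
                                    seed = seed + 1, term = "status")
disp <- permdisp(d_ait, md$site, seed = seed + 2)
ord <- pcoa_with_shepard(d_ait, k = 2)

# pathway-activity beta diversity (shifted weighted Jaccard on log ratios)
act <- compute_activity_table(paired)
d_ratio <- ratio_beta_diversity(act)
perm_ratio_status <- permanova_restricted(d_ratio, md$status,
                                          strata = md$subject_id,
                                          seed = seed + 3, term = "status")
ord_ratio <- pcoa_with_shepard(d_ratio, k = 2)

for (x in list(c("dist_aitchison_taxa.tsv", "d_ait"),
               c("dist_jaccard_activity.tsv", "d_ratio"))) {
  m <- as.matrix(get(x[2]))
  write.table(data.frame(sample = rownames(m), m, check.names = FALSE),
              file.path(out, x[1]), sep = "\t", quote = FALSE, row.names = FALSE)
}

cat(sprintf("alpha diversity ~ site: Kruskal-Wallis H = %.2f, p = %.3g\n", kw$H, kw$p))
print(perm_site); print(perm_status)
cat(sprintf("PERMDISP site: F = %.2f, p = %.3g (dispersion homogeneity check)\n",
            disp$F, disp$p))
cat(sprintf("taxa PCoA: %.1f%% + %.1f%% explained, Shepard r = %.3f\n",
            100 * ord$prop_explained[1], 100 * ord$prop_explained[2], ord$shepard_r))
print(perm_ratio_status)
cat(sprintf("activity PCoA Shepard r = %.3f\n", ord_ratio$shepard_r))
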