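# Parsing, validation, filtering and round-trips of the taxonomic and
# stratified functional table dialects.

test_that("MetaPhlAn reader keeps species rows and extracts leaves", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "#mpa_v30_CHOCOPhlAn_201901",
    "clade_name\tS1\tS2",
    "k__Bacteria\t100\t100",
    "k__Bacteria|p__Bacteroidetes|g__Tannerella\t12\t3",
    "k__Bacteria|p__Bacteroidetes|g__Tannerella|s__Tannerella_forsythia\t12\t3",
    "k__Bacteria|p__Bacteroidetes|g__Tannerella|s__Tannerella_forsythia|t__SGB1\t12\t3",
    "k__Bacteria|p__Firmicutes|g__Streptococcus|s__Streptococcus_oralis\t30\t55"
  ), path)
  tp <- read_taxonomic_profile(path)
  expect_setequal(tp$species, c("Tannerella_forsythia", "Streptococcus_oralis"))
  expect_equal(unname(tp$abundance["Tannerella_forsythia", ]), c(0.12, 0.03))
})

test_that("taxonomic reader rejects malformed tables", {
  genus_only <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clade_name\tS1", "k__Bacteria|g__Rothia\t50"), genus_only)
  expect_error(read_taxonomic_profile(genus_only), "no species-level rows")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clade_name\tS1",
               "k__A|s__Same_species\t10",
               "k__B|s__Same_species\t20"), dup)
  expect_error(read_taxonomic_profile(dup), "duplicate species")

  badnum <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clade_name\tS1", "k__A|s__Sp_x\tnot_a_number"), badnum)
  expect_error(read_taxonomic_profile(badnum), "unparseable numeric.*column 'S1'")
})

test_that("taxonomic write-then-read round-trips bit-identically", {
  # binary-exact percent values so the percent<->proportion scaling is lossless
  ab <- matrix(c(0.125, 0.25, 0.5, 0.0625, 0.375, 0.25), 3, 2,
               dimnames = list(NULL, c("S1", "S2")))
  tp <- taxonomic_profile(ab, species = c("Rothia_dentocariosa", "Streptococcus_oralis",
                                          "Tannerella_forsythia"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomic_profile(tp, path)
  tp2 <- read_taxonomic_profile(path)
  expect_identical(tp2$abundance[tp$species, ], tp$abundance)

  # general values round-trip to full double precision
  set.seed(1)
  ab2 <- matrix(stats::runif(6, 0, 0.3), 3, 2, dimnames = list(NULL, c("S1", "S2")))
  tp3 <- taxonomic_profile(ab2, species = tp$species)
  write_taxonomic_profile(tp3, path)
  expect_equal(read_taxonomic_profile(path)$abundance[tp$species, ], tp3$abundance,
               tolerance = 1e-14)
})

test_that("stratified reader separates strata, flags specials, regenerates totals", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# Pathway\tS1\tS2",
    "UNMAPPED\t0.40\t0.30",
    "PWY1\t0.35\t0.42",                           # community row: off by rounding
    "PWY1|g__Rothia.s__Rothia_dentocariosa\t0.20\t0.30",
    "PWY1|g__Streptococcus|s__Streptococcus_oralis\t0.10\t0.10",
    "PWY1|unclassified\t0.05\t0.01",
    "PWY2|g__Tannerella.s__Tannerella_forsythia\t0.25\t0.29" # no community row
  ), path)
  sp <- read_stratified_profile(path)
  expect_identical(sp$special, "UNMAPPED")
  tot <- community_totals(sp)
  expect_equal(unname(tot["PWY1", ]), c(0.35, 0.41))  # regenerated stratum sum
  expect_equal(sp$input_total_discrepancy, 0.01)
  # both stratum dialects normalize to "Genus species"
  sr <- stratum_rows(sp)
  expect_setequal(unique(sr$stratum),
                  c("Rothia dentocariosa", "Streptococcus oralis",
                    "Tannerella forsythia", "unclassified"))
})

test_that("stratified reader rejects empty and negative input", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# Pathway\tS1", empty)
  expect_error(read_stratified_profile(empty), "no data rows")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# Pathway\tS1", "PWY1\t-0.5"), neg)
  expect_error(read_stratified_profile(neg), "negative abundance")
})

test_that("stratified profile round-trips exactly", {
  sp <- tiny_stratified()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stratified_profile(sp, path)
  sp2 <- read_stratified_profile(path)
  key <- function(x) order(paste(x$feature, x$stratum))
  expect_identical(sp2$abundance[key(sp2), ], sp$abundance[key(sp), ])
  expect_identical(sp2$stratum[key(sp2)], sp$stratum[key(sp)])
  expect_identical(community_totals(sp2), community_totals(sp))
})

test_that("pair_profiles intersects, warns and order-normalizes", {
  dna <- tiny_stratified()
  rna <- tiny_stratified()
  md <- tiny_metadata()

  # RNA missing S4, metadata extra S5
  rna$abundance <- rna$abundance[, c("S2", "S3", "S1")]  # shuffled too
  rna$samples <- colnames(rna$abundance)
  md5 <- rbind(md, data.frame(sample_id = "S5", subject_id = "C", site = "saliva",
                              status = "healthy", smoking = "yes"))
  expect_warning(p <- pair_profiles(dna, rna, md5), "S4.*S5")
  expect_identical(p$samples, c("S1", "S2", "S3"))
  expect_identical(colnames(p$dna$abundance), colnames(p$rna$abundance))
  expect_identical(p$metadata$sample_id, p$samples)

  expect_no_warning(pair_profiles(dna, tiny_stratified(), md))
  expect_error(pair_profiles(dna, tiny_stratified(), md[0, ]), "no samples shared")
  expect_error(pair_profiles(dna, tiny_stratified(), md[, -2]), "missing required column")
})

test_that("strip_special_features removes bookkeeping rows and renormalizes", {
  sp <- tiny_stratified()
  stripped <- strip_special_features(sp, renormalize = TRUE)
  expect_false("UNMAPPED" %in% stripped$feature)
  expect_equal(unname(colSums(community_totals(stripped))), rep(1, 4), tolerance = 1e-9)

  # hand case: removing UNMAPPED = 0.4 from (0.3, 0.3, 0.4) renormalizes to (0.5, 0.5)
  f <- c("P1", "P2", "UNMAPPED")
  ab <- matrix(c(0.3, 0.3, 0.4), 3, 1, dimnames = list(NULL, "S1"))
  sp2 <- stratified_profile(f, c(NA, NA, NA), ab, level = "pathway")
  out <- strip_special_features(sp2, renormalize = TRUE)
  expect_equal(unname(community_totals(out)[, 1]), c(0.5, 0.5))

  no_special <- stratified_profile(c("P1"), NA_character_,
                                   matrix(1, 1, 1, dimnames = list(NULL, "S1")),
                                   level = "pathway")
  expect_identical(strip_special_features(no_special), no_special)
})

test_that("regroup_gene_families sums mapped features per stratum", {
  f <- c("UniRef90_A", "UniRef90_A", "UniRef90_B", "UniRef90_C", "UNMAPPED")
  s <- c("Rothia dentocariosa", "unclassified", "Rothia dentocariosa", "Tannerella forsythia", NA)
  ab <- matrix(c(1, 2, 3, 4, 5), 5, 1, dimnames = list(NULL, "S1"))
  gp <- stratified_profile(f, s, ab, level = "gene_family")
  mapping <- data.frame(from = c("UniRef90_A", "UniRef90_B"),
                        to = c("EC 1.2.1.12", "EC 1.2.1.12"))
  rg <- regroup_gene_families(gp, mapping, unmapped_policy = "drop")
  # A and B both map to the same EC: Rothia stratum = 1 + 3
  sr <- stratum_rows(rg)
  expect_equal(sr$abundance[sr$stratum == "Rothia dentocariosa", 1], 4)
  expect_false("UniRef90_C" %in% rg$feature)     # dropped
  expect_true("UNMAPPED" %in% rg$feature)        # specials carried through

  kept <- regroup_gene_families(gp, mapping, unmapped_policy = "keep")
  expect_true("UniRef90_C" %in% kept$feature)

  ident <- regroup_gene_families(gp, data.frame(from = unique(f[1:4]), to = unique(f[1:4])),
                                 unmapped_policy = "keep", level = "gene_family")
  expect_equal(community_totals(ident)[unique(f), ], community_totals(gp)[unique(f), ])

  expect_error(regroup_gene_families(gp, data.frame(from = "nope", to = "x")),
               "covers no feature")
})

test_that("prevalence filter uses the ceiling rule and is idempotent", {
  # study scale: n = 59 samples, 20% -> threshold 12
  set.seed(42)
  m <- matrix(0, 3, 59, dimnames = list(c("kept", "dropped", "zero"), NULL))
  m["kept", 1:12] <- 1
  m["dropped", 1:11] <- 1
  suppressMessages({
    out <- filter_prevalence(m, 0.2)
    expect_identical(rownames(out), "kept")
    expect_identical(filter_prevalence(out, 0.2), out)  # idempotent
    # min_fraction = 1 keeps only ubiquitous features
    m2 <- rbind(all = 1, m)
    expect_identical(rownames(filter_prevalence(m2, 1)), "all")
    # all-zero features always dropped
    expect_false("zero" %in% rownames(filter_prevalence(m, 0.01)))
    expect_warning(filter_prevalence(matrix(0, 2, 5), 0.2), "every feature")
  })
})

test_that("strip-then-regroup commutes with regroup-then-strip", {
  gp <- tiny_stratified(level = "gene_family")
  mapping <- data.frame(from = c("PWY1", "PWY2"), to = c("EC 1", "EC 1"))
  a <- regroup_gene_families(strip_special_features(gp), mapping)
  b <- strip_special_features(regroup_gene_families(gp, mapping))
  expect_equal(community_totals(a), community_totals(b))
})
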