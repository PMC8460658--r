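# Kruskal-Wallis, restricted-permutation PERMANOVA (with vegan::adonis2 as
# independent cross-check), PERMDISP, the Dirichlet-CLR test, the
# repeated-measures log-linear model, and BH FDR.

test_that("Kruskal-Wallis matches the hand rank computation", {
  kw <- kruskal_wallis_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)
  expect_error(kruskal_wallis_groups(1:5, rep("a", 5)), "two groups")
  expect_warning(kw0 <- kruskal_wallis_groups(rep(2, 6), rep(c("a", "b"), 3)),
                 "identical")
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)
})

test_that("PERMANOVA pseudo-F and R2 match a brute-force loop oracle", {
  set.seed(20)
  x <- matrix(stats::rnorm(9 * 3), 9, 3)
  x[1:3, 1] <- x[1:3, 1] + 2
  g <- rep(c("a", "b", "c"), each = 3)
  d <- stats::dist(x)
  res <- permanova_restricted(d, g, n_perm = 99, seed = 1)

  D2 <- as.matrix(d)^2
  n <- 9
  ss_t <- sum(D2[upper.tri(D2)]) / n
  ss_w <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    sub <- D2[idx, idx]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  expect_equal(res$R2, (ss_t - ss_w) / ss_t, tolerance = 1e-10)
  expect_equal(res$pseudo_F, ((ss_t - ss_w) / 2) / (ss_w / 6), tolerance = 1e-10)

  # independent cross-check: vegan::adonis2 on the same distances
  av <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(res$R2, av$R2[1], tolerance = 1e-10)
  expect_equal(res$pseudo_F, av$F[1], tolerance = 1e-10)
})

test_that("total separation attains the minimum permutation p", {
  set.seed(21)
  x <- rbind(matrix(stats::rnorm(20, 0, 0.05), 10, 2),
             matrix(stats::rnorm(20, 10, 0.05), 10, 2))
  g <- rep(c("a", "b"), each = 10)
  res <- permanova_restricted(stats::dist(x), g, n_perm = 999, seed = 2)
  expect_equal(res$p_value, 0.001)
})

test_that("restricted schemes respect the repeated-measures design", {
  set.seed(22)
  md <- expand.grid(subject = sprintf("S%02d", 1:8), site = c("plaque", "tongue", "saliva"),
                    stringsAsFactors = FALSE)
  md$status <- ifelse(md$subject %in% sprintf("S%02d", 1:4), "healthy", "periodontitis")
  x <- matrix(stats::rnorm(nrow(md) * 4), nrow(md), 4)
  d <- stats::dist(x)

  within <- permanova_restricted(d, md$site, strata = md$subject, n_perm = 99, seed = 3)
  expect_identical(within$strata, "within_subject")
  between <- permanova_restricted(d, md$status, strata = md$subject, n_perm = 99, seed = 3)
  expect_identical(between$strata, "between_subject")
  expect_true(between$p_value >= 1 / 100)
  # status confounded with a single level -> error
  expect_error(permanova_restricted(d, rep("x", nrow(md)), strata = md$subject),
               "single level")
  # factor == subject: nothing to permute
  expect_error(permanova_restricted(d, md$subject, strata = md$subject),
               "confounded")
})

test_that("unrestricted permanova p agrees with vegan within Monte-Carlo error", {
  set.seed(23)
  x <- matrix(stats::rnorm(12 * 3), 12, 3)
  x[1:6, ] <- x[1:6, ] + 0.8
  g <- rep(c("a", "b"), each = 6)
  d <- stats::dist(x)
  res <- permanova_restricted(d, g, n_perm = 999, seed = 4)
  av <- vegan::adonis2(d ~ g, permutations = 999)
  expect_lt(abs(res$p_value - av$`Pr(>F)`[1]), 0.05)
})

test_that("permdisp detects unequal dispersion and tolerates equal", {
  set.seed(24)
  n <- 20
  x_eq <- rbind(matrix(stats::rnorm(n * 2), n, 2), matrix(stats::rnorm(n * 2), n, 2))
  g <- rep(c("a", "b"), each = n)
  pd <- permdisp(stats::dist(x_eq), g, n_perm = 199, seed = 5)
  expect_true(all(pd$distances >= 0))
  expect_gt(pd$p, 0.05)

  # one group 4x dispersion: strong rejection
  x_un <- rbind(matrix(stats::rnorm(n * 2), n, 2), matrix(stats::rnorm(n * 2, 0, 4), n, 2))
  pd2 <- permdisp(stats::dist(x_un), g, n_perm = 199, seed = 6)
  expect_lt(pd2$p, 0.05)
  # cross-check distances against vegan::betadisper centroids
  bd <- vegan::betadisper(stats::dist(x_un), g, type = "centroid")
  expect_equal(unname(pd2$distances), unname(bd$distances), tolerance = 1e-8)
  expect_error(permdisp(stats::dist(x_un[1:3, ]), c("a", "b", "b")), "at least 2")
})

test_that("BH correction matches the hand step-up and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(25)
  p <- stats::runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_equal(bh_fdr(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("Dirichlet-CLR test finds a planted fold change and is deterministic", {
  set.seed(26)
  nfeat <- 50; nper <- 20
  base <- stats::rexp(nfeat) + 0.2
  mk <- function(shift) {
    p <- base; p[1] <- p[1] * shift
    stats::rmultinom(nper, 1e4, p / sum(p))
  }
  counts <- cbind(mk(8), mk(1))
  rownames(counts) <- sprintf("f%02d", seq_len(nfeat))
  g <- rep(c("case", "control"), each = nper)
  res <- clr_dirichlet_test(counts, g, n_instances = 64, seed = 7)
  expect_identical(res$feature[1], "f01")          # smallest q
  expect_lt(res$q[1], 0.05)
  res2 <- clr_dirichlet_test(counts, g, n_instances = 64, seed = 7)
  expect_identical(res, res2)

  # exchangeable null: both groups are the same samples
  same <- cbind(counts[, 1:10], counts[, 1:10])
  null <- clr_dirichlet_test(same, rep(c("x", "y"), each = 10), n_instances = 64, seed = 8)
  expect_lt(max(abs(null$effect)), 0.2)
  expect_gte(min(null$q), 0.5)
  expect_error(clr_dirichlet_test(counts, rep("a", ncol(counts))), "two groups")
})

test_that("log-linear model recovers planted effects and honors prevalence", {
  set.seed(27)
  n_subj <- 22; sites <- c("plaque", "tongue", "saliva")
  md <- data.frame(
    sample_id = paste0("s", 1:(n_subj * 3)),
    subject_id = rep(sprintf("S%02d", 1:n_subj), each = 3),
    site = rep(sites, n_subj),
    status = rep(rep(c("healthy", "periodontitis"), each = 3), length.out = n_subj * 3),
    smoking = "no", stringsAsFactors = FALSE
  )
  md$status <- rep(c("healthy", "periodontitis"), each = 3 * 11)[1:nrow(md)]
  nfeat <- 60
  tab <- matrix(stats::rnorm(nfeat * nrow(md), 0, 0.3), nfeat, nrow(md),
                dimnames = list(sprintf("f%02d", 1:nfeat), md$sample_id))
  planted <- 1:6
  tab[planted, md$status == "periodontitis"] <-
    tab[planted, md$status == "periodontitis"] - 0.5
  res <- loglinear_differential(tab, md, fixed_terms = c("status", "site"),
                                subject_random = TRUE, transform = "ratio")
  st <- res[res$term == "statusperiodontitis", ]
  hits <- st$feature[st$q < 0.05]
  expect_gte(sum(sprintf("f%02d", planted) %in% hits), 5)
  expect_true(all(st$effect[match(sprintf("f%02d", planted), st$feature)] < 0))
  # CI coverage of the planted effect
  ci <- st[match(sprintf("f%02d", planted), st$feature), ]
  expect_gte(sum(ci$ci_lo <= -0.5 & ci$ci_hi >= -0.5), 4)

  # prevalence: a feature defined in <20% of samples is absent from the output
  tab2 <- tab
  tab2[1, ] <- NA; tab2[1, 1:5] <- 0.2
  res2 <- loglinear_differential(tab2, md, transform = "ratio")
  expect_false("f01" %in% res2$feature)

  # zero-variance feature flagged degenerate with p = 1
  tab3 <- tab
  tab3[2, ] <- 1.5
  res3 <- loglinear_differential(tab3, md, transform = "ratio")
  f2 <- res3[res3$feature == "f02", ]
  expect_true(all(f2$degenerate))
  expect_true(all(f2$p == 1))
  expect_true(all(f2$effect == 0))
})

test_that("log-linear power rises with effect size", {
  set.seed(28)
  md <- data.frame(sample_id = paste0("s", 1:40),
                   subject_id = paste0("S", 1:40),
                   site = "plaque",
                   status = rep(c("healthy", "periodontitis"), each = 20),
                   smoking = "no", stringsAsFactors = FALSE)
  power <- vapply(c(0.1, 0.25, 0.5, 1.0), function(delta) {
    hits <- 0
    for (r in 1:10) {
      tab <- matrix(stats::rnorm(20 * 40, 0, 0.4), 20, 40,
                    dimnames = list(sprintf("f%02d", 1:20), md$sample_id))
      tab[1, md$status == "periodontitis"] <- tab[1, md$status == "periodontitis"] + delta
      res <- loglinear_differential(tab, md, fixed_terms = "status",
                                    subject_random = FALSE, transform = "ratio")
      st <- res[res$term == "statusperiodontitis", ]
      hits <- hits + (st$q[st$feature == "f01"] < 0.05)
    }
    hits / 10
  }, numeric(1))
  expect_true(all(diff(power) >= -0.1))   # monotone up to simulation noise
  expect_gt(power[4], power[1])
})

test_that("abundance tables are log-transformed with a half-minimum pseudocount", {
  set.seed(29)
  md <- tiny_metadata()
  tab <- matrix(c(0.1, 0.2, 0.3, 0.4,
                  0, 0.5, 0.5, 0.5), 2, 4, byrow = TRUE,
                dimnames = list(c("fA", "fB"), md$sample_id))
  res <- loglinear_differential(tab, md, fixed_terms = "status",
                                subject_random = FALSE, min_prevalence = 0.2,
                                transform = "log_abundance")
  expect_true(all(c("fA", "fB") %in% res$feature))
  # effect for fA equals the difference of log10 means under the pseudocount
  pc <- 0.5 * 0.1
  y <- log10(c(0.1, 0.2, 0.3, 0.4) + pc)
  expected <- mean(y[3:4]) - mean(y[1:2])
  expect_equal(res$effect[res$feature == "fA"], expected, tolerance = 1e-10)
})
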