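# Hypothesis-testing layer: group comparisons of alpha diversity,
# permutation tests on distance matrices with repeated-measures structure,
# and per-feature differential abundance/activity with BH-FDR control.

#' Kruskal-Wallis rank test on a per-sample scalar
#'
#' Thin wrapper around [stats::kruskal.test] with tie correction; the
#' all-constant degenerate case returns H = 0 and p = 1 with a warning.
#'
#' @param values numeric vector.
#' @param groups group labels, at least two groups.
#' @return list with `H` and `p`.
#' @export
kruskal_wallis_groups <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop_format("at least two groups required")
  if (length(unique(values[!is.na(values)])) <= 1) {
    warning("all values identical: H = 0, p reported as 1", call. = FALSE)
    return(list(H = 0, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

# Pseudo-F / R2 for a one-way grouping, computed directly from squared
# distances (Gower-centered sums of squares): SS_T = sum(d^2)/n over all
# pairs; SS_W = sum over groups of within-group d^2/n_g.
permanova_stats <- function(D2, groups) {
  n <- nrow(D2)
  lev <- unique(groups)
  a <- length(lev)
  ss_t <- sum(D2) / (2 * n)
  ss_w <- 0
  for (g in lev) {
    idx <- which(groups == g)
    ss_w <- ss_w + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ss_a <- ss_t - ss_w
  f <- (ss_a / (a - 1)) / (ss_w / (n - a))
  c(F = f, R2 = ss_a / ss_t)
}

#' PERMANOVA with subject-restricted permutations
#'
#' Distance-based one-way PERMANOVA (pseudo-F from Gower-centered sums of
#' squares, `R2 = SS_between / SS_total`,
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`). When `strata` (subject
#' identifiers) are supplied, permutations respect the repeated-measures
#' design: a factor varying within subjects (oral site) is permuted within
#' each subject; a factor constant within subjects (health status) is permuted
#' by exchanging whole subjects' labels.
#'
#' @param dm `dist` object or symmetric matrix.
#' @param labels factor to test, aligned with the samples of `dm`.
#' @param strata optional subject ids for restricted permutations.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param term label for the tested term (reporting only).
#' @return a `permanova_result`: `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`, `strata`, `term`.
#' @export
permanova_restricted <- function(dm, labels, strata = NULL, n_perm = 999,
                                 seed = 1L, term = "labels") {
  D <- as.matrix(dm)
  n <- nrow(D)
  labels <- as.character(labels)
  stopifnot(length(labels) == n, n_perm >= 99)
  if (length(unique(labels)) < 2) stop_format("factor has a single level")
  if (!is.null(strata)) stopifnot(length(strata) == n)
  D2 <- D^2
  obs <- permanova_stats(D2, labels)

  scheme <- "free"
  subj_idx <- NULL
  if (!is.null(strata)) {
    strata <- as.character(strata)
    subj_idx <- split(seq_len(n), strata)
    constant_within <- all(vapply(subj_idx, function(i) length(unique(labels[i])) == 1, TRUE))
    if (constant_within) {
      subj_lab0 <- vapply(subj_idx, function(i) labels[i[1]], "")
      if (length(unique(subj_lab0)) < 2 ||
          length(unique(subj_lab0)) == length(subj_lab0)) {
        stop_format("factor is confounded with strata: no valid permutation exists")
      }
      scheme <- "between_subject"
    } else {
      varies <- vapply(subj_idx, function(i) length(unique(labels[i])) > 1, TRUE)
      if (!any(varies)) stop_format("factor is confounded with strata: no valid permutation exists")
      scheme <- "within_subject"
    }
  }

  set.seed(seed)
  perm_f <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pl <- labels
    if (scheme == "free") {
      pl <- labels[sample.int(n)]
    } else if (scheme == "within_subject") {
      for (i in subj_idx) pl[i] <- labels[i][sample.int(length(i))]
    } else {
      subj_lab <- vapply(subj_idx, function(i) labels[i[1]], "")
      new_lab <- subj_lab[sample.int(length(subj_lab))]
      for (s in seq_along(subj_idx)) pl[subj_idx[[s]]] <- new_lab[s]
    }
    perm_f[b] <- permanova_stats(D2, pl)[["F"]]
  }
  p <- (1 + sum(perm_f >= obs[["F"]])) / (1 + n_perm)
  structure(list(pseudo_F = obs[["F"]], R2 = obs[["R2"]], p_value = p,
                 n_permutations = n_perm, strata = scheme, term = term),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA [%s, %s permutations]: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d perms)\n",
              x$term, x$strata, x$pseudo_F, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

#' Multivariate homogeneity of group dispersions (PERMDISP)
#'
#' Distances to group centroids in full principal-coordinate space; axes with
#' negative eigenvalues contribute negatively to the squared distances (the
#' standard construction for non-Euclidean distance matrices). The ANOVA F of
#' the distances is compared against permutations of those distances across
#' groups.
#'
#' @param dm `dist` object or symmetric matrix.
#' @param labels group labels (every group of size >= 2).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `F`, `p`, `distances` (per-sample distance to its group
#'   centroid).
#' @export
permdisp <- function(dm, labels, n_perm = 999, seed = 1L) {
  D <- as.matrix(dm)
  n <- nrow(D)
  labels <- as.factor(labels)
  stopifnot(length(labels) == n)
  if (any(table(labels) < 2)) stop_format("every group needs at least 2 samples")
  G <- -0.5 * D^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- abs(e$values) > 1e-8 * max(abs(e$values), 1e-12)
  lam <- e$values[keep]
  ax <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(abs(lam)), sum(keep))
  pos <- lam > 0
  z2 <- numeric(n)
  for (g in levels(labels)) {
    idx <- which(labels == g)
    cen <- colMeans(ax[idx, , drop = FALSE])
    dif2 <- sweep(ax[idx, , drop = FALSE], 2, cen)^2
    z2[idx] <- rowSums(dif2[, pos, drop = FALSE]) -
      (if (any(!pos)) rowSums(dif2[, !pos, drop = FALSE]) else 0)
  }
  z <- sqrt(pmax(z2, 0))
  anova_f <- function(y, gr) {
    gm <- tapply(y, gr, mean); ng <- tapply(y, gr, length)
    ss_b <- sum(ng * (gm - mean(y))^2)
    ss_w <- sum((y - gm[gr])^2)
    (ss_b / (nlevels(gr) - 1)) / (ss_w / (length(y) - nlevels(gr)))
  }
  f_obs <- anova_f(z, labels)
  set.seed(seed)
  f_perm <- replicate(n_perm, anova_f(z[sample.int(n)], labels))
  list(F = f_obs, p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm), distances = z)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up BH with enforced monotonicity; NA values pass through.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return vector of q-values.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop_format("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Dirichlet-Monte-Carlo CLR differential abundance test
#'
#' ALDEx2-style two-group test: per Monte-Carlo instance, per-sample
#' proportions are drawn from Dirichlet(counts + 0.5) (Jeffreys prior),
#' CLR-transformed, and compared per feature by Welch's t; the reported p is
#' the across-instance mean ("expected p"), BH-corrected across features. The
#' effect size is the across-instance mean of the between-group difference of
#' CLR medians scaled by the pooled within-group dispersion.
#'
#' @param counts feature x sample nonnegative integer matrix.
#' @param groups two-level factor over samples (>= 2 samples per group).
#' @param n_instances Monte-Carlo instances (default 128).
#' @param seed integer seed.
#' @return data.frame: `feature`, `effect`, `p`, `q`, `prevalence`, `test`.
#' @export
clr_dirichlet_test <- function(counts, groups, n_instances = 128, seed = 1L) {
  m <- as.matrix(counts)
  assert_matrix_nonneg(m, "counts")
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2) stop_format("exactly two groups required")
  if (any(table(groups) < 2)) stop_format("each group needs at least 2 samples")
  g1 <- groups == levels(groups)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  nf <- nrow(m)
  alpha <- m + 0.5
  set.seed(seed)
  p_acc <- numeric(nf); eff_acc <- numeric(nf)
  for (b in seq_len(n_instances)) {
    gam <- matrix(stats::rgamma(length(alpha), shape = alpha), nf, ncol(m))
    pr <- sweep(gam, 2, colSums(gam), "/")
    lg <- log(pr)
    clr <- sweep(lg, 2, colMeans(lg))
    x1 <- clr[, g1, drop = FALSE]; x2 <- clr[, g2, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- row_vars(x1, m1); v2 <- row_vars(x2, m2)
    se2 <- v1 / n1 + v2 / n2
    tt <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p_acc <- p_acc + 2 * stats::pt(-abs(tt), df)
    md1 <- row_medians(x1); md2 <- row_medians(x2)
    disp <- 1.4826 * row_medians(abs(cbind(x1 - md1, x2 - md2)))
    eff_acc <- eff_acc + (md2 - md1) / pmax(disp, 1e-12)
  }
  p_mean <- p_acc / n_instances
  out <- data.frame(
    feature = rownames(m) %||% sprintf("f%03d", seq_len(nf)),
    effect = eff_acc / n_instances,
    p = p_mean,
    q = bh_fdr(p_mean),
    prevalence = rowMeans(m > 0),
    test = "clr_dirichlet",
    stringsAsFactors = FALSE
  )
  out[order(out$q, out$p), , drop = FALSE]
}

#' Log-linear differential abundance / activity model
#'
#' MaAsLin2-style per-feature least-squares model with a repeated-measures
#' design. Abundance tables are log10-transformed after a half-minimum
#' pseudocount; ratio tables (already log scale) are used as-is. With
#' `subject_random = TRUE` the subject effect is absorbed as fixed effects:
#' terms varying within subjects (site) are tested in a model containing
#' subject indicators (equivalent to within-subject centering); terms constant
#' within subjects (health status, smoking) are tested on per-subject means
#' (the balanced split-plot whole-plot stratum). Wald p-values per
#' coefficient, BH q across features within each term.
#'
#' @param table feature x sample matrix: relative abundances
#'   (`transform = "log_abundance"`) or log10 ratios (`transform = "ratio"`,
#'   NAs allowed and dropped casewise).
#' @param metadata sample metadata aligned with the table columns.
#' @param fixed_terms metadata column names to test (default status + site).
#' @param subject_random absorb subject structure (default TRUE).
#' @param min_prevalence prevalence filter applied first (default 0.2; for
#'   ratio tables prevalence counts defined cells).
#' @param transform `"log_abundance"` or `"ratio"`.
#' @return data.frame: `feature`, `term`, `effect`, `se`, `ci_lo`, `ci_hi`,
#'   `p`, `q`, `prevalence`, `test`, `degenerate`.
#' @export
loglinear_differential <- function(table, metadata,
                                   fixed_terms = c("status", "site"),
                                   subject_random = TRUE,
                                   min_prevalence = 0.2,
                                   transform = c("log_abundance", "ratio")) {
  transform <- match.arg(transform)
  m <- as.matrix(table)
  stopifnot(ncol(m) == nrow(metadata))
  missing_cols <- setdiff(fixed_terms, names(metadata))
  if (length(missing_cols)) {
    stop_format("metadata missing term column(s): %s", paste(missing_cols, collapse = ", "))
  }
  present <- if (transform == "ratio") !is.na(m) else m > 0
  n <- ncol(m)
  need <- ceiling(min_prevalence * n)
  keep <- rowSums(present) >= need
  m <- m[keep, , drop = FALSE]
  present <- present[keep, , drop = FALSE]
  if (nrow(m) == 0) {
    warning("no feature passes the prevalence filter", call. = FALSE)
    return(empty_feature_table())
  }
  if (transform == "log_abundance") {
    pc <- 0.5 * min(m[m > 0])
    m <- log10(m + pc)
  }

  md <- metadata
  md$.subject <- as.factor(md$subject_id)
  between <- vapply(fixed_terms, function(tm) {
    all(tapply(as.character(md[[tm]]), md$.subject,
               function(v) length(unique(v)) == 1))
  }, TRUE)

  rows <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    feat <- rownames(m)[i] %||% sprintf("f%03d", i)
    prev <- mean(present[i, ])
    if (stats::sd(y, na.rm = TRUE) == 0 || all(is.na(y))) {
      rows[[i]] <- degenerate_rows(feat, fixed_terms, md, prev)
      next
    }
    pieces <- list()
    if (!subject_random) {
      fml <- stats::as.formula(paste("y ~", paste(fixed_terms, collapse = " + ")))
      pieces[[1]] <- wald_rows(fml, cbind(md, y = y), fixed_terms, feat, prev)
    } else {
      wt <- fixed_terms[!between]
      bt <- fixed_terms[between]
      if (length(wt)) {
        fml <- stats::as.formula(paste("y ~ .subject +", paste(wt, collapse = " + ")))
        pieces[[length(pieces) + 1]] <- wald_rows(fml, cbind(md, y = y), wt, feat, prev)
      }
      if (length(bt)) {
        agg <- stats::aggregate(y, by = list(.subject = md$.subject), FUN = mean, na.rm = TRUE)
        names(agg)[2] <- "y"
        subj_md <- unique(md[, c(".subject", bt), drop = FALSE])
        agg <- merge(agg, subj_md, by = ".subject")
        fml <- stats::as.formula(paste("y ~", paste(bt, collapse = " + ")))
        pieces[[length(pieces) + 1]] <- wald_rows(fml, agg, bt, feat, prev)
      }
    }
    rows[[i]] <- do.call(rbind, pieces)
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (tm in unique(out$term)) {
    sel <- out$term == tm
    out$q[sel] <- bh_fdr(out$p[sel])
  }
  out$test <- if (subject_random) "loglinear_subject" else "loglinear"
  out <- out[order(out$term, out$q, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

wald_rows <- function(fml, dat, terms, feat, prev) {
  for (tm in terms) if (!is.numeric(dat[[tm]])) dat[[tm]] <- as.factor(dat[[tm]])
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    aliased <- aliased[!grepl("^\\.subject", aliased)]
    if (length(aliased)) {
      stop_format("rank-deficient design: aliased term(s) %s", paste(aliased, collapse = ", "))
    }
  }
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  pieces <- lapply(terms, function(tm) {
    hits <- rownames(sm)[startsWith(rownames(sm), tm) & rownames(sm) != "(Intercept)"]
    if (!length(hits)) return(NULL)
    data.frame(feature = feat, term = hits,
               effect = sm[hits, "Estimate"], se = sm[hits, "Std. Error"],
               ci_lo = ci[hits, 1], ci_hi = ci[hits, 2],
               p = sm[hits, "Pr(>|t|)"], prevalence = prev,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

degenerate_rows <- function(feat, fixed_terms, md, prev) {
  terms <- unlist(lapply(fixed_terms, function(tm) {
    v <- md[[tm]]
    if (is.numeric(v)) tm else paste0(tm, sort(unique(as.character(v)))[-1])
  }))
  data.frame(feature = feat, term = terms, effect = 0, se = NA_real_,
             ci_lo = NA_real_, ci_hi = NA_real_, p = 1, prevalence = prev,
             degenerate = TRUE, stringsAsFactors = FALSE)
}

empty_feature_table <- function() {
  data.frame(feature = character(0), term = character(0), effect = numeric(0),
             se = numeric(0), ci_lo = numeric(0), ci_hi = numeric(0),
             p = numeric(0), q = numeric(0), prevalence = numeric(0),
             test = character(0), degenerate = logical(0),
             stringsAsFactors = FALSE)
}
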