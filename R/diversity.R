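# Alpha diversity, compositional (Aitchison) and abundance/ratio (Jaccard)
# beta diversity, and principal-coordinate ordination with a Shepard fidelity
# check.

#' Per-sample alpha diversity
#'
#' @param matrix feature x sample nonnegative table (any scale; Shannon and
#'   Pielou are computed on per-sample proportions).
#' @return data.frame: `sample`, `observed_richness`, `shannon` (nats),
#'   `pielou` (NA for richness <= 1).
#' @export
alpha_diversity <- function(matrix) {
  m <- as.matrix(matrix)
  assert_matrix_nonneg(m)
  richness <- colSums(m > 0)
  shannon <- vegan::diversity(t(m), index = "shannon")
  pielou <- ifelse(richness > 1, shannon / log(richness), NA_real_)
  data.frame(sample = colnames(m) %||% as.character(seq_len(ncol(m))),
             observed_richness = as.integer(richness),
             shannon = as.numeric(shannon), pielou = pielou,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Centered log-ratio transform with multiplicative zero replacement
#'
#' Zeros in a sample are replaced by delta = half that sample's smallest
#' nonzero proportion, with the nonzero part rescaled to keep the sample on
#' the simplex (multiplicative replacement); then
#' `clr(x) = ln(x) - mean(ln(x))`.
#'
#' @param matrix feature x sample proportions (per-sample sums within `tol`
#'   of 1).
#' @param tol closure tolerance (default 1e-4).
#' @return real-valued matrix of the same shape; per-sample CLR values sum
#'   to 0.
#' @export
clr_transform <- function(matrix, tol = 1e-4) {
  m <- as.matrix(matrix)
  assert_matrix_nonneg(m)
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop_format("sample(s) with all-zero composition: %s",
                paste(colnames(m)[cs == 0], collapse = ", "))
  }
  if (any(abs(cs - 1) > tol)) {
    stop_format("per-sample proportions must sum to 1 (max deviation %.3g)",
                max(abs(cs - 1)))
  }
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    z <- x == 0
    if (any(z)) {
      delta <- 0.5 * min(x[!z])
      x[!z] <- x[!z] * (1 - sum(z) * delta)
      x[z] <- delta
    }
    lx <- log(x)
    out[, j] <- lx - mean(lx)
  }
  out
}

#' Aitchison distance between samples
#'
#' Euclidean distance between CLR-transformed compositions; scale-invariant
#' and invariant to feature reordering.
#'
#' @inheritParams clr_transform
#' @return a `stats::dist` object with `method = "aitchison"`.
#' @export
aitchison_distance <- function(matrix, tol = 1e-4) {
  clr <- clr_transform(matrix, tol = tol)
  d <- stats::dist(t(clr), method = "euclidean")
  attr(d, "method") <- "aitchison"
  d
}

#' Weighted (Ruzicka) or binary Jaccard distance
#'
#' Weighted: `d = 1 - sum(min(x, y)) / sum(max(x, y))`; binary: Jaccard on
#' presence/absence. Both are bounded in `[0, 1]`. A pair of all-zero samples
#' has distance 0, with a warning.
#'
#' @param matrix feature x sample nonnegative table.
#' @param binary use presence/absence (default FALSE).
#' @return a `stats::dist` object.
#' @export
weighted_jaccard_distance <- function(matrix, binary = FALSE) {
  m <- as.matrix(matrix)
  assert_matrix_nonneg(m)
  d <- suppressWarnings(vegan::vegdist(t(m), method = "jaccard", binary = binary))
  if (anyNA(d)) {
    warning("pair(s) of all-zero samples: distance set to 0", call. = FALSE)
    d[is.na(d)] <- 0
  }
  attr(d, "method") <- if (binary) "binary_jaccard" else "weighted_jaccard"
  d
}

#' Beta diversity of signed log10(RNA/DNA) activity tables
#'
#' Weighted Jaccard requires nonnegative input; a signed activity table is
#' made compatible by imputing undefined cells at 0 (neutral activity) and
#' shifting the whole table by its global minimum. Distances are invariant to
#' adding any constant to the table. This shift convention is one defensible
#' reading of applying weighted Jaccard to log-ratio data; it is recorded in
#' the distance's `method` attribute.
#'
#' @param activity an `activity_table`.
#' @return a `stats::dist` object with `method = "weighted_jaccard_shifted"`.
#' @export
ratio_beta_diversity <- function(activity) {
  stopifnot(inherits(activity, "activity_table"))
  if (!any(activity$mask)) stop_format("activity table has no defined cells")
  v <- activity$value
  v[!activity$mask] <- 0
  v <- v - min(v)
  d <- weighted_jaccard_distance(v, binary = FALSE)
  attr(d, "method") <- "weighted_jaccard_shifted"
  d
}

#' Principal coordinates analysis with Shepard fidelity check
#'
#' Classical metric MDS: eigendecomposition of the double-centered Gram matrix
#' `-0.5 * J D^2 J`. Negative eigenvalues are reported, never silently
#' dropped; no Lingoes/Cailliez correction is applied. `shepard_r` is the
#' Pearson correlation between the input distances and the k-dimensional
#' ordination distances.
#'
#' @param dm a `dist` object or symmetric distance matrix.
#' @param k number of ordination axes (2 <= k <= n-1).
#' @return a `pcoa_ordination`: `points` (n x k), `eig` (all eigenvalues,
#'   non-increasing), `prop_explained` (of the positive eigenvalue mass),
#'   `shepard_r`.
#' @export
pcoa_with_shepard <- function(dm, k = 2) {
  D <- as.matrix(dm)
  n <- nrow(D)
  if (k < 2) stop_format("k must be at least 2")
  if (k > n - 1) stop_format("k = %d exceeds n - 1 = %d", k, n - 1)
  if (max(abs(D - t(D))) > 1e-10) stop_format("distance matrix is not symmetric")
  G <- -0.5 * D^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  eig <- e$values
  pos <- pmax(eig, 0)
  lam_k <- pos[seq_len(k)]
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam_k), k)
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("Axis", seq_len(k))
  prop <- if (sum(pos) > 0) pos / sum(pos) else rep(0, n)
  d_in <- as.vector(stats::as.dist(D))
  dk <- as.vector(stats::dist(pts))
  shepard_r <- if (stats::sd(d_in) == 0 || stats::sd(dk) == 0) NA_real_
               else stats::cor(d_in, dk)
  structure(list(points = pts, eig = eig, prop_explained = prop,
                 shepard_r = shepard_r),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("<pcoa_ordination> %d samples, %d axes (%.1f%%, %.1f%% explained), shepard r = %.3f\n",
              nrow(x$points), ncol(x$points),
              100 * x$prop_explained[1], 100 * x$prop_explained[2], x$shepard_r))
  invisible(x)
}
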