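# Spearman machinery: rank rows once, then standardized cross-products.
# Constant rows get correlation 0 (with a warning) so degenerate features
# stay in the matrix but can never be selected.

.rank_standardize <- function(m, label) {
  r <- t(apply(m, 1L, rank))          # average ranks for ties
  r <- r - rowMeans(r)
  ss <- sqrt(rowSums(r^2))
  const <- ss == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) in ", label,
            "; their correlations are set to 0")
    ss[const] <- 1
    r[const, ] <- 0
  }
  r / ss
}

#' Spearman correlation matrix between two feature sets
#'
#' c[i, j] is the Pearson correlation of the average-ranked values of row i
#' of `A` and row j of `B` across the shared samples.
#'
#' @param A,B omics matrices (features x samples).
#' @param sample_ids sample ordering to use; default: intersection of the
#'   two column sets, in `A`'s order.
#' @return object of class `correlation_result`: list with
#'   `row_feature_ids`, `col_feature_ids`, `c` (matrix in [-1, 1]).
#' @export
spearman_matrix <- function(A, B, sample_ids = NULL) {
  A <- as_omics_matrix(A); B <- as_omics_matrix(B)
  if (is.null(sample_ids)) sample_ids <- intersect(colnames(A), colnames(B))
  missing <- setdiff(sample_ids, colnames(A))
  if (length(missing)) stop("samples missing from A: ", paste(missing, collapse = ", "))
  missing <- setdiff(sample_ids, colnames(B))
  if (length(missing)) stop("samples missing from B: ", paste(missing, collapse = ", "))
  if (length(sample_ids) < 3L) stop("need at least 3 shared samples")
  ra <- .rank_standardize(A[, sample_ids, drop = FALSE], "A")
  rb <- .rank_standardize(B[, sample_ids, drop = FALSE], "B")
  cc <- tcrossprod(ra, rb)
  cc[cc > 1] <- 1; cc[cc < -1] <- -1
  structure(list(row_feature_ids = rownames(A), col_feature_ids = rownames(B),
                 c = cc),
            class = "correlation_result")
}

.bin_counts <- function(x, grid_bins) {
  binw <- 2 / grid_bins
  idx <- pmin(grid_bins, pmax(1L, 1L + floor((x + 1) / binw)))
  tabulate(idx, nbins = grid_bins)
}

#' Permutation null distribution of cross-matrix correlation coefficients
#'
#' For each permutation, the sample linkage between `A` and `B` is destroyed
#' by randomly re-ordering `B`'s sample columns relative to `A`; the full
#' coefficient matrix is recomputed and its histogram accumulated.  The
#' returned null density is the per-bin average over permutations, on the
#' same grid as the observed-coefficient density.
#'
#' @inheritParams spearman_matrix
#' @param n_permutations number of permutations (>= 1; the reference
#'   analysis used 10,000, 1,000 is plenty at test scale).
#' @param seed RNG seed.
#' @param grid_bins histogram bins over [-1, 1] (odd value keeps a bin
#'   centred at 0).
#' @return object of class `null_distribution`: `grid` (bin centres),
#'   `original_density`, `null_density`, `n_permutations`, `seed`.
#' @export
permutation_null <- function(A, B, n_permutations = 1000, seed = 1L,
                             grid_bins = 201) {
  n_permutations <- .assert_count(n_permutations, "n_permutations")
  grid_bins <- .assert_count(grid_bins, "grid_bins", min = 3L)
  A <- as_omics_matrix(A); B <- as_omics_matrix(B)
  sample_ids <- intersect(colnames(A), colnames(B))
  if (length(sample_ids) < 3L) stop("need at least 3 shared samples")
  ra <- .rank_standardize(A[, sample_ids, drop = FALSE], "A")
  rb <- .rank_standardize(B[, sample_ids, drop = FALSE], "B")
  n <- length(sample_ids)
  binw <- 2 / grid_bins
  N <- nrow(ra) * nrow(rb)
  orig <- tcrossprod(ra, rb)
  orig_counts <- .bin_counts(orig, grid_bins)
  null_counts <- numeric(grid_bins)
  .with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perm <- sample.int(n)
      null_counts <- null_counts +
        .bin_counts(tcrossprod(ra, rb[, perm, drop = FALSE]), grid_bins)
    }
  })
  structure(list(
    grid = seq(-1 + binw / 2, 1 - binw / 2, length.out = grid_bins),
    original_density = orig_counts / (N * binw),
    null_density = null_counts / (n_permutations * N * binw),
    n_permutations = n_permutations,
    n_coefficients = N,
    seed = seed
  ), class = "null_distribution")
}

# 'quantile' of |c| under the binned null density (fallback threshold)
.null_abs_quantile <- function(dist, q) {
  mass <- dist$null_density
  mass <- mass / sum(mass)
  ord <- order(abs(dist$grid))
  cum <- cumsum(mass[ord])
  val <- abs(dist$grid)[ord][which(cum >= q)[1]]
  max(val, min(abs(dist$grid[dist$grid > 0])))  # keep strictly positive
}

#' Correlation threshold from the observed/null density intersection
#'
#' On each side of zero, the threshold is the point where the observed
#' coefficient density crosses the averaged permutation-null density from
#' below, beyond which the observed tail dominates.  Numerically the
#' crossing is located as the grid point maximizing the tail-mass
#' difference \eqn{T_o(g) - T_n(g)} (the integral of original minus null
#' density from g outward): the derivative of that difference is
#' null minus original density, so its maximum sits exactly at the density
#' intersection, while cumulative masses are robust to the bin-level
#' sparsity of small coefficient matrices.  A side is degenerate (no
#' crossing) when its maximal tail-mass excess is at most `min_excess`;
#' that side then falls back to the +/- `fallback_quantile` quantile of
#' |c| under the null and the result is flagged.
#'
#' @param dist a [permutation_null()] result.
#' @param fallback_quantile quantile of the absolute null coefficients used
#'   when no crossing exists (default 0.95).
#' @param min_excess minimal tail-probability excess of the observed
#'   distribution over the null for a side to count as a real crossing
#'   (default 0.02, above the sampling fluctuations of desk-scale
#'   coefficient sets; see the methods vignette).
#' @return object of class `threshold_pair`: `lower` < 0 < `upper`,
#'   `degenerate_flag`.
#' @export
threshold_from_intersection <- function(dist, fallback_quantile = 0.95,
                                        min_excess = 0.02) {
  stopifnot(inherits(dist, "null_distribution"))
  o <- dist$original_density; nl <- dist$null_density; g <- dist$grid
  if (all(o == 0) || all(nl == 0)) stop("empty densities")
  fallback_quantile <- .assert_number(fallback_quantile, "fallback_quantile",
                                      min = 0, max = 1, strict_min = TRUE,
                                      strict_max = TRUE)
  binw <- g[2L] - g[1L]
  # histogram sampling error of a tail mass; zero (exact argmax) when the
  # densities were supplied analytically rather than estimated from
  # n_coefficients draws
  n_coef <- dist$n_coefficients %||% Inf

  side_threshold <- function(idx) {
    # idx: grid indices of one side, ordered from zero outward
    # tail mass from each grid point outward (inclusive)
    to <- rev(cumsum(rev(o[idx]))) * binw
    tn <- rev(cumsum(rev(nl[idx]))) * binw
    excess <- to - tn
    mx <- max(excess)
    if (mx <= min_excess) return(NA_real_)
    i_star <- which.max(excess)
    tol <- if (is.finite(n_coef))
      2 * sqrt(tn[i_star] * (1 - tn[i_star]) / n_coef) else 0
    # within sampling tolerance of the maximum the crossing location is not
    # resolved; take the outermost candidate (the more specific threshold)
    g[idx[max(which(excess >= mx - tol))]]
  }

  pos <- which(g > 0)                 # ascending = zero outward
  neg <- rev(which(g < 0))            # descending = zero outward
  upper <- side_threshold(pos)
  lower <- side_threshold(neg)
  degenerate <- is.na(upper) || is.na(lower)
  if (degenerate) {
    q <- .null_abs_quantile(dist, fallback_quantile)
    if (is.na(upper)) upper <- q
    if (is.na(lower)) lower <- -q
  }
  structure(list(lower = lower, upper = upper, degenerate_flag = degenerate),
            class = "threshold_pair")
}

#' Mean absolute-correlation selection scores
#'
#' For a correlation matrix between feature set I (rows) and feature set J
#' (columns), the row score G_i is the mean of |c[i, ]| over the J columns
#' and the column score T_j the mean of |c[, j]| over the I rows.  When rows
#' are tissue metabolites and columns serum metabolites, the column score is
#' the serum statistic S_k.
#'
#' @param corr a [spearman_matrix()] result.
#' @return object of class `selection_scores`: named vectors `G` and `T`,
#'   totals `I` and `J`.
#' @export
selection_scores <- function(corr) {
  stopifnot(inherits(corr, "correlation_result"))
  if (length(corr$c) == 0L) stop("empty correlation matrix")
  a <- abs(corr$c)
  structure(list(
    G = stats::setNames(rowMeans(a), corr$row_feature_ids),
    T = stats::setNames(colMeans(a), corr$col_feature_ids),
    I = nrow(a), J = ncol(a)
  ), class = "selection_scores")
}

#' Select features whose mean |correlation| exceeds a threshold
#'
#' Strict inequality: a score exactly equal to the threshold is not
#' selected.
#'
#' @param scores a [selection_scores()] result.
#' @param threshold positive threshold (typically the `upper` of a
#'   [threshold_from_intersection()] result).
#' @return list with `rows` and `cols`: selected feature ids.
#' @export
select_by_threshold <- function(scores, threshold) {
  stopifnot(inherits(scores, "selection_scores"))
  threshold <- .assert_number(threshold, "threshold", min = 0, strict_min = TRUE)
  list(rows = names(scores$G)[scores$G > threshold],
       cols = names(scores$T)[scores$T > threshold])
}
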