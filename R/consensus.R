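#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with the classical Lance-Williams ward.D update
#' applied to the dissimilarities as given, cut at k clusters.
#'
#' @param dissimilarity square symmetric nonnegative matrix with zero
#'   diagonal (or a `dist`).
#' @param k number of clusters, 2 <= k <= items.
#' @return integer cluster labels in 1..k, named by item if the input has
#'   dimnames.
#' @export
ward_hclust <- function(dissimilarity, k) {
  if (inherits(dissimilarity, "dist"))
    dissimilarity <- as.matrix(dissimilarity)
  if (!is.matrix(dissimilarity) || nrow(dissimilarity) != ncol(dissimilarity) ||
      !isSymmetric(unname(dissimilarity), tol = 1e-8))
    stop("dissimilarity must be a square symmetric matrix")
  if (any(dissimilarity < -1e-12)) stop("dissimilarities must be nonnegative")
  n <- nrow(dissimilarity)
  k <- .assert_count(k, "k", min = 2L)
  if (k > n) stop("k must be <= number of items")
  if (k == n) {
    labels <- seq_len(n)
  } else {
    hc <- stats::hclust(stats::as.dist(dissimilarity), method = "ward.D")
    labels <- stats::cutree(hc, k = k)
  }
  stats::setNames(as.integer(labels), rownames(dissimilarity))
}

#' Consensus clustering parameters
#'
#' Defaults mirror the reference parameterization (maxK 8, item fraction
#' 0.8, feature fraction 1, ward.D linkage on 1 - Spearman, seed 3044)
#' except for the resample count, which defaults to the test-scale 250
#' (20,000 in the reference run; unnecessary for convergence at cohort
#' sizes used here).
#'
#' @param k_max largest k evaluated.
#' @param n_resamples number of subsampling rounds.
#' @param item_fraction fraction of items drawn (without replacement) per
#'   round.
#' @param feature_fraction fraction of features drawn per round.
#' @param seed RNG seed.
#' @param k_override force the chosen k regardless of the delta-area rule.
#' @param delta_area_floor minimum relative CDF-area increase for a larger
#'   k to be preferred.
#' @param median_center subtract each feature's median before computing
#'   item-item correlations (the standard consensus-clustering
#'   preprocessing; removes the shared baseline profile so between-item
#'   correlation reflects relative, not absolute, abundance).
#' @return list of class `consensus_params`.
#' @export
consensus_params <- function(k_max = 8, n_resamples = 250, item_fraction = 0.8,
                             feature_fraction = 1, seed = 3044L,
                             k_override = NULL, delta_area_floor = 0.025,
                             median_center = TRUE) {
  structure(list(
    median_center = .assert_flag(median_center, "median_center"),
    k_max = .assert_count(k_max, "k_max", min = 2L),
    n_resamples = .assert_count(n_resamples, "n_resamples"),
    item_fraction = .assert_number(item_fraction, "item_fraction",
                                   min = 0, max = 1, strict_min = TRUE),
    feature_fraction = .assert_number(feature_fraction, "feature_fraction",
                                      min = 0, max = 1, strict_min = TRUE),
    seed = .assert_count(seed, "seed", min = 0L),
    k_override = if (is.null(k_override)) NULL else
      .assert_count(k_override, "k_override", min = 2L),
    delta_area_floor = .assert_number(delta_area_floor, "delta_area_floor", min = 0)
  ), class = "consensus_params")
}

# item-item dissimilarity: 1 - Spearman correlation of sample profiles
.spearman_dissimilarity <- function(data) {
  d <- 1 - suppressWarnings(stats::cor(data, method = "spearman"))
  d[is.na(d)] <- 1            # constant profiles: maximally dissimilar
  diag(d) <- 0
  d
}

# shared engine: one subsample per resample, evaluated at every k
.consensus_engine <- function(data, ks, params) {
  if (params$median_center)
    data <- data - apply(data, 1L, stats::median)
  n <- ncol(data)
  if (max(ks) > n - 1L) stop("k_max must be <= items - 1")
  n_draw <- ceiling(params$item_fraction * n)
  if (n_draw < max(ks)) stop("item subsample smaller than k")
  f_draw <- ceiling(params$feature_fraction * nrow(data))
  seeds <- .spawn_seeds(params$seed, params$n_resamples)
  conn <- array(0, c(length(ks), n, n))      # co-cluster counts per k
  pair <- matrix(0, n, n)                    # co-sample counts
  for (b in seq_len(params$n_resamples)) {
    sub <- .with_seed(seeds[b], {
      items <- sort(sample.int(n, n_draw))
      feats <- if (f_draw < nrow(data)) sort(sample.int(nrow(data), f_draw))
               else seq_len(nrow(data))
      list(items = items, feats = feats)
    })
    d <- .spearman_dissimilarity(data[sub$feats, sub$items, drop = FALSE])
    hc <- stats::hclust(stats::as.dist(d), method = "ward.D")
    pair[sub$items, sub$items] <- pair[sub$items, sub$items] + 1
    for (ki in seq_along(ks)) {
      lab <- stats::cutree(hc, k = ks[ki])
      same <- outer(lab, lab, "==")
      conn[ki, sub$items, sub$items] <- conn[ki, sub$items, sub$items] + same
    }
  }
  never <- pair == 0 & upper.tri(pair)
  if (any(never))
    warning(sum(never), " item pair(s) never co-sampled; their consensus is 0.",
            " Consider more resamples.")
  out <- lapply(seq_along(ks), function(ki) {
    m <- conn[ki, , ] / ifelse(pair == 0, 1, pair)
    m[pair == 0] <- 0
    diag(m) <- 1
    dimnames(m) <- list(colnames(data), colnames(data))
    m
  })
  names(out) <- paste0("k", ks)
  out
}

#' Consensus matrix at a single k
#'
#' Entry (a, b) is the fraction of resamples in which items a and b were
#' co-sampled and assigned to the same cluster (Ward on 1 - Spearman of the
#' subsampled data).  Pairs never co-sampled score 0 with a warning; the
#' diagonal is 1.
#'
#' @param data omics matrix, features x items (items are clustered).
#' @param k number of clusters.
#' @param params a [consensus_params()].
#' @return items x items consensus matrix in [0, 1].
#' @export
consensus_matrix <- function(data, k, params = consensus_params()) {
  data <- as_omics_matrix(data)
  k <- .assert_count(k, "k", min = 2L)
  .consensus_engine(data, k, params)[[1L]]
}

#' Final cluster labels from a consensus matrix
#'
#' Ward clustering of 1 - consensus, cut at k.
#'
#' @param consensus consensus matrix from [consensus_matrix()].
#' @param k number of clusters (>= 2).
#' @return integer labels named by item.
#' @export
consensus_labels <- function(consensus, k) {
  ward_hclust(1 - consensus, k)
}

#' Choose k from per-k consensus matrices by the delta-area rule
#'
#' Computes the area under the empirical CDF of off-diagonal consensus
#' values for each k, the relative area increase delta_area(k) vs k - 1,
#' and selects the largest k whose delta_area stays above `floor` (all
#' smaller k must also stay above it, so the search stops at the first
#' drop).  `override` wins unconditionally.
#'
#' @param consensus_list named list of consensus matrices for k = 2, 3, ...
#' @param floor minimum relative increase (default 0.025).
#' @param override optional fixed k.
#' @return list with `chosen_k` and a data frame `table` (k, cdf_area,
#'   delta_area).
#' @export
select_k <- function(consensus_list, floor = 0.025, override = NULL) {
  ks <- as.integer(sub("^k", "", names(consensus_list)))
  if (length(ks) < 2L) stop("need at least two values of k")
  area <- vapply(consensus_list, function(m) {
    x <- sort(m[upper.tri(m)])
    n <- length(x)
    # area under the ECDF over [0, 1]
    sum(diff(c(x, 1)) * seq_len(n) / n)
  }, numeric(1))
  delta <- c(area[1L], diff(area) / pmax(area[-length(area)], .Machine$double.eps))
  tab <- data.frame(k = ks, cdf_area = unname(area), delta_area = unname(delta))
  if (!is.null(override)) {
    chosen <- .assert_count(override, "override", min = 2L)
  } else {
    chosen <- ks[1L]
    for (i in seq_along(ks)[-1L]) {
      if (delta[i] >= floor) chosen <- ks[i] else break
    }
  }
  list(chosen_k = chosen, table = tab)
}

#' Full consensus clustering run over k = 2..k_max
#'
#' @param data omics matrix, features x items.
#' @param params a [consensus_params()].
#' @return object of class `consensus_result`: per-k consensus matrices and
#'   labels, the k-selection table, `chosen_k`, and `labels` (at
#'   `chosen_k`).
#' @export
run_consensus <- function(data, params = consensus_params()) {
  data <- as_omics_matrix(data)
  ks <- 2:params$k_max
  mats <- .consensus_engine(data, ks, params)
  labels_k <- lapply(seq_along(ks), function(i) consensus_labels(mats[[i]], ks[i]))
  names(labels_k) <- names(mats)
  sel <- select_k(mats, floor = params$delta_area_floor,
                  override = params$k_override)
  structure(list(consensus = mats, labels_per_k = labels_k,
                 k_table = sel$table, chosen_k = sel$chosen_k,
                 labels = labels_k[[paste0("k", sel$chosen_k)]],
                 params = params),
            class = "consensus_result")
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions (up to label
#' names), ~0 for independent ones.
#'
#' @param a,b cluster label vectors of equal length.
#' @return ARI in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
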