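#' Per-cluster centroid profiles
#'
#' Centroid = per-feature median across the cluster's samples (robust to
#' heavy-tailed abundances).
#'
#' @param matrix omics matrix (features x samples).
#' @param labels cluster labels, one per sample column (named or in column
#'   order).
#' @return features x clusters matrix; columns named by cluster label.
#' @export
cluster_centroids <- function(matrix, labels) {
  matrix <- as_omics_matrix(matrix)
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(matrix), names(labels))
    if (length(missing)) stop("labels missing for: ", paste(missing, collapse = ", "))
    labels <- labels[colnames(matrix)]
  }
  if (length(labels) != ncol(matrix))
    stop("one label per sample required")
  lv <- sort(unique(labels))
  cent <- vapply(lv, function(g) {
    idx <- which(labels == g)
    if (!length(idx)) stop("empty cluster: ", g)
    apply(matrix[, idx, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(matrix)))
  colnames(cent) <- as.character(lv)
  cent
}

#' Cross-cohort cluster correspondence by centroid correlation
#'
#' A desk-scale stand-in for subclass mapping: for every (discovery,
#' validation) cluster pair, the statistic is the Spearman correlation of
#' the two centroid profiles over the shared features; its null is built by
#' permuting the validation cohort's cluster labels.  p-values carry the
#' (1 + #null >= observed) / (1 + n_permutations) correction and are BH
#' adjusted across all pairs.  A pair is `matched` when it is a mutual best
#' match (by statistic) with q < `q_max`.  This is deliberately NOT the
#' GenePattern SubMap algorithm (see the methods vignette).
#'
#' @param discovery,validation omics matrices (features x samples).
#' @param discovery_labels,validation_labels cluster labels per sample.
#' @param shared_features features to use; default: intersection of row
#'   names (>= 10 required).
#' @param n_permutations label permutations for the null.
#' @param seed RNG seed.
#' @param q_max FDR cutoff for a match.
#' @param median_center subtract each feature's median within each cohort
#'   before computing centroids (default TRUE), so centroid correlation
#'   reflects relative subtype signatures rather than cohort-specific
#'   baselines; feed log-scale data when enabled.
#' @return object of class `match_table`: data frame with discovery,
#'   validation, statistic, p_value, q_value, matched; plus attribute
#'   `unmatched_discovery` listing discovery clusters with no match.
#' @export
match_clusters <- function(discovery, discovery_labels, validation,
                           validation_labels, shared_features = NULL,
                           n_permutations = 1000, seed = 1L, q_max = 0.05,
                           median_center = TRUE) {
  discovery <- as_omics_matrix(discovery)
  validation <- as_omics_matrix(validation)
  n_permutations <- .assert_count(n_permutations, "n_permutations")
  shared_features <- shared_features %||%
    intersect(rownames(discovery), rownames(validation))
  if (length(shared_features) < 10L)
    stop("need at least 10 shared features, got ", length(shared_features))
  if (median_center) {
    discovery <- discovery - apply(discovery, 1L, stats::median)
    validation <- validation - apply(validation, 1L, stats::median)
  }
  dc <- cluster_centroids(discovery[shared_features, , drop = FALSE],
                          discovery_labels)
  vc <- cluster_centroids(validation[shared_features, , drop = FALSE],
                          validation_labels)
  obs <- stats::cor(dc, vc, method = "spearman")
  vl <- if (!is.null(names(validation_labels)))
    validation_labels[colnames(validation)] else validation_labels
  exceed <- matrix(0L, nrow(obs), ncol(obs))
  vmat <- validation[shared_features, , drop = FALSE]
  .with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perm <- sample(vl)
      vcp <- cluster_centroids(vmat, stats::setNames(perm, colnames(vmat)))
      exceed <- exceed + (stats::cor(dc, vcp, method = "spearman") >= obs)
    }
  })
  p <- (1 + exceed) / (1 + n_permutations)
  q <- matrix(bh_adjust(as.vector(p)), nrow(p))
  mutual_best <- outer(seq_len(nrow(obs)), seq_len(ncol(obs)),
                       Vectorize(function(i, j)
                         which.max(obs[i, ]) == j && which.max(obs[, j]) == i))
  matched <- mutual_best & q < q_max
  tab <- data.frame(
    discovery = rep(rownames(obs), times = ncol(obs)),
    validation = rep(colnames(obs), each = nrow(obs)),
    statistic = as.vector(obs),
    p_value = as.vector(p),
    q_value = as.vector(q),
    matched = as.vector(matched),
    stringsAsFactors = FALSE
  )
  attr(tab, "unmatched_discovery") <-
    rownames(obs)[!rownames(obs) %in% tab$discovery[tab$matched]]
  class(tab) <- c("match_table", "data.frame")
  tab
}
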