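#' Paired t-test of tumor vs adjacent non-tumor samples, per feature
#'
#' Two-sided Student t on per-patient differences (tumor minus non-tumor)
#' with n_pairs - 1 degrees of freedom.  Features whose differences have
#' zero variance get t = 0, p = 1 by convention, so degenerate features are
#' never selected and never propagate NaN.
#'
#' @param matrix omics matrix containing all paired samples.
#' @param design pairing table (see [validate_pairing()]).
#' @param log2_transform compute differences on log2-transformed abundances
#'   (default TRUE; appropriate for positive abundance data).
#' @return data frame with feature_id, t_statistic, p_value, and (via
#'   [bh_adjust()] downstream) q_value columns added by [feature_stats()].
#' @export
paired_t_test <- function(matrix, design, log2_transform = TRUE) {
  matrix <- as_omics_matrix(matrix)
  design <- validate_pairing(design, matrix)
  n <- nrow(design)
  if (n < 2L) stop("need at least 2 pairs for a paired t-test")
  tum <- matrix[, design$tumor_sample, drop = FALSE]
  non <- matrix[, design$nontumor_sample, drop = FALSE]
  if (log2_transform) {
    if (any(matrix <= 0)) stop("log2 transform requires positive values")
    tum <- log2(tum); non <- log2(non)
  }
  d <- tum - non
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  t_stat <- ifelse(s == 0, 0, m / (s / sqrt(n)))
  p <- ifelse(s == 0, 1, 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE))
  data.frame(feature_id = rownames(matrix), t_statistic = t_stat,
             p_value = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over the standard BH procedure: monotone step-up
#' q-values capped at 1.
#'
#' @param p_values numeric vector in [0, 1].
#' @return q-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop("p-values must all lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Tumor vs non-tumor fold change per feature
#'
#' FC = mean(tumor abundance) / mean(non-tumor abundance), arithmetic means
#' of raw (not log) abundances.  Inputs must be strictly positive; there is
#' no silent pseudocount.
#'
#' @inheritParams paired_t_test
#' @return data frame with feature_id, fold_change, log2_fc.
#' @export
fold_change <- function(matrix, design) {
  matrix <- as_omics_matrix(matrix, positive = TRUE)
  design <- validate_pairing(design, matrix)
  fc <- rowMeans(matrix[, design$tumor_sample, drop = FALSE]) /
    rowMeans(matrix[, design$nontumor_sample, drop = FALSE])
  data.frame(feature_id = rownames(matrix), fold_change = fc,
             log2_fc = log2(fc), row.names = NULL, stringsAsFactors = FALSE)
}

#' Full per-feature screening statistics
#'
#' Combines [paired_t_test()], [bh_adjust()] and [fold_change()] into the
#' standard screening table.
#'
#' @inheritParams paired_t_test
#' @return data frame: feature_id, t_statistic, p_value, q_value,
#'   fold_change, log2_fc.
#' @export
feature_stats <- function(matrix, design, log2_transform = TRUE) {
  tt <- paired_t_test(matrix, design, log2_transform = log2_transform)
  tt$q_value <- bh_adjust(tt$p_value)
  fc <- fold_change(matrix, design)
  merge(tt, fc, by = "feature_id", sort = FALSE)
}

#' Select features by FDR and (optionally) fold change
#'
#' Keeps features with q-value strictly below `q_max` and, when `fc_min` is
#' given, a two-sided fold change (FC >= fc_min or FC <= 1/fc_min).
#'
#' @param stats data frame from [feature_stats()] (needs q_value and, if
#'   `fc_min` is used, fold_change).
#' @param q_max FDR cutoff; strict `<` per convention.
#' @param fc_min fold-change cutoff >= 1, or NULL to skip.
#' @return character vector of retained feature ids.
#' @export
filter_features <- function(stats, q_max = 0.05, fc_min = NULL) {
  keep <- stats$q_value < q_max
  if (!is.null(fc_min)) {
    fc_min <- .assert_number(fc_min, "fc_min", min = 1)
    keep <- keep & (stats$fold_change >= fc_min | stats$fold_change <= 1 / fc_min)
  }
  stats$feature_id[keep]
}

#' Top variable features
#'
#' Ranks features by sample variance, descending; ties broken by feature id
#' (lexicographic).  Asking for more features than exist returns all of
#' them with a warning.
#'
#' @param matrix omics matrix.
#' @param n number of features.
#' @return character vector of feature ids, most variable first.
#' @export
top_variable_features <- function(matrix, n) {
  matrix <- as_omics_matrix(matrix)
  n <- .assert_count(n, "n")
  if (nrow(matrix) == 0L) stop("empty matrix")
  v <- apply(matrix, 1L, stats::var)
  ord <- order(-v, rownames(matrix))
  if (n > nrow(matrix)) {
    warning("requested ", n, " features but only ", nrow(matrix), " available")
    n <- nrow(matrix)
  }
  rownames(matrix)[ord[seq_len(n)]]
}

#' Centered principal-component projection of samples
#'
#' @param matrix omics matrix (features x samples); samples are projected.
#' @param n_components number of components (<= samples - 1).
#' @return list with `coordinates` (samples x components), `rotation`
#'   (features x components, orthonormal), `explained` (variance
#'   fractions, nonincreasing).
#' @export
pca_projection <- function(matrix, n_components = 3) {
  matrix <- as_omics_matrix(matrix)
  n_components <- .assert_count(n_components, "n_components")
  if (n_components > ncol(matrix) - 1L)
    stop("n_components must be <= samples - 1")
  pc <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
  list(coordinates = pc$x[, seq_len(n_components), drop = FALSE],
       rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)])
}
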