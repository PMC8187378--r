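#' Parameters for the two-step correlation selection
#'
#' @param q_max FDR cutoff for the paired-t screen (strict <).
#' @param screen_genes,screen_tissue_mets apply the paired-t/FDR screen to
#'   the gene / tissue-metabolite matrix before correlation (default both
#'   TRUE: both layers are screened for tumor specificity).
#' @param fc_min two-sided fold-change cutoff defining tumor-specific
#'   tissue metabolites (reference analysis: 1.5).
#' @param n_permutations permutations for the null distribution.
#' @param grid_bins histogram bins for the coefficient densities.
#' @param fallback_quantile see [threshold_from_intersection()].
#' @param step2_threshold fixed tissue-serum threshold magnitude (reference
#'   analysis: 0.15); used when `step2_method = "fixed"`.
#' @param step2_method `"fixed"` uses `step2_threshold`; `"permutation"`
#'   re-derives the step-2 threshold from its own permutation null.
#' @param seed RNG seed for the permutation nulls.
#' @return a list of class `two_step_params`.
#' @export
two_step_params <- function(q_max = 0.05, screen_genes = TRUE,
                            screen_tissue_mets = TRUE, fc_min = 1.5,
                            n_permutations = 1000, grid_bins = 201,
                            fallback_quantile = 0.95, step2_threshold = 0.15,
                            step2_method = c("fixed", "permutation"),
                            seed = 1L) {
  structure(list(
    q_max = .assert_number(q_max, "q_max", min = 0, max = 1),
    screen_genes = .assert_flag(screen_genes, "screen_genes"),
    screen_tissue_mets = .assert_flag(screen_tissue_mets, "screen_tissue_mets"),
    fc_min = if (is.null(fc_min)) NULL else .assert_number(fc_min, "fc_min", min = 1),
    n_permutations = .assert_count(n_permutations, "n_permutations"),
    grid_bins = .assert_count(grid_bins, "grid_bins", min = 3L),
    fallback_quantile = fallback_quantile,
    step2_threshold = .assert_number(step2_threshold, "step2_threshold",
                                     min = 0, strict_min = TRUE),
    step2_method = match.arg(step2_method),
    seed = .assert_count(seed, "seed", min = 0L)
  ), class = "two_step_params")
}

.nonempty <- function(ids, step) {
  if (length(ids) == 0L) stop("empty panel at step ", step, call. = FALSE)
  ids
}

#' Two-step correlation selection: genes -> tissue metabolites -> serum
#'
#' Step 0 screens genes (and by default tissue metabolites) for
#' tumor/non-tumor differential abundance (paired t, BH FDR < `q_max`).
#' Step 1 computes the Spearman matrix between screened genes and tissue
#' metabolites on tumor samples, calibrates a threshold from the
#' permutation-null intersection, and selects features whose mean absolute
#' correlation (G for genes, T for tissue metabolites) strictly exceeds it.
#' Step 1b keeps tissue metabolites passing a two-sided fold-change cutoff
#' (the tumor-specific panel).  Step 2 correlates the tumor-specific panel
#' with serum metabolites on patient-matched samples and selects serum
#' metabolites whose S score exceeds the step-2 threshold (fixed or
#' re-derived by permutation).
#'
#' @param genes,tissue_mets paired omics matrices (tumor + non-tumor
#'   columns).
#' @param serum_mets omics matrix, one column per patient (column names are
#'   patient ids).
#' @param pairing pairing table (patient_id, tumor_sample, nontumor_sample).
#' @param params a [two_step_params()].
#' @return object of class `two_step_result` with the three panels
#'   (`gene_panel`, `tissue_panel`, `tumor_specific_tissue_panel`,
#'   `serum_panel`) and all intermediates (screen tables, correlation
#'   results, null distributions, thresholds, scores).
#' @export
two_step_select <- function(genes, tissue_mets, serum_mets, pairing,
                            params = two_step_params()) {
  stopifnot(inherits(params, "two_step_params"))
  genes <- as_omics_matrix(genes)
  tissue_mets <- as_omics_matrix(tissue_mets)
  serum_mets <- as_omics_matrix(serum_mets)
  pairing <- validate_pairing(pairing, genes)
  validate_pairing(pairing, tissue_mets)
  missing <- setdiff(pairing$patient_id, colnames(serum_mets))
  if (length(missing))
    stop("patients missing from serum matrix: ", paste(missing, collapse = ", "))
  seeds <- .spawn_seeds(params$seed, 2L)
  out <- list(params = params)

  # step 0: tumor-specificity screen
  out$gene_stats <- feature_stats(genes, pairing)
  gene_ids <- if (params$screen_genes)
    filter_features(out$gene_stats, q_max = params$q_max) else rownames(genes)
  .nonempty(gene_ids, "0 (gene screen)")
  out$tissue_stats <- feature_stats(tissue_mets, pairing)
  tmet_ids <- if (params$screen_tissue_mets)
    filter_features(out$tissue_stats, q_max = params$q_max) else rownames(tissue_mets)
  .nonempty(tmet_ids, "0 (tissue metabolite screen)")

  # step 1: gene <-> tissue metabolite correlation on tumor samples
  gt <- genes[gene_ids, pairing$tumor_sample, drop = FALSE]
  tt <- tissue_mets[tmet_ids, pairing$tumor_sample, drop = FALSE]
  out$step1_corr <- spearman_matrix(gt, tt)
  out$step1_null <- permutation_null(gt, tt,
                                     n_permutations = params$n_permutations,
                                     seed = seeds[1L],
                                     grid_bins = params$grid_bins)
  out$step1_threshold <- threshold_from_intersection(out$step1_null,
                                                     params$fallback_quantile)
  out$step1_scores <- selection_scores(out$step1_corr)
  sel1 <- select_by_threshold(out$step1_scores, out$step1_threshold$upper)
  out$gene_panel <- .nonempty(sel1$rows, "1 (gene selection)")
  out$tissue_panel <- .nonempty(sel1$cols, "1 (tissue metabolite selection)")

  # step 1b: tumor-specific tissue metabolites by fold change
  if (!is.null(params$fc_min)) {
    fc <- out$tissue_stats[match(out$tissue_panel, out$tissue_stats$feature_id),
                           "fold_change"]
    keep <- fc >= params$fc_min | fc <= 1 / params$fc_min
    out$tumor_specific_tissue_panel <-
      .nonempty(out$tissue_panel[keep], "1b (fold-change filter)")
  } else {
    out$tumor_specific_tissue_panel <- out$tissue_panel
  }

  # step 2: tumor-specific tissue metabolites <-> serum, patient-matched
  ts <- tissue_mets[out$tumor_specific_tissue_panel, pairing$tumor_sample,
                    drop = FALSE]
  colnames(ts) <- pairing$patient_id
  sm <- serum_mets[, pairing$patient_id, drop = FALSE]
  out$step2_corr <- spearman_matrix(ts, sm)
  if (params$step2_method == "permutation") {
    out$step2_null <- permutation_null(ts, sm,
                                       n_permutations = params$n_permutations,
                                       seed = seeds[2L],
                                       grid_bins = params$grid_bins)
    out$step2_threshold <- threshold_from_intersection(out$step2_null,
                                                       params$fallback_quantile)
  } else {
    out$step2_threshold <- structure(
      list(lower = -params$step2_threshold, upper = params$step2_threshold,
           degenerate_flag = FALSE),
      class = "threshold_pair")
  }
  out$step2_scores <- selection_scores(out$step2_corr)
  out$S <- out$step2_scores$T          # serum-side statistic
  sel2 <- select_by_threshold(out$step2_scores, out$step2_threshold$upper)
  out$serum_panel <- .nonempty(sel2$cols, "2 (serum selection)")

  structure(out, class = "two_step_result")
}

#' @export
print.two_step_result <- function(x, ...) {
  cat(sprintf(paste0("two_step_result: %d genes, %d tissue metabolites ",
                     "(%d tumor-specific), %d serum metabolites\n",
                     "  step-1 thresholds [%0.4g, %0.4g]%s; ",
                     "step-2 thresholds [%0.4g, %0.4g]%s\n"),
              length(x$gene_panel), length(x$tissue_panel),
              length(x$tumor_specific_tissue_panel), length(x$serum_panel),
              x$step1_threshold$lower, x$step1_threshold$upper,
              if (x$step1_threshold$degenerate_flag) " (degenerate)" else "",
              x$step2_threshold$lower, x$step2_threshold$upper,
              if (x$step2_threshold$degenerate_flag) " (degenerate)" else ""))
  invisible(x)
}
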