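# Shared synthetic-cohort configurations.  The standard planted cohort is
# the package default (the acceptance criteria's stated world); the null
# cohort removes every planted effect; the small cohort keeps unit tests
# fast.

null_cohort_config <- function(seed, n_patients = 60, n_features = 50) {
  cohort_config(n_patients = n_patients, n_genes = n_features,
                n_tissue_mets = n_features, n_serum_mets = n_features,
                n_planted_genes = 1, n_planted_tissue_mets = 1,
                n_planted_serum_mets = 1, subtype_shift = 0,
                within_block_corr = 0, tissue_serum_corr = 0,
                tumor_nontumor_logfc = 0, subtype_hr = 1, seed = seed)
}

small_cohort_config <- function(seed) {
  cohort_config(n_patients = 40, n_genes = 200, n_tissue_mets = 100,
                n_serum_mets = 120, n_planted_genes = 30,
                n_planted_tissue_mets = 15, n_planted_serum_mets = 12,
                seed = seed)
}

# log2 tumor-sample view of a layer, columns renamed to patient ids
tumor_log2 <- function(cohort, matrix_name, features = NULL) {
  m <- cohort[[matrix_name]]
  if (matrix_name == "serum_met_matrix") {
    m <- m[, cohort$pairing$patient_id, drop = FALSE]
  } else {
    m <- m[, cohort$pairing$tumor_sample, drop = FALSE]
    colnames(m) <- cohort$pairing$patient_id
  }
  if (!is.null(features)) m <- m[features, , drop = FALSE]
  log2(m)
}

.read_tsv_for_test <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
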