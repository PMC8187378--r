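#' Coerce and validate a features-by-samples abundance matrix
#'
#' An omics matrix in this package is a plain numeric matrix with feature
#' identifiers as row names and sample identifiers as column names.
#'
#' @param x matrix-like object with dimnames.
#' @param positive require all values to be strictly positive
#'   (abundance-scale data).
#' @return a validated numeric matrix.
#' @export
as_omics_matrix <- function(x, positive = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("omics matrix needs feature row names and sample column names")
  if (anyDuplicated(rownames(x))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  if (anyNA(x)) stop("omics matrix contains missing values")
  if (positive && any(x <= 0)) stop("omics matrix contains non-positive values")
  x
}

#' Read an omics matrix from TSV
#'
#' Expects a header row, a first column `feature_id`, and one column per
#' sample.
#'
#' @param path file path.
#' @return numeric matrix, features x samples.
#' @export
read_omics_matrix <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1] != "feature_id") stop("first column must be 'feature_id'")
  m <- as.matrix(df[-1])
  rownames(m) <- df$feature_id
  as_omics_matrix(m)
}

#' Write an omics matrix as TSV
#'
#' @param x omics matrix.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
write_omics_matrix <- function(x, path) {
  x <- as_omics_matrix(x)
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Validate a tumor / adjacent non-tumor pairing table
#'
#' @param pairing data frame with columns `patient_id`, `tumor_sample`,
#'   `nontumor_sample`.
#' @param matrix optional omics matrix whose columns must contain every
#'   referenced sample id.
#' @return the pairing data frame, checked.
#' @export
validate_pairing <- function(pairing, matrix = NULL) {
  need <- c("patient_id", "tumor_sample", "nontumor_sample")
  if (!all(need %in% names(pairing)))
    stop("pairing must have columns patient_id, tumor_sample, nontumor_sample")
  ids <- c(pairing$tumor_sample, pairing$nontumor_sample)
  if (anyDuplicated(ids)) stop("pairing sample ids are not unique")
  if (anyDuplicated(pairing$patient_id)) stop("duplicate patient ids in pairing")
  if (!is.null(matrix)) {
    missing <- setdiff(ids, colnames(matrix))
    if (length(missing))
      stop("sample id(s) missing from matrix: ", paste(missing, collapse = ", "))
  }
  pairing
}
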