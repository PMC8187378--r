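#' Configuration for a synthetic multi-omic cohort
#'
#' Defaults describe the standard planted cohort used throughout the test
#' suite: 60 patients, 500 metabolic genes (50 planted), 200 tissue
#' metabolites (20 planted), 300 serum metabolites (15 planted), planted
#' block correlation 0.7 at both steps, a 1 log2-unit tumor shift, three
#' equiprobable subtypes separated by 1 SD on their marker features, and
#' exponential survival with hazard ratio 3 for the worst subtype.
#'
#' @param n_patients,n_genes,n_tissue_mets,n_serum_mets cohort dimensions.
#' @param n_planted_genes,n_planted_tissue_mets,n_planted_serum_mets sizes
#'   of the planted (truly linked) feature panels.
#' @param n_subtypes number of latent patient subtypes.
#' @param subtype_props sampling probabilities of the subtypes (sums to 1).
#' @param subtype_shift mean shift, in within-feature SD units, applied to a
#'   planted feature in tumor/serum samples of its marker subtype.
#' @param within_block_corr target pairwise Spearman correlation between
#'   planted genes and planted tissue metabolites (via a shared per-patient
#'   latent factor); in [0, 1).
#' @param tissue_serum_corr target pairwise correlation between planted
#'   tissue and serum metabolites; must be < sqrt(within_block_corr) unless
#'   both are 0.
#' @param tumor_nontumor_logfc mean log2 shift of planted tissue features in
#'   tumor vs adjacent non-tumor samples.
#' @param baseline_hazard exponential event rate, events per month.
#' @param subtype_hr hazard ratio of the worst subtype (subtype 1) vs the
#'   others.
#' @param censor_rate approximate fraction of patients administratively
#'   censored.
#' @param covariate_assoc named list of log-odds shifts linking a clinical
#'   covariate's positive level to subtype 1 (default: all independent).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 60, n_genes = 500, n_tissue_mets = 200,
                          n_serum_mets = 300, n_planted_genes = 50,
                          n_planted_tissue_mets = 20, n_planted_serum_mets = 15,
                          n_subtypes = 3, subtype_props = NULL,
                          subtype_shift = 1, within_block_corr = 0.7,
                          tissue_serum_corr = 0.7, tumor_nontumor_logfc = 1,
                          baseline_hazard = 0.02, subtype_hr = 3,
                          censor_rate = 0.3, covariate_assoc = list(),
                          seed = 1L) {
  cfg <- list(
    n_patients = .assert_count(n_patients, "n_patients"),
    n_genes = .assert_count(n_genes, "n_genes"),
    n_tissue_mets = .assert_count(n_tissue_mets, "n_tissue_mets"),
    n_serum_mets = .assert_count(n_serum_mets, "n_serum_mets"),
    n_planted_genes = .assert_count(n_planted_genes, "n_planted_genes"),
    n_planted_tissue_mets = .assert_count(n_planted_tissue_mets, "n_planted_tissue_mets"),
    n_planted_serum_mets = .assert_count(n_planted_serum_mets, "n_planted_serum_mets"),
    n_subtypes = .assert_count(n_subtypes, "n_subtypes"),
    subtype_shift = .assert_number(subtype_shift, "subtype_shift", min = 0),
    within_block_corr = .assert_number(within_block_corr, "within_block_corr",
                                       min = 0, max = 1, strict_max = TRUE),
    tissue_serum_corr = .assert_number(tissue_serum_corr, "tissue_serum_corr",
                                       min = 0, max = 1, strict_max = TRUE),
    tumor_nontumor_logfc = .assert_number(tumor_nontumor_logfc, "tumor_nontumor_logfc"),
    baseline_hazard = .assert_number(baseline_hazard, "baseline_hazard",
                                     min = 0, strict_min = TRUE),
    subtype_hr = .assert_number(subtype_hr, "subtype_hr", min = 0, strict_min = TRUE),
    censor_rate = .assert_number(censor_rate, "censor_rate", min = 0, max = 1,
                                 strict_max = TRUE),
    covariate_assoc = covariate_assoc,
    seed = .assert_count(seed, "seed", min = 0L)
  )
  cfg$subtype_props <- subtype_props %||% rep(1 / cfg$n_subtypes, cfg$n_subtypes)
  if (length(cfg$subtype_props) != cfg$n_subtypes ||
      any(cfg$subtype_props <= 0) || abs(sum(cfg$subtype_props) - 1) > 1e-8)
    stop("'subtype_props' must be ", cfg$n_subtypes,
         " positive probabilities summing to 1")
  if (cfg$n_planted_genes > cfg$n_genes)
    stop("'n_planted_genes' exceeds 'n_genes'")
  if (cfg$n_planted_tissue_mets > cfg$n_tissue_mets)
    stop("'n_planted_tissue_mets' exceeds 'n_tissue_mets'")
  if (cfg$n_planted_serum_mets > cfg$n_serum_mets)
    stop("'n_planted_serum_mets' exceeds 'n_serum_mets'")
  # serum loading on the shared factor; keeps tissue-serum pair correlation
  # at its target (see methods vignette)
  if (cfg$tissue_serum_corr > 0 && cfg$within_block_corr == 0)
    stop("'tissue_serum_corr' > 0 requires 'within_block_corr' > 0")
  if (cfg$within_block_corr > 0 &&
      cfg$tissue_serum_corr / sqrt(cfg$within_block_corr) >= 1)
    stop("'tissue_serum_corr' must be < sqrt(within_block_corr)")
  structure(cfg, class = "cohort_config")
}

#' Simulate subtype-dependent exponential survival
#'
#' Event times are exponential with rate `baseline_hazard`, multiplied by
#' `subtype_hr` for subtype 1 (the planted worst-prognosis subtype).
#' Censoring is administrative at the (1 - censor_rate) quantile of the
#' simulated event times.
#'
#' @param subtype integer subtype label per patient.
#' @param baseline_hazard events per month.
#' @param subtype_hr hazard ratio of subtype 1 vs the rest.
#' @param censor_rate target censored fraction.
#' @param seed RNG seed.
#' @return data frame with `time_months` and `event` (1 = event, 0 =
#'   censored).
#' @export
simulate_survival <- function(subtype, baseline_hazard = 0.02, subtype_hr = 3,
                              censor_rate = 0.3, seed = 1L) {
  .with_seed(seed, {
    rate <- baseline_hazard * ifelse(subtype == 1L, subtype_hr, 1)
    t_event <- stats::rexp(length(subtype), rate = rate)
    if (censor_rate > 0) {
      cutoff <- stats::quantile(t_event, 1 - censor_rate, names = FALSE)
      data.frame(time_months = pmin(t_event, cutoff),
                 event = as.integer(t_event <= cutoff))
    } else {
      data.frame(time_months = t_event, event = 1L)
    }
  })
}

# planted feature f (1..n_planted) is a marker of subtype ((f-1) mod S) + 1
.marker_subtype <- function(n_planted, n_subtypes) {
  ((seq_len(n_planted) - 1L) %% n_subtypes) + 1L
}

#' Generate a synthetic multi-omic cohort with planted structure
#'
#' Produces paired tumor / adjacent non-tumor gene-expression and tissue
#' metabolite matrices, a per-patient serum metabolite matrix, a pairing
#' table, a clinical table with survival and categorical covariates, and the
#' ground truth (subtype labels, planted feature panels, true hazard ratio).
#'
#' All signals are built on a log2 scale and exponentiated, so abundances
#' are strictly positive and log-normal-like; Spearman-based stages are
#' invariant to the exponentiation.  Planted features load a shared
#' per-patient latent factor, carry a log2 fold-change in tumor samples, and
#' are shifted in their marker subtype; background features are independent
#' noise.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: list with `gene_matrix`,
#'   `tissue_met_matrix`, `serum_met_matrix`, `pairing`, `clinical`,
#'   `truth`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, config)
  P <- config$n_patients
  S <- config$n_subtypes
  .with_seed(config$seed, {
    patient_id <- sprintf("P%04d", seq_len(P))
    tumor_id <- paste0(patient_id, "_T")
    nontumor_id <- paste0(patient_id, "_N")
    z <- sample.int(S, P, replace = TRUE, prob = config$subtype_props)
    u <- stats::rnorm(P)                       # shared latent factor

    l_gt <- sqrt(config$within_block_corr)     # gene / tissue loading
    l_s <- if (config$tissue_serum_corr == 0) 0 else
      config$tissue_serum_corr / sqrt(config$within_block_corr)

    build_paired <- function(n_feat, n_planted, prefix, loading) {
      ids <- sprintf("%s%04d", prefix, seq_len(n_feat))
      mu <- stats::rnorm(n_feat, mean = 6, sd = 1)
      noise_sd <- sqrt(1 - loading^2)
      marker <- .marker_subtype(n_planted, S)
      X <- matrix(stats::rnorm(n_feat * 2 * P), n_feat, 2 * P)
      X <- mu + X            # background: unit-variance noise around baseline
      if (n_planted > 0) {
        pl <- seq_len(n_planted)
        sig_t <- outer(rep(loading, n_planted), u) +
          config$subtype_shift * outer(marker, z, "==") +
          config$tumor_nontumor_logfc
        sig_n <- outer(rep(loading, n_planted), u)
        eps <- matrix(stats::rnorm(n_planted * 2 * P, sd = noise_sd),
                      n_planted, 2 * P)
        X[pl, ] <- mu[pl] + cbind(sig_t, sig_n) + eps
      }
      dimnames(X) <- list(ids, c(tumor_id, nontumor_id))
      list(mat = 2^X, planted = ids[seq_len(n_planted)])
    }

    genes <- build_paired(config$n_genes, config$n_planted_genes, "gene", l_gt)
    tmets <- build_paired(config$n_tissue_mets, config$n_planted_tissue_mets,
                          "tmet", l_gt)

    # serum: one sample per patient, no tumor fold-change
    n_sm <- config$n_serum_mets
    smarker <- .marker_subtype(config$n_planted_serum_mets, S)
    mu_s <- stats::rnorm(n_sm, mean = 6, sd = 1)
    Xs <- mu_s + matrix(stats::rnorm(n_sm * P), n_sm, P)
    if (config$n_planted_serum_mets > 0) {
      pl <- seq_len(config$n_planted_serum_mets)
      Xs[pl, ] <- mu_s[pl] +
        outer(rep(l_s, length(pl)), u) +
        config$subtype_shift * outer(smarker, z, "==") +
        matrix(stats::rnorm(length(pl) * P, sd = sqrt(1 - l_s^2)),
               length(pl), P)
    }
    dimnames(Xs) <- list(sprintf("smet%04d", seq_len(n_sm)), patient_id)
    Xs <- 2^Xs

    surv_seed <- .spawn_seeds(config$seed, 2L)[2L]
    surv <- simulate_survival(z, config$baseline_hazard, config$subtype_hr,
                              config$censor_rate, seed = surv_seed)

    clinical <- data.frame(patient_id = patient_id,
                           time_months = surv$time_months,
                           event = surv$event,
                           stringsAsFactors = FALSE)
    covs <- list(sex = c("male", 0.75), age_group = c("over60", 0.5),
                 bmi_group = c("over24", 0.5), diabetes = c("yes", 0.2),
                 ca199_group = c("high", 0.3), afp_group = c("over300", 0.4),
                 cirrhosis = c("yes", 0.6), tnm_group = c("III_IV", 0.5),
                 hbv = c("pos", 0.4), hcv = c("pos", 0.2), ov = c("pos", 0.2))
    for (cv in names(covs)) {
      base_p <- as.numeric(covs[[cv]][2])
      shift <- config$covariate_assoc[[cv]] %||% 0
      p <- stats::plogis(stats::qlogis(base_p) + shift * (z == 1L))
      pos <- stats::rbinom(P, 1L, p) == 1L
      clinical[[cv]] <- ifelse(pos, covs[[cv]][1], paste0("not_", covs[[cv]][1]))
    }

    structure(list(
      gene_matrix = genes$mat,
      tissue_met_matrix = tmets$mat,
      serum_met_matrix = Xs,
      pairing = data.frame(patient_id = patient_id, tumor_sample = tumor_id,
                           nontumor_sample = nontumor_id,
                           stringsAsFactors = FALSE),
      clinical = clinical,
      truth = list(subtype_label = stats::setNames(z, patient_id),
                   planted_gene_ids = genes$planted,
                   planted_tissue_met_ids = tmets$planted,
                   planted_serum_met_ids = rownames(Xs)[seq_len(config$n_planted_serum_mets)],
                   true_hr = config$subtype_hr),
      config = config
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("synthetic_cohort: %d patients, %d genes (%d planted), ",
                     "%d tissue mets (%d planted), %d serum mets (%d planted), ",
                     "%d subtypes\n"),
              cfg$n_patients, cfg$n_genes, cfg$n_planted_genes,
              cfg$n_tissue_mets, cfg$n_planted_tissue_mets,
              cfg$n_serum_mets, cfg$n_planted_serum_mets, cfg$n_subtypes))
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits `genes.tsv`, `tissue_mets.tsv`, `serum_mets.tsv`, `pairing.tsv`,
#' `clinical.tsv`, `truth_labels.tsv` and one `planted_*.txt` feature list
#' per planted panel.
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  if (!inherits(cohort, "synthetic_cohort")) stop("not a synthetic_cohort")
  if (ncol(cohort$serum_met_matrix) == 0L || nrow(cohort$pairing) == 0L)
    stop("no samples")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  write_omics_matrix(cohort$gene_matrix, p("genes.tsv"))
  write_omics_matrix(cohort$tissue_met_matrix, p("tissue_mets.tsv"))
  write_omics_matrix(cohort$serum_met_matrix, p("serum_mets.tsv"))
  .write_tsv(cohort$pairing, p("pairing.tsv"))
  .write_tsv(cohort$clinical, p("clinical.tsv"))
  .write_tsv(data.frame(patient_id = names(cohort$truth$subtype_label),
                        subtype = as.integer(cohort$truth$subtype_label),
                        stringsAsFactors = FALSE),
             p("truth_labels.tsv"))
  writeLines(cohort$truth$planted_gene_ids, p("planted_genes.txt"))
  writeLines(cohort$truth$planted_tissue_met_ids, p("planted_tissue_mets.txt"))
  writeLines(cohort$truth$planted_serum_met_ids, p("planted_serum_mets.txt"))
  files <- c("genes.tsv", "tissue_mets.tsv", "serum_mets.tsv", "pairing.tsv",
             "clinical.tsv", "truth_labels.tsv", "planted_genes.txt",
             "planted_tissue_mets.txt", "planted_serum_mets.txt")
  invisible(stats::setNames(file.path(directory, files), files))
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param directory directory holding the TSV files.
#' @return a `synthetic_cohort` (config not recoverable from disk; the
#'   `config` element is NULL).
#' @export
read_cohort <- function(directory) {
  p <- function(f) file.path(directory, f)
  labels <- .read_tsv(p("truth_labels.tsv"))
  structure(list(
    gene_matrix = read_omics_matrix(p("genes.tsv")),
    tissue_met_matrix = read_omics_matrix(p("tissue_mets.tsv")),
    serum_met_matrix = read_omics_matrix(p("serum_mets.tsv")),
    pairing = .read_tsv(p("pairing.tsv")),
    clinical = .read_tsv(p("clinical.tsv")),
    truth = list(subtype_label = stats::setNames(labels$subtype, labels$patient_id),
                 planted_gene_ids = readLines(p("planted_genes.txt")),
                 planted_tissue_met_ids = readLines(p("planted_tissue_mets.txt")),
                 planted_serum_met_ids = readLines(p("planted_serum_mets.txt")),
                 true_hr = NA_real_),
    config = NULL
  ), class = "synthetic_cohort")
}
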