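#' Assemble and validate a pipeline run configuration
#'
#' A run takes either a `synthetic` block (arguments for [cohort_config()])
#' or an `input` block with `directory` pointing at TSV inputs in the
#' layout written by [write_cohort()].  Stage parameter blocks mirror the
#' module constructors.  Validation is fail-fast: missing input files or a
#' survival stage without a clinical table error before any compute.
#'
#' @param synthetic list of [cohort_config()] arguments, or NULL.
#' @param input list with `directory`, or NULL.
#' @param select list of [two_step_params()] arguments.
#' @param consensus list of [consensus_params()] arguments; `k_override`
#'   defaults to 3 (the reference analysis fixed k = 3).
#' @param survival run the survival/association stage.
#' @param seed root seed; deterministically spawns per-stage seeds.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = list(), input = NULL, select = list(),
                            consensus = list(), survival = TRUE, seed = 1L) {
  seed <- .assert_count(seed, "seed", min = 0L)
  survival <- .assert_flag(survival, "survival")
  stage_seeds <- .spawn_seeds(seed, 3L)
  if (is.null(input)) {
    if (is.null(synthetic)) stop("provide either a synthetic block or an input block")
    synthetic$seed <- synthetic$seed %||% stage_seeds[1L]
    synthetic <- do.call(cohort_config, synthetic)
  } else {
    dir <- input$directory
    if (is.null(dir) || !dir.exists(dir)) stop("input directory not found: ", dir)
    need <- c("genes.tsv", "tissue_mets.tsv", "serum_mets.tsv", "pairing.tsv")
    missing <- need[!file.exists(file.path(dir, need))]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    if (survival && !file.exists(file.path(dir, "clinical.tsv")))
      stop("survival stage enabled but clinical.tsv is missing from ", dir)
    synthetic <- NULL
  }
  select$seed <- select$seed %||% stage_seeds[2L]
  select <- do.call(two_step_params, select)
  consensus$k_override <- consensus$k_override %||% 3L
  consensus$seed <- consensus$seed %||% stage_seeds[3L]
  consensus <- do.call(consensus_params, consensus)
  structure(list(synthetic = synthetic, input = input, select = select,
                 consensus = consensus, survival = survival, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose top-level keys are the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

.digest_files <- function(paths) {
  d <- tools::md5sum(paths)
  stats::setNames(unname(d), basename(paths))
}

#' Run the full analysis pipeline
#'
#' Simulate or load the cohort; run the two-step correlation selection;
#' consensus-cluster the patients independently on the metabolic-gene
#' panel, the tumor-specific tissue-metabolite panel, and the serum panel;
#' report cross-layer label agreement (ARI); and run per-layer survival
#' (KM, log-rank, Cox worst-vs-rest) and Fisher clinical associations.
#' All stage outputs are written as TSV/JSON under `out_dir` at 12
#' significant digits; the manifest lists every output with its MD5 digest,
#' so identical config + seed reproduces byte-identical digests.
#'
#' @param config a [pipeline_config()] (or list of its arguments).
#' @param out_dir output directory, created if needed.
#' @return the run manifest (list), invisibly; written as manifest.json.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character(0)
  run_stage <- function(name, expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }
  p <- function(f) file.path(out_dir, f)

  # stage 1: data
  cohort <- run_stage("data", {
    if (!is.null(config$synthetic)) generate_cohort(config$synthetic)
    else read_cohort(config$input$directory)
  })
  if (config$survival && is.null(cohort$clinical))
    stop("stage data: clinical table required for survival stage")

  # stage 2: two-step correlation selection
  sel <- run_stage("select", two_step_select(
    cohort$gene_matrix, cohort$tissue_met_matrix, cohort$serum_met_matrix,
    cohort$pairing, config$select))
  writeLines(sel$gene_panel, p("panel_genes.txt"))
  writeLines(sel$tumor_specific_tissue_panel, p("panel_tissue_mets.txt"))
  writeLines(sel$serum_panel, p("panel_serum_mets.txt"))
  .write_tsv(sel$gene_stats, p("screen_genes.tsv"))
  .write_tsv(sel$tissue_stats, p("screen_tissue_mets.tsv"))
  .write_tsv(data.frame(grid = sel$step1_null$grid,
                        original_density = sel$step1_null$original_density,
                        null_density = sel$step1_null$null_density),
             p("step1_null.tsv"))
  jsonlite::write_json(
    list(step1 = unclass(sel$step1_threshold),
         step2 = unclass(sel$step2_threshold),
         n_permutations = config$select$n_permutations,
         seed = config$select$seed),
    p("thresholds.json"), auto_unbox = TRUE, digits = NA)

  # stage 3: consensus clustering per data layer
  tumor_cols <- cohort$pairing$tumor_sample
  layer_data <- list(
    MetGene = cohort$gene_matrix[sel$gene_panel, tumor_cols, drop = FALSE],
    TissueMet = cohort$tissue_met_matrix[sel$tumor_specific_tissue_panel,
                                         tumor_cols, drop = FALSE],
    SerumMet = cohort$serum_met_matrix[sel$serum_panel,
                                       cohort$pairing$patient_id, drop = FALSE])
  # cluster items are patients in every layer; consensus distance operates
  # on log2 abundances (median centering needs the additive scale)
  layer_data <- lapply(layer_data, function(m) {
    colnames(m) <- cohort$pairing$patient_id
    log2(m)
  })
  clusters <- run_stage("cluster",
                        lapply(layer_data, run_consensus, params = config$consensus))
  lab_df <- data.frame(patient_id = cohort$pairing$patient_id)
  for (ly in names(clusters)) lab_df[[ly]] <- unname(clusters[[ly]]$labels)
  .write_tsv(lab_df, p("cluster_labels.tsv"))
  for (ly in names(clusters))
    .write_tsv(clusters[[ly]]$k_table, p(paste0("k_selection_", ly, ".tsv")))

  # stage 4: cross-layer agreement
  layers <- names(clusters)
  ari <- data.frame()
  for (i in seq_along(layers)) for (j in seq_along(layers)) if (i < j)
    ari <- rbind(ari, data.frame(
      layer_a = layers[i], layer_b = layers[j],
      ari = adjusted_rand_index(clusters[[layers[i]]]$labels,
                                clusters[[layers[j]]]$labels)))
  .write_tsv(ari, p("cross_layer_ari.tsv"))

  # stage 5: survival and clinical association per layer
  surv_out <- NULL
  if (config$survival) {
    cl <- cohort$clinical
    surv_out <- run_stage("survive", lapply(clusters, function(cc) {
      lab <- cc$labels[cl$patient_id]
      cox <- cox_worst_vs_rest(cl$time_months, cl$event, lab)
      lr <- logrank_test(cl$time_months, cl$event, lab)
      list(cox = cox, logrank = lr, labels = lab)
    }))
    cox_df <- do.call(rbind, lapply(names(surv_out), function(ly) {
      cx <- surv_out[[ly]]$cox
      data.frame(layer = ly, worst_group = cx$worst_group, hr = cx$hr,
                 ci_low = cx$ci_low, ci_high = cx$ci_high,
                 logrank_p_worst_vs_rest = cx$logrank_p,
                 logrank_p_all_groups = surv_out[[ly]]$logrank$p_value,
                 ph_test_p = cx$ph_test_p)
    }))
    .write_tsv(cox_df, p("cox_worst_vs_rest.tsv"))
    km_df <- do.call(rbind, lapply(names(surv_out), function(ly) {
      lab <- surv_out[[ly]]$labels
      do.call(rbind, lapply(sort(unique(lab)), function(g) {
        km <- km_estimate(cl$time_months[lab == g], cl$event[lab == g])
        cbind(layer = ly, group = g, km)
      }))
    }))
    .write_tsv(km_df, p("km_curves.tsv"))
    covars <- setdiff(names(cl), c("patient_id", "time_months", "event"))
    if (length(covars)) {
      fish <- do.call(rbind, lapply(names(surv_out), function(ly) {
        cbind(layer = ly,
              run_stage("associate",
                        fisher_association(surv_out[[ly]]$labels, cl, covars,
                                           seed = config$seed)))
      }))
      .write_tsv(fish, p("fisher_associations.tsv"))
    }
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("metlink")),
    seed = config$seed,
    config = list(select = unclass(config$select),
                  consensus = unclass(config$consensus),
                  survival = config$survival,
                  synthetic = if (!is.null(config$synthetic))
                    unclass(config$synthetic) else NULL),
    outputs = as.list(.digest_files(files)),
    warnings = warnings_seen
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
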