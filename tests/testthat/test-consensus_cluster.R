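test_that("ward_hclust handles forced geometries and bad input", {
  two <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(sort(unname(ward_hclust(two, 2))), c(1L, 2L))

  x <- c(0, 1, 10)
  d <- as.matrix(stats::dist(x))^2
  dimnames(d) <- list(c("p0", "p1", "p10"), c("p0", "p1", "p10"))
  lab <- ward_hclust(d, 2)
  expect_equal(lab[["p0"]], lab[["p1"]])
  expect_false(lab[["p0"]] == lab[["p10"]])

  asym <- matrix(c(0, 1, 2, 0), 2)
  expect_error(ward_hclust(asym, 2), "symmetric")
  expect_error(ward_hclust(two, 1), "k")
})

test_that("ward_hclust matches the exhaustive Ward-objective oracle", {
  # separable instances: greedy agglomeration is only guaranteed optimal
  # when the partition structure is unambiguous (see methods vignette)
  for (s in 1:100) {
    inst <- blob_instance(s)
    got <- ward_hclust(inst$d, inst$k)
    best <- Inf
    for (p in partitions_k(inst$n, inst$k))
      best <- min(best, ward_objective(inst$d, p))
    expect_equal(ward_objective(inst$d, got), best, tolerance = 1e-9)
  }
})

make_items <- function(n_per, n_feat = 30, sep = 2, seed = 1, groups = 2) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(groups * n_feat, sd = sep), groups, n_feat)
  z <- rep(seq_len(groups), each = n_per)
  m <- t(centers[z, ] + matrix(stats::rnorm(length(z) * n_feat, sd = 0.4),
                               length(z), n_feat))
  dimnames(m) <- list(paste0("f", seq_len(n_feat)), paste0("i", seq_along(z)))
  list(m = m, z = z)
}

test_that("consensus_matrix respects its degenerate and planted contracts", {
  it <- make_items(6, seed = 3)
  # item_fraction = 1: every resample identical; entries are 0/1 and equal
  # one plain clustering's co-membership
  pars <- consensus_params(k_max = 2, n_resamples = 20, item_fraction = 1,
                           seed = 11, median_center = FALSE)
  cm <- consensus_matrix(it$m, 2, pars)
  expect_true(all(cm %in% c(0, 1)))
  lab <- ward_hclust(1 - stats::cor(it$m, method = "spearman"), 2)
  expect_equal(cm, outer(lab, lab, function(a, b) (a == b) * 1),
               ignore_attr = TRUE)

  # two well-separated groups of 10
  it2 <- make_items(10, seed = 4)
  pars <- consensus_params(k_max = 2, n_resamples = 100, seed = 12,
                           median_center = FALSE)
  cm2 <- consensus_matrix(it2$m, 2, pars)
  within <- cm2[it2$z == 1, it2$z == 1]
  between <- cm2[it2$z == 1, it2$z == 2]
  expect_gte(min(within[upper.tri(within)]), 0.95)
  expect_lte(max(between), 0.05)

  expect_identical(cm2, consensus_matrix(it2$m, 2, pars))
  expect_true(isSymmetric(cm2))
  expect_true(all(diag(cm2) == 1))
  expect_true(all(cm2 >= 0 & cm2 <= 1))
})

test_that("consensus is equivariant to item order when resampling is trivial", {
  it <- make_items(5, seed = 9)
  pars <- consensus_params(k_max = 2, n_resamples = 5, item_fraction = 1,
                           seed = 2, median_center = FALSE)
  cm <- consensus_matrix(it$m, 2, pars)
  perm <- sample(ncol(it$m))
  cmp <- consensus_matrix(it$m[, perm], 2, pars)
  expect_equal(cmp, cm[perm, perm], ignore_attr = TRUE)
})

test_that("consensus_labels recovers block structure and validates k", {
  blocks <- rbind(cbind(matrix(1, 4, 4), matrix(0, 4, 3)),
                  cbind(matrix(0, 3, 4), matrix(1, 3, 3)))
  dimnames(blocks) <- list(paste0("i", 1:7), paste0("i", 1:7))
  lab <- consensus_labels(blocks, 2)
  expect_equal(length(unique(lab[1:4])), 1L)
  expect_equal(length(unique(lab[5:7])), 1L)
  expect_false(lab[1] == lab[5])
  expect_error(consensus_labels(blocks, 1), "k")
})

test_that("select_k follows the delta-area rule with override", {
  # perfect 3-block consensus at k = 3; k = 2 merges two blocks noisily,
  # k = 4 only perturbs the perfect matrix -> delta area collapses past 3
  n <- 12
  z <- rep(1:3, each = 4)
  perfect <- outer(z, z, "==") * 1
  merged <- outer(z != 3, z != 3, "&") * 0.6 + outer(z == 3, z == 3, "&") * 1
  set.seed(4)
  jitter <- matrix(stats::runif(n * n, 0, 0.05), n)
  jitter <- (jitter + t(jitter)) / 2
  split4 <- pmax(perfect - jitter, 0)
  diag(merged) <- diag(split4) <- 1
  cl <- list(k2 = merged, k3 = perfect, k4 = split4)
  sk <- select_k(cl)
  expect_equal(sk$chosen_k, 3L)
  expect_gt(sk$table$delta_area[2], 0.025)
  expect_lt(sk$table$delta_area[3], 0.025)
  expect_equal(select_k(cl, override = 4)$chosen_k, 4L)

  # engine end-to-end: the k = 3 structure dominates the area gain
  it3 <- make_items(8, seed = 6, groups = 3, sep = 3)
  res <- run_consensus(it3$m, consensus_params(k_max = 6, n_resamples = 120,
                                               seed = 13, median_center = FALSE))
  expect_equal(which.max(res$k_table$delta_area[-1]) + 2L, 3L)

  flat <- lapply(2:4, function(k) {
    m <- matrix(0.4, 10, 10); diag(m) <- 1; m
  })
  names(flat) <- paste0("k", 2:4)
  sk <- select_k(flat)
  expect_equal(sk$chosen_k, 2L)
  expect_true(all(abs(sk$table$delta_area[-1]) < 1e-12))
})

test_that("consensus recovers planted subtypes on a 75-metabolite panel", {
  co <- generate_cohort(cohort_config(n_serum_mets = 300,
                                      n_planted_serum_mets = 75, seed = 17))
  panel <- co$truth$planted_serum_met_ids
  m <- tumor_log2(co, "serum_met_matrix", panel)
  res <- run_consensus(m, consensus_params(k_max = 5, n_resamples = 250,
                                           k_override = 3, seed = 3044))
  truth <- co$truth$subtype_label[names(res$labels)]
  expect_gte(adjusted_rand_index(res$labels, truth), 0.9)
})

test_that("adjusted_rand_index behaves at the reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 1, 1), c(1, 1, 1, 1)), 1)
  set.seed(2)
  a <- sample(1:3, 300, replace = TRUE)
  b <- sample(1:3, 300, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.1)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})
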