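make_paired <- function(values_t, values_n, feature = "f1") {
  n <- length(values_t)
  pid <- sprintf("P%02d", seq_len(n))
  m <- rbind(c(values_t, values_n))
  dimnames(m) <- list(feature, c(paste0(pid, "_T"), paste0(pid, "_N")))
  list(m = m, design = data.frame(patient_id = pid,
                                  tumor_sample = paste0(pid, "_T"),
                                  nontumor_sample = paste0(pid, "_N")))
}

test_that("paired_t_test matches closed-form and degenerate conventions", {
  # differences (1, 2, 3): t = 2 / (1 / sqrt(3)), df = 2
  px <- make_paired(c(2, 4, 6), c(1, 2, 3))
  out <- paired_t_test(px$m, px$design, log2_transform = FALSE)
  expect_equal(out$t_statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(out$p_value, 2 * stats::pt(2 * sqrt(3), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(out$p_value, 0.07417990, tolerance = 1e-7)

  # symmetric differences (-1, +1) and all-zero differences: t = 0, p = 1
  sym <- make_paired(c(1, 3), c(2, 2))
  out <- paired_t_test(sym$m, sym$design, log2_transform = FALSE)
  expect_equal(out$t_statistic, 0)
  expect_equal(out$p_value, 1)
  flat <- make_paired(c(5, 5, 5), c(5, 5, 5))
  out <- paired_t_test(flat$m, flat$design, log2_transform = FALSE)
  expect_equal(out$t_statistic, 0)
  expect_equal(out$p_value, 1)

  expect_error(paired_t_test(make_paired(1, 1)$m, make_paired(1, 1)$design),
               "at least 2 pairs")
  bad <- make_paired(c(1, 2), c(1, 2))
  bad$design$tumor_sample[1] <- "missing_id"
  expect_error(paired_t_test(bad$m, bad$design), "missing_id")
})

test_that("paired_t_test agrees with t.test on random inputs", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    px <- make_paired(stats::rexp(n) + 0.5, stats::rexp(n) + 0.5)
    mine <- paired_t_test(px$m, px$design, log2_transform = FALSE)
    ref <- stats::t.test(px$m[1, px$design$tumor_sample],
                         px$m[1, px$design$nontumor_sample], paired = TRUE)
    expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("bh_adjust implements step-up with cap and rejects bad input", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.9, 0.8)), c(0.9, 0.9))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")

  set.seed(7)
  for (i in 1:25) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("fold_change uses raw-scale means and refuses nonpositive input", {
  px <- make_paired(c(2, 4), c(1, 1))
  expect_equal(fold_change(px$m, px$design)$fold_change, 3)
  down <- make_paired(c(1, 1), c(2, 2))
  expect_equal(fold_change(down$m, down$design)$fold_change, 0.5)
  neg <- make_paired(c(2, -1), c(1, 1))
  expect_error(fold_change(neg$m, neg$design), "non-positive")
})

test_that("filter_features applies strict q cutoff and two-sided FC", {
  stats_df <- data.frame(feature_id = c("a", "b", "c", "d"),
                         q_value = c(0.049, 0.05, 0.01, 0.01),
                         fold_change = c(2, 2, 1.4, 0.5))
  expect_equal(filter_features(stats_df, q_max = 0.05), c("a", "c", "d"))
  expect_equal(filter_features(stats_df, q_max = 0.05, fc_min = 1.5), c("a", "d"))
})

test_that("top_variable_features ranks by variance with lexicographic ties", {
  m <- rbind(a = c(1, 1, 1), z = c(0, 2, 4), b = c(0, 1, 2), c = c(2, 1, 0))
  colnames(m) <- paste0("s", 1:3)
  expect_equal(top_variable_features(m, 1), "z")
  # b and c tie at variance 1: lexicographic order
  expect_equal(top_variable_features(m, 3), c("z", "b", "c"))
  expect_equal(sort(top_variable_features(m, 4)), sort(rownames(m)))
  expect_warning(got <- top_variable_features(m, 10), "only 4")
  expect_equal(length(got), 4L)
})

test_that("pca_projection is orthonormal with correct variance split", {
  # exact sample covariance [[2, 1], [1, 2]]: eigenvalues 3 and 1
  u1 <- c(-1, 0, 1) / sqrt(2)
  u2 <- c(1, -2, 1) / sqrt(6)
  L <- chol(matrix(c(2, 1, 1, 2), 2))
  X <- sqrt(2) * t(L) %*% rbind(u1, u2)    # 2 features x 3 samples
  dimnames(X) <- list(c("f1", "f2"), c("s1", "s2", "s3"))
  pc <- pca_projection(X, 2)
  expect_equal(pc$explained, c(0.75, 0.25), tolerance = 1e-10)
  expect_equal(crossprod(pc$rotation), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)

  # collinear samples: one component carries all variance
  line <- rbind(f1 = c(0, 1, 2, 3), f2 = c(0, 2, 4, 6))
  colnames(line) <- paste0("s", 1:4)
  pc <- pca_projection(line, 2)
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)

  expect_error(pca_projection(line, 4), "samples - 1")
})

test_that("null-cohort screen keeps roughly the nominal false positive rate", {
  co <- generate_cohort(null_cohort_config(seed = 5, n_patients = 40,
                                           n_features = 400))
  st <- feature_stats(co$gene_matrix, co$pairing)
  frac <- mean(st$q_value < 0.05)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lte(frac, 0.05 + 3 * se)
})
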