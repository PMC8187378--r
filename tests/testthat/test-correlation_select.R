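row_matrix <- function(..., prefix = "f") {
  m <- rbind(...)
  dimnames(m) <- list(paste0(prefix, seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  m
}

test_that("spearman_matrix reproduces hand and oracle values", {
  A <- row_matrix(c(1, 2, 3, 4))
  expect_equal(spearman_matrix(A, A)$c[1, 1], 1)
  B <- row_matrix(c(4, 3, 2, 1))
  expect_equal(spearman_matrix(A, B)$c[1, 1], -1)
  A5 <- row_matrix(c(1, 2, 3, 4, 5))
  B5 <- row_matrix(c(2, 1, 4, 3, 5))
  expect_equal(spearman_matrix(A5, B5)$c[1, 1], 0.8)  # 1 - 6*4/(5*24)

  expect_error(spearman_matrix(row_matrix(c(1, 2)), row_matrix(c(2, 1))),
               "at least 3")
  expect_warning(cc <- spearman_matrix(row_matrix(c(1, 1, 1, 1)), A),
                 "constant")
  expect_equal(cc$c[1, 1], 0)
})

test_that("spearman_matrix equals rank-then-Pearson brute force, with ties", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    x <- sample(1:6, n, replace = TRUE) + stats::rnorm(n, sd = ifelse(i %% 2, 0, 1))
    y <- sample(1:6, n, replace = TRUE) + stats::rnorm(n, sd = 0.5)
    got <- spearman_matrix(row_matrix(x), row_matrix(y))$c[1, 1]
    expect_equal(got, stats::cor(rank(x), rank(y)), tolerance = 1e-10)
    expect_equal(got, suppressWarnings(stats::cor(x, y, method = "spearman")),
                 tolerance = 1e-10)
  }
})

test_that("spearman_matrix is invariant to strictly monotone transforms", {
  set.seed(8)
  A <- matrix(stats::rnorm(5 * 12), 5,
              dimnames = list(paste0("a", 1:5), paste0("s", 1:12)))
  B <- matrix(stats::rnorm(4 * 12), 4,
              dimnames = list(paste0("b", 1:4), paste0("s", 1:12)))
  base <- spearman_matrix(A, B)$c
  expect_equal(spearman_matrix(exp(A), B)$c, base, tolerance = 1e-12)
  expect_equal(spearman_matrix(A, B^3)$c, base, tolerance = 1e-12)
})

test_that("permutation_null is deterministic with unit-mass densities", {
  set.seed(5)
  A <- matrix(stats::rexp(20 * 15), 20,
              dimnames = list(paste0("a", 1:20), paste0("s", 1:15)))
  B <- matrix(stats::rexp(10 * 15), 10,
              dimnames = list(paste0("b", 1:10), paste0("s", 1:15)))
  d1 <- permutation_null(A, B, n_permutations = 50, seed = 9)
  d2 <- permutation_null(A, B, n_permutations = 50, seed = 9)
  expect_identical(d1, d2)
  binw <- d1$grid[2] - d1$grid[1]
  expect_equal(sum(d1$original_density) * binw, 1, tolerance = 1e-9)
  expect_equal(sum(d1$null_density) * binw, 1, tolerance = 1e-9)
  expect_error(permutation_null(A, B, n_permutations = 0), "n_permutations")
})

test_that("independent data give agreeing densities; planted blocks fatten tails", {
  co <- generate_cohort(null_cohort_config(seed = 2, n_patients = 60,
                                           n_features = 50))
  nd <- permutation_null(co$gene_matrix[, co$pairing$tumor_sample],
                         co$tissue_met_matrix[, co$pairing$tumor_sample],
                         n_permutations = 100, seed = 4)
  binw <- nd$grid[2] - nd$grid[1]
  ks <- max(abs(cumsum(nd$original_density) - cumsum(nd$null_density))) * binw
  expect_lt(ks, 0.05)

  pl <- generate_cohort(cohort_config(n_patients = 60, n_genes = 50,
                                      n_tissue_mets = 50, n_serum_mets = 10,
                                      n_planted_genes = 25, n_planted_tissue_mets = 25,
                                      n_planted_serum_mets = 2, seed = 6))
  ndp <- permutation_null(pl$gene_matrix[, pl$pairing$tumor_sample],
                          pl$tissue_met_matrix[, pl$pairing$tumor_sample],
                          n_permutations = 100, seed = 4)
  null_sd <- sqrt(sum(ndp$null_density * binw * ndp$grid^2))
  beyond <- abs(ndp$grid) > 2 * null_sd
  orig_mass <- sum(ndp$original_density[beyond]) * binw
  null_mass <- sum(ndp$null_density[beyond]) * binw
  expect_gt(orig_mass, null_mass)
})

test_that("threshold_from_intersection finds the analytic density crossing", {
  grid_bins <- 201
  binw <- 2 / grid_bins
  g <- seq(-1 + binw / 2, 1 - binw / 2, length.out = grid_bins)
  orig <- 0.9 * stats::dnorm(g, 0, 0.1) + 0.1 * stats::dnorm(g, 0, 0.3)
  null <- stats::dnorm(g, 0, 0.1)
  dist <- structure(list(grid = g, original_density = orig, null_density = null,
                         n_permutations = 1L, seed = 1L),
                    class = "null_distribution")
  th <- threshold_from_intersection(dist)
  # oracle: root of the closed-form density difference
  cross <- stats::uniroot(function(x)
    0.9 * stats::dnorm(x, 0, 0.1) + 0.1 * stats::dnorm(x, 0, 0.3) -
      stats::dnorm(x, 0, 0.1), c(0.05, 0.5))$root
  expect_false(th$degenerate_flag)
  expect_lt(abs(th$upper - cross), binw + 1e-9)
  expect_lt(abs(th$lower + cross), binw + 1e-9)
  expect_true(th$lower < 0 && th$upper > 0)
})

test_that("identical densities are degenerate with quantile fallback", {
  grid_bins <- 201
  binw <- 2 / grid_bins
  g <- seq(-1 + binw / 2, 1 - binw / 2, length.out = grid_bins)
  null <- stats::dnorm(g, 0, 0.1)
  dist <- structure(list(grid = g, original_density = null, null_density = null,
                         n_permutations = 1L, seed = 1L),
                    class = "null_distribution")
  th <- threshold_from_intersection(dist)
  expect_true(th$degenerate_flag)
  # 0.95 quantile of |N(0, 0.1)| is qnorm(0.975) * 0.1, up to binning
  expect_lt(abs(th$upper - stats::qnorm(0.975) * 0.1), 2 * binw)
  expect_equal(th$lower, -th$upper)

  bad <- dist
  bad$original_density <- bad$null_density <- rep(0, grid_bins)
  expect_error(threshold_from_intersection(bad), "empty")
})

test_that("selection scores and strict thresholding follow the definitions", {
  cr <- structure(list(row_feature_ids = c("g1", "g2"),
                       col_feature_ids = c("m1", "m2"),
                       c = matrix(c(0.2, 0.6, -0.4, 0.0), 2)),
                  class = "correlation_result")
  sc <- selection_scores(cr)
  expect_equal(unname(sc$G), c(0.3, 0.3))
  expect_equal(unname(sc$T), c(0.4, 0.2))
  expect_equal(sc$I, 2L)
  expect_equal(sc$J, 2L)

  allhalf <- structure(list(row_feature_ids = "g", col_feature_ids = c("a", "b"),
                            c = matrix(c(0.5, -0.5), 1)),
                       class = "correlation_result")
  expect_equal(unname(selection_scores(allhalf)$G), 0.5)

  # boundary is strict: a score equal to the threshold is not selected
  exact <- structure(list(row_feature_ids = c("g1", "g2"),
                          col_feature_ids = c("m1", "m2"),
                          c = matrix(c(0.25, 0.75, -0.75, 0.5), 2)),
                     class = "correlation_result")
  sel <- select_by_threshold(selection_scores(exact), 0.5)
  expect_equal(sel$rows, "g2")       # G = (0.5, 0.625): 0.5 is not > 0.5
  expect_equal(sel$cols, "m2")       # T = (0.5, 0.625): same rule

})

test_that("pure-noise selection stays bounded across seeds", {
  fracs <- vapply(1:5, function(s) {
    set.seed(s)
    A <- matrix(stats::rnorm(40 * 30), 40,
                dimnames = list(paste0("a", 1:40), paste0("s", 1:30)))
    B <- matrix(stats::rnorm(40 * 30), 40,
                dimnames = list(paste0("b", 1:40), paste0("s", 1:30)))
    nd <- permutation_null(A, B, n_permutations = 100, seed = s)
    th <- threshold_from_intersection(nd)
    sel <- select_by_threshold(selection_scores(spearman_matrix(A, B)),
                               th$upper)
    (length(sel$rows) + length(sel$cols)) / 80
  }, numeric(1))
  expect_lte(mean(fracs), 0.10)
})
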