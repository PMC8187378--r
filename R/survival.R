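#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous nonincreasing step function with S(0) = 1.  At tied
#' times, events are handled before censorings (standard convention).
#'
#' @param time follow-up times (> 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @return data frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("need at least one record")
  if (any(time <= 0)) stop("times must be positive")
  event <- as.integer(event)
  ts <- sort(unique(time))
  n <- length(time)
  out <- data.frame(time = ts, n_risk = NA_real_, n_event = NA_real_,
                    n_censor = NA_real_, survival = NA_real_)
  s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1L)
    cns <- sum(time == ts[i] & event == 0L)
    if (d > 0) s <- s * (1 - d / at_risk)
    out$n_risk[i] <- at_risk; out$n_event[i] <- d
    out$n_censor[i] <- cns; out$survival[i] <- s
  }
  out
}

# restricted mean survival time: integral of the KM step function on [0, tau]
.rmst <- function(time, event, tau) {
  km <- km_estimate(time, event)
  km <- km[km$time <= tau, , drop = FALSE]
  tpts <- c(0, km$time, tau)
  surv <- c(1, km$survival)
  sum(diff(tpts) * surv)
}

#' Multi-group log-rank test
#'
#' Classical observed-minus-expected statistic with the multivariate
#' hypergeometric variance at each event time; chi-square on groups - 1
#' degrees of freedom.
#'
#' @param time,event survival data.
#' @param group group labels (>= 2 groups, each nonempty).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  if (any(time <= 0)) stop("times must be positive")
  lv <- sort(unique(group))
  G <- length(lv)
  if (G < 2L) stop("need at least 2 groups")
  event <- as.integer(event)
  ev_times <- sort(unique(time[event == 1L]))
  OE <- numeric(G)
  V <- matrix(0, G, G)
  for (t in ev_times) {
    n_t <- sum(time >= t)
    d_t <- sum(time == t & event == 1L)
    n_g <- vapply(lv, function(g) sum(time >= t & group == g), numeric(1))
    d_g <- vapply(lv, function(g) sum(time == t & event == 1L & group == g),
                  numeric(1))
    e_g <- n_g * d_t / n_t
    OE <- OE + (d_g - e_g)
    if (n_t > 1) {
      # multivariate hypergeometric covariance of the group event counts
      frac <- n_g / n_t
      vt <- d_t * (n_t - d_t) / (n_t - 1) *
        (diag(frac, G) - tcrossprod(frac))
      V <- V + vt
    }
  }
  idx <- seq_len(G - 1L)
  stat <- tryCatch(
    drop(t(OE[idx]) %*% solve(V[idx, idx, drop = FALSE], OE[idx])),
    error = function(e) {
      if (sum(abs(OE)) < 1e-10) 0 else stop("singular log-rank variance matrix")
    })
  stat <- max(stat, 0)
  list(statistic = stat, df = G - 1L,
       p_value = stats::pchisq(stat, df = G - 1L, lower.tail = FALSE))
}

#' Identify the worst-survival group
#'
#' The group with the lowest restricted mean survival time, integrating
#' each group's KM curve up to the last shared follow-up time (the minimum
#' over groups of the longest follow-up).  Ties break by label sort order.
#'
#' @inheritParams logrank_test
#' @return the worst group's label.
#' @export
identify_worst_group <- function(time, event, group) {
  group <- as.character(group)
  lv <- sort(unique(group))
  if (length(lv) < 2L) stop("need at least 2 groups")
  tau <- min(vapply(lv, function(g) max(time[group == g]), numeric(1)))
  rm <- vapply(lv, function(g)
    .rmst(time[group == g], event[group == g], tau), numeric(1))
  lv[which.min(rm)]    # which.min takes the first = lowest label on ties
}

#' Cox proportional-hazards model, worst group vs the rest
#'
#' Binary-covariate Cox partial likelihood with Efron tie handling; Wald
#' 95% CI on the log hazard ratio; log-rank p for worst vs rest; Schoenfeld
#' residual test of the proportional-hazards assumption.
#'
#' @inheritParams logrank_test
#' @return object of class `cox_result`: `hr`, `ci_low`, `ci_high`,
#'   `logrank_p`, `ph_test_p`, `worst_group`.
#' @export
cox_worst_vs_rest <- function(time, event, group) {
  worst <- identify_worst_group(time, event, group)
  x <- as.integer(as.character(group) == worst)
  event <- as.integer(event)
  if (sum(event) == 0L) stop("no events")
  if (sum(event[x == 1L]) == 0L || sum(event[x == 0L]) == 0L)
    stop("need at least one event in both the worst group and the rest")
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || se > 100)
    stop("Cox model did not converge (log HR ", signif(beta, 3),
         ", SE ", signif(se, 3), ")")
  lr <- logrank_test(time, event, ifelse(x == 1L, "worst", "rest"))
  ph_p <- tryCatch(survival::cox.zph(fit)$table["x", "p"],
                   error = function(e) NA_real_)
  structure(list(hr = exp(beta),
                 ci_low = exp(beta - stats::qnorm(0.975) * se),
                 ci_high = exp(beta + stats::qnorm(0.975) * se),
                 logrank_p = lr$p_value,
                 ph_test_p = ph_p,
                 worst_group = worst),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox worst-vs-rest: group '%s', HR %.3g [%.3g-%.3g], log-rank p = %.3g\n",
              x$worst_group, x$hr, x$ci_low, x$ci_high, x$logrank_p))
  invisible(x)
}

#' Fisher's exact test of cluster labels against clinical covariates
#'
#' Per covariate, an exact two-sided test (probability-based rule: sum of
#' probabilities of tables, given the margins, no more probable than the
#' observed one).  Tables whose total count exceeds `exact_limit` are
#' evaluated by seeded Monte-Carlo instead of full enumeration.  p-values
#' are BH adjusted across covariates.
#'
#' @param labels cluster labels per patient.
#' @param clinical data frame of categorical covariates (one row per
#'   patient, same order as `labels`).
#' @param covariates covariate columns to test; default: all columns.
#' @param exact_limit largest table total for exact enumeration.
#' @param n_mc Monte-Carlo replicates beyond the limit.
#' @param seed RNG seed for Monte-Carlo p-values.
#' @return data frame: covariate, p_value, q_value.
#' @export
fisher_association <- function(labels, clinical, covariates = names(clinical),
                               exact_limit = 1000, n_mc = 10000, seed = 1L) {
  p <- vapply(covariates, function(cv) {
    tab <- table(factor(labels), factor(clinical[[cv]]))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (any(dim(tab) < 2L))
      stop("covariate '", cv, "' has an empty margin")
    if (sum(tab) <= exact_limit && prod(dim(tab)) <= 30) {
      stats::fisher.test(tab, workspace = 2e7)$p.value
    } else {
      .with_seed(seed, stats::fisher.test(tab, simulate.p.value = TRUE,
                                          B = n_mc)$p.value)
    }
  }, numeric(1))
  p <- pmin(unname(p), 1)        # fisher.test can exceed 1 by rounding
  data.frame(covariate = covariates, p_value = p,
             q_value = bh_adjust(p), stringsAsFactors = FALSE)
}
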