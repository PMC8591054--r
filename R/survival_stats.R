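#' Kaplan-Meier product-limit estimate
#'
#' @param time Numeric follow-up times in days (>= 0).
#' @param event 0 = censored, 1 = death.
#' @return List with `time`, `surv` (step values), `n_risk`, `n_event`,
#'   and `median` (earliest time with S(t) <= 0.5; `NA` = not reached).
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("survival times must be >= 0")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  # median convention: earliest observed time at which S(t) <= 0.5
  hit <- fit$surv <= 0.5
  med <- if (any(hit)) fit$time[which(hit)[1]] else NA_real_
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, median = med)
}

#' Log-rank test between survival groups
#'
#' Standard log-rank: per event time, observed minus expected events per
#' group with hypergeometric variance; chi-square with (groups - 1) df.
#' For two groups the signed standardized statistic
#' `z = (O2 - E2) / sqrt(V)` is also returned (positive when the second
#' group level has more events than expected, i.e. worse survival).
#'
#' @param time,event Survival record vectors.
#' @param group Group labels (>= 2 groups, coerced to factor).
#' @return List with `chisq`, `df`, `p_value`, and `z` (2 groups only).
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) < 2) stop("log-rank test needs at least 2 groups")
  if (sum(event) < 1) stop("log-rank test needs at least 1 event")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- nlevels(g) - 1L
  p <- stats::pchisq(sd_fit$chisq, df = df, lower.tail = FALSE)
  z <- NA_real_
  if (nlevels(g) == 2) {
    v <- if (is.matrix(sd_fit$var)) sd_fit$var[2, 2] else sd_fit$var
    z <- (sd_fit$obs[2] - sd_fit$exp[2]) / sqrt(v)
  }
  list(chisq = unname(sd_fit$chisq), df = df, p_value = unname(p), z = unname(z))
}

#' Maximally selected rank-statistic survival cutpoint
#'
#' Evaluates, at every admissible candidate threshold (midpoints of
#' consecutive distinct score values whose split keeps both sides at
#' `minprop` of the cohort), the standardized two-group log-rank statistic
#' between samples above (`high`, strictly greater) and at-or-below
#' (`low`) the threshold, and returns the threshold maximising the
#' absolute statistic. Ties in |statistic| go to the smallest threshold.
#'
#' @param score Numeric per-sample score.
#' @param time,event Survival record vectors, aligned with `score`.
#' @param minprop Minimum fraction of samples on each side (default 0.1).
#' @return List of class `"cutpoint_result"`: `threshold`,
#'   `standardized_statistic`, `n_high`, `n_low`, `minprop`, `group`
#'   (factor high/low per sample), `candidates` (per-candidate table).
#' @export
optimal_cutpoint <- function(score, time, event, minprop = 0.1) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  n <- length(score)
  s_sorted <- sort(unique(score))
  if (length(s_sorted) < 2) stop("need at least 2 distinct score values")
  cand <- (s_sorted[-1] + s_sorted[-length(s_sorted)]) / 2
  n_high <- vapply(cand, function(ct) sum(score > ct), 0L)
  ok <- pmin(n_high, n - n_high) >= minprop * n
  cand <- cand[ok]
  if (!length(cand)) stop("no candidate threshold satisfies minprop = ", minprop)
  stat <- vapply(cand, function(ct) {
    grp <- factor(ifelse(score > ct, "high", "low"), levels = c("low", "high"))
    logrank_test(time, event, grp)$z
  }, numeric(1))
  best <- which.max(abs(stat))  # first index = smallest threshold on ties
  thr <- cand[best]
  grp <- factor(ifelse(score > thr, "high", "low"), levels = c("low", "high"))
  structure(list(threshold = thr, standardized_statistic = stat[best],
                 n_high = sum(grp == "high"), n_low = sum(grp == "low"),
                 minprop = minprop, group = grp,
                 candidates = data.frame(threshold = cand, statistic = stat)),
            class = "cutpoint_result")
}

#' Wilcoxon rank-sum test
#'
#' Midrank ties with normal approximation; exact enumeration when the
#' combined sample size is at most 10 and there are no ties.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `statistic` (W) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) stop("empty group")
  exact <- (length(x) + length(y)) <= 10 && !anyDuplicated(c(x, y))
  ht <- stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                           correct = !exact)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Kruskal-Wallis rank test
#' @param x Numeric values.
#' @param group Group labels (>= 2 non-empty groups).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(x, group) {
  g <- factor(group)
  if (any(table(g) == 0) || nlevels(g) < 2) stop("need >= 2 non-empty groups")
  ht <- stats::kruskal.test(x, g)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Spearman rank correlation with tie correction
#' @param x,y Paired numeric vectors.
#' @return List with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need >= 3 paired values")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ht$estimate), p_value = ht$p.value)
}

#' Pearson chi-square test on a contingency table
#' @param tab Matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Benjamini-Hochberg adjustment
#' @param p Vector of p-values.
#' @return Adjusted p-values (step-up FDR).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
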