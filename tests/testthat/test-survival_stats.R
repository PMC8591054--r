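test_that("Kaplan-Meier estimator matches hand-computed product-limit tables", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)

  km_c <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km_c$surv == 1))
  expect_true(is.na(km_c$median))

  # mixed 6-record case, hand product-limit:
  # t=2 (5 at risk after censoring at 1): S = 4/5
  # t=4 (3 at risk): S = 4/5 * 2/3
  # t=6 (1 at risk): S = 4/5 * 2/3 * 0
  km_m <- km_estimate(c(1, 2, 3, 4, 5, 6), c(0, 1, 0, 1, 0, 1))
  ev <- km_m$n_event > 0
  expect_equal(km_m$surv[ev], c(4 / 5, 4 / 5 * 2 / 3, 0))
  expect_equal(km_m$median, 6)  # S first reaches <= 0.5 at the last event
  expect_error(km_estimate(c(-1, 2), c(1, 1)), ">= 0")

  # non-increasing with S(0) = 1 implied
  expect_true(all(diff(km_m$surv) <= 0))
})

test_that("log-rank statistic is zero for identical groups and matches a hand-worked case", {
  t2 <- c(1, 2, 3, 4); e2 <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(t2, t2), c(e2, e2), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  # 4 subjects, 1 event per group at distinct times:
  # g1: (1, event), (4, censored); g2: (2, event), (3, censored)
  # t=1: E1 = 1/2, V = 1/4;  t=2: E1 = 1/3, V = 2/9
  # O1 - E1 = 1 - 5/6 = 1/6;  V = 17/36;  chisq = (1/6)^2 / (17/36) = 1/17
  lr <- logrank_test(c(1, 4, 2, 3), c(1, 0, 1, 0), c(1, 1, 2, 2))
  expect_equal(lr$chisq, 1 / 17, tolerance = 1e-10)
  expect_error(logrank_test(t2, e2, rep("a", 4)), "2 groups")
})

test_that("log-rank holds its nominal type-I error under the null", {
  withr::with_seed(71, {
    reject <- vapply(seq_len(400), function(i) {
      tt <- rexp(60); cc <- runif(60, 0, 3)
      logrank_test(pmin(tt, cc), as.integer(tt <= cc),
                   rep(c(1, 2), 30))$p_value < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(reject) - 0.05), 0.03)
})

test_that("the optimal cutpoint equals brute force over admissible thresholds", {
  brute <- function(score, time, event, minprop = 0.1) {
    s <- sort(unique(score))
    cand <- (s[-1] + s[-length(s)]) / 2
    n <- length(score)
    best <- NULL
    for (ct in cand) {
      hi <- score > ct
      if (min(sum(hi), n - sum(hi)) < minprop * n) next
      z <- logrank_test(time, event, factor(ifelse(hi, "high", "low"),
                                            levels = c("low", "high")))$z
      if (is.null(best) || abs(z) > abs(best$z) + 1e-12) best <- list(ct = ct, z = z)
    }
    best
  }
  withr::with_seed(72, {
    for (rep in 1:10) {
      n <- sample(20:60, 1)
      score <- rnorm(n)
      tt <- rexp(n, exp(0.5 * score)); cc <- runif(n, 0, 2)
      time <- pmin(tt, cc); event <- as.integer(tt <= cc)
      if (sum(event) < 2) next
      cp <- optimal_cutpoint(score, time, event)
      oracle <- brute(score, time, event)
      expect_equal(cp$threshold, oracle$ct)
      expect_equal(cp$standardized_statistic, oracle$z, tolerance = 1e-10)
      expect_gte(min(cp$n_high, cp$n_low), 0.1 * n)
    }
  })
})

test_that("cutpoint degenerate cases behave as specified", {
  # only one admissible candidate: two distinct values
  score <- c(rep(0, 5), rep(1, 5))
  time <- c(1, 2, 3, 4, 5, 10, 11, 12, 13, 14)
  event <- rep(1, 10)
  cp <- optimal_cutpoint(score, time, event)
  expect_equal(cp$threshold, 0.5)
  # two score blocs perfectly separating early deaths (unordered within
  # bloc) from long survivors: threshold falls between the blocs
  score2 <- c(1:5, 101:105) / 10
  time2 <- c(2, 1, 3, 1.5, 2.5, 12, 10, 14, 11, 13)
  cp2 <- optimal_cutpoint(score2, time2, event)
  expect_gt(cp2$threshold, 0.5); expect_lt(cp2$threshold, 10.1)
  expect_error(optimal_cutpoint(rep(1, 10), time, event), "distinct")
  expect_error(optimal_cutpoint(score, time, event, minprop = 0.6), "minprop")
  # ties at the threshold go to the low group
  expect_equal(sum(cp$group == "high"), 5)
})

test_that("rank tests reproduce exact and hand-derived reference values", {
  # one-sided exact Wilcoxon on {1,2} vs {3,4}: p = 1/6
  expect_equal(wilcoxon_rank_sum(c(3, 4), c(1, 2), alternative = "greater")$p_value,
               1 / 6, tolerance = 1e-12)
  # BH step-up on (0.01, 0.02, 0.03, 0.04): all adjusted to 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4), tolerance = 1e-12)
  # perfectly monotone pairs: Spearman rho = 1
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  # chi-square on a 2x2, hand value: n(ad-bc)^2 / (r1 r2 c1 c2)
  tab <- matrix(c(20, 10, 5, 25), nrow = 2)
  hand <- 60 * (20 * 25 - 10 * 5)^2 / (25 * 35 * 30 * 30)
  expect_equal(chi_square_table(tab)$statistic, hand, tolerance = 1e-10)
  # Kruskal-Wallis on an obvious 3-group shift
  kw <- kruskal_wallis(c(1:5, 11:15, 21:25), rep(1:3, each = 5))
  expect_lt(kw$p_value, 0.01)
  expect_error(kruskal_wallis(1:4, rep(1, 4)), "2 non-empty")
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")
})

test_that("Wilcoxon and Spearman p-values are calibrated under their nulls", {
  withr::with_seed(73, {
    p_w <- vapply(seq_len(400), function(i)
      wilcoxon_rank_sum(rnorm(25), rnorm(25))$p_value, numeric(1))
    p_s <- vapply(seq_len(400), function(i)
      spearman_cor(rnorm(60), rnorm(60))$p_value, numeric(1))
  })
  expect_lt(abs(mean(p_w < 0.05) - 0.05), 0.03)
  expect_lt(abs(mean(p_s < 0.05) - 0.05), 0.03)
  expect_gt(mean(p_w), 0.45); expect_lt(mean(p_w), 0.55)
})
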