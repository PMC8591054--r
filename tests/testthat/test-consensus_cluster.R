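# exhaustive-search oracle for 2-medoid partitioning on small point sets
brute_pam2 <- function(x) {
  n <- length(x)
  d <- as.matrix(dist(x))
  best <- NULL
  for (m1 in 1:(n - 1)) for (m2 in (m1 + 1):n) {
    assign <- ifelse(d[, m1] <= d[, m2], 1L, 2L)
    cost <- sum(d[cbind(1:n, c(m1, m2)[assign])])
    if (is.null(best) || cost < best$cost) best <- list(cost = cost, labels = assign)
  }
  best
}

test_that("PAM separates well-separated groups and matches brute force on small sets", {
  x <- c(0, 0.1, 10, 10.1)
  fit <- pam_cluster(as.matrix(dist(x)), k = 2)
  expect_equal(fit$labels[1], fit$labels[2])
  expect_equal(fit$labels[3], fit$labels[4])
  expect_false(fit$labels[1] == fit$labels[3])

  # k = n: every sample its own medoid, zero cost
  fit_n <- pam_cluster(as.matrix(dist(x)), k = 4)
  expect_equal(sort(fit_n$labels), 1:4)
  expect_equal(sort(fit_n$medoids), 1:4)

  withr::with_seed(91, {
    for (rep in 1:5) {
      x8 <- c(rnorm(4, 0, 0.4), rnorm(4, 6, 0.4))[sample(8)]
      pam_lab <- pam_cluster(as.matrix(dist(x8)), k = 2)$labels
      oracle <- brute_pam2(x8)$labels
      expect_equal(rand_ari(pam_lab, oracle), 1)
    }
  })
  expect_error(pam_cluster(as.matrix(dist(x)), k = 1), "out of range")
})

test_that("identical samples always co-cluster with consensus 1", {
  withr::with_seed(14, X <- matrix(rnorm(40), nrow = 8))
  X <- rbind(X, X)   # each row i duplicated as row i+8
  cc <- consensus_cluster(X, k_range = 2:3, n_resample = 60, seed = 3)
  for (k in c("2", "3")) {
    M <- cc$consensus_matrices[[k]]
    for (i in 1:8) {
      pair <- M[i, i + 8]
      # ignore never-co-drawn pairs (consensus 0 by convention)
      if (pair > 0) expect_equal(pair, 1)
    }
  }
})

test_that("single-resample consensus entries are 0/1 and PAC is 0 for crisp structure", {
  withr::with_seed(15, {
    X <- rbind(matrix(rnorm(60, 0, 0.05), ncol = 3),
               matrix(rnorm(60, 8, 0.05), ncol = 3))
  })
  cc1 <- suppressMessages(consensus_cluster(X, k_range = 2, n_resample = 1, seed = 1))
  expect_true(all(cc1$consensus_matrices[["2"]] %in% c(0, 1)))

  cc <- consensus_cluster(X, k_range = 2:4, n_resample = 100, seed = 2)
  # planted 2-block structure: consensus at k=2 is a block matrix of ones
  M <- cc$consensus_matrices[["2"]]
  expect_true(all(M[1:20, 1:20] == 1))
  expect_true(all(M[21:40, 21:40] == 1))
  expect_true(all(M[1:20, 21:40] == 0))
  expect_equal(unname(cc$pac[["2"]]), 0)
  expect_equal(cc$chosen_k, 2L)
  expect_error(consensus_cluster(X[1:5, ], k_range = 2:6, n_resample = 5), "config error")
})

test_that("k selection follows PAC argmin with smaller-k ties and delta-area rule", {
  fake <- structure(list(k_range = c(2L, 3L, 4L),
                         pac = c(`2` = 0.4, `3` = 0.05, `4` = 0.2)),
                    class = "consensus_result")
  expect_equal(select_k(fake, "pac"), 3L)
  fake$pac <- c(`2` = 0.2, `3` = 0.2, `4` = 0.4)
  expect_equal(select_k(fake, "pac"), 2L)

  # delta-area: flat CDF gain after k=3 selects 3
  fake2 <- structure(list(
    k_range = c(2L, 3L, 4L),
    cdf = list(`2` = stats::ecdf(c(rep(0, 50), rep(1, 50))),
               `3` = stats::ecdf(c(rep(0, 30), rep(1, 70))),
               `4` = stats::ecdf(c(rep(0, 29), rep(1, 71))))),
    class = "consensus_result")
  expect_equal(select_k(fake2, "delta_area"), 3L)
  expect_error(select_k(structure(list(k_range = 2L), class = "consensus_result")),
               "at least 2")
})

test_that("planted 4-group expression signatures select k = 4", {
  # four equidistant expression programs (3 private features each), so
  # under-clustering is ambiguous and only k = 4 is stable
  centers <- kronecker(diag(4), matrix(1, 1, 3)) * 4
  withr::with_seed(77,
    X <- centers[rep(1:4, each = 20), ] + matrix(rnorm(80 * 12, 0, 1), 80))
  cc <- consensus_cluster(X, k_range = 2:6, n_resample = 100, seed = 5)
  expect_equal(cc$chosen_k, 4L)
  expect_gt(rand_ari(cc$labels[["4"]], rep(1:4, each = 20)), 0.95)
})

test_that("cluster recovery is invariant to sample order", {
  co <- simulate_cohort(small_config(seed = 18))
  X <- co$true_fractions
  perm <- withr::with_seed(1, sample(nrow(X)))
  cc1 <- consensus_cluster(X, k_range = 2:4, n_resample = 80, seed = 9)
  cc2 <- consensus_cluster(X[perm, ], k_range = 2:4, n_resample = 80, seed = 9)
  expect_equal(cc1$chosen_k, cc2$chosen_k)
  k <- as.character(cc1$chosen_k)
  expect_gt(rand_ari(cc1$labels[[k]][perm], cc2$labels[[k]]), 0.9)
})
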