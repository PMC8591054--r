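sig <- synthetic_signature_matrix()

test_that("noiseless mixtures are recovered exactly by NNLS", {
  mix <- 0.5 * sig[, "T cells CD8"] + 0.5 * sig[, "Macrophages M0"]
  expr <- log2(cbind(s1 = mix, s2 = sig[, "NK cells activated"]))
  fr <- deconvolve(expr, sig, method = "nnls")
  expect_equal(ncol(fr$fractions), 22L)
  expect_lt(abs(fr$fractions["s1", "T cells CD8"] - 0.5), 1e-6)
  expect_lt(abs(fr$fractions["s1", "Macrophages M0"] - 0.5), 1e-6)
  expect_lt(max(fr$fractions["s1", !colnames(fr$fractions) %in%
                               c("T cells CD8", "Macrophages M0")]), 1e-6)
  # single basis column: fraction 1 on that type
  expect_lt(abs(fr$fractions["s2", "NK cells activated"] - 1), 1e-6)
})

test_that("NNLS fractions are invariant to sample-wise positive rescaling", {
  withr::with_seed(21, {
    f_true <- rdirichlet_one(rep(1, 22))
    mix <- stats::setNames(as.vector(sig %*% f_true), rownames(sig))
  })
  expr <- log2(cbind(a = mix, b = 3.7 * mix))
  fr <- deconvolve(expr, sig, method = "nnls")
  expect_equal(fr$fractions["a", ], fr$fractions["b", ], tolerance = 1e-8)
  expect_equal(unname(fr$fractions["a", ]), f_true, tolerance = 1e-6)
})

test_that("noisy mixtures are recovered with MAE below 0.05", {
  n <- 100
  withr::with_seed(33, {
    truth <- t(vapply(seq_len(n), function(i) rdirichlet_one(rep(0.8, 22)),
                      numeric(22)))
    lin <- sig %*% t(truth)
    expr <- log2(lin) + matrix(rnorm(length(lin), 0, 0.1), nrow(lin))
  })
  colnames(expr) <- paste0("m", seq_len(n))
  fr <- deconvolve(expr, sig, method = "nnls")
  expect_lt(mean(abs(fr$fractions - truth)), 0.05)
})

test_that("nu-SVR mode recovers the dominant cell types", {
  mix <- 0.7 * sig[, "T cells CD8"] + 0.3 * sig[, "Monocytes"]
  expr <- log2(cbind(s1 = mix, s2 = mix))
  fr <- deconvolve(expr, sig, method = "nusvr", seed = 4)
  expect_lt(abs(fr$fractions["s1", "T cells CD8"] - 0.7), 0.1)
  expect_lt(abs(fr$fractions["s1", "Monocytes"] - 0.3), 0.1)
})

test_that("permutation p-values are present, bounded, and small for real mixtures", {
  mix <- 0.5 * sig[, 1] + 0.5 * sig[, 2]
  expr <- log2(cbind(s1 = mix, s2 = mix))
  fr <- deconvolve(expr, sig, method = "nnls", n_perm = 19, seed = 2)
  p <- fr$diagnostics$permutation_p
  expect_true(all(!is.na(p)))
  expect_true(all(p >= 1 / 20 & p <= 1))
  expect_equal(p, c(1 / 20, 1 / 20))
  expect_error(deconvolve(expr, sig, n_perm = -1), "n_perm")
})

test_that("insufficient marker coverage raises a coverage error", {
  expr <- log2(cbind(a = sig[1:30, 1], b = sig[1:30, 2]))
  expect_error(deconvolve(expr, sig), "coverage")
})

test_that("ssGSEA matches a hand-enumerated toy case and behaves monotonically", {
  # 3-gene universe, 1-gene set, sample with expression g1=5 > g2=3 > g3=1
  expr <- matrix(c(5, 3, 1), ncol = 1, dimnames = list(c("g1", "g2", "g3"), "s"))
  # ranks (3,2,1); descending order g1,g2,g3; set = {g2}
  # position 1: P_in=0,    P_out=1/2 -> -1/2
  # position 2: P_in=1,    P_out=1/2 -> +1/2
  # position 3: P_in=1,    P_out=1   -> 0
  expect_equal(unname(ssgsea_score(expr, c("g2", "ghost"), alpha = 0.25)), 0,
               tolerance = 1e-12)
  # set = {g1}: positions give (1 - 0) + (1 - 1/2) + (1 - 1) = 1.5
  expr2 <- cbind(expr, s2 = c(5, 3, 1))
  expect_equal(unname(ssgsea_score(expr2, c("g1", "ghost"))), c(1.5, 1.5),
               tolerance = 1e-12)

  # uniform +5 shift of set genes raises the score
  co <- simulate_cohort(small_config(seed = 12))
  set <- co$genes_A[1:10]
  expr_up <- co$expression[, 1:2]
  expr_up[set, 1] <- expr_up[set, 1] + 5
  sc <- ssgsea_score(expr_up, set)
  expect_gt(sc[1], sc[2])

  expect_error(ssgsea_score(expr, c("g1", "g2", "g3")), "universe")
  expect_error(ssgsea_score(expr, "absent_gene"), "no gene")
})

test_that("immune/stromal scores respond to targeted upregulation", {
  co <- simulate_cohort(small_config(seed = 13))
  imm <- co$genes_A[1:15]; str <- co$genes_B[1:15]
  expr <- co$expression
  sub <- 1:30
  expr[imm, sub] <- expr[imm, sub] + 3
  sc <- estimate_scores(expr, imm, str)
  expect_gt(mean(sc$immune_score[sub]), mean(sc$immune_score[-sub]))
  # identical expression across samples gives identical scores
  same <- expr[, c(1, 1, 1)]
  colnames(same) <- c("a", "b", "c")
  sc2 <- estimate_scores(same, imm, str)
  expect_equal(sc2$immune_score, rep(sc2$immune_score[1], 3))
  expect_equal(sc2$stromal_score, rep(sc2$stromal_score[1], 3))
})
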