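test_that("moderated t reduces to the ordinary t-test in the d0 -> 0 limit", {
  withr::with_seed(51, {
    X <- matrix(rnorm(50 * 12), nrow = 50,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  })
  grp <- rep(c("low", "high"), each = 6)
  de <- differential_expression(X, factor(grp, levels = c("low", "high")),
                                d0 = 0, s0_sq = 1)
  ref_t <- apply(X, 1, function(x)
    stats::t.test(x[grp == "high"], x[grp == "low"], var.equal = TRUE)$statistic)
  expect_equal(de$statistic, unname(ref_t), tolerance = 1e-10)
})

test_that("moderated t agrees with limma given the same variance prior", {
  skip_if_not_installed("limma")
  withr::with_seed(52, {
    X <- matrix(rnorm(200 * 16, sd = rep(runif(200, 0.5, 2), 16)), nrow = 200,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:16)))
  })
  grp <- factor(rep(c("low", "high"), each = 8), levels = c("low", "high"))
  design <- stats::model.matrix(~grp)
  fit <- limma::eBayes(limma::lmFit(X, design))
  de <- differential_expression(X, grp, d0 = fit$df.prior, s0_sq = fit$s2.prior)
  expect_equal(de$statistic, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(de$log2_fold_change, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  # the method-of-moments prior is in the same regime as limma's fit
  own <- attr(differential_expression(X, grp), "prior")
  expect_gt(own["d0"], 1)
})

test_that("null data yield no calls; planted signal is found with controlled FDR", {
  withr::with_seed(53, {
    X <- matrix(rnorm(300 * 20, mean = 5), nrow = 300,
                dimnames = list(paste0("g", 1:300), paste0("s", 1:20)))
  })
  grp <- factor(rep(c("low", "high"), each = 10), levels = c("low", "high"))
  # identical group means per gene: duplicate the low block
  X_dup <- cbind(X[, 1:10], X[, 1:10])
  colnames(X_dup) <- paste0("s", 1:20)
  de0 <- differential_expression(X_dup, grp)
  expect_true(all(de0$log2_fold_change == 0))
  expect_true(all(de0$direction == "ns"))

  withr::with_seed(54, {
    n <- 100
    Xb <- matrix(rnorm(1000 * 2 * n, mean = 5, sd = 0.7), nrow = 1000,
                 dimnames = list(paste0("g", 1:1000), paste0("s", 1:(2 * n))))
    grp2 <- factor(rep(c("low", "high"), each = n), levels = c("low", "high"))
    planted <- paste0("g", 1:200)
    Xb[planted, grp2 == "high"] <- Xb[planted, grp2 == "high"] + 1.5
  })
  de <- differential_expression(Xb, grp2)
  called <- de$gene[de$direction == "up_in_high"]
  expect_gt(mean(planted %in% called), 0.9)                      # sensitivity
  expect_lt(mean(!called %in% planted), 0.1)                     # empirical FDR
})

test_that("zero-variance genes get p = 1 with a log message", {
  X <- rbind(flat = rep(2, 8), g2 = c(1:4, 6:9) / 2)
  colnames(X) <- paste0("s", 1:8)
  grp <- factor(rep(c("low", "high"), each = 4), levels = c("low", "high"))
  expect_message(de <- differential_expression(X, grp), "zero-variance")
  expect_equal(de$p_value[de$gene == "flat"], 1)
  expect_error(differential_expression(X, rep("a", 8)), "binary")
})

test_that("gene types split by association with the reference cluster", {
  withr::with_seed(55, {
    lab <- rep(c(1, 2), each = 15)
    up1 <- matrix(rnorm(10 * 30, mean = rep(ifelse(lab == 1, 8, 4), each = 10)), 10)
    up2 <- matrix(rnorm(10 * 30, mean = rep(ifelse(lab == 2, 8, 4), each = 10)), 10)
  })
  expr <- rbind(up1, up2)
  rownames(expr) <- paste0("g", 1:20)
  gt <- assign_gene_types(expr, lab, reference_cluster = 1)
  expect_true(all(gt$type[1:10] == "A"))
  expect_true(all(gt$type[11:20] == "B"))
  expect_true(all(gt$association[1:10] > 0.8))
  expect_true(all(gt$best_cluster[11:20] == "2"))

  # perfectly bimodal gene, high in cluster 1 only -> association ~ 1
  g <- matrix(ifelse(lab == 1, 10, 0), nrow = 1, dimnames = list("bimodal", NULL))
  gt1 <- assign_gene_types(rbind(g, g + 1), lab, reference_cluster = 1)
  expect_equal(gt1$association[1], 1, tolerance = 1e-12)
  expect_error(assign_gene_types(expr, rep(1, 30)), "single cluster")
})

test_that("Boruta confirms an informative feature and rejects noise", {
  withr::with_seed(56, {
    n <- 200
    target <- factor(rep(c("low", "high"), each = n / 2))
    X <- matrix(rnorm(n * 31), nrow = n,
                dimnames = list(NULL, c("signal", paste0("noise", 1:29), "flat")))
    X[, "signal"] <- as.numeric(target) + rnorm(n, 0, 0.1)
    X[, "flat"] <- 0
  })
  sel <- boruta_select(X, target, max_iter = 30, seed = 7)
  expect_true("signal" %in% sel)
  expect_false("flat" %in% sel)
  # noise features confirmed at most at chance level (with slack)
  expect_lte(sum(grepl("noise", sel)), 3)
  expect_error(boruta_select(X, target, max_iter = 5), "config error")
  expect_error(boruta_select(X[, 1:3], target), "5 features")
})

test_that("pure-noise Boruta confirms almost nothing", {
  withr::with_seed(57, {
    n <- 120
    X <- matrix(rnorm(n * 25), nrow = n, dimnames = list(NULL, paste0("n", 1:25)))
    target <- factor(rep(c("a", "b"), each = n / 2))
  })
  sel <- boruta_select(X, target, max_iter = 25, seed = 8)
  expect_lte(length(sel), ceiling(0.05 * 25) + 1)
})

test_that("PC1 fitting matches a dense eigendecomposition oracle", {
  withr::with_seed(58, {
    X <- matrix(rnorm(5 * 40, mean = 4), nrow = 5,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:40)))
    Y <- matrix(rnorm(5 * 40), nrow = 5,
                dimnames = list(paste0("h", 1:5), paste0("s", 1:40)))
  })
  m <- fit_ici_model(rbind(X, Y), paste0("g", 1:5), paste0("h", 1:5))
  # oracle: leading eigenvector of the gene-gene covariance across samples
  C <- stats::cov(t(X))
  ev <- eigen(C, symmetric = TRUE)$vectors[, 1]
  load_A <- m$A$loading
  expect_equal(abs(sum(load_A * ev)), 1, tolerance = 1e-8)  # same axis up to sign
  expect_equal(sqrt(sum(load_A^2)), 1, tolerance = 1e-12)   # unit norm
})

test_that("identical A and B sets give an identically zero ICI score", {
  co <- simulate_cohort(small_config(seed = 59))
  g <- co$genes_A[1:10]
  m <- fit_ici_model(co$expression, g, g)
  expect_true(all(abs(m$training$ici_score) < 1e-10))
})

test_that("two perfectly correlated genes give a rank-1 PC1 equal to their scaled mean", {
  x <- seq(1, 5, length.out = 20)
  expr <- rbind(g1 = x, g2 = 2 * x, g3 = rnorm(20), g4 = rnorm(20))
  colnames(expr) <- paste0("s", 1:20)
  m <- fit_ici_model(expr, c("g1", "g2"), c("g3", "g4"))
  expect_equal(m$A$var_explained, 1, tolerance = 1e-10)
  expect_equal(cor(m$training$score_A, x), 1, tolerance = 1e-10)
})

test_that("scoring is exact on the training cohort and linear in constant shifts", {
  co <- simulate_cohort(small_config(seed = 60))
  m <- fit_ici_model(co$expression, co$genes_A, co$genes_B)
  sc <- score_samples(m, co$expression)
  expect_equal(sc$ici_score, m$training$ici_score, tolerance = 1e-12)

  expr2 <- co$expression
  expr2[m$genes_A, 3] <- expr2[m$genes_A, 3] + 2.5
  sc2 <- score_samples(m, expr2)
  expect_equal(sc2$score_A[3] - sc$score_A[3], 2.5 * sum(m$A$loading),
               tolerance = 1e-10)
  expect_equal(sc2$score_B, sc$score_B, tolerance = 1e-12)
})

test_that("the ICI score is invariant to gene and sample order and refitting is reproducible", {
  co <- simulate_cohort(small_config(seed = 61))
  m1 <- fit_ici_model(co$expression, co$genes_A, co$genes_B)
  perm_g <- withr::with_seed(2, sample(nrow(co$expression)))
  perm_s <- withr::with_seed(3, sample(ncol(co$expression)))
  m2 <- fit_ici_model(co$expression[perm_g, perm_s],
                      withr::with_seed(4, sample(co$genes_A)), co$genes_B)
  sc1 <- score_samples(m1, co$expression)
  sc2 <- score_samples(m2, co$expression)
  expect_equal(sc1$ici_score, sc2$ici_score, tolerance = 1e-8)
  m3 <- fit_ici_model(co$expression, co$genes_A, co$genes_B)
  expect_identical(m1$A$loading, m3$A$loading)
})

test_that("gene coverage at scoring time is enforced at 80% with mean imputation above it", {
  co <- simulate_cohort(small_config(seed = 62))
  m <- fit_ici_model(co$expression, co$genes_A, co$genes_B)
  dropA <- co$genes_A[1:3]  # 10% of 30 genes
  expr_miss <- co$expression[!rownames(co$expression) %in% dropA, ]
  expect_warning(sc <- score_samples(m, expr_miss), "imputed")
  expect_true(all(is.finite(sc$ici_score)))
  expr_gone <- co$expression[!rownames(co$expression) %in% co$genes_A[1:10], ]
  expect_error(score_samples(m, expr_gone), "cover")
  expect_error(fit_ici_model(co$expression, c("nope1", "nope2"), co$genes_B), "nope1")
})

test_that("model JSON round-trips and reproduces the scores", {
  co <- simulate_cohort(small_config(seed = 63))
  m <- fit_ici_model(co$expression, co$genes_A[1:10], co$genes_B[1:10])
  f <- withr::local_tempfile(fileext = ".json")
  write_ici_model(m, f)
  m2 <- read_ici_model(f)
  expect_equal(score_samples(m2, co$expression)$ici_score,
               m$training$ici_score, tolerance = 1e-10)
})

test_that("panel contrasts detect a planted checkpoint shift and report skipped genes", {
  co <- simulate_cohort(small_config(seed = 64))
  grp <- factor(ifelse(co$true_latent_score > stats::median(co$true_latent_score),
                       "high", "low"), levels = c("low", "high"))
  expr <- co$expression
  expr["CD274", grp == "high"] <- expr["CD274", grp == "high"] + 2
  pt <- compare_gene_panels(expr, grp)
  row <- pt[pt$gene == "CD274", ]
  expect_lt(row$adjusted_p, 0.01)
  expect_equal(row$direction, "up_in_high")
  # absent panel gene lands in the skipped report
  expr2 <- expr[rownames(expr) != "TNF", ]
  pt2 <- compare_gene_panels(expr2, grp)
  expect_true("TNF" %in% attr(pt2, "skipped"))
})
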