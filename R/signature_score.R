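#' Differential expression with an empirical-Bayes moderated t-statistic
#'
#' Per gene, an ordinary two-sample t-statistic whose pooled variance
#' \eqn{s^2_g} is shrunk toward a prior: \eqn{\tilde{s}^2_g = (d_0 s_0^2 +
#' d_g s_g^2) / (d_0 + d_g)}, with the prior \eqn{(d_0, s_0^2)} fitted by
#' method of moments on the observed distribution of \eqn{s^2_g} under the
#' scaled-F model. Two-sided p-values use a t distribution on
#' \eqn{d_0 + d_g} degrees of freedom, followed by Benjamini-Hochberg
#' adjustment. A gene passes when `adjusted_p < p_cutoff` and
#' `|log2FC| > lfc_cutoff`.
#'
#' The log2 fold change is the second group level minus the first, so with
#' `group` leveled `c("low", "high")` positive values are up in the high
#' group.
#'
#' @param expr Expression matrix (genes x samples), log2 scale.
#' @param group Binary labels, one per sample; both groups need >= 2
#'   samples.
#' @param method `"moderated_t"` (default) or `"wilcoxon"` fallback.
#' @param p_cutoff Adjusted-p threshold (default 0.05).
#' @param lfc_cutoff Absolute log2-fold-change threshold (default 1).
#' @param d0,s0_sq Optional fixed prior hyperparameters (both `NULL`: fit
#'   by method of moments; `d0 = 0` recovers the ordinary t-test).
#' @return Data.frame per gene: `gene`, `log2_fold_change`, `statistic`,
#'   `p_value`, `adjusted_p`, `direction` in
#'   `{up_in_high, up_in_low, ns}`. Attribute `prior` carries the fitted
#'   `(d0, s0_sq)`.
#' @export
differential_expression <- function(expr, group,
                                    method = c("moderated_t", "wilcoxon"),
                                    p_cutoff = 0.05, lfc_cutoff = 1,
                                    d0 = NULL, s0_sq = NULL) {
  method <- match.arg(method)
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must be binary")
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  if (min(n1, n2) < 2) stop("both groups need >= 2 samples")
  X1 <- expr[, g == levels(g)[1], drop = FALSE]
  X2 <- expr[, g == levels(g)[2], drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  lfc <- m2 - m1

  if (method == "wilcoxon") {
    p <- vapply(seq_len(nrow(expr)), function(i)
      suppressWarnings(stats::wilcox.test(X2[i, ], X1[i, ])$p.value), numeric(1))
    stat <- rep(NA_real_, nrow(expr))
    prior <- c(d0 = NA_real_, s0_sq = NA_real_)
  } else {
    v1 <- apply(X1, 1, stats::var); v2 <- apply(X2, 1, stats::var)
    dg <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
    if (is.null(d0) || is.null(s0_sq)) {
      mom <- fit_variance_prior(s2, dg)
      if (is.null(d0)) d0 <- mom["d0"]
      if (is.null(s0_sq)) s0_sq <- mom["s0_sq"]
    }
    s_tilde2 <- if (is.finite(d0)) (d0 * s0_sq + dg * s2) / (d0 + dg) else rep(s0_sq, length(s2))
    df_mod <- min(d0 + dg, 1e6)
    se <- sqrt(s_tilde2 * (1 / n1 + 1 / n2))
    stat <- ifelse(se > 0, lfc / se, 0)
    p <- 2 * stats::pt(abs(stat), df = df_mod, lower.tail = FALSE)
    zero_var <- s2 == 0
    if (any(zero_var)) {
      message(sum(zero_var), " zero-variance gene(s); p set to 1")
      p[zero_var] <- 1
      stat[zero_var] <- 0
    }
    prior <- c(d0 = unname(d0), s0_sq = unname(s0_sq))
  }
  adj <- bh_adjust(p)
  sig <- adj < p_cutoff & abs(lfc) > lfc_cutoff
  direction <- ifelse(!sig, "ns", ifelse(lfc > 0, "up_in_high", "up_in_low"))
  structure(data.frame(gene = rownames(expr), log2_fold_change = lfc,
                       statistic = stat, p_value = p, adjusted_p = adj,
                       direction = direction, row.names = NULL,
                       stringsAsFactors = FALSE),
            prior = prior)
}

# method-of-moments fit of the scaled-F prior for gene-level variances:
# s2 ~ s0^2 * F(dg, d0); matches the first two moments of s2
fit_variance_prior <- function(s2, dg) {
  m <- mean(s2)
  v <- stats::var(s2)
  if (m <= 0 || !is.finite(v) || v <= 0)
    return(c(d0 = Inf, s0_sq = max(m, .Machine$double.eps)))
  r <- v / m^2
  denom <- r * dg - 2
  if (denom <= 0) return(c(d0 = Inf, s0_sq = m))
  d0 <- (4 * r * dg + 2 * dg - 4) / denom
  if (d0 <= 4) d0 <- max(d0, 4.01)  # keep the prior variance finite
  c(d0 = d0, s0_sq = m * (d0 - 2) / d0)
}

#' Assign differentially expressed genes to signature types A and B
#'
#' Each gene's association statistic is its point-biserial correlation with
#' the indicator of the reference sample cluster (one-vs-rest). Genes with
#' positive association form type A (positively related to the
#' classification), the remainder type B. Per-gene best-matching clusters
#' (maximal one-vs-rest correlation) are reported for diagnostics.
#'
#' @param expr Expression of the DEG set (genes x samples).
#' @param sample_clusters Per-sample cluster labels from consensus
#'   clustering of the DEG expression (>= 2 clusters).
#' @param reference_cluster Cluster whose indicator defines the
#'   association sign; default the first factor level. The pipeline passes
#'   the highest-mean-IPS cluster (the immunogenicity-high subtype).
#' @return Data.frame per gene: `gene`, `association`, `best_cluster`,
#'   `type` in `{A, B}`.
#' @export
assign_gene_types <- function(expr, sample_clusters, reference_cluster = NULL) {
  cl <- factor(sample_clusters)
  if (nlevels(cl) < 2) stop("association undefined with a single cluster")
  if (is.null(reference_cluster)) reference_cluster <- levels(cl)[1]
  reference_cluster <- as.character(reference_cluster)
  if (!reference_cluster %in% levels(cl))
    stop("reference_cluster '", reference_cluster, "' not among cluster labels")
  ind <- vapply(levels(cl), function(l) as.numeric(cl == l), numeric(length(cl)))
  cors <- suppressWarnings(stats::cor(t(expr), ind))
  cors[is.na(cors)] <- 0
  assoc <- cors[, reference_cluster]
  best <- levels(cl)[max.col(cors, ties.method = "first")]
  data.frame(gene = rownames(expr), association = unname(assoc),
             best_cluster = best,
             type = ifelse(assoc > 0, "A", "B"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Boruta-style all-relevant feature selection
#'
#' At each iteration every feature gets a shuffled "shadow" copy; a random
#' forest (ranger, permutation importance) is fitted on the joint matrix,
#' and a feature scores a hit when its importance exceeds the maximum
#' shadow importance. Across iterations a two-sided binomial test at
#' `alpha` (alpha/2 per tail) confirms features with significantly more
#' than half hits and rejects those with significantly fewer; remaining
#' tentative features are resolved by comparing their final-iteration
#' importance to the median shadow importance. Iteration stops early once
#' every feature is decided.
#'
#' @param features Samples x features numeric matrix (>= 5 features).
#' @param target Per-sample target: factor/character (classification, e.g.
#'   the IPS-derived high/low label) or numeric (regression).
#' @param max_iter Maximum iterations (>= 10; default 100).
#' @param alpha Significance level of the binomial decision (default 0.05).
#' @param seed Seed for shadows and forests.
#' @param num_trees Trees per forest (default 100).
#' @return Character vector of confirmed feature names; attributes `hits`,
#'   `n_iter`, `decision` (per-feature factor).
#' @export
boruta_select <- function(features, target, max_iter = 100L, alpha = 0.05,
                          seed = 1L, num_trees = 100L) {
  if (max_iter < 10) stop("config error: max_iter must be >= 10")
  features <- as.matrix(features)
  if (ncol(features) < 5) stop("need >= 5 features")
  if (is.character(target)) target <- factor(target)
  if (is.factor(target) && nlevels(droplevels(target)) < 2)
    stop("target needs >= 2 levels")
  p <- ncol(features)
  feat_names <- colnames(features)
  if (is.null(feat_names)) feat_names <- paste0("f", seq_len(p))
  colnames(features) <- feat_names

  hits <- stats::setNames(integer(p), feat_names)
  last_imp <- NULL; last_shadow <- NULL
  n_iter <- 0L
  withr::with_seed(seed, {
    for (it in seq_len(max_iter)) {
      shadow <- apply(features, 2, sample)
      colnames(shadow) <- paste0("shadow_", feat_names)
      dat <- data.frame(cbind(features, shadow), check.names = FALSE)
      fit <- ranger::ranger(x = dat, y = target, num.trees = num_trees,
                            importance = "permutation",
                            num.threads = 1,
                            seed = sample.int(.Machine$integer.max, 1))
      imp <- fit$variable.importance
      real <- imp[feat_names]
      sh <- imp[paste0("shadow_", feat_names)]
      hits <- hits + (real > max(sh))
      last_imp <- real; last_shadow <- sh
      n_iter <- it
      if (it >= 10) {
        conf <- stats::pbinom(hits - 1, it, 0.5, lower.tail = FALSE) < alpha / 2
        rej  <- stats::pbinom(hits, it, 0.5) < alpha / 2
        if (all(conf | rej)) break
      }
    }
  })
  conf <- stats::pbinom(hits - 1, n_iter, 0.5, lower.tail = FALSE) < alpha / 2
  rej  <- stats::pbinom(hits, n_iter, 0.5) < alpha / 2
  tent <- !conf & !rej
  if (any(tent)) conf[tent] <- last_imp[tent] > stats::median(last_shadow)
  decision <- factor(ifelse(conf, "confirmed", ifelse(rej, "rejected", "tentative")),
                     levels = c("confirmed", "tentative", "rejected"))
  structure(feat_names[conf], hits = hits, n_iter = n_iter,
            decision = stats::setNames(decision, feat_names))
}

fit_pc1 <- function(expr, genes, label) {
  present <- intersect(genes, rownames(expr))
  if (length(present) < 2)
    stop("gene set ", label, " has fewer than 2 genes in the expression matrix; missing: ",
         paste(utils::head(setdiff(genes, rownames(expr)), 10), collapse = ", "))
  X <- t(expr[present, , drop = FALSE])          # samples x genes
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  loading <- pc$rotation[, 1]
  scores <- as.vector(Xc %*% loading)
  # sign convention: PC1 scores align with the set's mean expression across
  # samples, which removes the eigenvector sign ambiguity
  ref <- rowMeans(X)
  s <- suppressWarnings(stats::cor(scores, ref))
  if (is.na(s)) s <- sign(sum(loading))
  if (s < 0) { loading <- -loading; scores <- -scores }
  list(genes = present, center = center, loading = loading, scores = scores,
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Fit the ICI scoring model from gene sets A and B
#'
#' Per gene set, centers the genes at their training means and extracts the
#' first principal component over samples; the per-sample ICI score is the
#' PC1 projection on set A minus the PC1 projection on set B. Loading signs
#' are fixed by aligning each set's scores with its mean expression, making
#' the fit reproducible. The model stores the centering vectors and unit
#' loadings needed to score external cohorts.
#'
#' @param expr Training expression matrix (genes x samples), >= 3 samples.
#' @param genes_A,genes_B Gene symbol vectors (>= 2 present each; disjoint).
#' @param scale_genes Also divide genes by their training sd before PCA
#'   (default FALSE: centering only).
#' @return List of class `"ici_model"`: `genes_A`, `genes_B`, per-set
#'   `center`/`loading`/`var_explained`, `score_mean`/`score_sd` of the
#'   training ICI score, and `training` (per-sample score table).
#' @export
fit_ici_model <- function(expr, genes_A, genes_B, scale_genes = FALSE) {
  if (ncol(expr) < 3) stop("need >= 3 samples to fit the model")
  if (scale_genes) {
    sds <- apply(expr, 1, stats::sd)
    expr <- sweep(expr[sds > 0, , drop = FALSE], 1, sds[sds > 0], "/")
  }
  A <- fit_pc1(expr, genes_A, "A")
  B <- fit_pc1(expr, genes_B, "B")
  ici <- A$scores - B$scores
  model <- structure(list(
    genes_A = A$genes, genes_B = B$genes,
    A = list(center = A$center, loading = A$loading, var_explained = A$var_explained),
    B = list(center = B$center, loading = B$loading, var_explained = B$var_explained),
    score_mean = mean(ici), score_sd = stats::sd(ici),
    scale_genes = scale_genes,
    training = data.frame(sample_id = colnames(expr),
                          score_A = A$scores, score_B = B$scores,
                          ici_score = ici, row.names = NULL,
                          stringsAsFactors = FALSE)),
    class = "ici_model")
  model
}

project_set <- function(expr, genes, center, loading, label, min_coverage = 0.8) {
  present <- intersect(genes, rownames(expr))
  coverage <- length(present) / length(genes)
  if (length(present) == 0) stop("no gene of set ", label, " present in the cohort")
  if (coverage < min_coverage)
    stop(sprintf("cohort covers only %.0f%% of gene set %s (need >= %.0f%%)",
                 100 * coverage, label, 100 * min_coverage))
  if (coverage < 1)
    warning(sprintf("%d gene(s) of set %s missing; imputed at training mean",
                    length(genes) - length(present), label))
  Xc <- sweep(t(expr[present, , drop = FALSE]), 2, center[present])
  as.vector(Xc %*% loading[present])  # missing genes contribute 0 (training mean)
}

#' Score samples with a fitted ICI model
#'
#' `score_A` and `score_B` are projections of the centered sample vectors
#' on the stored PC1 loadings; `ici_score = score_A - score_B`. Each gene
#' set must be covered at >= 80% by the cohort (missing genes are imputed
#' at their training mean with a warning). Scoring the training cohort
#' reproduces the training scores exactly.
#'
#' @param model An `"ici_model"` from [fit_ici_model()].
#' @param expr Cohort expression matrix (genes x samples), log2 scale.
#' @param min_coverage Required fraction of each gene list (default 0.8).
#' @return Data.frame: `sample_id`, `score_A`, `score_B`, `ici_score`.
#' @export
score_samples <- function(model, expr, min_coverage = 0.8) {
  stopifnot(inherits(model, "ici_model"))
  sA <- project_set(expr, model$genes_A, model$A$center, model$A$loading, "A", min_coverage)
  sB <- project_set(expr, model$genes_B, model$B$center, model$B$loading, "B", min_coverage)
  data.frame(sample_id = colnames(expr), score_A = sA, score_B = sB,
             ici_score = sA - sB, row.names = NULL, stringsAsFactors = FALSE)
}

#' Contrast a gene panel between score groups
#'
#' Per panel gene, a Wilcoxon rank-sum test between the high and low score
#' groups with BH adjustment and reported direction. Default panel: the six
#' immune checkpoint genes plus nine immune activation-related genes of
#' [ici_gene_panels()]. Panel genes absent from the expression matrix are
#' listed in the `skipped` attribute.
#'
#' @param expr Expression matrix (genes x samples).
#' @param group Factor with levels `c("low", "high")` (or any binary
#'   labels; second level is treated as "high").
#' @param panel Character vector of gene symbols.
#' @return Data.frame per tested gene: `gene`, `log2_fold_change`
#'   (high - low means), `statistic`, `p_value`, `adjusted_p`, `direction`;
#'   attribute `skipped`.
#' @export
compare_gene_panels <- function(expr, group,
                                panel = unlist(ici_gene_panels(), use.names = FALSE)) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must be binary")
  present <- intersect(panel, rownames(expr))
  skipped <- setdiff(panel, present)
  if (!length(present)) stop("no panel gene present in the expression matrix")
  hi <- g == levels(g)[2]
  res <- lapply(present, function(gn) {
    x_hi <- expr[gn, hi]; x_lo <- expr[gn, !hi]
    wt <- suppressWarnings(stats::wilcox.test(x_hi, x_lo))
    data.frame(gene = gn, log2_fold_change = mean(x_hi) - mean(x_lo),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- bh_adjust(out$p_value)
  out$direction <- ifelse(out$log2_fold_change > 0, "up_in_high", "up_in_low")
  structure(out, skipped = skipped)
}

#' Serialize an ICI model to JSON
#' @param model An `"ici_model"`.
#' @param path Output path.
#' @export
write_ici_model <- function(model, path) {
  obj <- list(genes_A = model$genes_A, genes_B = model$genes_B,
              A = list(center = as.list(model$A$center),
                       loading = as.list(model$A$loading),
                       var_explained = model$A$var_explained),
              B = list(center = as.list(model$B$center),
                       loading = as.list(model$B$loading),
                       var_explained = model$B$var_explained),
              score_mean = model$score_mean, score_sd = model$score_sd,
              scale_genes = model$scale_genes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an ICI model from JSON
#' @param path Path written by [write_ici_model()].
#' @return An `"ici_model"` (without the training score table).
#' @export
read_ici_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(genes_A = obj$genes_A, genes_B = obj$genes_B,
                 A = list(center = unlist(obj$A$center),
                          loading = unlist(obj$A$loading),
                          var_explained = obj$A$var_explained),
                 B = list(center = unlist(obj$B$center),
                          loading = unlist(obj$B$loading),
                          var_explained = obj$B$var_explained),
                 score_mean = obj$score_mean, score_sd = obj$score_sd,
                 scale_genes = obj$scale_genes, training = NULL),
            class = "ici_model")
}
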