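lm22_cell_types <- c(
  "B cells naive", "B cells memory", "Plasma cells", "T cells CD8",
  "T cells CD4 naive", "T cells CD4 memory resting", "T cells CD4 memory activated",
  "T cells follicular helper", "T cells regulatory (Tregs)", "T cells gamma delta",
  "NK cells resting", "NK cells activated", "Monocytes", "Macrophages M0",
  "Macrophages M1", "Macrophages M2", "Dendritic cells resting",
  "Dendritic cells activated", "Mast cells resting", "Mast cells activated",
  "Eosinophils", "Neutrophils")

#' Built-in synthetic 22-type immune signature matrix
#'
#' A deterministic LM22-style basis matrix for tests and simulations: each
#' of the 22 immune cell types carries `n_markers_per_type` private
#' high-expression marker genes over a low shared background, on a non-log
#' linear scale. It is synthetic — it shares LM22's shape and cell-type
#' names, not its content; supply the real LM22 as TSV for real cohorts.
#'
#' @param n_markers_per_type Markers per cell type (default 5).
#' @param seed Seed for the deterministic construction.
#' @return Numeric matrix (markers x 22 cell types).
#' @export
synthetic_signature_matrix <- function(n_markers_per_type = 5L, seed = 220L) {
  k <- length(lm22_cell_types)
  n <- n_markers_per_type * k
  withr::with_seed(seed, {
    mat <- matrix(stats::runif(n * k, 5, 40), nrow = n, ncol = k)
    for (j in seq_len(k)) {
      rows <- ((j - 1L) * n_markers_per_type + 1L):(j * n_markers_per_type)
      mat[rows, j] <- stats::runif(n_markers_per_type, 400, 1000)
    }
  })
  rownames(mat) <- sprintf("MK_%02d_%d",
                           rep(seq_len(k), each = n_markers_per_type),
                           rep(seq_len(n_markers_per_type), k))
  colnames(mat) <- lm22_cell_types
  mat
}

#' Immune checkpoint and immune activation gene panels
#'
#' The two default panels contrasted between ICI score groups: six immune
#' checkpoint genes and nine immune activation-related genes.
#'
#' @return Named list with character vectors `checkpoint` and `activation`.
#' @export
ici_gene_panels <- function() {
  list(checkpoint = c("CD274", "CTLA4", "HAVCR2", "IDO1", "LAG3", "PDCD1"),
       activation = c("CD8A", "CXCL10", "CXCL9", "GZMA", "GZMB", "IFNG",
                      "PRF1", "TBX2", "TNF"))
}

# one gamma draw per component, normalised: standard Dirichlet sampler
rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

default_concentrations <- function(n_phenotypes, n_types = 22L) {
  conc <- matrix(0.6, nrow = n_types, ncol = n_phenotypes)
  if (n_phenotypes == 3L && n_types == 22L) {
    # cold (low latent) / intermediate / hot (high latent) blocks
    blocks <- list(c(14, 16, 19, 18, 9),   # M0, M2, mast resting, DC activated, Tregs
                   c(1, 13, 22, 5, 21),    # B naive, monocytes, neutrophils, CD4 naive, eos
                   c(4, 12, 15, 7, 8))     # CD8 T, NK act., M1, CD4 mem act., Tfh
  } else {
    blocks <- split(seq_len(n_types), rep_len(seq_len(n_phenotypes), n_types))
  }
  for (p in seq_len(n_phenotypes)) conc[blocks[[p]], p] <- 6
  conc
}

#' Simulation configuration for synthetic tumor cohorts
#'
#' Bundles and validates every generator parameter. Defaults describe the
#' study conditions emulated throughout the package: a 300-sample cohort
#' with 3 latent immune phenotypes driving cell fractions, signature-gene
#' expression, immunophenoscore, survival hazard, mutation burden and
#' immunotherapy response.
#'
#' @param n_samples Cohort size (default 300).
#' @param n_phenotypes Number of latent immune phenotypes (default 3).
#' @param n_genes Total gene universe size (default 2000); must exceed the
#'   signature markers plus both signal gene panels.
#' @param n_signal_genes_A,n_signal_genes_B Planted signal genes up in
#'   high- resp. low-latent-score samples (defaults 200/200). The A panel's
#'   first genes are the checkpoint/activation symbols of
#'   [ici_gene_panels()].
#' @param fraction_dirichlet_concentration 22 x `n_phenotypes` matrix of
#'   Dirichlet concentration parameters (one column per phenotype); default
#'   a block design separating the phenotypes.
#' @param expression_noise_sd Gaussian noise on log2 expression (default 0.5).
#' @param effect_log2fc Signal-gene effect per unit standardized latent
#'   score, log2 units (default 1).
#' @param hazard_coefficient Log-hazard per unit standardized latent score
#'   (default -0.8: immune-hot samples live longer).
#' @param baseline_median_os Baseline median overall survival in days for a
#'   latent score of 0 (default 2000).
#' @param censoring_rate Target fraction of censored samples (default 0.9).
#' @param tmb_poisson_means Per-phenotype Poisson means of the nonsilent
#'   mutation count (default c(8, 16, 32), ordered cold to hot).
#' @param responder_logit_coefficient Logistic coefficient of response on
#'   the standardized latent score (default 2).
#' @param response_base_rate Responder rate at latent score 0 (default 0.25).
#' @param signature Signature matrix used for marker-gene expression
#'   (default [synthetic_signature_matrix()]).
#' @param seed Integer seed; the single source of randomness.
#' @return List of class `"ici_sim_config"`.
#' @export
sim_config <- function(n_samples = 300L, n_phenotypes = 3L, n_genes = 2000L,
                       n_signal_genes_A = 200L, n_signal_genes_B = 200L,
                       fraction_dirichlet_concentration = NULL,
                       expression_noise_sd = 0.5, effect_log2fc = 1,
                       hazard_coefficient = -0.8, baseline_median_os = 2000,
                       censoring_rate = 0.9,
                       tmb_poisson_means = NULL,
                       responder_logit_coefficient = 2,
                       response_base_rate = 0.25,
                       signature = synthetic_signature_matrix(),
                       seed = 1L) {
  if (n_samples < 1L) stop("n_samples must be positive")
  if (n_phenotypes < 1L || n_genes < 1L || n_signal_genes_A < 1L || n_signal_genes_B < 1L)
    stop("all counts must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1) stop("censoring_rate must be in [0, 1)")
  if (expression_noise_sd < 0) stop("expression_noise_sd must be >= 0")
  n_types <- ncol(signature)
  if (is.null(fraction_dirichlet_concentration))
    fraction_dirichlet_concentration <- default_concentrations(n_phenotypes, n_types)
  conc <- as.matrix(fraction_dirichlet_concentration)
  if (nrow(conc) != n_types)
    stop("concentration matrix must have one row per cell type (", n_types, ")")
  if (n_phenotypes > ncol(conc))
    stop("config error: ", n_phenotypes, " phenotypes but only ", ncol(conc),
         " Dirichlet concentration vectors")
  if (any(conc <= 0)) stop("Dirichlet concentrations must be > 0")
  if (is.null(tmb_poisson_means))
    tmb_poisson_means <- round(8 * 2^(seq_len(n_phenotypes) - 1))
  if (length(tmb_poisson_means) != n_phenotypes)
    stop("tmb_poisson_means must have one entry per phenotype")
  panels <- unlist(ici_gene_panels(), use.names = FALSE)
  if (n_signal_genes_A < length(panels))
    panels <- panels[seq_len(n_signal_genes_A)]
  n_named <- nrow(signature) + n_signal_genes_A + n_signal_genes_B
  if (n_genes < n_named)
    stop("n_genes (", n_genes, ") smaller than markers + signal genes (", n_named, ")")
  structure(list(
    n_samples = as.integer(n_samples), n_phenotypes = as.integer(n_phenotypes),
    n_genes = as.integer(n_genes),
    n_signal_genes_A = as.integer(n_signal_genes_A),
    n_signal_genes_B = as.integer(n_signal_genes_B),
    fraction_dirichlet_concentration = conc,
    expression_noise_sd = expression_noise_sd, effect_log2fc = effect_log2fc,
    hazard_coefficient = hazard_coefficient,
    baseline_median_os = baseline_median_os, censoring_rate = censoring_rate,
    tmb_poisson_means = tmb_poisson_means,
    responder_logit_coefficient = responder_logit_coefficient,
    response_base_rate = response_base_rate,
    signature = signature, panel_genes = panels, seed = as.integer(seed)),
    class = "ici_sim_config")
}

sim_gene_universe <- function(config) {
  nA <- config$n_signal_genes_A
  nB <- config$n_signal_genes_B
  panels <- config$panel_genes
  genes_A <- c(panels, sprintf("GA%04d", seq_len(nA - length(panels))))[seq_len(nA)]
  genes_B <- sprintf("GB%04d", seq_len(nB))
  markers <- rownames(config$signature)
  n_filler <- config$n_genes - length(markers) - nA - nB
  filler <- if (n_filler > 0) sprintf("GN%04d", seq_len(n_filler)) else character(0)
  list(markers = markers, genes_A = genes_A, genes_B = genes_B, filler = filler)
}

# uniform-censoring upper bound u with mean event probability 1 - rate,
# given per-sample exponential hazards
calibrate_censoring <- function(hazard, rate) {
  if (rate <= 0) return(Inf)
  target <- 1 - rate
  f <- function(u) mean(1 - (1 - exp(-hazard * u)) / (hazard * u)) - target
  stats::uniroot(f, lower = 1e-8, upper = 1e12, tol = 1e-10)$root
}

#' Simulate a tumor cohort with known immune ground truth
#'
#' Draws, per sample: a latent phenotype and continuous latent immune score;
#' 22 cell-type fractions from the phenotype's Dirichlet; marker-gene linear
#' expression as signature x fractions, then `log2(1+x)` plus Gaussian
#' noise; signal genes A (B) shifted up in high (low) latent-score samples;
#' an immunophenoscore on a 0-10 scale monotone in the latent score;
#' exponential survival with log-hazard proportional to the standardized
#' latent score and uniform censoring calibrated to the target rate;
#' per-phenotype Poisson mutation counts realised as MAF records; and a
#' 4-level immunotherapy response (CR/PR/SD/PD) with responder probability
#' logistic in the latent score.
#'
#' @param config A [sim_config()] object.
#' @return List of class `"ici_cohort"`: `expression` (genes x samples,
#'   log2), `clinical` (data.frame incl. `ips` and `response`), `maf`,
#'   `true_fractions` (samples x 22, rows sum to 1), `true_phenotype`,
#'   `true_latent_score`, `response`, and the planted `genes_A` / `genes_B`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "ici_sim_config"))
  n <- config$n_samples
  sig <- config$signature
  uni <- sim_gene_universe(config)
  sample_ids <- sprintf("S%04d", seq_len(n))

  withr::with_seed(config$seed, {
    pheno <- sample.int(config$n_phenotypes, n, replace = TRUE)
    mus <- if (config$n_phenotypes == 1L) 0 else
      seq(-1.5, 1.5, length.out = config$n_phenotypes)
    z <- mus[pheno] + stats::rnorm(n, 0, 0.6)
    z_std <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0

    fractions <- t(vapply(pheno, function(p)
      rdirichlet_one(config$fraction_dirichlet_concentration[, p]),
      numeric(ncol(sig))))
    dimnames(fractions) <- list(sample_ids, colnames(sig))

    noise <- function(nr) if (config$expression_noise_sd > 0)
      matrix(stats::rnorm(nr * n, 0, config$expression_noise_sd), nr, n) else 0
    marker_expr <- log2(1 + sig %*% t(fractions)) + noise(nrow(sig))
    base_A <- stats::runif(length(uni$genes_A), 3, 7)
    base_B <- stats::runif(length(uni$genes_B), 3, 7)
    expr_A <- outer(base_A, rep(1, n)) + config$effect_log2fc * outer(rep(1, length(base_A)), z_std) + noise(length(base_A))
    expr_B <- outer(base_B, rep(1, n)) - config$effect_log2fc * outer(rep(1, length(base_B)), z_std) + noise(length(base_B))
    expr_N <- if (length(uni$filler))
      outer(stats::runif(length(uni$filler), 2, 8), rep(1, n)) + noise(length(uni$filler))
    else NULL
    expression <- rbind(marker_expr, expr_A, expr_B, expr_N)
    expression[expression < 0] <- 0
    dimnames(expression) <- list(c(uni$markers, uni$genes_A, uni$genes_B, uni$filler),
                                 sample_ids)

    ips <- pmin(10, pmax(0, 5.5 + 2 * tanh(z_std) + stats::rnorm(n, 0, 0.4)))

    h0 <- log(2) / config$baseline_median_os
    hazard <- h0 * exp(config$hazard_coefficient * z_std)
    t_event <- stats::rexp(n, rate = hazard)
    u <- calibrate_censoring(hazard, config$censoring_rate)
    t_cens <- if (is.finite(u)) stats::runif(n, 0, u) else rep(Inf, n)
    os_time <- round(pmin(t_event, t_cens), 1)
    os_event <- as.integer(t_event <= t_cens)

    p_resp <- stats::plogis(stats::qlogis(config$response_base_rate) +
                              config$responder_logit_coefficient * z_std)
    responder <- stats::rbinom(n, 1, p_resp) == 1
    response <- ifelse(responder,
                       ifelse(stats::runif(n) < 0.3, "CR", "PR"),
                       ifelse(stats::runif(n) < 0.4, "SD", "PD"))

    clinical <- data.frame(
      sample_id = sample_ids,
      os_time = os_time, os_event = os_event,
      age = pmin(90, pmax(18, round(stats::rnorm(n, 47, 15)))),
      gender = sample(c("Female", "Male"), n, TRUE, prob = c(0.727, 0.273)),
      stage = sample(table1_levels$stage, n, TRUE, prob = c(284, 52, 112, 55, 2)),
      t_stage = sample(table1_levels$t_stage, n, TRUE, prob = c(142, 165, 174, 22, 2)),
      n_stage = sample(table1_levels$n_stage, n, TRUE, prob = c(227, 229, 49)),
      m_stage = sample(table1_levels$m_stage, n, TRUE, prob = c(286, 8, 210, 1)),
      rt = sample(table1_levels$rt, n, TRUE, prob = c(310, 177, 18)),
      tmt = sample(table1_levels$tmt, n, TRUE, prob = c(5, 94, 406)),
      ips = ips, response = response,
      stringsAsFactors = FALSE)

    maf <- simulate_maf(sample_ids, pheno, config$tmb_poisson_means)
  })

  structure(list(expression = expression, clinical = clinical, maf = maf,
                 true_fractions = fractions, true_phenotype = pheno,
                 true_latent_score = z_std, response = response,
                 genes_A = uni$genes_A, genes_B = uni$genes_B,
                 config = config),
            class = "ici_cohort")
}

mutation_gene_pool <- function() {
  data.frame(gene = c("BRAF", "NRAS", "HRAS", "TP53", "TERT", sprintf("MUT%02d", 1:35)),
             weight = c(8, 2, 1.5, 1.5, 1, rep(0.5, 35)),
             stringsAsFactors = FALSE)
}

simulate_maf <- function(sample_ids, pheno, tmb_means) {
  pool <- mutation_gene_pool()
  ns_classes <- maf_nonsilent_classes()
  ns_probs <- c(0.70, 0.08, 0.01, 0.05, 0.05, 0.02, 0.02, 0.06, 0.01)
  rows <- lapply(seq_along(sample_ids), function(i) {
    n_ns <- stats::rpois(1, tmb_means[pheno[i]])
    n_sil <- stats::rpois(1, 0.2 * tmb_means[pheno[i]])
    n_tot <- n_ns + n_sil
    if (n_tot == 0) return(NULL)
    data.frame(
      sample_id = sample_ids[i],
      hugo_symbol = sample(pool$gene, n_tot, TRUE, prob = pool$weight),
      variant_classification = c(sample(ns_classes, n_ns, TRUE, prob = ns_probs),
                                 rep("Silent", n_sil)),
      chromosome = as.character(sample.int(22L, n_tot, TRUE)),
      start_position = sample.int(100000000L, n_tot, TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(0), hugo_symbol = character(0),
                      variant_classification = character(0),
                      chromosome = character(0), start_position = integer(0))
  rownames(out) <- NULL
  out
}

#' Simulate an immunotherapy validation cohort for a frozen ICI model
#'
#' Generates an independent cohort (same generative process, new seed via
#' `config`) whose response labels are coupled to the true latent score,
#' after checking that the model's gene lists are contained in the cohort's
#' gene universe.
#'
#' @param config A [sim_config()]; its `responder_logit_coefficient`
#'   controls the response coupling.
#' @param truth_model An `ici_model` (see [fit_ici_model()]).
#' @return An `"ici_cohort"` as from [simulate_cohort()].
#' @export
simulate_validation_cohort <- function(config, truth_model) {
  stopifnot(inherits(config, "ici_sim_config"))
  uni <- sim_gene_universe(config)
  universe <- c(uni$markers, uni$genes_A, uni$genes_B, uni$filler)
  missing <- setdiff(c(truth_model$genes_A, truth_model$genes_B), universe)
  if (length(missing))
    stop("model genes absent from the simulated gene universe: ",
         paste(utils::head(missing, 10), collapse = ", "))
  simulate_cohort(config)
}

#' Write a synthetic cohort's fixture files
#'
#' Writes `expression.tsv`, `clinical.tsv`, `cohort.maf`,
#' `true_fractions.tsv` and `truth.tsv` under `dir` using the package's
#' standard formats.
#'
#' @param cohort An `"ici_cohort"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_maf(cohort$maf, file.path(dir, "cohort.maf"))
  utils::write.table(data.frame(sample_id = rownames(cohort$true_fractions),
                                cohort$true_fractions, check.names = FALSE),
                     file.path(dir, "true_fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = cohort$clinical$sample_id,
                                true_phenotype = cohort$true_phenotype,
                                true_latent_score = cohort$true_latent_score),
                     file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
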