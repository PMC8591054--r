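#' Assemble and validate a pipeline configuration
#'
#' Inputs may be in-memory objects (matrix / data.frame / list) or file
#' paths in the package's standard formats; paths are checked at
#' validation time. All stochastic stages draw from the single `seed`.
#'
#' @param expression Expression matrix or TSV/GCT path.
#' @param clinical Clinical data.frame or TSV path (needs `ips` for the
#'   signature stages).
#' @param maf Optional MAF data.frame or path; mutation stages are skipped
#'   when absent.
#' @param signature Signature matrix or TSV path (default
#'   [synthetic_signature_matrix()]).
#' @param gene_sets Optional named list of gene sets or GMT path (enables
#'   the GSEA stage).
#' @param out_dir Output directory for the per-stage tables and manifest.
#' @param deconv_method,n_perm Deconvolution method and permutations.
#' @param k_range_ici,k_range_deg Candidate k for the two consensus runs.
#' @param consensus_reps,subsample_frac Consensus resampling parameters.
#' @param p_cutoff,lfc_cutoff DEG thresholds (defaults 0.05 / 1).
#' @param minprop Cutpoint minimum group proportion (default 0.1).
#' @param exome_mb,top_n TMB denominator and driver-gene count.
#' @param boruta_max_iter,boruta_alpha Boruta parameters.
#' @param gsea_n_perm GSEA permutations.
#' @param seed Master seed.
#' @return List of class `"ici_pipeline_config"`.
#' @export
pipeline_config <- function(expression, clinical, maf = NULL,
                            signature = synthetic_signature_matrix(),
                            gene_sets = NULL, out_dir = tempfile("ici_run_"),
                            deconv_method = "nnls", n_perm = 20L,
                            k_range_ici = 2:5, k_range_deg = 2:6,
                            consensus_reps = 200L, subsample_frac = 0.8,
                            p_cutoff = 0.05, lfc_cutoff = 1, minprop = 0.1,
                            exome_mb = 38, top_n = 30L,
                            boruta_max_iter = 30L, boruta_alpha = 0.05,
                            gsea_n_perm = 200L, seed = 1L) {
  for (nm in c("expression", "clinical", "maf", "signature", "gene_sets")) {
    v <- get(nm)
    if (is.character(v) && length(v) == 1 && !file.exists(v))
      stop("config error: ", nm, " file not found: ", v)
  }
  structure(list(expression = expression, clinical = clinical, maf = maf,
                 signature = signature, gene_sets = gene_sets,
                 out_dir = out_dir, deconv_method = deconv_method,
                 n_perm = n_perm, k_range_ici = k_range_ici,
                 k_range_deg = k_range_deg, consensus_reps = consensus_reps,
                 subsample_frac = subsample_frac, p_cutoff = p_cutoff,
                 lfc_cutoff = lfc_cutoff, minprop = minprop,
                 exome_mb = exome_mb, top_n = top_n,
                 boruta_max_iter = boruta_max_iter, boruta_alpha = boruta_alpha,
                 gsea_n_perm = gsea_n_perm, seed = as.integer(seed)),
            class = "ici_pipeline_config")
}

load_input <- function(x, loader) if (is.character(x) && length(x) == 1) loader(x) else x

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

safe_logrank <- function(time, event, group) {
  tryCatch(logrank_test(time, event, group),
           error = function(e) list(chisq = NA_real_, df = NA_integer_,
                                    p_value = NA_real_, z = NA_real_,
                                    note = conditionMessage(e)))
}

#' Run the full ICI analysis pipeline
#'
#' Executes, over one cohort: deconvolution; ICI consensus subtyping with
#' subtype survival and fraction contrasts (plus PDCD1/CD274 when
#' present); IPS survival cutpoint; IPS-group differential expression; DEG
#' consensus subtyping; gene-type A/B assignment (reference = the
#' highest-mean-IPS cluster); Boruta reduction of each type; ICI model fit
#' and scoring; score survival cutpoint with KM/log-rank;
#' checkpoint/activation panel tests; preranked GSEA between score groups
#' (when gene sets are supplied); and TMB integration (cutpoint, Wilcoxon,
#' Spearman, TMB-stratified log-rank, driver-frequency contrast, waterfall
#' export) when a MAF is supplied. Every stage writes its tables under
#' `config$out_dir` before the next begins; a manifest records the
#' parameters, seed and per-file hashes.
#'
#' @param config An `"ici_pipeline_config"` (or a YAML file path whose
#'   fields are passed to [pipeline_config()]).
#' @return List of class `"ici_pipeline_result"` with each stage's objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- do.call(pipeline_config, yaml::read_yaml(config))
  stopifnot(inherits(config, "ici_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) outputs[[name]] <<- write_tsv(df, file.path(config$out_dir, name))
  stage <- function(name, fun) {
    message("[", name, "] running")
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  res <- list(config = config)

  expr <- load_input(config$expression, read_expression)
  clinical <- load_input(config$clinical, read_clinical)
  sig <- load_input(config$signature, read_signature_matrix)
  maf <- if (!is.null(config$maf)) load_input(config$maf, read_maf) else NULL
  gene_sets <- if (!is.null(config$gene_sets)) load_input(config$gene_sets, read_gmt) else NULL
  common <- intersect(colnames(expr), clinical$sample_id)
  expr <- expr[, common, drop = FALSE]
  clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  os_time <- clinical$os_time; os_event <- clinical$os_event

  res$fractions <- stage("deconvolution", function() {
    fr <- deconvolve(expr, sig, method = config$deconv_method,
                     n_perm = config$n_perm, seed = config$seed)
    emit(data.frame(sample_id = rownames(fr$fractions), fr$fractions,
                    check.names = FALSE), "cell_fractions.tsv")
    emit(fr$diagnostics, "deconvolution_diagnostics.tsv")
    fr
  })

  res$ici_subtypes <- stage("ici_subtypes", function() {
    cc <- consensus_cluster(res$fractions$fractions, k_range = config$k_range_ici,
                            n_resample = config$consensus_reps,
                            subsample_frac = config$subsample_frac,
                            seed = config$seed)
    lab <- cc$labels[[as.character(cc$chosen_k)]]
    emit(data.frame(sample_id = names(lab), ici_subtype = lab), "ici_subtypes.tsv")
    emit(data.frame(k = cc$k_range, pac = unname(cc$pac)), "ici_subtype_pac.tsv")
    lr <- safe_logrank(os_time, os_event, lab)
    kw <- lapply(colnames(res$fractions$fractions), function(ct)
      data.frame(cell_type = ct,
                 p_value = kruskal_wallis(res$fractions$fractions[, ct], lab)$p_value))
    kw <- do.call(rbind, kw)
    kw$adjusted_p <- bh_adjust(kw$p_value)
    emit(kw, "ici_subtype_fraction_tests.tsv")
    cp <- intersect(c("PDCD1", "CD274"), rownames(expr))
    cp_tests <- if (length(cp)) do.call(rbind, lapply(cp, function(gn)
      data.frame(gene = gn, p_value = kruskal_wallis(expr[gn, ], lab)$p_value))) else NULL
    if (!is.null(cp_tests)) emit(cp_tests, "ici_subtype_checkpoint_tests.tsv")
    list(consensus = cc, labels = lab, logrank = lr,
         fraction_tests = kw, checkpoint_tests = cp_tests)
  })

  if (is.null(clinical$ips) || all(is.na(clinical$ips))) {
    message("no IPS column: signature stages skipped")
    res$manifest <- write_manifest(config, outputs)
    return(structure(res, class = "ici_pipeline_result"))
  }

  res$ips_cut <- stage("ips_cutpoint", function() {
    cp <- optimal_cutpoint(clinical$ips, os_time, os_event, config$minprop)
    emit(data.frame(sample_id = clinical$sample_id, ips = clinical$ips,
                    ips_group = cp$group), "ips_groups.tsv")
    cp
  })
  ips_group <- res$ips_cut$group

  res$deg <- stage("differential_expression", function() {
    de <- differential_expression(expr, ips_group, p_cutoff = config$p_cutoff,
                                  lfc_cutoff = config$lfc_cutoff)
    emit(de, "deg_ips_groups.tsv")
    de
  })
  deg_genes <- res$deg$gene[res$deg$direction != "ns"]
  if (length(deg_genes) < 10)
    stop("stage 'differential_expression' found too few DEGs (", length(deg_genes), ")")

  res$deg_clusters <- stage("deg_clusters", function() {
    cc <- consensus_cluster(t(expr[deg_genes, , drop = FALSE]),
                            k_range = config$k_range_deg,
                            n_resample = config$consensus_reps,
                            subsample_frac = config$subsample_frac,
                            seed = config$seed + 1L)
    lab <- cc$labels[[as.character(cc$chosen_k)]]
    emit(data.frame(sample_id = names(lab), deg_cluster = lab), "deg_clusters.tsv")
    emit(data.frame(k = cc$k_range, pac = unname(cc$pac)), "deg_cluster_pac.tsv")
    list(consensus = cc, labels = lab,
         logrank = safe_logrank(os_time, os_event, lab))
  })

  res$gene_types <- stage("gene_types", function() {
    lab <- res$deg_clusters$labels
    ref <- names(which.max(tapply(clinical$ips, lab, mean)))
    gt <- assign_gene_types(expr[deg_genes, , drop = FALSE], lab, ref)
    emit(gt, "gene_types.tsv")
    gt
  })
  genes_A <- res$gene_types$gene[res$gene_types$type == "A"]
  genes_B <- res$gene_types$gene[res$gene_types$type == "B"]

  res$boruta <- stage("boruta", function() {
    reduce <- function(genes, label) {
      if (length(genes) < 5) return(genes)
      kept <- boruta_select(t(expr[genes, , drop = FALSE]), ips_group,
                            max_iter = config$boruta_max_iter,
                            alpha = config$boruta_alpha, seed = config$seed)
      if (length(kept) < 2) {
        message("Boruta confirmed < 2 genes for type ", label, "; keeping full set")
        return(genes)
      }
      kept
    }
    out <- list(genes_A = reduce(genes_A, "A"), genes_B = reduce(genes_B, "B"))
    emit(data.frame(gene = c(out$genes_A, out$genes_B),
                    type = rep(c("A", "B"), c(length(out$genes_A), length(out$genes_B)))),
         "boruta_selected.tsv")
    out
  })

  res$model <- stage("ici_model", function() {
    m <- fit_ici_model(expr, res$boruta$genes_A, res$boruta$genes_B)
    write_ici_model(m, file.path(config$out_dir, "ici_model.json"))
    outputs[["ici_model.json"]] <<- file.path(config$out_dir, "ici_model.json")
    m
  })
  res$scores <- stage("ici_scores", function() {
    sc <- score_samples(res$model, expr)
    emit(sc, "ici_scores.tsv")
    sc
  })

  res$score_cut <- stage("score_cutpoint", function() {
    cp <- optimal_cutpoint(res$scores$ici_score, os_time, os_event, config$minprop)
    lr <- safe_logrank(os_time, os_event, cp$group)
    km_hi <- km_estimate(os_time[cp$group == "high"], os_event[cp$group == "high"])
    km_lo <- km_estimate(os_time[cp$group == "low"], os_event[cp$group == "low"])
    emit(data.frame(sample_id = res$scores$sample_id,
                    ici_score = res$scores$ici_score, score_group = cp$group),
         "score_groups.tsv")
    emit(data.frame(threshold = cp$threshold,
                    statistic = cp$standardized_statistic,
                    n_high = cp$n_high, n_low = cp$n_low,
                    logrank_p = lr$p_value,
                    median_os_high = km_hi$median, median_os_low = km_lo$median),
         "score_cutpoint.tsv")
    list(cutpoint = cp, logrank = lr, km_high = km_hi, km_low = km_lo)
  })
  score_group <- res$score_cut$cutpoint$group

  res$panels <- stage("gene_panels", function() {
    pt <- compare_gene_panels(expr, score_group)
    emit(pt, "panel_tests.tsv")
    pt
  })

  if (!is.null(gene_sets)) {
    res$gsea <- stage("gsea", function() {
      de_sc <- differential_expression(expr, score_group,
                                       p_cutoff = config$p_cutoff,
                                       lfc_cutoff = config$lfc_cutoff)
      rk <- stats::setNames(de_sc$log2_fold_change, de_sc$gene)
      gs <- preranked_gsea(rk, gene_sets, n_perm = config$gsea_n_perm,
                           seed = config$seed + 2L)
      emit(gs, "gsea_score_groups.tsv")
      gs
    })
  } else message("no gene sets supplied: GSEA stage skipped")

  if (!is.null(maf)) {
    res$tmb <- stage("tmb", function() {
      tmb <- compute_tmb(maf, samples = clinical$sample_id, exome_mb = config$exome_mb)
      emit(tmb, "tmb.tsv")
      wx <- wilcoxon_rank_sum(tmb$tmb[score_group == "high"],
                              tmb$tmb[score_group == "low"])
      sp <- spearman_cor(res$scores$ici_score, tmb$tmb)
      tmb_cp <- tryCatch(optimal_cutpoint(tmb$tmb, os_time, os_event, config$minprop),
                         error = function(e) NULL)
      strat <- if (!is.null(tmb_cp)) {
        do.call(rbind, lapply(c("high", "low"), function(tg) {
          sel <- tmb_cp$group == tg
          lr <- safe_logrank(os_time[sel], os_event[sel], score_group[sel])
          data.frame(tmb_group = tg, n = sum(sel), logrank_p = lr$p_value)
        }))
      } else NULL
      grp <- stats::setNames(as.character(score_group), clinical$sample_id)
      freq <- mutation_frequency_contrast(maf, grp, top_n = config$top_n)
      emit(freq, "driver_frequency_contrast.tsv")
      for (sg in c("high", "low")) {
        wf <- waterfall_export(maf, samples = clinical$sample_id[score_group == sg],
                               top_n = config$top_n)
        emit(data.frame(gene = rownames(wf), wf, check.names = FALSE),
             paste0("waterfall_", sg, ".tsv"))
      }
      tests <- data.frame(test = c("wilcoxon_tmb_by_score_group",
                                   "spearman_tmb_vs_score"),
                          estimate = c(NA, sp$rho),
                          p_value = c(wx$p_value, sp$p_value))
      if (!is.null(tmb_cp))
        tests <- rbind(tests, data.frame(test = "tmb_cutpoint_logrank",
                                         estimate = tmb_cp$threshold,
                                         p_value = safe_logrank(os_time, os_event,
                                                                tmb_cp$group)$p_value))
      emit(tests, "tmb_tests.tsv")
      if (!is.null(strat)) emit(strat, "tmb_stratified_logrank.tsv")
      list(tmb = tmb, wilcoxon = wx, spearman = sp, cutpoint = tmb_cp,
           stratified = strat, frequency = freq)
    })
  } else message("no MAF supplied: mutation stages skipped")

  res$manifest <- write_manifest(config, outputs)
  structure(res, class = "ici_pipeline_result")
}

write_manifest <- function(config, outputs) {
  files <- unlist(outputs)
  manifest <- list(
    package = "iciscore",
    version = as.character(utils::packageVersion("iciscore")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("expression", "clinical", "maf", "signature",
                                  "gene_sets"))],
    files = lapply(stats::setNames(as.list(files), basename(files)),
                   function(f) unname(tools::md5sum(f))))
  path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Validate an ICI model on an immunotherapy cohort
#'
#' Scores the cohort with a frozen model, splits it at a survival-optimal
#' cutpoint refitted on the cohort (the default) or at a supplied
#' threshold, and reports: Wilcoxon of the ICI score by responder status
#' (responder = CR/PR, non-responder = SD/PD), chi-square of responder
#' proportion by score group, and the log-rank test of overall survival by
#' score group. Without a `response` column a survival-only report is
#' returned.
#'
#' @param model An `"ici_model"`.
#' @param expr Cohort expression matrix (genes x samples).
#' @param clinical Cohort clinical data.frame (`sample_id`, `os_time`,
#'   `os_event`, optional `response` with levels CR/PR/SD/PD).
#' @param cutpoint Numeric threshold to transfer; `NULL` (default) refits
#'   on this cohort.
#' @param minprop Cutpoint constraint when refitting.
#' @return List of class `"ici_validation_report"`: `scores`, `group`,
#'   `cutpoint`, `cutpoint_source`, `responder_definition`,
#'   `wilcoxon_score_by_response`, `chisq_response_by_group`,
#'   `logrank_os_by_group`, `responder_rate_by_group`.
#' @export
validate_cohort <- function(model, expr, clinical, cutpoint = NULL, minprop = 0.1) {
  common <- intersect(colnames(expr), clinical$sample_id)
  expr <- expr[, common, drop = FALSE]
  clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  scores <- score_samples(model, expr)
  if (is.null(cutpoint)) {
    cp <- optimal_cutpoint(scores$ici_score, clinical$os_time, clinical$os_event,
                           minprop)
    thr <- cp$threshold; src <- "refit_on_cohort"
  } else {
    thr <- cutpoint; src <- "transferred"
  }
  group <- factor(ifelse(scores$ici_score > thr, "high", "low"),
                  levels = c("low", "high"))
  out <- list(scores = scores, group = group, cutpoint = thr,
              cutpoint_source = src,
              responder_definition = "responder = CR/PR; non-responder = SD/PD",
              logrank_os_by_group = safe_logrank(clinical$os_time,
                                                 clinical$os_event, group))
  if (!is.null(clinical$response)) {
    responder <- clinical$response %in% c("CR", "PR")
    out$wilcoxon_score_by_response <-
      wilcoxon_rank_sum(scores$ici_score[responder], scores$ici_score[!responder])
    tab <- table(group, factor(responder, levels = c(FALSE, TRUE),
                               labels = c("non_responder", "responder")))
    out$chisq_response_by_group <- chi_square_table(tab)
    out$responder_rate_by_group <- prop.table(tab, 1)[, "responder"]
  } else message("no response column: survival-only validation report")
  structure(out, class = "ici_validation_report")
}
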