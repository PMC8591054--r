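#!/usr/bin/env Rscript
# Stage 3: build the ICI scoring model.
# IPS survival cutpoint -> moderated-t differential expression -> consensus
# clustering of samples on the DEG panel -> gene types A/B (reference =
# highest-IPS cluster) -> Boruta reduction -> PC1-difference ICI score ->
# survival-optimal score cutpoint and checkpoint/activation panel tests.

library(iciscore)

expr <- read_expression("results/cohort/expression.tsv")
clinical <- read_clinical("results/cohort/clinical.tsv")

ips_cut <- optimal_cutpoint(clinical$ips, clinical$os_time, clinical$os_event)
message("IPS cutpoint ", round(ips_cut$threshold, 2), ": ",
        ips_cut$n_high, " high / ", ips_cut$n_low, " low")

de <- differential_expression(expr, ips_cut$group)
write.table(de, "results/deg_ips_groups.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
deg <- de$gene[de$direction != "ns"]
message(length(deg), " DEGs (BH < 0.05, |log2FC| > 1): ",
        sum(de$direction == "up_in_high"), " up in high-IPS, ",
        sum(de$direction == "up_in_low"), " up in low-IPS")

cc <- consensus_cluster(t(expr[deg, ]), k_range = 2:6, n_resample = 200, seed = 8)
lab <- cc$labels[[as.character(cc$chosen_k)]]
message("DEG expression subtypes: k = ", cc$chosen_k)

ref <- names(which.max(tapply(clinical$ips, lab, mean)))
gt <- assign_gene_types(expr[deg, ], lab, ref)
write.table(gt, "results/gene_types.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message("gene types vs reference cluster ", ref, ": ",
        sum(gt$type == "A"), " type A, ", sum(gt$type == "B"), " type B")

reduce <- function(genes, label) {
  kept <- boruta_select(t(expr[genes, ]), ips_cut$group, max_iter = 30, seed = 9)
  message("Boruta type ", label, ": ", length(kept), " of ", length(genes), " confirmed")
  if (length(kept) < 2) genes else kept
}
genes_A <- reduce(gt$gene[gt$type == "A"], "A")
genes_B <- reduce(gt$gene[gt$type == "B"], "B")

model <- fit_ici_model(expr, genes_A, genes_B)
write_ici_model(model, "results/ici_model.json")
scores <- score_samples(model, expr)
write.table(scores, "results/ici_scores.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message("ICI score: PC1 explains ", round(100 * model$A$var_explained, 1),
        "% (A) and ", round(100 * model$B$var_explained, 1), "% (B) of set variance")

cut <- optimal_cutpoint(scores$ici_score, clinical$os_time, clinical$os_event)
lr <- logrank_test(clinical$os_time, clinical$os_event, cut$group)
write.table(data.frame(sample_id = scores$sample_id, ici_score = scores$ici_score,
                       score_group = cut$group),
            "results/score_groups.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message("score cutpoint ", round(cut$threshold, 2), " (", cut$n_high, " high / ",
        cut$n_low, " low); log-rank p = ", signif(lr$p_value, 3),
        "; standardized statistic ", round(cut$standardized_statistic, 2),
        " (negative = high group protected)")

pt <- compare_gene_panels(expr, cut$group)
write.table(pt, "results/panel_tests.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message(sum(pt$adjusted_p < 0.05 & pt$direction == "up_in_high"), " of ",
        nrow(pt), " checkpoint/activation genes up in the high-score group (BH < 0.05)")
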