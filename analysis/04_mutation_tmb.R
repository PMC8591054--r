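#!/usr/bin/env Rscript
# Stage 4: somatic mutation integration.
# Per-sample TMB from the MAF, TMB survival cutpoint, TMB vs ICI score
# contrasts, TMB-stratified survival by score group, and driver-gene
# frequency contrasts with waterfall exports.

library(iciscore)

clinical <- read_clinical("results/cohort/clinical.tsv")
maf <- read_maf("results/cohort/cohort.maf")
sg <- read.delim("results/score_groups.tsv")
score_group <- factor(sg$score_group, levels = c("low", "high"))

tmb <- compute_tmb(maf, samples = clinical$sample_id, exome_mb = 38)
write.table(tmb, "results/tmb.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message("TMB: median ", round(median(tmb$tmb), 3), " mut/Mb (range ",
        round(min(tmb$tmb), 2), "-", round(max(tmb$tmb), 2), ")")

cut <- optimal_cutpoint(tmb$tmb, clinical$os_time, clinical$os_event)
lr <- logrank_test(clinical$os_time, clinical$os_event, cut$group)
message("TMB survival cutpoint ", round(cut$threshold, 3),
        " mut/Mb; log-rank p = ", signif(lr$p_value, 3))

wx <- wilcoxon_rank_sum(tmb$tmb[score_group == "high"], tmb$tmb[score_group == "low"])
sp <- spearman_cor(sg$ici_score, tmb$tmb)
message("TMB higher in the high-ICI group: Wilcoxon p = ", signif(wx$p_value, 3))
message("ICI score vs TMB: Spearman rho = ", round(sp$rho, 3),
        ", p = ", signif(sp$p_value, 3))

strat <- do.call(rbind, lapply(c("high", "low"), function(tg) {
  sel <- cut$group == tg
  lr_s <- logrank_test(clinical$os_time[sel], clinical$os_event[sel], score_group[sel])
  data.frame(tmb_group = tg, n = sum(sel), logrank_p = lr_s$p_value)
}))
write.table(strat, "results/tmb_stratified_logrank.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("score-group survival within TMB strata: p = ",
        paste(signif(strat$logrank_p, 3), collapse = " (high TMB), "), " (low TMB)")

grp <- setNames(as.character(score_group), clinical$sample_id)
freq <- mutation_frequency_contrast(maf, grp, top_n = 30)
write.table(freq, "results/driver_frequency_contrast.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("top mutated gene: ", freq$gene[1], " (",
        round(100 * freq$pooled_frequency[1]), "% of samples); ",
        sum(freq$adjusted_p < 0.05), " of ", nrow(freq),
        " drivers differ between score groups (BH < 0.05)")

for (g in c("high", "low")) {
  wf <- waterfall_export(maf, samples = clinical$sample_id[score_group == g], top_n = 30)
  write.table(data.frame(gene = rownames(wf), wf, check.names = FALSE),
              paste0("results/waterfall_", g, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
message("waterfall matrices written for both score groups")
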