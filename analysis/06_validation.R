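#!/usr/bin/env Rscript
# Stage 6: immunotherapy-cohort validation.
# Scores an independent synthetic cohort (response coupled to its latent
# immune score) with the frozen ICI model, refits the survival cutpoint on
# the new cohort, and tests score-response and score-survival associations.

library(iciscore)

model <- read_ici_model("results/ici_model.json")
vcfg <- sim_config(n_samples = 250L, responder_logit_coefficient = 2, seed = 77)
vc <- simulate_validation_cohort(vcfg, model)

report <- validate_cohort(model, vc$expression, vc$clinical)
rates <- report$responder_rate_by_group
tab <- data.frame(
  metric = c("cutpoint", "responder_rate_high", "responder_rate_low",
             "wilcoxon_score_by_response_p", "chisq_response_by_group_p",
             "logrank_os_by_group_p"),
  value = c(report$cutpoint, rates[["high"]], rates[["low"]],
            report$wilcoxon_score_by_response$p_value,
            report$chisq_response_by_group$p_value,
            report$logrank_os_by_group$p_value))
write.table(tab, "results/validation_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("validation cohort: ", length(report$group), " samples; ",
        report$responder_definition)
message("responder rate: ", round(100 * rates[["high"]], 1), "% (high ICI) vs ",
        round(100 * rates[["low"]], 1), "% (low ICI); chi-square p = ",
        signif(report$chisq_response_by_group$p_value, 3))
message("ICI score by response: Wilcoxon p = ",
        signif(report$wilcoxon_score_by_response$p_value, 3))
message("OS by score group: log-rank p = ",
        signif(report$logrank_os_by_group$p_value, 3))
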