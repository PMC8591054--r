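#!/usr/bin/env Rscript
# Stage 1: generate the study cohort.
# A 300-sample synthetic tumor cohort with three latent immune phenotypes
# driving cell fractions, expression, immunophenoscore, survival, mutation
# burden and immunotherapy response, written in the pipeline's exchange
# formats under results/cohort/.

library(iciscore)

out <- "results/cohort"
cfg <- sim_config(seed = 42)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, out)
write_signature_matrix(cfg$signature, file.path(out, "signature.tsv"))

message("cohort: ", ncol(cohort$expression), " samples x ",
        nrow(cohort$expression), " genes; ",
        nrow(cohort$maf), " MAF records")
message("events: ", sum(cohort$clinical$os_event), " deaths (",
        round(100 * mean(cohort$clinical$os_event), 1), "% event rate)")
message("phenotype sizes: ",
        paste(table(cohort$true_phenotype), collapse = " / "))
message("responders (CR/PR): ",
        round(100 * mean(cohort$response %in% c("CR", "PR")), 1), "%")
message("wrote fixtures to ", out)
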