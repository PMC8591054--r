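#!/usr/bin/env Rscript
# Stage 5: enrichment analyses.
# Preranked GSEA between ICI score groups (ranking metric: moderated-t
# log2 fold change) and hypergeometric over-representation of gene types A
# and B, against a small synthetic gene-set collection built over the
# cohort's gene universe.

library(iciscore)

expr <- read_expression("results/cohort/expression.tsv")
sg <- read.delim("results/score_groups.tsv")
gt <- read.delim("results/gene_types.tsv")
score_group <- factor(sg$score_group, levels = c("low", "high"))

# synthetic gene-set collection: two planted programs plus random sets
panels <- unlist(ici_gene_panels(), use.names = FALSE)
genes_A_all <- grep("^GA|^CD|^CXCL|^GZ|^IFN|^PRF|^TBX|^TNF|^CTLA|^HAVCR|^IDO|^LAG|^PDCD",
                    rownames(expr), value = TRUE)
gene_sets <- c(
  list("BP:immune_activation_program" = c(panels, grep("^GA", rownames(expr), value = TRUE)[1:25]),
       "BP:suppressive_program" = grep("^GB", rownames(expr), value = TRUE)[1:40]),
  withr::with_seed(31, setNames(
    lapply(1:4, function(i) sample(rownames(expr), 30)),
    paste0("BP:random_", 1:4))))
write_gmt(gene_sets, "results/gene_sets.gmt")

de <- differential_expression(expr, score_group)
rk <- setNames(de$log2_fold_change, de$gene)
gsea <- preranked_gsea(rk, gene_sets, n_perm = 1000, seed = 10)
write.table(gsea, "results/gsea_score_groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- gsea[order(gsea$nominal_p, -abs(gsea$nes)), ][1, ]
message("GSEA: strongest set '", top$set, "' (ES = ", round(top$es, 2),
        ", NES = ", round(top$nes, 2), ", p = ", signif(top$nominal_p, 3), ")")

ora_A <- ora_hypergeometric(gt$gene[gt$type == "A"], rownames(expr), gene_sets)
ora_B <- ora_hypergeometric(gt$gene[gt$type == "B"], rownames(expr), gene_sets)
ora_A$query <- "type_A"; ora_B$query <- "type_B"
write.table(rbind(ora_A, ora_B), "results/ora_gene_types.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("ORA: type A most enriched in '", ora_A$set[1], "' (p = ",
        signif(ora_A$p_value[1], 3), "); type B in '", ora_B$set[1],
        "' (p = ", signif(ora_B$p_value[1], 3), ")")
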