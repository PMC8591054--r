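#' Per-sample tumor mutation burden from a MAF table
#'
#' Counts variants whose classification belongs to the nonsilent set and
#' divides by the exome size in megabases. Samples listed in `samples` but
#' absent from the MAF receive count 0 and are flagged. Variants with a
#' classification outside the MAF-standard vocabulary are excluded with a
#' warning and listed in the `excluded_classes` attribute.
#'
#' @param maf Data.frame from [read_maf()].
#' @param samples Character vector of sample ids to report (default: those
#'   present in the MAF).
#' @param exome_mb Exome size in megabases (default 38).
#' @param nonsilent_classes Classifications counted (default
#'   [maf_nonsilent_classes()]).
#' @return Data.frame per sample: `sample_id`, `nonsilent_count`, `tmb`
#'   (mutations per Mb), `in_maf`; attribute `excluded_classes`.
#' @export
compute_tmb <- function(maf, samples = NULL, exome_mb = 38,
                        nonsilent_classes = maf_nonsilent_classes()) {
  if (exome_mb <= 0) stop("exome_mb must be > 0")
  if (is.null(samples)) samples <- unique(maf$sample_id)
  unknown <- setdiff(unique(maf$variant_classification), maf_known_classes())
  if (length(unknown)) {
    warning("unknown variant classification(s) excluded: ",
            paste(unknown, collapse = ", "))
    maf <- maf[!maf$variant_classification %in% unknown, , drop = FALSE]
  }
  ns <- maf[maf$variant_classification %in% nonsilent_classes, , drop = FALSE]
  counts <- table(factor(ns$sample_id, levels = samples))
  structure(data.frame(sample_id = samples,
                       nonsilent_count = as.integer(counts),
                       tmb = as.numeric(counts) / exome_mb,
                       in_maf = samples %in% maf$sample_id,
                       row.names = NULL, stringsAsFactors = FALSE),
            excluded_classes = unknown)
}

#' Mutation-frequency contrast of top driver genes between two groups
#'
#' A sample counts once per gene regardless of variant multiplicity. The
#' `top_n` genes by pooled mutation frequency (ties broken alphabetically)
#' are kept; per gene, Fisher's exact test contrasts mutated-sample counts
#' between the two groups, with BH adjustment across the kept genes.
#'
#' @param maf Data.frame from [read_maf()].
#' @param group Named factor/character: group label per sample id (2 groups).
#' @param top_n Number of top genes (default 30).
#' @return Data.frame per gene: per-group mutated counts and frequencies,
#'   `pooled_frequency`, `p_value`, `adjusted_p`, ranked by pooled
#'   frequency.
#' @export
mutation_frequency_contrast <- function(maf, group, top_n = 30L) {
  grp <- factor(group)
  if (nlevels(grp) != 2) stop("need exactly two groups")
  if (any(table(grp) == 0)) stop("both groups must be non-empty")
  samples <- names(group)
  if (is.null(samples)) stop("group must be named by sample id")
  maf <- maf[maf$sample_id %in% samples, , drop = FALSE]
  if (!nrow(maf)) {
    warning("no MAF records for the grouped samples; empty table")
    return(data.frame(gene = character(0)))
  }
  hit <- unique(maf[, c("hugo_symbol", "sample_id")])
  pooled <- sort(table(hit$hugo_symbol), decreasing = TRUE)
  ord <- order(-as.integer(pooled), names(pooled))
  genes <- names(pooled)[ord][seq_len(min(top_n, length(pooled)))]
  n1 <- sum(grp == levels(grp)[1]); n2 <- sum(grp == levels(grp)[2])
  rows <- lapply(genes, function(gn) {
    mut_samples <- hit$sample_id[hit$hugo_symbol == gn]
    k1 <- sum(group[mut_samples] == levels(grp)[1], na.rm = TRUE)
    k2 <- sum(group[mut_samples] == levels(grp)[2], na.rm = TRUE)
    ft <- stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2))
    data.frame(gene = gn, n_mutated_1 = k1, n_mutated_2 = k2,
               frequency_1 = k1 / n1, frequency_2 = k2 / n2,
               pooled_frequency = (k1 + k2) / (n1 + n2),
               p_value = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("n_mutated_", levels(grp)),
                       paste0("frequency_", levels(grp)))
  out$adjusted_p <- bh_adjust(out$p_value)
  out
}

# classification severity for multi-hit cells, most severe first
waterfall_severity <- function() {
  c("Nonsense_Mutation", "Frame_Shift_Del", "Frame_Shift_Ins", "Splice_Site",
    "Nonstop_Mutation", "Translation_Start_Site", "In_Frame_Del",
    "In_Frame_Ins", "Missense_Mutation", "Silent")
}

#' Waterfall (oncoplot) matrix export
#'
#' Gene x sample matrix holding, per cell, the most severe variant
#' classification observed (severity order [waterfall_severity()]; empty
#' string if unmutated), restricted to the `top_n` most frequently mutated
#' genes. Genes are sorted by mutation frequency; samples by memo-sort
#' (lexicographic on the gene-ordered mutation pattern, mutated first).
#'
#' @param maf Data.frame from [read_maf()].
#' @param samples Sample ids forming the columns (default those in the MAF).
#' @param top_n Number of genes (default 30).
#' @return Character matrix (genes x samples) with attributes
#'   `gene_totals` and `sample_totals` (mutated-sample / mutated-gene
#'   counts).
#' @export
waterfall_export <- function(maf, samples = NULL, top_n = 30L) {
  if (is.null(samples)) samples <- unique(maf$sample_id)
  maf <- maf[maf$sample_id %in% samples, , drop = FALSE]
  hit <- unique(maf[, c("hugo_symbol", "sample_id")])
  pooled <- table(hit$hugo_symbol)
  ord <- order(-as.integer(pooled), names(pooled))
  genes <- names(pooled)[ord][seq_len(min(top_n, length(pooled)))]
  sev <- waterfall_severity()
  mat <- matrix("", nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  sub <- maf[maf$hugo_symbol %in% genes, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    g <- sub$hugo_symbol[i]; s <- sub$sample_id[i]
    vc <- sub$variant_classification[i]
    cur <- mat[g, s]
    rank_new <- match(vc, sev, nomatch = length(sev) + 1L)
    rank_cur <- match(cur, sev, nomatch = length(sev) + 2L)
    if (cur == "" || rank_new < rank_cur) mat[g, s] <- vc
  }
  # memo-sort: treat each sample's mutation pattern over the ordered genes
  # as binary digits, mutated first
  bin <- mat != ""
  keys <- apply(bin, 2, function(col) paste(as.integer(!col), collapse = ""))
  mat <- mat[, order(keys, colnames(mat)), drop = FALSE]
  structure(mat,
            gene_totals = rowSums(mat != ""),
            sample_totals = colSums(mat != ""))
}
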