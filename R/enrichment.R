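# weighted Kolmogorov-Smirnov-like running sum: hit steps proportional to
# |score|^weight, miss steps 1/(N - Nh); ES = deviation of maximal
# magnitude (signed)
gsea_es <- function(ranked_scores, in_set, weight = 1) {
  N <- length(ranked_scores)
  Nh <- sum(in_set)
  w <- abs(ranked_scores)^weight
  hit_steps <- ifelse(in_set, w, 0)
  denom <- sum(hit_steps)
  if (denom == 0) hit_steps[in_set] <- 1 / Nh else hit_steps <- hit_steps / denom
  run <- cumsum(hit_steps - ifelse(in_set, 0, 1 / (N - Nh)))
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted running-sum GSEA on a preranked gene list. The
#' enrichment score (ES) is the maximum-magnitude deviation of the running
#' sum (hit increments proportional to `|score|^weight`, miss decrements
#' `1/(N - Nh)`); the null is built by gene-label permutation, the NES
#' divides the ES by the mean magnitude of same-sign null ES, nominal p
#' uses the same-sign null with a +1 correction, and FDR q follows the
#' standard positive/negative pooled procedure.
#'
#' @param ranked_genes Named numeric vector: gene -> ranking score (e.g.
#'   log2 fold change between score groups); no duplicate names.
#' @param gene_sets Named list of gene symbol vectors (GMT-style).
#' @param weight Hit-weight exponent (default 1; 0 gives the unweighted
#'   statistic).
#' @param n_perm Gene-label permutations (default 1000).
#' @param min_size Minimum set overlap with the ranking (default 5);
#'   smaller sets are skipped with a message.
#' @param seed Permutation seed.
#' @return Data.frame per retained set: `set`, `size`, `es`, `nes`,
#'   `nominal_p`, `fdr_q`, `leading_edge` (slash-separated genes).
#' @export
preranked_gsea <- function(ranked_genes, gene_sets, weight = 1, n_perm = 1000L,
                           min_size = 5L, seed = 1L) {
  if (anyDuplicated(names(ranked_genes))) stop("duplicate genes in ranking")
  ord <- order(ranked_genes, decreasing = TRUE)
  scores <- ranked_genes[ord]
  genes <- names(scores)
  N <- length(genes)

  sizes <- vapply(gene_sets, function(s) sum(genes %in% s), 0L)
  skip <- sizes < min_size | sizes >= N
  if (any(skip))
    message(sum(skip), " gene set(s) below min_size (or covering the universe); skipped")
  gene_sets <- gene_sets[!skip]
  if (!length(gene_sets))
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), nominal_p = numeric(0),
                      fdr_q = numeric(0), leading_edge = character(0)))

  es_obs <- numeric(length(gene_sets))
  led <- character(length(gene_sets))
  for (i in seq_along(gene_sets)) {
    in_set <- genes %in% gene_sets[[i]]
    es_obs[i] <- gsea_es(scores, in_set, weight)
    w <- abs(scores)^weight
    hs <- ifelse(in_set, w, 0); hs <- hs / sum(hs[in_set])
    run <- cumsum(hs - ifelse(in_set, 0, 1 / (N - sum(in_set))))
    peak <- which.max(abs(run))
    led[i] <- if (es_obs[i] >= 0) paste(genes[seq_len(peak)][in_set[seq_len(peak)]], collapse = "/")
    else paste(genes[peak:N][in_set[peak:N]], collapse = "/")
  }

  null_es <- matrix(NA_real_, n_perm, length(gene_sets))
  withr::with_seed(seed, {
    set_sizes <- vapply(gene_sets, function(s) sum(genes %in% s), 0L)
    for (p in seq_len(n_perm)) {
      for (i in seq_along(gene_sets)) {
        in_perm <- logical(N)
        in_perm[sample.int(N, set_sizes[i])] <- TRUE
        null_es[p, i] <- gsea_es(scores, in_perm, weight)
      }
    }
  })

  nes <- numeric(length(gene_sets))
  nominal_p <- numeric(length(gene_sets))
  for (i in seq_along(gene_sets)) {
    same <- null_es[, i][sign(null_es[, i]) == sign(es_obs[i]) | es_obs[i] == 0]
    denom <- mean(abs(same))
    nes[i] <- if (length(same) && denom > 0) es_obs[i] / denom else NA_real_
    nominal_p[i] <- (1 + sum(abs(same) >= abs(es_obs[i]))) / (1 + n_perm)
  }
  # pooled-null FDR: null NES from every permutation and set
  null_nes <- null_es
  for (i in seq_along(gene_sets)) {
    pos <- null_es[, i] >= 0
    mp <- mean(null_es[pos, i]); mn <- mean(abs(null_es[!pos, i]))
    null_nes[pos, i] <- if (is.finite(mp) && mp > 0) null_es[pos, i] / mp else NA
    null_nes[!pos, i] <- if (is.finite(mn) && mn > 0) null_es[!pos, i] / mn else NA
  }
  all_null <- as.vector(null_nes); all_null <- all_null[is.finite(all_null)]
  fdr_q <- vapply(seq_along(gene_sets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(all_null[all_null >= 0] >= nes[i])
      den <- mean(nes[nes >= 0 & !is.na(nes)] >= nes[i])
    } else {
      num <- mean(all_null[all_null < 0] <= nes[i])
      den <- mean(nes[nes < 0 & !is.na(nes)] <= nes[i])
    }
    if (!is.finite(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  data.frame(set = names(gene_sets), size = sizes[!skip], es = es_obs,
             nes = nes, nominal_p = nominal_p, fdr_q = fdr_q,
             leading_edge = led, row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Per gene set, the upper-tail hypergeometric probability
#' P(X >= overlap) of observing at least the seen overlap between the
#' query and the set within the universe, BH-adjusted across tested sets.
#'
#' @param query_genes Character vector (must be contained in the universe).
#' @param universe_genes Character vector of background genes.
#' @param gene_sets Named list of gene symbol vectors; intersected with the
#'   universe before testing.
#' @param top_k_report Rows flagged as `reported` per namespace when set
#'   names carry a `namespace:term` tag (default 10).
#' @return Data.frame per set: `set`, `set_size`, `overlap`,
#'   `fold_enrichment`, `p_value`, `adjusted_p`, `reported`, sorted by p.
#' @export
ora_hypergeometric <- function(query_genes, universe_genes, gene_sets,
                               top_k_report = 10L) {
  query_genes <- unique(query_genes)
  universe_genes <- unique(universe_genes)
  if (!length(query_genes)) stop("empty query gene list")
  extra <- setdiff(query_genes, universe_genes)
  if (length(extra))
    stop("query genes outside the universe: ", paste(utils::head(extra, 5), collapse = ", "))
  Nu <- length(universe_genes)
  nq <- length(query_genes)
  if (nq == Nu) warning("query equals the universe; all tests degenerate (p = 1)")
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe_genes)
    m <- length(set)
    if (m == 0) return(NULL)
    ov <- length(intersect(set, query_genes))
    p <- stats::phyper(ov - 1, m, Nu - m, nq, lower.tail = FALSE)
    fe <- if (ov == 0) 0 else (ov / nq) / (m / Nu)
    data.frame(set = nm, set_size = m, overlap = ov, fold_enrichment = fe,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set overlaps the universe")
  out$adjusted_p <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  ns <- sub(":.*$", "", out$set)
  ns[!grepl(":", out$set)] <- "default"
  out$reported <- stats::ave(seq_along(ns), ns, FUN = seq_along) <= top_k_report
  rownames(out) <- NULL
  out
}
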