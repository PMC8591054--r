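# one shared default-condition cohort, built once per test run
.cohort_cache <- new.env(parent = emptyenv())

get_default_cohort <- function() {
  if (is.null(.cohort_cache$cohort))
    .cohort_cache$cohort <- simulate_cohort(sim_config(seed = 42))
  .cohort_cache$cohort
}

# small cohort configuration for fast pipeline-level tests
small_config <- function(seed = 11, ...) {
  args <- list(n_samples = 120L, n_genes = 200L,
               n_signal_genes_A = 30L, n_signal_genes_B = 30L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# independent adjusted Rand index (contingency-table formula)
rand_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# rank-sum AUC of a score for a binary condition
rank_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
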