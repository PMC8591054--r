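#' Partitioning around medoids on a distance matrix
#'
#' k-medoids via the BUILD + SWAP algorithm (delegated to
#' [cluster::pam()]). Deterministic for a given input; `seed` only
#' influences tie-breaking in degenerate inputs.
#'
#' @param dist_matrix Square symmetric non-negative distance matrix (or a
#'   `dist` object).
#' @param k Number of clusters, `2 <= k <= n - 1` (`k = n` is allowed as the
#'   degenerate all-singletons partition).
#' @param seed Tie-break seed.
#' @return List with `labels` (integer vector in 1..k) and `medoids`
#'   (indices).
#' @export
pam_cluster <- function(dist_matrix, k, seed = 1L) {
  d <- if (inherits(dist_matrix, "dist")) dist_matrix else stats::as.dist(dist_matrix)
  n <- attr(d, "Size")
  if (k < 2 || k > n) stop("k out of range: need 2 <= k <= n")
  if (k == n)
    return(list(labels = seq_len(n), medoids = seq_len(n)))
  fit <- withr::with_seed(seed, cluster::pam(d, k = k, diss = TRUE,
                                             cluster.only = FALSE))
  list(labels = as.integer(fit$clustering), medoids = as.integer(fit$id.med))
}

#' Consensus clustering by resampled PAM
#'
#' For each k, repeatedly subsamples `ceiling(subsample_frac * n)` samples
#' without replacement, clusters the subsample (PAM on Euclidean feature
#' distance, or Ward hierarchical as an alternative base learner), and
#' accumulates co-clustering counts. The consensus matrix entry (i, j) is
#' the number of times i and j co-clustered divided by the number of times
#' both were drawn (0 if never co-drawn, which is logged). Final per-k
#' labels cut an average-linkage tree of `1 - consensus` at k. The CDF of
#' upper-triangle consensus values and the PAC (proportion of entries in
#' (0.1, 0.9)) summarise per-k stability.
#'
#' @param data_matrix Samples x features matrix.
#' @param k_range Integer vector of candidate k (default 2:6).
#' @param n_resample Resampling repetitions per k (default 1000).
#' @param subsample_frac Fraction of samples per draw (default 0.8).
#' @param seed Seed driving all resampling.
#' @param scale_features Standardise feature columns first (default TRUE).
#' @param base_method `"pam"` (default) or `"ward"` base learner.
#' @return List of class `"consensus_result"`: `k_range`,
#'   `consensus_matrices`, `labels` (per-k integer labels), `cdf` (per-k
#'   function), `pac` (named vector), `chosen_k` (by [select_k()], PAC rule).
#' @export
consensus_cluster <- function(data_matrix, k_range = 2:6, n_resample = 1000L,
                              subsample_frac = 0.8, seed = 1L,
                              scale_features = TRUE,
                              base_method = c("pam", "ward")) {
  base_method <- match.arg(base_method)
  X <- as.matrix(data_matrix)
  n <- nrow(X)
  m <- ceiling(subsample_frac * n)
  if (m < max(k_range)) stop("config error: subsample size ", m,
                             " smaller than max(k_range) = ", max(k_range))
  if (scale_features) {
    sds <- apply(X, 2, stats::sd)
    X <- scale(X[, sds > 0, drop = FALSE])
  }
  ids <- rownames(data_matrix)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  cons <- list(); labels <- list(); cdfs <- list()
  pac <- stats::setNames(numeric(length(k_range)), k_range)
  zero_cooccur <- 0L
  withr::with_seed(seed, {
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      co <- matrix(0, n, n)
      cnt <- matrix(0, n, n)
      for (b in seq_len(n_resample)) {
        idx <- sort(sample.int(n, m))
        d <- stats::dist(X[idx, , drop = FALSE])
        lab <- if (base_method == "pam") {
          cluster::pam(d, k = k, diss = TRUE, cluster.only = TRUE)
        } else {
          stats::cutree(stats::hclust(d, method = "ward.D2"), k = k)
        }
        cnt[idx, idx] <- cnt[idx, idx] + 1
        for (cl in unique(lab)) {
          mem <- idx[lab == cl]
          co[mem, mem] <- co[mem, mem] + 1
        }
      }
      M <- matrix(0, n, n)
      pos <- cnt > 0
      M[pos] <- co[pos] / cnt[pos]
      zero_cooccur <- zero_cooccur + sum(!pos[upper.tri(pos)])
      diag(M) <- 1
      dimnames(M) <- list(ids, ids)
      hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
      lab_final <- stats::cutree(hc, k = k)
      up <- M[upper.tri(M)]
      cons[[as.character(k)]] <- M
      labels[[as.character(k)]] <- stats::setNames(as.integer(lab_final), ids)
      cdfs[[as.character(k)]] <- stats::ecdf(up)
      pac[ki] <- mean(up > 0.1 & up < 0.9)
    }
  })
  if (zero_cooccur > 0)
    message(zero_cooccur, " sample pair(s) never co-drawn; consensus set to 0")
  res <- structure(list(k_range = as.integer(k_range),
                        consensus_matrices = cons, labels = labels,
                        cdf = cdfs, pac = pac, chosen_k = NA_integer_),
                   class = "consensus_result")
  res$chosen_k <- if (length(k_range) > 1) select_k(res, "pac") else as.integer(k_range)
  res
}

#' Select the number of clusters from a consensus result
#'
#' `"pac"`: the k with minimal proportion of ambiguous clustering (ties go
#' to the smaller k). `"delta_area"`: the smallest k whose relative
#' increase in area under the consensus CDF over the previous k drops below
#' 0.1 (the first k is always eligible).
#'
#' @param result A `"consensus_result"`.
#' @param method `"pac"` (default) or `"delta_area"`.
#' @return An integer k from `result$k_range`.
#' @export
select_k <- function(result, method = c("pac", "delta_area")) {
  method <- match.arg(method)
  ks <- result$k_range
  if (length(ks) < 2) stop("need at least 2 candidate k")
  if (method == "pac") {
    return(ks[which.min(result$pac)])  # which.min takes the first = smallest k on ties
  }
  auc <- vapply(as.character(ks), function(k) {
    f <- result$cdf[[k]]
    xs <- seq(0, 1, length.out = 201)
    mean(f(xs))
  }, numeric(1))
  delta <- c(auc[1], diff(auc) / pmax(auc[-length(auc)], .Machine$double.eps))
  below <- which(delta < 0.1)
  if (length(below)) ks[below[1]] else ks[length(ks)]
}
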