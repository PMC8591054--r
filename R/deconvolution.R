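#' Deconvolve immune-cell fractions from bulk expression
#'
#' Estimates, per sample, the proportions of the signature matrix's cell
#' types in the bulk mixture. Expression is de-logged (`2^x`) to the linear
#' scale, restricted to the signature's marker genes (at least 50% of them
#' must be present), and both mixture and signature are put through one
#' shared z-normalization (mean/sd of the signature submatrix) so that
#' convex mixtures of basis columns remain exactly recoverable.
#'
#' `method = "nusvr"` fits nu-support-vector regression at
#' nu in {0.25, 0.5, 0.75} (linear kernel) and keeps the lowest-RMSE fit,
#' as in CIBERSORT; `"nnls"` solves non-negative least squares and is the
#' deterministic default. Either way negative coefficients are clipped to 0
#' and the vector is renormalised to sum 1.
#'
#' The permutation p-value is the fraction (with +1 correction) of
#' `n_perm` marker-shuffled mixtures whose fitted Pearson correlation
#' reaches the observed one.
#'
#' @param expr Expression matrix (genes x samples), log2 scale unless
#'   `delog = FALSE`.
#' @param sig Signature matrix (markers x cell types), linear scale.
#' @param method `"nnls"` (default) or `"nusvr"`.
#' @param n_perm Permutations for the per-sample p-value (0 skips; p = NA).
#' @param delog De-log expression with `2^x` first (default TRUE).
#' @param seed Seed for permutations and SVR.
#' @return List of class `"cell_fractions"`: `fractions` (samples x cell
#'   types, rows sum to 1) and `diagnostics` (per-sample `rmse`,
#'   `pearson_r`, `permutation_p`).
#' @export
deconvolve <- function(expr, sig, method = c("nnls", "nusvr"), n_perm = 0L,
                       delog = TRUE, seed = 1L) {
  method <- match.arg(method)
  if (n_perm < 0) stop("n_perm must be >= 0")
  common <- intersect(rownames(sig), rownames(expr))
  coverage <- length(common) / nrow(sig)
  if (coverage < 0.5)
    stop(sprintf("signature coverage too low: %.0f%% of marker genes present (need >= 50%%)",
                 100 * coverage))
  S <- sig[common, , drop = FALSE]
  X <- expr[common, , drop = FALSE]
  if (delog) X <- 2^X

  # shared affine transform: exactness for convex mixtures is preserved
  mu <- mean(S); sdv <- stats::sd(as.vector(S))
  Sz <- (S - mu) / sdv
  # free intercept as a +/- column pair keeps NNLS exactly invariant to
  # sample-wise rescaling of the mixture
  Az <- cbind(Sz, 1, -1)
  kk <- ncol(S)
  fit_one <- function(y) {
    yz <- (y - mu) / sdv
    intercept <- 0
    w <- switch(method,
      nnls = {
        wf <- pracma::lsqnonneg(Az, yz)$x
        intercept <- wf[kk + 1L] - wf[kk + 2L]
        wf[seq_len(kk)]
      },
      nusvr = {
        best <- NULL
        for (nu in c(0.25, 0.5, 0.75)) {
          m <- e1071::svm(Sz, yz, type = "nu-regression", kernel = "linear",
                          nu = nu, scale = FALSE)
          wc <- t(m$coefs) %*% m$SV
          wc[wc < 0] <- 0
          r <- sqrt(mean((Sz %*% t(wc) - yz)^2))
          if (is.null(best) || r < best$rmse) best <- list(w = as.vector(wc), rmse = r)
        }
        best$w
      })
    w[w < 0] <- 0
    frac <- if (sum(w) > 0) w / sum(w) else rep(1 / ncol(S), ncol(S))
    fitted <- Sz %*% w + intercept
    list(frac = frac,
         rmse = sqrt(mean((fitted - yz)^2)),
         r = if (stats::sd(fitted) > 0) stats::cor(as.vector(fitted), yz) else 0)
  }

  n <- ncol(X)
  fractions <- matrix(NA_real_, n, ncol(S), dimnames = list(colnames(X), colnames(S)))
  diag_df <- data.frame(sample_id = colnames(X), rmse = NA_real_,
                        pearson_r = NA_real_, permutation_p = NA_real_,
                        stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      res <- fit_one(X[, i])
      fractions[i, ] <- res$frac
      diag_df$rmse[i] <- res$rmse
      diag_df$pearson_r[i] <- res$r
      if (n_perm > 0) {
        hits <- 0L
        for (p in seq_len(n_perm)) {
          ypz <- (X[sample.int(nrow(X)), i] - mu) / sdv
          wp <- pracma::lsqnonneg(Az, ypz)$x
          fp <- Sz %*% wp[seq_len(kk)] + (wp[kk + 1L] - wp[kk + 2L])
          rp <- if (stats::sd(fp) > 0) stats::cor(as.vector(fp), ypz) else 0
          if (rp >= res$r) hits <- hits + 1L
        }
        diag_df$permutation_p[i] <- (hits + 1) / (n_perm + 1)
      }
    }
  })
  structure(list(fractions = fractions, diagnostics = diag_df, method = method),
            class = "cell_fractions")
}

#' Single-sample gene-set enrichment (ssGSEA) score
#'
#' Per sample, genes are ranked by expression (average ranks for ties) and
#' the score is the sum over all rank positions of the difference between
#' the weighted in-set empirical CDF (step heights proportional to
#' `rank^alpha`) and the uniform out-of-set empirical CDF.
#'
#' @param expr Expression matrix (genes x samples).
#' @param gene_set Character vector of gene symbols.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @return Named numeric vector, one score per sample.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  genes <- rownames(expr)
  in_set <- genes %in% gene_set
  if (sum(in_set) < 1) stop("no gene of the set present in the expression matrix")
  if (all(in_set)) stop("gene set covers the full gene universe; score undefined")
  N <- length(genes)
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    hit <- in_set[ord]
    w <- r[ord]^alpha
    p_in <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
    p_out <- cumsum(!hit) / (N - sum(hit))
    sum(p_in - p_out)
  }, numeric(1))
  stats::setNames(scores, colnames(expr))
}

#' Immune and stromal infiltration scores
#'
#' ssGSEA scores of an immune and a stromal gene set, per sample, as a
#' summary of the degree of immune infiltration and stromal content.
#'
#' @param expr Expression matrix (genes x samples).
#' @param immune_set,stromal_set Character vectors of gene symbols.
#' @param alpha Rank-weighting exponent passed to [ssgsea_score()].
#' @return Data.frame with `sample_id`, `immune_score`, `stromal_score`.
#' @export
estimate_scores <- function(expr, immune_set, stromal_set, alpha = 0.25) {
  data.frame(sample_id = colnames(expr),
             immune_score = ssgsea_score(expr, immune_set, alpha),
             stromal_score = ssgsea_score(expr, stromal_set, alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}
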