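# Cross-tissue comparison of MR results: sign concordance of shared
# protein-phenotype pairs, phenotype-category proportion tests, and Storey
# pi1 replication rates.

#' Cross-tissue sign concordance of significant MR results
#'
#' For every (protein, phenotype) pair carried by two or more tissues among
#' the significant, colocalized records, the pair is concordant when all
#' tissue-level MR estimates share one sign.
#'
#' @param records MR records (columns `protein`, `phenotype`, `tissue`,
#'   `beta_mr`, and optionally `significant` which is filtered on when
#'   present).
#' @return list: `pairs` (one row per shared pair with `concordant` flag),
#'   `n_shared`, `n_concordant`, `percent` (half-up integer percent).
#' @export
concordance <- function(records) {
  if ("significant" %in% names(records))
    records <- records[records$significant, , drop = FALSE]
  key <- paste(records$protein, records$phenotype, sep = "\r")
  shared_keys <- names(which(
    tapply(records$tissue, key, function(t) length(unique(t))) >= 2))
  rows <- lapply(shared_keys, function(k) {
    r <- records[key == k, ]
    data.frame(protein = r$protein[1], phenotype = r$phenotype[1],
               n_tissues = length(unique(r$tissue)),
               concordant = length(unique(sign(r$beta_mr))) == 1L,
               stringsAsFactors = FALSE)
  })
  pairs <- if (length(rows)) do.call(rbind, rows)
           else data.frame(protein = character(0), phenotype = character(0),
                           n_tissues = integer(0), concordant = logical(0))
  n_shared <- nrow(pairs); n_conc <- sum(pairs$concordant)
  list(pairs = pairs, n_shared = n_shared, n_concordant = n_conc,
       percent = if (n_shared > 0) percent_round(100 * n_conc / n_shared)
                 else NA_real_)
}

#' Two-sided test of phenotype-category proportions between two tissues
#'
#' Chi-square test of homogeneity of the category count vectors. Categories
#' whose expected count falls below `pool_below` in any cell are pooled into
#' an "other" category first.
#'
#' @param counts_a,counts_b named nonnegative integer vectors over the same
#'   category universe.
#' @param pool_below expected-count threshold for pooling (default 1).
#' @return list: `p_value`, `statistic`, `df`, `pooled` (category names
#'   merged into "other").
#' @export
proportion_test <- function(counts_a, counts_b, pool_below = 1) {
  stop_if_not(length(counts_a) == length(counts_b),
              "count vectors must share the category universe")
  stop_if_not(sum(counts_a) > 0 && sum(counts_b) > 0, "zero-total input")
  tab <- rbind(a = counts_a, b = counts_b)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  low <- apply(exp_tab, 2, min) < pool_below
  pooled <- colnames(tab)[low] %||% character(0)
  if (any(low) && sum(!low) >= 1) {
    tab <- cbind(tab[, !low, drop = FALSE], other = rowSums(tab[, low,
                                                                drop = FALSE]))
  }
  tab <- tab[, colSums(tab) > 0, drop = FALSE]   # empty categories carry
  if (ncol(tab) < 2)                             # no information
    return(list(p_value = 1, statistic = 0, df = 0, pooled = pooled))
  # Yates continuity correction applies automatically for 2x2 tables
  ct <- suppressWarnings(stats::chisq.test(tab))
  list(p_value = ct$p.value, statistic = unname(ct$statistic),
       df = unname(ct$parameter), pooled = pooled)
}

#' Storey pi1 replication statistic
#'
#' Estimates pi0, the proportion of true nulls in a p-value set, by the
#' lambda-grid smoother: pi0(lambda) = mean(p > lambda)/(1 - lambda) on
#' lambda = 0.05, 0.10, ..., 0.95, smoothed with a natural cubic smoothing
#' spline (df = 3) and evaluated at the largest lambda, clipped to [0, 1].
#' pi1 = 1 - pi0 is the replication rate. A fixed-lambda estimator
#' (`method = "fixed"`, default lambda 0.5) is exposed for small m where
#' the smoother is unstable.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param method "smoother" (default) or "fixed".
#' @param lambda grid for the smoother (default seq(0.05, 0.95, 0.05)).
#' @param fixed_lambda lambda for the fixed estimator (default 0.5).
#' @return scalar pi1 in [0, 1].
#' @export
storey_pi1 <- function(pvalues, method = c("smoother", "fixed"),
                       lambda = seq(0.05, 0.95, by = 0.05),
                       fixed_lambda = 0.5) {
  method <- match.arg(method)
  stop_if_not(length(pvalues) > 0, "empty p-value input")
  stop_if_not(all(pvalues > 0 & pvalues <= 1), "p-values must lie in (0, 1]")
  if (method == "fixed") {
    pi0 <- mean(pvalues > fixed_lambda) / (1 - fixed_lambda)
  } else {
    pi0_l <- vapply(lambda, function(l) mean(pvalues > l) / (1 - l),
                    numeric(1))
    pi0 <- tryCatch({
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      stats::predict(fit, x = max(lambda))$y
    }, error = function(e) mean(pvalues > fixed_lambda) / (1 - fixed_lambda))
  }
  1 - min(max(pi0, 0), 1)
}
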