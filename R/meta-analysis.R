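# Fixed-effect meta-analysis in the two classic GWAS schemes
# (inverse-variance "STDERR" and sample-size-weighted "SAMPLESIZE") with
# Cochran-Q heterogeneity flags.

#' Inverse-variance-weighted fixed-effect meta-analysis (STDERR scheme)
#'
#' w_i = 1/se_i^2; beta_meta = sum(w_i b_i)/sum(w_i);
#' se_meta = 1/sqrt(sum(w_i)); two-sided normal p.
#'
#' @param beta per-study effect estimates (alleles pre-aligned to a common
#'   effect allele).
#' @param se per-study standard errors (> 0).
#' @param allow_single if TRUE a single study is passed through unchanged
#'   instead of raising an error.
#' @return list: `beta_meta`, `se_meta`, `p_meta`, `q_stat`, `het_pval`,
#'   `n_studies`.
#' @export
meta_fixed_stderr <- function(beta, se, allow_single = FALSE) {
  stop_if_not(length(beta) == length(se), "beta and se must align")
  stop_if_not(all(se > 0), "all standard errors must be positive")
  k <- length(beta)
  if (k < 2 && !allow_single)
    stop("need at least two studies (set allow_single to pass through)",
         call. = FALSE)
  w <- 1 / se^2
  bm <- sum(w * beta) / sum(w)
  sem <- 1 / sqrt(sum(w))
  het <- if (k >= 2) heterogeneity(beta = beta, se = se, scheme = "stderr")
         else list(q_stat = NA_real_, het_pval = NA_real_)
  list(beta_meta = bm, se_meta = sem,
       p_meta = 2 * stats::pnorm(-abs(bm / sem)),
       q_stat = het$q_stat, het_pval = het$het_pval, n_studies = k)
}

#' Sample-size-weighted meta-analysis (SAMPLESIZE scheme)
#'
#' With w_i = sqrt(n_i), z_meta = sum(w_i z_i) / sqrt(sum(w_i^2));
#' two-sided normal p. z-scores must already be sign-aligned to a common
#' effect allele.
#'
#' @param z per-study z-statistics (beta/se).
#' @param n per-study sample sizes.
#' @param allow_single as in [meta_fixed_stderr()].
#' @return list: `z_meta`, `p_z`, `q_stat`, `het_pval`, `n_studies`.
#' @export
meta_samplesize <- function(z, n, allow_single = FALSE) {
  stop_if_not(length(z) == length(n), "z and n must align")
  stop_if_not(all(is.finite(n) & n > 0), "missing or invalid sample sizes")
  k <- length(z)
  if (k < 2 && !allow_single)
    stop("need at least two studies (set allow_single to pass through)",
         call. = FALSE)
  w <- sqrt(n)
  zm <- sum(w * z) / sqrt(sum(w^2))
  het <- if (k >= 2) heterogeneity(z = z, n = n, scheme = "samplesize")
         else list(q_stat = NA_real_, het_pval = NA_real_)
  list(z_meta = zm, p_z = 2 * stats::pnorm(-abs(zm)),
       q_stat = het$q_stat, het_pval = het$het_pval, n_studies = k)
}

#' Cochran-Q heterogeneity statistic
#'
#' STDERR scheme: Q = sum w_i (b_i - beta_meta)^2 with w_i = 1/se_i^2.
#' SAMPLESIZE scheme: each z_i has unit variance, and under a homogeneous
#' standardized effect E(z_i) = z_meta sqrt(n_i / sum n); the scheme's Q is
#' the squared deviation of the observed z from that projection,
#' Q = sum (z_i - z_meta sqrt(n_i / sum n))^2, which is chi-square with
#' k - 1 df under homogeneity. Both het p-values are the upper chi-square
#' tail with n_studies - 1 df.
#'
#' @param beta,se per-study effects and SEs (STDERR scheme).
#' @param z,n per-study z-statistics and sample sizes (SAMPLESIZE scheme).
#' @param scheme "stderr" or "samplesize".
#' @return list: `q_stat`, `het_pval`, `df`.
#' @export
heterogeneity <- function(beta = NULL, se = NULL, z = NULL, n = NULL,
                          scheme = c("stderr", "samplesize")) {
  scheme <- match.arg(scheme)
  if (scheme == "stderr") {
    stop_if_not(length(beta) >= 2, "need at least two studies")
    stop_if_not(all(se > 0), "all standard errors must be positive")
    w <- 1 / se^2
    bm <- sum(w * beta) / sum(w)
    q <- sum(w * (beta - bm)^2)
    k <- length(beta)
  } else {
    stop_if_not(length(z) >= 2, "need at least two studies")
    w <- sqrt(n)
    zm <- sum(w * z) / sqrt(sum(w^2))
    q <- sum((z - zm * sqrt(n / sum(n)))^2)
    k <- length(z)
  }
  list(q_stat = q, het_pval = stats::pchisq(q, df = k - 1, lower.tail = FALSE),
       df = k - 1)
}

#' Meta-analyse per-study summary statistics across shared variants
#'
#' Aligns every study's alleles to the first (reference) study with the
#' harmonization rules of [harmonize()], then combines each variant under
#' both schemes and attaches the heterogeneity flags:
#' `flag_heterogeneity` (STDERR het p < 0.05), `flag_heterogeneity2`
#' (SAMPLESIZE het p < 0.05) and `flag_hetero.all` (both). Variants present
#' in a single study are passed through unflagged with `n_studies = 1`.
#'
#' @param studies named list of summary-statistics data.frames (columns
#'   `variant_id`, `ea`, `nea`, `eaf`, `beta`, `se`, `pval`, `n`).
#' @return data.frame with one row per variant: meta estimates under both
#'   schemes plus heterogeneity statistics and flags.
#' @export
meta_analyse <- function(studies) {
  stop_if_not(length(studies) >= 2, "need at least two studies")
  ref <- studies[[1]]
  aligned <- c(list(ref), lapply(studies[-1], align_to_reference, ref = ref))
  ids <- unique(unlist(lapply(aligned, `[[`, "variant_id")))
  rows <- lapply(ids, function(v) {
    per <- do.call(rbind, lapply(aligned, function(s)
      s[s$variant_id == v, c("beta", "se", "n"), drop = FALSE]))
    k <- nrow(per)
    st <- meta_fixed_stderr(per$beta, per$se, allow_single = TRUE)
    ss <- meta_samplesize(per$beta / per$se, per$n, allow_single = TRUE)
    f1 <- isTRUE(st$het_pval < 0.05)
    f2 <- isTRUE(ss$het_pval < 0.05)
    data.frame(variant_id = v,
               beta_meta = st$beta_meta, se_meta = st$se_meta,
               p_meta = st$p_meta, q_stderr = st$q_stat,
               het_pval_stderr = st$het_pval,
               z_meta = ss$z_meta, p_z = ss$p_z, q_samplesize = ss$q_stat,
               het_pval_samplesize = ss$het_pval,
               flag_heterogeneity = f1, flag_heterogeneity2 = f2,
               flag_hetero.all = f1 && f2,
               n_studies = k, n_total = sum(per$n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# align a study's alleles (and effect signs / EAFs) to the reference study
align_to_reference <- function(study, ref) {
  idx <- match(study$variant_id, ref$variant_id)
  keep <- rep(TRUE, nrow(study))
  for (i in which(!is.na(idx))) {
    r <- ref[idx[i], ]
    act <- allele_action(r$ea, r$nea, study$ea[i], study$nea[i],
                         r$eaf, study$eaf[i])
    if (act == "drop") { keep[i] <- FALSE; next }
    if (act %in% c("flip", "strand_flip_swap")) {
      study$beta[i] <- -study$beta[i]
      study$eaf[i] <- 1 - study$eaf[i]
    }
    study$ea[i] <- r$ea; study$nea[i] <- r$nea
  }
  study[keep, , drop = FALSE]
}
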