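# pQTL mapping: additive-model regression of protein level on genotype
# dosage with covariates, the principal-component-derived study-wide
# significance threshold, and cis/trans classification.

#' Fit additive-model pQTL regressions
#'
#' For every protein-variant pair, ordinary least squares of protein level
#' on dosage with covariates (plus intercept). Implemented by residualizing
#' both sides on the covariates (Frisch-Waugh), so the per-pair slope, its
#' standard error and the two-sided p-value from the t reference with
#' n - k - 2 degrees of freedom (k covariates) match the full multiple
#' regression exactly.
#'
#' @param proteins a [protein_matrix()] (log scale) or numeric matrix,
#'   samples x proteins.
#' @param panel a [genotype_panel()] with samples aligned to `proteins`.
#' @param covariates optional numeric sample x covariate matrix (age, sex,
#'   population-stratification PCs, platform indicators, ...).
#' @param maf_min minimum realized minor-allele frequency (default 0.02,
#'   the MAF >= 2\% genotype-QC convention); variants below it are skipped.
#' @return data.frame of association records: `protein`, `variant_id`,
#'   `chrom`, `pos`, `ea`, `nea`, `eaf`, `beta`, `se`, `tstat`, `pval`,
#'   `n`, `cis_flag` (NA until classified).
#' @export
fit_pqtl <- function(proteins, panel, covariates = NULL, maf_min = 0.02) {
  P <- if (inherits(proteins, "protein_matrix")) sample_values(proteins)
       else as.matrix(proteins)
  D <- panel$dosages
  if (!is.null(rownames(P)) && !is.null(rownames(D)) &&
      !identical(rownames(P), rownames(D))) {
    # QC may have dropped outlier samples; align the panel to the proteins
    idx <- match(rownames(P), rownames(D))
    stop_if_not(!anyNA(idx), "samples not aligned across inputs")
    D <- D[idx, , drop = FALSE]
    if (!is.null(covariates)) {
      covariates <- as.matrix(covariates)
      stop_if_not(nrow(covariates) == nrow(panel$dosages) ||
                    nrow(covariates) == nrow(P),
                  "covariates not aligned with samples")
      if (nrow(covariates) == nrow(panel$dosages))
        covariates <- covariates[idx, , drop = FALSE]
    }
  }
  stop_if_not(nrow(P) == nrow(D), "samples not aligned across inputs")
  n <- nrow(P)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  df <- n - k - 2L
  stop_if_not(df >= 1, "n too small for the covariate count")

  eaf <- colMeans(D) / 2
  keep <- pmin(eaf, 1 - eaf) >= maf_min
  stop_if_not(any(keep), "no variant passes the MAF filter")
  D <- D[, keep, drop = FALSE]

  X <- cbind(`(Intercept)` = rep(1, nrow(P)), covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient covariate matrix", call. = FALSE)
  Rd <- qr.resid(qx, D)
  Rp <- qr.resid(qx, P)
  sxx <- colSums(Rd^2)
  if (any(sxx < 1e-12))
    stop("zero-variance dosage after covariate adjustment", call. = FALSE)
  syy <- colSums(Rp^2)
  Sxy <- crossprod(Rd, Rp)                        # variants x proteins
  beta <- Sxy / sxx
  rss <- pmax(outer(rep(1, ncol(D)), syy) - beta * Sxy, 0)
  se <- sqrt(rss / df / sxx)
  tt <- beta / se
  vm <- panel$variant_meta[keep, , drop = FALSE]
  nv <- nrow(vm); np <- ncol(P)
  data.frame(
    protein = rep(colnames(P), each = nv),
    variant_id = rep(vm$variant_id, np),
    chrom = rep(vm$chrom, np), pos = rep(vm$pos, np),
    ea = rep(vm$ea, np), nea = rep(vm$nea, np),
    eaf = rep(colMeans(D) / 2, np),
    beta = as.vector(beta), se = as.vector(se), tstat = as.vector(tt),
    pval = as.vector(2 * stats::pt(-abs(tt), df = df)),
    n = n, cis_flag = NA, stringsAsFactors = FALSE)
}

#' Study-wide alpha from a principal-component count
#'
#' The multiple-testing threshold dividing genome-wide significance by the
#' number of principal components that explain 95\% of the proteomic
#' variance: alpha = 5e-8 / n_pcs. Filtering uses the unrounded value;
#' reports print it at one significant figure.
#'
#' @param n_pcs positive integer count of principal components.
#' @param genome_wide_alpha numerator (default 5e-8).
#' @return list: `study_wide_alpha` (unrounded) and
#'   `study_wide_alpha_printed` (one significant figure).
#' @export
study_wide_alpha <- function(n_pcs, genome_wide_alpha = 5e-8) {
  stop_if_not(n_pcs >= 1, "n_pcs must be a positive count")
  a <- genome_wide_alpha / n_pcs
  list(study_wide_alpha = a, study_wide_alpha_printed = signif(a, 1))
}

#' Derive the study-wide significance threshold from proteome PCs
#'
#' The number of principal components is the smallest k such that the top-k
#' PCs of the column-standardized protein matrix cumulatively explain at
#' least 95\% of the total variance; the study-wide alpha is
#' 5e-8 / n_pcs (unrounded; one-significant-figure rounding is applied only
#' when reporting).
#'
#' @param proteins a [protein_matrix()] or numeric matrix (>= 2 analytes).
#' @param var_explained cumulative variance target (default 0.95).
#' @return list of class `threshold_spec`: `n_pcs`, `study_wide_alpha`,
#'   `genome_wide_alpha` (5e-8), `study_wide_alpha_printed` (1 significant
#'   figure) and the per-PC variance fractions.
#' @export
derive_study_wide_threshold <- function(proteins, var_explained = 0.95) {
  P <- if (inherits(proteins, "protein_matrix")) sample_values(proteins)
       else as.matrix(proteins)
  stop_if_not(ncol(P) >= 2, "need at least two analytes")
  sds <- apply(P, 2, stats::sd)
  if (all(sds == 0)) stop("protein matrix has zero total variance",
                          call. = FALSE)
  Z <- scale(P[, sds > 0, drop = FALSE])
  d <- La.svd(Z, nu = 0, nv = 0)$d
  varfrac <- d^2 / sum(d^2)
  n_pcs <- which(cumsum(varfrac) >= var_explained)[1]
  alpha <- study_wide_alpha(n_pcs)
  structure(list(n_pcs = n_pcs,
                 study_wide_alpha = alpha$study_wide_alpha,
                 genome_wide_alpha = 5e-8,
                 study_wide_alpha_printed = alpha$study_wide_alpha_printed,
                 var_explained = varfrac),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("threshold_spec: n_pcs = %d, study-wide alpha = %.3g (printed %.0e)\n",
              x$n_pcs, x$study_wide_alpha, x$study_wide_alpha_printed))
  invisible(x)
}

#' Classify associations as cis or trans
#'
#' An association is cis when the variant lies on the same chromosome as the
#' protein's encoding gene and within `window` base pairs of its TSS
#' (closed interval); otherwise trans.
#'
#' @param assoc data.frame of association records from [fit_pqtl()].
#' @param genes annotation data.frame with columns `protein`, `chrom`, `tss`.
#' @param window cis window in bp (default 1e6).
#' @return `assoc` with `cis_flag` filled in.
#' @export
classify_cis_trans <- function(assoc, genes, window = 1e6) {
  idx <- match(assoc$protein, genes$protein)
  if (anyNA(idx))
    stop("missing gene annotation for: ",
         paste(unique(assoc$protein[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  assoc$cis_flag <- assoc$chrom == genes$chrom[idx] &
    abs(assoc$pos - genes$tss[idx]) <= window
  assoc
}
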