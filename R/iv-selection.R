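# Instrument selection: pleiotropy filter, LD clumping, F-statistic cutoff,
# under the cis-only (workflow-a, study-wide alpha) and cis+trans
# (workflow-b, genome-wide alpha) significance regimes.

#' Instrument strength F-statistic
#'
#' F = (beta/se)^2, the squared t-statistic of the association; F >= 10 is
#' the conventional weak-instrument cutoff.
#'
#' @param beta,se association effect and standard error (se > 0).
#' @return numeric F statistics.
#' @export
compute_f_stat <- function(beta, se) {
  stop_if_not(all(se > 0), "standard errors must be positive")
  (beta / se)^2
}

# squared Pearson correlation of two dosage vectors
dosage_r2 <- function(panel, v1, v2) {
  stats::cor(panel$dosages[, v1], panel$dosages[, v2])^2
}

#' Remove pleiotropic variants and their LD neighborhoods
#'
#' A variant significantly associated with `max_proteins` or more proteins
#' is a pleiotropic sentinel and is removed; so is any variant in LD with a
#' sentinel (r^2 >= `ld_r2` within `ld_window` bp on the same chromosome),
#' mirroring removal of the sentinel's LD block.
#'
#' @param assocs significance-filtered association records for all proteins
#'   in one tissue (columns `protein`, `variant_id`, `chrom`, `pos`, `pval`).
#' @param panel a [genotype_panel()] used to compute dosage r^2.
#' @param max_proteins pleiotropy bound: variants hitting fewer than this
#'   many proteins are retained (default 5).
#' @param alpha significance level defining "associated" (default 5e-8).
#' @param ld_r2 LD threshold for removing sentinel neighborhoods
#'   (default 0.1).
#' @param ld_window neighborhood window in bp (default 1e6).
#' @return `assocs` with pleiotropic sentinels and their LD neighbors
#'   removed; removed sentinel ids in `attr(, "sentinels")`.
#' @export
filter_pleiotropic <- function(assocs, panel, max_proteins = 5,
                               alpha = 5e-8, ld_r2 = 0.1, ld_window = 1e6) {
  sig <- assocs[assocs$pval < alpha, , drop = FALSE]
  hits <- tapply(sig$protein, sig$variant_id,
                 function(p) length(unique(p)))
  sentinels <- names(hits)[hits >= max_proteins]
  if (length(sentinels) == 0L) {
    attr(assocs, "sentinels") <- character(0)
    return(assocs)
  }
  vm <- panel$variant_meta
  drop_ids <- sentinels
  for (s in sentinels) {
    sv <- vm[vm$variant_id == s, ]
    nbr <- vm$variant_id[vm$chrom == sv$chrom &
                           abs(vm$pos - sv$pos) <= ld_window &
                           vm$variant_id != s]
    nbr <- nbr[nbr %in% assocs$variant_id]
    if (length(nbr)) {
      r2 <- vapply(nbr, function(v) dosage_r2(panel, s, v), numeric(1))
      drop_ids <- c(drop_ids, nbr[r2 >= ld_r2])
    }
  }
  out <- assocs[!(assocs$variant_id %in% drop_ids), , drop = FALSE]
  attr(out, "sentinels") <- sentinels
  out
}

#' Greedy LD clumping of one protein's associations
#'
#' Sorts by ascending p-value (ties broken by variant id) and accepts a
#' variant iff its dosage r^2 with every previously accepted variant stays
#' below `r2_threshold`.
#'
#' @param assocs one protein's association records.
#' @param panel a [genotype_panel()] covering all candidate variants.
#' @param r2_threshold pairwise r^2 ceiling (default 0.001).
#' @return `assocs` restricted to the clumped, independent variants.
#' @export
ld_clump <- function(assocs, panel, r2_threshold = 0.001) {
  miss <- setdiff(assocs$variant_id, colnames(panel$dosages))
  if (length(miss))
    stop("variants missing from panel: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(assocs) <= 1L) return(assocs)
  ord <- order(assocs$pval, assocs$variant_id)
  assocs <- assocs[ord, , drop = FALSE]
  accepted <- integer(0)
  for (i in seq_len(nrow(assocs))) {
    ok <- TRUE
    for (j in accepted) {
      if (dosage_r2(panel, assocs$variant_id[i],
                    assocs$variant_id[j]) >= r2_threshold) {
        ok <- FALSE; break
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  assocs[accepted, , drop = FALSE]
}

#' Select instrumental variables for every protein
#'
#' Applies, in order: the workflow significance filter (workflow "a": cis
#' variants at the study-wide alpha; workflow "b": cis and trans variants at
#' genome-wide 5e-8), the pleiotropy filter, LD clumping (r^2 < 0.001) and
#' the F >= 10 instrument-strength cutoff. Counts retained after each step
#' are recorded as provenance.
#'
#' @param assocs cis/trans-classified association records for one tissue.
#' @param panel a [genotype_panel()].
#' @param thresholds a `threshold_spec` from
#'   [derive_study_wide_threshold()].
#' @param workflow "a" (cis-only, study-wide) or "b" (cis+trans,
#'   genome-wide).
#' @param f_min instrument F cutoff (default 10).
#' @param max_proteins,ld_r2,ld_window passed to [filter_pleiotropic()].
#' @param clump_r2 passed to [ld_clump()] (default 0.001).
#' @return list of `instrument_set` objects (possibly with zero variants),
#'   one per protein that had any significant association.
#' @export
select_ivs <- function(assocs, panel, thresholds, workflow = c("a", "b"),
                       f_min = 10, max_proteins = 5, ld_r2 = 0.1,
                       ld_window = 1e6, clump_r2 = 0.001) {
  workflow <- match.arg(workflow)
  stop_if_not(!anyNA(assocs$cis_flag), "cis/trans must be classified first")
  sig <- if (workflow == "a") {
    assocs[assocs$cis_flag &
             assocs$pval <= thresholds$study_wide_alpha, , drop = FALSE]
  } else {
    assocs[assocs$pval < thresholds$genome_wide_alpha, , drop = FALSE]
  }
  proteins <- unique(assocs$protein)
  n_sig <- table(factor(sig$protein, levels = proteins))
  plei <- filter_pleiotropic(sig, panel, max_proteins = max_proteins,
                             alpha = thresholds$genome_wide_alpha,
                             ld_r2 = ld_r2, ld_window = ld_window)
  out <- list()
  for (p in proteins) {
    a <- plei[plei$protein == p, , drop = FALSE]
    n_plei <- nrow(a)
    a <- ld_clump(a, panel, r2_threshold = clump_r2)
    n_clump <- nrow(a)
    f <- compute_f_stat(a$beta, a$se)
    a <- a[f >= f_min, , drop = FALSE]
    out[[p]] <- structure(
      list(protein = p, workflow = workflow, variants = a,
           f_stats = f[f >= f_min],
           provenance = c(significant = as.integer(n_sig[[p]]),
                          post_pleiotropy = n_plei,
                          post_clump = n_clump,
                          post_f = nrow(a))),
      class = "instrument_set")
  }
  out
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set: %s, workflow-%s, %d instrument(s) [%s]\n",
              x$protein, x$workflow, nrow(x$variants),
              paste(names(x$provenance), x$provenance,
                    sep = "=", collapse = ", ")))
  invisible(x)
}
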