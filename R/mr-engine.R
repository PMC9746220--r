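# Two-sample MR: summary-statistic harmonization, Wald-ratio and IVW
# estimators, Benjamini-Hochberg FDR, Steiger directionality filtering, and
# the end-to-end workflow composition.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, nea) COMPLEMENT[[ea]] == nea

# decide how a second dataset's alleles relate to the reference orientation:
# "none" (already aligned), "strand_flip" (complement strand, sign kept),
# "flip" (effect/other swapped), "strand_flip_swap" (both), or "drop"
# (incompatible alleles / ambiguous palindromic variant).
allele_action <- function(ea1, nea1, ea2, nea2, eaf1 = NA, eaf2 = NA,
                          eaf_band = c(0.42, 0.58)) {
  if (is_palindromic(ea1, nea1)) {
    same_set <- setequal(c(ea2, nea2), c(ea1, nea1))
    if (!same_set) return("drop")
    ambiguous <- function(f) is.na(f) || (f >= eaf_band[1] && f <= eaf_band[2])
    if (ambiguous(eaf1) || ambiguous(eaf2)) return("drop")
    # orient so the effect allele is the one on the same frequency side
    f2 <- if (ea2 == ea1) eaf2 else 1 - eaf2
    if ((eaf1 < 0.5) == (f2 < 0.5)) {
      return(if (ea2 == ea1) "none" else "strand_flip")
    }
    return(if (ea2 == ea1) "flip" else "strand_flip_swap")
  }
  if (ea2 == ea1 && nea2 == nea1) return("none")
  if (ea2 == nea1 && nea2 == ea1) return("flip")
  ea2c <- COMPLEMENT[[ea2]]; nea2c <- COMPLEMENT[[nea2]]
  if (ea2c == ea1 && nea2c == nea1) return("strand_flip")
  if (ea2c == nea1 && nea2c == ea1) return("strand_flip_swap")
  "drop"
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches variants by chromosome and position (falling back to variant id)
#' and applies the four harmonization steps: (1) swapped effect/other
#' alleles are corrected by sign-flipping the outcome beta and reflecting
#' its EAF, (2) strand flips are resolved via A/T and C/G complements,
#' (3) palindromic (A/T, C/G) variants are oriented by allele frequency and
#' dropped when either EAF falls inside the ambiguity band, (4) variants
#' with incompatible alleles are dropped.
#'
#' @param exposure data.frame of instrument-level exposure statistics
#'   (columns `variant_id`, `chrom`, `pos`, `ea`, `nea`, `eaf`, `beta`,
#'   `se`, `n`), e.g. the `variants` element of an instrument set.
#' @param outcome outcome summary-statistics data.frame (same dialect).
#' @param eaf_band palindromic ambiguity band (default [0.42, 0.58]).
#' @return data.frame of harmonized pairs with columns `variant_id`, `ea`,
#'   `nea`, `beta_exp`, `se_exp`, `eaf_exp`, `n_exp`, `beta_out`, `se_out`,
#'   `eaf_out`, `n_out`, `action`, `kept`. Only `kept` rows enter
#'   estimation; dropped rows carry the reason in `action`.
#' @export
harmonize <- function(exposure, outcome, eaf_band = c(0.42, 0.58)) {
  if (inherits(exposure, "instrument_set")) exposure <- exposure$variants
  key <- function(d) {
    if (all(c("chrom", "pos") %in% names(d))) paste(d$chrom, d$pos)
    else d$variant_id
  }
  idx <- match(key(exposure), key(outcome))
  out <- lapply(seq_len(nrow(exposure)), function(i) {
    e <- exposure[i, ]
    row <- data.frame(variant_id = e$variant_id, ea = e$ea, nea = e$nea,
                      beta_exp = e$beta, se_exp = e$se, eaf_exp = e$eaf,
                      n_exp = e$n, beta_out = NA_real_, se_out = NA_real_,
                      eaf_out = NA_real_, n_out = NA_real_,
                      action = "drop_missing", kept = FALSE,
                      stringsAsFactors = FALSE)
    if (is.na(idx[i])) return(row)
    o <- outcome[idx[i], ]
    act <- allele_action(e$ea, e$nea, o$ea, o$nea, e$eaf, o$eaf, eaf_band)
    if (act == "drop") { row$action <- "drop_incompatible"; return(row) }
    flip <- act %in% c("flip", "strand_flip_swap")
    row$beta_out <- if (flip) -o$beta else o$beta
    row$eaf_out <- if (flip) 1 - o$eaf else o$eaf
    row$se_out <- o$se; row$n_out <- o$n
    row$action <- act; row$kept <- TRUE
    row
  })
  do.call(rbind, out)
}

#' Wald-ratio MR estimate from a single instrument
#'
#' beta_mr = beta_out / beta_exp; se_mr = se_out / |beta_exp| (first-order
#' delta method, exposure uncertainty ignored); two-sided normal p.
#'
#' @param beta_exp,se_exp instrument-exposure effect and SE.
#' @param beta_out,se_out instrument-outcome effect and SE.
#' @return list: `beta_mr`, `se_mr`, `p_mr`, `method = "wald"`, `n_ivs = 1`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  stop_if_not(beta_exp != 0, "exposure effect must be nonzero")
  b <- beta_out / beta_exp
  s <- se_out / abs(beta_exp)
  list(beta_mr = b, se_mr = s, p_mr = 2 * stats::pnorm(-abs(b / s)),
       method = "wald", n_ivs = 1L)
}

#' Inverse-variance-weighted MR estimate from multiple instruments
#'
#' Fixed-effect combination of the per-variant Wald ratios with weights
#' 1/se_ratio^2 — algebraically the zero-intercept weighted regression of
#' outcome betas on exposure betas with weights 1/se_out^2.
#'
#' @param pairs harmonized pairs (kept rows) with columns `beta_exp`,
#'   `beta_out`, `se_out`.
#' @return list: `beta_mr`, `se_mr`, `p_mr`, `method = "ivw"`, `n_ivs`.
#' @export
ivw <- function(pairs) {
  pairs <- pairs[pairs$kept %||% TRUE == TRUE, , drop = FALSE]
  stop_if_not(nrow(pairs) >= 2,
              "IVW needs >= 2 instruments; use wald_ratio for one")
  ratio <- pairs$beta_out / pairs$beta_exp
  se_r <- pairs$se_out / abs(pairs$beta_exp)
  w <- 1 / se_r^2
  b <- sum(w * ratio) / sum(w)
  s <- 1 / sqrt(sum(w))
  list(beta_mr = b, se_mr = s, p_mr = 2 * stats::pnorm(-abs(b / s)),
       method = "ivw", n_ivs = nrow(pairs))
}

#' Benjamini-Hochberg FDR adjustment within analysis scopes
#'
#' Adds a `fdr_q` column, adjusting within each combination of the scope
#' columns (default tissue x workflow, one FDR per analysis table).
#'
#' @param records data.frame with a `p_mr` column.
#' @param scope character vector of grouping column names present in
#'   `records`; scalar groups are fine (whole-table FDR).
#' @return `records` with `fdr_q`.
#' @export
fdr_adjust <- function(records, scope = intersect(c("tissue", "workflow"),
                                                 names(records))) {
  if (nrow(records) == 0L) { records$fdr_q <- numeric(0); return(records) }
  grp <- if (length(scope)) interaction(records[scope], drop = TRUE)
         else factor(rep(1, nrow(records)))
  records$fdr_q <- NA_real_
  for (g in levels(grp)) {
    i <- grp == g
    records$fdr_q[i] <- stats::p.adjust(records$p_mr[i], method = "BH")
  }
  records
}

#' Steiger directionality filter
#'
#' Converts instrument t-statistics to variance explained,
#' r^2 = t^2 / (t^2 + n - 2), summed over the instruments for each trait.
#' The inferred direction is correct when the instruments explain strictly
#' more variance in the exposure than in the outcome; the p-value compares
#' the two correlations by Fisher's z:
#' z = (atanh(r_exp) - atanh(r_out)) / sqrt(1/(n_exp-3) + 1/(n_out-3)).
#'
#' @param pairs harmonized, kept pairs with `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`.
#' @param n_exp,n_out exposure and outcome GWAS sample sizes (> 3).
#' @return list: `steiger_correct`, `steiger_p`, `r2_exp`, `r2_out`.
#' @export
steiger_filter <- function(pairs, n_exp, n_out) {
  stop_if_not(n_exp > 3 && n_out > 3, "sample sizes must exceed 3")
  pairs <- pairs[pairs$kept %||% TRUE == TRUE, , drop = FALSE]
  stop_if_not(nrow(pairs) >= 1, "no instruments")
  t_exp <- pairs$beta_exp / pairs$se_exp
  t_out <- pairs$beta_out / pairs$se_out
  r2_exp <- min(sum(t_exp^2 / (t_exp^2 + n_exp - 2)), 1 - 1e-12)
  r2_out <- min(sum(t_out^2 / (t_out^2 + n_out - 2)), 1 - 1e-12)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(steiger_correct = r2_exp > r2_out,
       steiger_p = 2 * stats::pnorm(-abs(z)),
       r2_exp = r2_exp, r2_out = r2_out)
}

#' Run the full MR + colocalization workflow on staged inputs
#'
#' Composes the pipeline within one tissue: pQTL mapping (or user-supplied
#' associations), threshold derivation, cis/trans classification, instrument
#' selection under the requested workflow(s), harmonization, Wald/IVW
#' estimation, Steiger filtering, per-instrument ABF colocalization with the
#' averaged PP.H4 rule, and BH-FDR within tissue x workflow. A record is
#' called significant iff fdr_q < 0.05 AND PP.H4 > 0.80 AND the Steiger
#' direction is correct. When both workflows run, results are combined by
#' union: pairs shared with workflow-a are labelled "cis-only", pairs unique
#' to workflow-b "trans-additional".
#'
#' @param config list with elements: `panel` (genotype_panel), `proteins`
#'   (clean log-scale protein_matrix), `outcomes` (named list of outcome
#'   summary-statistics data.frames), `genes` (annotation with `protein`,
#'   `chrom`, `tss`); optional `covariates`, `assoc` (precomputed
#'   associations), `thresholds` (threshold_spec), `tissue` (label, default
#'   "tissue1"), `workflow` ("a", "b" or "both"; default "both"),
#'   `coloc_window` (default 5e5), `priors` (default c(1e-4, 1e-4, 1e-5)),
#'   `prior_sd_exp` / `prior_sd_out` (default 0.15), `run_coloc` (default
#'   TRUE), `fdr_alpha` (default 0.05), `pp_threshold` (default 0.80).
#' @return data.frame of MR records: one row per protein x phenotype x
#'   workflow with estimate, FDR q, Steiger verdict, averaged PP.H4,
#'   significance call and workflow provenance.
#' @export
run_workflow <- function(config) {
  for (nm in c("panel", "proteins", "outcomes", "genes"))
    if (is.null(config[[nm]]))
      stop("config is missing '", nm, "'", call. = FALSE)
  panel <- config$panel
  tissue <- config$tissue %||% "tissue1"
  wf <- config$workflow %||% "both"
  wfs <- if (wf == "both") c("a", "b") else wf
  fdr_alpha <- config$fdr_alpha %||% 0.05
  pp_thr <- config$pp_threshold %||% 0.80
  run_coloc <- config$run_coloc %||% TRUE
  window <- config$coloc_window %||% 5e5
  priors <- config$priors %||% c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5)

  assoc <- config$assoc %||%
    fit_pqtl(config$proteins, panel, config$covariates)
  thresholds <- config$thresholds %||%
    derive_study_wide_threshold(config$proteins)
  assoc <- classify_cis_trans(assoc, config$genes)

  records <- list()
  for (w in wfs) {
    ivsets <- select_ivs(assoc, panel, thresholds, w)
    for (ivs in ivsets) {
      if (nrow(ivs$variants) == 0L) next
      for (ph in names(config$outcomes)) {
        outcome <- config$outcomes[[ph]]
        pairs <- harmonize(ivs$variants, outcome)
        kept <- pairs[pairs$kept, , drop = FALSE]
        if (nrow(kept) == 0L) next
        est <- if (nrow(kept) == 1L)
          wald_ratio(kept$beta_exp, kept$se_exp, kept$beta_out, kept$se_out)
        else ivw(kept)
        stg <- steiger_filter(kept, n_exp = kept$n_exp[1],
                              n_out = kept$n_out[1])
        pp4 <- NA_real_
        if (run_coloc) {
          pp4s <- vapply(seq_len(nrow(kept)), function(i) {
            v <- kept$variant_id[i]
            ctr <- assoc[assoc$variant_id == v, ][1, ]
            win_exp <- assoc[assoc$protein == ivs$protein &
                               assoc$chrom == ctr$chrom &
                               abs(assoc$pos - ctr$pos) <= window, ]
            win_out <- outcome[outcome$chrom == ctr$chrom &
                                 abs(outcome$pos - ctr$pos) <= window, ]
            res <- coloc_abf(win_exp, win_out, priors = priors,
                             prior_sd = c(config$prior_sd_exp %||% 0.15,
                                          config$prior_sd_out %||% 0.15))
            res$pp[["PP.H4"]]
          }, numeric(1))
          pp4 <- combine_pph4(pp4s)
        }
        records[[length(records) + 1L]] <- data.frame(
          protein = ivs$protein, phenotype = ph, tissue = tissue,
          workflow = w, n_ivs = est$n_ivs, method = est$method,
          beta_mr = est$beta_mr, se_mr = est$se_mr, p_mr = est$p_mr,
          steiger_correct = stg$steiger_correct, steiger_p = stg$steiger_p,
          pp_h4 = pp4, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(records) == 0L)
    return(data.frame(protein = character(0), phenotype = character(0),
                      tissue = character(0), workflow = character(0),
                      n_ivs = integer(0), method = character(0),
                      beta_mr = numeric(0), se_mr = numeric(0),
                      p_mr = numeric(0), steiger_correct = logical(0),
                      steiger_p = numeric(0), pp_h4 = numeric(0),
                      fdr_q = numeric(0), significant = logical(0),
                      iv_source = character(0), stringsAsFactors = FALSE))
  rec <- do.call(rbind, records)
  rec <- fdr_adjust(rec, scope = c("tissue", "workflow"))
  pp_ok <- if (run_coloc) rec$pp_h4 > pp_thr else TRUE
  rec$significant <- rec$fdr_q < fdr_alpha & pp_ok & rec$steiger_correct
  # combine workflows: union with provenance
  if (length(wfs) == 2L) {
    key <- paste(rec$protein, rec$phenotype)
    in_a <- unique(key[rec$workflow == "a"])
    rec$iv_source <- ifelse(key %in% in_a, "cis-only", "trans-additional")
  } else {
    rec$iv_source <- if (wfs == "a") "cis-only" else "trans-additional"
  }
  rec
}
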