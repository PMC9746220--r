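# Aptamer-proteomics quality control: four analyte-level filters
# (detection limit, plate scale-factor difference, calibrator coefficient of
# variation, 1.5-fold IQR on log10 values) followed by an iterative
# sample-outlier procedure.

QC_OUTLIER_FRAC <- 0.15   # "> 15% of the total" rule, strict inequality
QC_SCALE_MAX    <- 0.5
QC_CV_MAX       <- 0.15
QC_SHARED_FRAC  <- 0.80   # analytes shared by ~80% of sample outliers

#' Analyte-level QC filters
#'
#' Applies the four analyte filters to a raw protein matrix:
#' \enumerate{
#'   \item detection limit: LOD = mean(buffer wells) + 2 sd(buffer wells)
#'     per analyte; a study sample below the LOD is an outlier; the analyte
#'     fails when outliers exceed 15\% of samples;
#'   \item scale-factor difference: per analyte and plate, the calibration
#'     scale factor is median(reference) / median(plate calibrators), with
#'     reference the cross-plate median of plate calibrator medians; the
#'     analyte fails when the maximum absolute deviation from the median
#'     scale factor exceeds 0.5;
#'   \item calibrator coefficient of variation: sd/mean of pooled calibrator
#'     wells (sample sd, n-1); fails above 0.15;
#'   \item 1.5-fold IQR on log10 values (type-7 quartiles): a sample outside
#'     [Q1 - 1.5 IQR, Q3 + 1.5 IQR] is an outlier; fails when outliers
#'     exceed 15\% of samples. A zero IQR collapses the fence to the median.
#' }
#' An analyte is kept only when it passes all four. The primary removal
#' reason is the first failing filter in the order above.
#'
#' @param matrix a raw-scale (or log10-flagged) [protein_matrix()] with at
#'   least one buffer and two calibrator wells per plate.
#' @return list of class `qc_report` with per-analyte verdicts
#'   (`$analytes`), the per-sample-per-analyte IQR outlier matrix
#'   (`$iqr_outlier`), and the thresholds used (`$params`).
#' @export
filter_analytes <- function(matrix) {
  stop_if_not(inherits(matrix, "protein_matrix"), "need a protein_matrix")
  sm <- matrix$sample_meta
  raw <- if (matrix$log10) 10^matrix$values else matrix$values
  stop_if_not(all(raw > 0), "non-positive abundances")
  for (pl in unique(sm$plate[sm$role != "sample"])) {
    stop_if_not(sum(sm$role == "buffer" & sm$plate == pl) >= 1,
                paste("no buffer well on", pl))
    stop_if_not(sum(sm$role == "calibrator" & sm$plate == pl) >= 2,
                paste("fewer than two calibrator wells on", pl))
  }
  stop_if_not(any(sm$role == "buffer"), "no buffer wells")
  stop_if_not(sum(sm$role == "calibrator") >= 2, "too few calibrator wells")

  is_samp <- sm$role == "sample"
  S <- raw[is_samp, , drop = FALSE]
  n <- nrow(S)
  B <- raw[sm$role == "buffer", , drop = FALSE]
  Cw <- raw[sm$role == "calibrator", , drop = FALSE]
  cplate <- sm$plate[sm$role == "calibrator"]

  # (1) limit of detection
  lod <- colMeans(B) + 2 * apply(B, 2, stats::sd)
  lod_out <- colSums(S < matrix(lod, n, ncol(S), byrow = TRUE))
  lod_fail <- lod_out > QC_OUTLIER_FRAC * n

  # (2) scale-factor difference
  plate_med <- apply(Cw, 2, function(v) tapply(v, cplate, stats::median))
  if (is.null(dim(plate_med))) plate_med <- matrix(plate_med, nrow = 1)
  sf_diff <- apply(plate_med, 2, function(pm) {
    sf <- stats::median(pm) / pm
    max(abs(sf - stats::median(sf)))
  })
  scale_fail <- sf_diff > QC_SCALE_MAX

  # (3) calibrator coefficient of variation
  cv <- apply(Cw, 2, stats::sd) / colMeans(Cw)
  cv_fail <- cv > QC_CV_MAX

  # (4) 1.5-fold IQR on log10 values
  iqr_mat <- apply(log10(S), 2, iqr_outlier_flags)
  iqr_out <- colSums(iqr_mat)
  iqr_fail <- iqr_out > QC_OUTLIER_FRAC * n

  removed <- lod_fail | scale_fail | cv_fail | iqr_fail
  reason <- rep(NA_character_, ncol(S))
  reason[iqr_fail] <- "iqr"
  reason[cv_fail] <- "cv"
  reason[scale_fail] <- "scale_factor"
  reason[lod_fail] <- "lod"
  rep_df <- data.frame(
    analyte_id = colnames(S),
    lod_outliers = lod_out, lod_fail = lod_fail,
    scale_factor_diff = sf_diff, scale_fail = scale_fail,
    cv = cv, cv_fail = cv_fail,
    iqr_outliers = iqr_out, iqr_fail = iqr_fail,
    removed = removed, reason = reason,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(analytes = rep_df, iqr_outlier = iqr_mat,
                 samples = NULL, iterations = list(),
                 params = list(outlier_frac = QC_OUTLIER_FRAC,
                               scale_max = QC_SCALE_MAX, cv_max = QC_CV_MAX,
                               shared_frac = QC_SHARED_FRAC,
                               quartile_type = 7)),
            class = "qc_report")
}

# TRUE where x lies outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR]; zero IQR
# degenerates to "different from the median"
iqr_outlier_flags <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr
}

#' Iterative sample-outlier detection
#'
#' A sample is an outlier when it is an IQR outlier in more than 15\% of the
#' analytes that passed the analyte filters. Analytes that are outlying in at
#' least 80\% of those sample outliers are removed, sample outliers are
#' re-called once on the remaining analytes, and the final outlier samples
#' are marked for removal.
#'
#' The shared-analyte removal requires at least `min_outliers` flagged
#' samples: with a single outlying sample every analyte it deviates in would
#' be "shared by 100\%", and the blame belongs to the sample, not the
#' analytes.
#'
#' @param matrix the [protein_matrix()] passed to [filter_analytes()].
#' @param qc the `qc_report` returned by [filter_analytes()].
#' @param min_outliers minimum number of sample outliers before the
#'   shared-analyte removal applies (default 2).
#' @return the `qc_report` augmented with `$samples` (per-sample outlier
#'   fractions and verdicts) and analytes removed as shared sample-outlier
#'   carriers (reason `"shared_sample_outlier"`).
#' @export
detect_sample_outliers <- function(matrix, qc, min_outliers = 2) {
  stop_if_not(inherits(qc, "qc_report"), "need a qc_report")
  keep <- qc$analytes$analyte_id[!qc$analytes$removed]
  M <- qc$iqr_outlier[, keep, drop = FALSE]
  frac1 <- rowMeans(M)
  out1 <- frac1 > QC_OUTLIER_FRAC
  shared <- character(0)
  if (sum(out1) >= min_outliers) {
    shared_frac <- colMeans(M[out1, , drop = FALSE])
    shared <- keep[shared_frac >= QC_SHARED_FRAC]
  }
  keep2 <- setdiff(keep, shared)
  M2 <- qc$iqr_outlier[, keep2, drop = FALSE]
  frac2 <- rowMeans(M2)
  out2 <- frac2 > QC_OUTLIER_FRAC
  qc$analytes$removed[qc$analytes$analyte_id %in% shared] <- TRUE
  qc$analytes$reason[qc$analytes$analyte_id %in% shared] <-
    "shared_sample_outlier"
  qc$samples <- data.frame(
    sample_id = rownames(M),
    outlier_fraction = frac1, outlier_iter1 = out1,
    outlier_fraction2 = frac2, outlier = out2,
    row.names = NULL, stringsAsFactors = FALSE)
  qc$iterations <- list(
    list(n_sample_outliers = sum(out1), analytes_removed = shared),
    list(n_sample_outliers = sum(out2)))
  qc
}

#' Run the complete proteomics QC pipeline
#'
#' Applies [filter_analytes()] then [detect_sample_outliers()], and returns
#' the cleaned log10-scale matrix (failed analytes and outlier samples
#' dropped; calibrator and buffer wells retained so the result can be
#' re-validated) together with the full report. Idempotent: re-running on
#' the cleaned output removes nothing further on defect-free data.
#'
#' @param matrix a [protein_matrix()].
#' @return list with elements `matrix` (cleaned, log10 scale) and `report`.
#' @export
run_qc <- function(matrix) {
  qc <- filter_analytes(matrix)
  if (all(qc$analytes$removed))
    stop("all analytes removed by QC", call. = FALSE)
  qc <- detect_sample_outliers(matrix, qc)
  keep_analyte <- qc$analytes$analyte_id[!qc$analytes$removed]
  if (length(keep_analyte) == 0L)
    stop("all analytes removed by QC", call. = FALSE)
  drop_sample <- qc$samples$sample_id[qc$samples$outlier]
  sm <- matrix$sample_meta
  keep_row <- !(sm$sample_id %in% drop_sample & sm$role == "sample")
  vals <- matrix$values[keep_row, keep_analyte, drop = FALSE]
  if (!matrix$log10) vals <- log10(vals)
  cleaned <- protein_matrix(
    vals, sm[keep_row, , drop = FALSE],
    matrix$analyte_meta[matrix$analyte_meta$analyte_id %in% keep_analyte, ,
                        drop = FALSE],
    log10 = TRUE)
  list(matrix = cleaned, report = qc)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", sum(x$analytes$removed), "of", nrow(x$analytes),
      "analytes removed")
  if (!is.null(x$samples))
    cat(";", sum(x$samples$outlier), "sample outliers")
  cat("\n")
  invisible(x)
}
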