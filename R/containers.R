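# Lightweight S3 containers shared across the pipeline.

#' Construct a genotype panel
#'
#' Holds additive-coded dosages together with per-variant metadata and the
#' LD-block assignment used by the simulator and by LD-aware filters.
#'
#' @param dosages numeric sample x variant matrix with values in \{0, 1, 2\};
#'   column names are variant ids, row names sample ids.
#' @param variant_meta data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based), `ea` (effect allele), `nea` (other allele), `maf`
#'   (population minor-allele frequency of the effect allele).
#' @param block_map integer vector, one LD-block id per variant.
#' @return object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, variant_meta, block_map) {
  stop_if_not(is.matrix(dosages), "dosages must be a matrix")
  stop_if_not(ncol(dosages) == nrow(variant_meta),
              "variant_meta must have one row per dosage column")
  stop_if_not(all(colnames(dosages) == variant_meta$variant_id),
              "dosage columns must match variant_meta$variant_id")
  stop_if_not(length(block_map) == ncol(dosages),
              "block_map must have one entry per variant")
  # positions strictly increasing within each chromosome
  for (ch in unique(variant_meta$chrom)) {
    p <- variant_meta$pos[variant_meta$chrom == ch]
    stop_if_not(all(diff(p) > 0), "positions must strictly increase per chromosome")
  }
  structure(
    list(dosages = dosages, variant_meta = variant_meta,
         block_map = stats::setNames(block_map, variant_meta$variant_id)),
    class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "variants in", length(unique(x$block_map)), "LD blocks\n")
  invisible(x)
}

#' Construct a protein abundance matrix
#'
#' Samples-by-analytes abundances plus the well metadata (study sample,
#' calibrator, buffer; plate id) that the QC filters consume.
#'
#' @param values numeric sample x analyte matrix. Raw relative-fluorescence
#'   scale when `log10 = FALSE`, log10 scale otherwise.
#' @param sample_meta data.frame with columns `sample_id`, `role`
#'   (one of "sample", "calibrator", "buffer") and `plate`.
#' @param analyte_meta data.frame with columns `analyte_id`, `protein` and
#'   optionally `gene_id`.
#' @param log10 logical, whether `values` are already log10-transformed.
#' @return object of class `protein_matrix`.
#' @export
protein_matrix <- function(values, sample_meta, analyte_meta, log10 = FALSE) {
  stop_if_not(is.matrix(values), "values must be a matrix")
  stop_if_not(nrow(values) == nrow(sample_meta),
              "sample_meta must have one row per value row")
  stop_if_not(ncol(values) == nrow(analyte_meta),
              "analyte_meta must have one row per value column")
  stop_if_not(all(sample_meta$role %in% c("sample", "calibrator", "buffer")),
              "sample roles must be sample/calibrator/buffer")
  if (!log10 && any(values <= 0))
    stop("raw abundances must be strictly positive", call. = FALSE)
  rownames(values) <- sample_meta$sample_id
  colnames(values) <- analyte_meta$analyte_id
  structure(
    list(values = values, sample_meta = sample_meta,
         analyte_meta = analyte_meta, log10 = log10),
    class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  ns <- table(factor(x$sample_meta$role,
                     levels = c("sample", "calibrator", "buffer")))
  cat("protein_matrix:", ns[["sample"]], "samples (+", ns[["calibrator"]],
      "calibrator,", ns[["buffer"]], "buffer wells) x",
      ncol(x$values), "analytes;",
      if (x$log10) "log10" else "raw", "scale\n")
  invisible(x)
}

#' Extract study-sample rows of a protein matrix
#' @param x a `protein_matrix`.
#' @return numeric matrix restricted to wells with role "sample".
#' @export
sample_values <- function(x) {
  stop_if_not(inherits(x, "protein_matrix"), "x must be a protein_matrix")
  x$values[x$sample_meta$role == "sample", , drop = FALSE]
}
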