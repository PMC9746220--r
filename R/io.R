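# Tab-delimited I/O in the summary-statistics dialect used throughout:
# variant_id, chrom, pos, ea, nea, eaf, beta, se, pval, n.

SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "ea", "nea",
                   "eaf", "beta", "se", "pval", "n")

#' Write summary statistics to a TSV file
#' @param sumstats data.frame in the standard dialect.
#' @param path output file path.
#' @export
write_sumstats <- function(sumstats, path) {
  missing <- setdiff(SUMSTATS_COLS, names(sumstats))
  stop_if_not(length(missing) == 0,
              paste("missing columns:", paste(missing, collapse = ", ")))
  utils::write.table(sumstats[SUMSTATS_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Read summary statistics from a TSV file
#' @param path file path written by [write_sumstats()] or any
#'   tab-delimited file with the standard header.
#' @return data.frame in the standard dialect.
#' @export
read_sumstats <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(SUMSTATS_COLS, names(d))
  stop_if_not(length(missing) == 0,
              paste("missing columns:", paste(missing, collapse = ", ")))
  d
}

#' Write a protein matrix as TSV plus a sample-metadata sidecar
#' @param x a [protein_matrix()].
#' @param values_path,meta_path output paths for the abundance table and the
#'   sample-metadata sidecar (sample_id, role, plate).
#' @export
write_protein_matrix <- function(x, values_path, meta_path) {
  stop_if_not(inherits(x, "protein_matrix"), "x must be a protein_matrix")
  v <- data.frame(sample_id = rownames(x$values), x$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(v, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$sample_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a protein matrix written by [write_protein_matrix()]
#' @param values_path,meta_path the two files.
#' @param log10 whether the stored values are log10 scale (default FALSE).
#' @return a [protein_matrix()]; analyte metadata is reconstructed minimally
#'   from the column names.
#' @export
read_protein_matrix <- function(values_path, meta_path, log10 = FALSE) {
  v <- utils::read.delim(values_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(v[, -1, drop = FALSE])
  rownames(m) <- v$sample_id
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  ameta <- data.frame(analyte_id = colnames(m), protein = colnames(m),
                      stringsAsFactors = FALSE)
  protein_matrix(m, meta[match(rownames(m), meta$sample_id), , drop = FALSE],
                 ameta, log10 = log10)
}
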