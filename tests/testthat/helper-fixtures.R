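# Shared fixture builders. All fixtures are generated in code at test time.

# small multi-block panel: nb blocks of nv variants each
fixture_panel <- function(n = 500, nb = 4, nv = 10, rho = 0.5,
                          maf = c(0.1, 0.5), seed = 11) {
  simulate_genotypes(n, rep(list(list(n_variants = nv, rho = rho,
                                      maf = maf)), nb), seed = seed)
}

# hand-built protein_matrix: one plate per block of samples, with clean
# calibrator and buffer wells appended; `samples` is samples x analytes raw
toy_plate_matrix <- function(samples, n_plates = 1,
                             calib = NULL, buffer = NULL) {
  m <- ncol(samples)
  analytes <- colnames(samples) %||% sprintf("an%02d", seq_len(m))
  colnames(samples) <- analytes
  if (is.null(rownames(samples)))
    rownames(samples) <- sprintf("s%03d", seq_len(nrow(samples)))
  plate <- rep_len(sprintf("p%d", seq_len(n_plates)), nrow(samples))
  calw <- list(); bufw <- list(); meta <- list()
  for (p in seq_len(n_plates)) {
    pl <- sprintf("p%d", p)
    cw <- if (is.null(calib)) {
      matrix(rep(apply(samples, 2, stats::median), each = 3) *
               rep(c(0.98, 1, 1.02), m), 3, m)
    } else calib[[p]]
    colnames(cw) <- analytes
    rownames(cw) <- sprintf("%s_cal%d", pl, seq_len(nrow(cw)))
    bw <- if (is.null(buffer)) {
      matrix(rep(apply(samples, 2, min) / 100, each = 2) * c(0.9, 1.1), 2, m)
    } else buffer[[p]]
    colnames(bw) <- analytes
    rownames(bw) <- sprintf("%s_buf%d", pl, seq_len(nrow(bw)))
    calw[[p]] <- cw; bufw[[p]] <- bw
    meta[[p]] <- data.frame(
      sample_id = c(rownames(cw), rownames(bw)),
      role = c(rep("calibrator", nrow(cw)), rep("buffer", nrow(bw))),
      plate = pl, stringsAsFactors = FALSE)
  }
  values <- rbind(samples, do.call(rbind, calw), do.call(rbind, bufw))
  smeta <- rbind(
    data.frame(sample_id = rownames(samples), role = "sample",
               plate = plate, stringsAsFactors = FALSE),
    do.call(rbind, meta))
  ameta <- data.frame(analyte_id = analytes, protein = analytes,
                      stringsAsFactors = FALSE)
  protein_matrix(values, smeta, ameta, log10 = FALSE)
}

# minimal association-record data.frame for IV-selection tests
assoc_df <- function(protein, variant_id, pval, beta = 1, se = 0.1,
                     chrom = 1, pos = seq_along(variant_id) * 1000,
                     cis_flag = TRUE, eaf = 0.3, n = 500) {
  data.frame(protein = protein, variant_id = variant_id, chrom = chrom,
             pos = pos, ea = "A", nea = "G", eaf = eaf, beta = beta,
             se = se, tstat = beta / se, pval = pval, n = n,
             cis_flag = cis_flag, stringsAsFactors = FALSE)
}

# one-variant exposure/outcome simulation used in MR recovery checks:
# protein <- b_cis * dosage; outcome <- theta * protein (+ noise)
simulate_mr_pair <- function(n = 2000, maf = 0.3, b_cis = 0.5, theta = 0.3,
                             seed = 1) {
  panel <- simulate_genotypes(n, list(list(n_variants = 1, rho = 0,
                                           maf = c(maf, maf))), seed = seed)
  man <- make_truth_manifest(panel, n_proteins = 1, n_outcomes = 1,
                             b_cis = b_cis,
                             theta = matrix(theta, 1, 1), seed = seed + 1)
  prot <- simulate_proteins(panel, man, noise_sd = 1, seed = seed + 2)
  gw <- simulate_outcome_gwas(panel, prot, man, outcome_noise_sd = 1,
                              seed = seed + 3)
  exposure <- marginal_gwas(panel, sample_values(prot)[, 1])
  list(panel = panel, manifest = man, exposure = exposure,
       outcome = gw[[1]])
}
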