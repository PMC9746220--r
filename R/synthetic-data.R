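# Synthetic-data generator: LD-blocked genotypes, proteomes with known cis /
# trans architecture, outcome GWAS with known protein-mediated causal effects,
# and raw proteomic plates with injected QC failures. The generator is
# first-class code: every downstream recovery test is phrased against the
# ground truth recorded here.

#' Simulate LD-blocked genotype dosages
#'
#' Genotypes are drawn with a Gaussian copula: per haplotype, a latent AR(1)
#' normal vector is thresholded at the allele-frequency quantile, and the two
#' haplotype indicators are summed to an additive dosage in \{0,1,2\}. This
#' yields Hardy-Weinberg genotypes with controllable within-block LD and
#' independent blocks. Thresholding attenuates the latent correlation, so
#' the latent AR(1) coefficient of each adjacent pair is calibrated (by
#' inverting the bivariate-normal quadrant probability) so that the realized
#' adjacent dosage correlation equals the requested `rho`; adjacent r^2 is
#' therefore rho^2 by design, up to sampling noise and the Frechet bound of
#' the MAF pair. Each block sits on its own chromosome, positions 5 kb apart.
#'
#' @param n_samples number of individuals (>= 2).
#' @param blocks list of blocks, each a list with elements `n_variants`,
#'   `rho` (latent AR(1) autocorrelation, 0 <= rho < 1) and `maf`
#'   (length-2 range within [0.02, 0.5] from which per-variant MAFs are
#'   drawn uniformly, matching the MAF >= 2\% genotype-QC convention).
#' @param seed integer RNG seed; fixed seeds reproduce identical panels.
#' @param pos_step base-pair spacing between adjacent variants (default 5000).
#' @return a [genotype_panel()].
#' @export
simulate_genotypes <- function(n_samples, blocks, seed, pos_step = 5000) {
  stop_if_not(n_samples >= 2, "n_samples must be >= 2")
  set.seed(as.integer(seed))
  mats <- list(); meta <- list(); bmap <- integer(0)
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    m <- blk$n_variants
    rho <- blk$rho %||% 0
    mafr <- blk$maf %||% c(0.05, 0.5)
    stop_if_not(m >= 1, "block sizes must be positive")
    stop_if_not(rho >= 0 && rho < 1, "rho must lie in [0, 1)")
    stop_if_not(all(mafr > 0) && all(mafr <= 0.5),
                "MAF range must lie within (0, 0.5]")
    maf <- stats::runif(m, mafr[1], mafr[2])
    lat <- if (m > 1 && rho > 0)
      vapply(seq_len(m - 1), function(j)
        latent_rho_for(maf[j], maf[j + 1], rho), numeric(1))
    else numeric(0)
    dos <- ar1_haplotypes(n_samples, m, lat, maf) +
      ar1_haplotypes(n_samples, m, lat, maf)
    ids <- sprintf("chr%d_v%d", b, seq_len(m))
    colnames(dos) <- ids
    mats[[b]] <- dos
    meta[[b]] <- data.frame(
      variant_id = ids, chrom = b, pos = 1e6 + (seq_len(m) - 1L) * pos_step,
      ea = "A", nea = "G", maf = maf, stringsAsFactors = FALSE)
    bmap <- c(bmap, rep.int(b, m))
  }
  dosages <- do.call(cbind, mats)
  rownames(dosages) <- sprintf("s%04d", seq_len(n_samples))
  genotype_panel(dosages, do.call(rbind, meta), bmap)
}

# one haplotype per row: latent AR(1) normals (per-step correlations `lat`)
# thresholded at qnorm(1 - maf)
ar1_haplotypes <- function(n, m, lat, maf) {
  z <- matrix(stats::rnorm(n * m), n, m)
  if (m > 1 && length(lat)) {
    for (j in 2:m) {
      l <- lat[j - 1]
      z[, j] <- l * z[, j - 1] + sqrt(1 - l^2) * z[, j]
    }
  }
  # effect allele carried when the latent value exceeds the upper-maf quantile
  (z > matrix(stats::qnorm(1 - maf), n, m, byrow = TRUE)) + 0L
}

# P(Z1 > t1, Z2 > t2) under a standard bivariate normal with correlation rho
bvn_quadrant <- function(t1, t2, rho) {
  stats::integrate(function(z) stats::dnorm(z) *
                     stats::pnorm((rho * z - t2) / sqrt(1 - rho^2)),
                   t1, Inf, rel.tol = 1e-9)$value
}

# correlation of the two thresholded allele indicators given latent rho
threshold_cor <- function(maf1, maf2, rho) {
  t1 <- stats::qnorm(1 - maf1); t2 <- stats::qnorm(1 - maf2)
  (bvn_quadrant(t1, t2, rho) - maf1 * maf2) /
    sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

# latent correlation delivering an indicator (= dosage) correlation of
# `target`; capped when the MAF pair's Frechet bound is tighter
latent_rho_for <- function(maf1, maf2, target) {
  upper <- 0.9999
  if (threshold_cor(maf1, maf2, upper) <= target) return(upper)
  stats::uniroot(function(l) threshold_cor(maf1, maf2, l) - target,
                 lower = target, upper = upper, tol = 1e-6)$root
}

#' Build a ground-truth manifest for a simulated study
#'
#' Assigns one cis variant (with effect `b_cis`) per protein, an encoding-gene
#' TSS at that variant's position, optional trans effects, optional
#' pleiotropic hub variants affecting at least `hub_targets` proteins, a
#' protein-to-outcome causal-effect matrix `theta`, and optional direct
#' variant-to-outcome effects (confounding pleiotropy).
#'
#' @param panel a [genotype_panel()].
#' @param n_proteins number of simulated proteins; each is given a distinct
#'   cis variant (cyclically over LD blocks, one variant per protein).
#' @param n_outcomes number of outcome phenotypes.
#' @param b_cis cis effect size per allele (default 0.5, scalar or vector).
#' @param theta protein x outcome causal-effect matrix; default all zero.
#' @param n_hubs number of pleiotropic hub variants (default 0).
#' @param hub_targets number of proteins each hub affects (default 5).
#' @param b_trans trans/hub effect size (default 0.3).
#' @param direct_effects data.frame (`variant_id`, `outcome`, `beta`) of
#'   direct variant-to-outcome effects, or NULL.
#' @param cis_window bp window within which a cis variant must sit relative
#'   to its gene's TSS (default 1e6); TSS placement respects it by
#'   construction.
#' @param seed integer seed recorded in the manifest.
#' @return object of class `truth_manifest` with elements `cis`, `trans`,
#'   `hubs`, `theta`, `direct`, `genes`, `cis_window`, `seed`.
#' @export
make_truth_manifest <- function(panel, n_proteins, n_outcomes = 1,
                                b_cis = 0.5, theta = NULL,
                                n_hubs = 0, hub_targets = 5, b_trans = 0.3,
                                direct_effects = NULL, cis_window = 1e6,
                                seed = 1) {
  set.seed(as.integer(seed))
  vm <- panel$variant_meta
  stop_if_not(n_proteins <= nrow(vm),
              "need at least one variant per protein")
  proteins <- sprintf("prot%03d", seq_len(n_proteins))
  outcomes <- sprintf("pheno%02d", seq_len(n_outcomes))
  # spread cis variants across blocks: first variant of block 1, block 2, ...
  ord <- order(panel$block_map, vm$pos)
  by_block <- split(ord, panel$block_map[ord])
  pick <- integer(n_proteins)
  k <- 1L
  for (depth in seq_len(max(lengths(by_block)))) {
    for (blk in by_block) {
      if (depth <= length(blk) && k <= n_proteins) {
        pick[k] <- blk[depth]; k <- k + 1L
      }
    }
    if (k > n_proteins) break
  }
  cis <- data.frame(protein = proteins, variant_id = vm$variant_id[pick],
                    beta = rep_len(b_cis, n_proteins),
                    stringsAsFactors = FALSE)
  genes <- data.frame(protein = proteins,
                      gene_id = sprintf("GENE%03d", seq_len(n_proteins)),
                      chrom = vm$chrom[pick],
                      tss = pmax(1, vm$pos[pick] - 1000L),
                      stringsAsFactors = FALSE)
  trans <- data.frame(protein = character(0), variant_id = character(0),
                      beta = numeric(0), stringsAsFactors = FALSE)
  hubs <- character(0)
  if (n_hubs > 0) {
    stop_if_not(hub_targets >= 1 && hub_targets <= n_proteins,
                "hub_targets must be in [1, n_proteins]")
    free <- setdiff(seq_len(nrow(vm)), pick)
    stop_if_not(length(free) >= n_hubs, "not enough variants for hubs")
    hub_idx <- sample(free, n_hubs)
    hubs <- vm$variant_id[hub_idx]
    for (h in hubs) {
      tgt <- sample(proteins, hub_targets)
      trans <- rbind(trans, data.frame(protein = tgt, variant_id = h,
                                       beta = b_trans,
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(theta)) {
    theta <- matrix(0, n_proteins, n_outcomes)
  }
  dimnames(theta) <- list(proteins, outcomes)
  if (!is.null(direct_effects)) {
    stop_if_not(all(direct_effects$variant_id %in% vm$variant_id),
                "direct_effects reference unknown variants")
  }
  structure(list(cis = cis, trans = trans, hubs = hubs, theta = theta,
                 direct = direct_effects, genes = genes,
                 cis_window = cis_window, seed = as.integer(seed)),
            class = "truth_manifest")
}

#' Simulate log-scale protein abundances from a genotype panel
#'
#' Each protein is the linear genetic predictor from the manifest (cis plus
#' trans terms), plus covariate effects, plus independent Gaussian noise:
#' protein_j = sum(b * dosage) + covariates \%*\% gamma_j + eps,
#' eps ~ N(0, noise_sd^2). Abundances are on the log scale (interpreted as
#' log10 relative-fluorescence units by the raw-plate generator).
#'
#' @param panel a [genotype_panel()].
#' @param manifest a `truth_manifest`.
#' @param covariates optional numeric sample x covariate matrix.
#' @param gamma optional covariate x protein coefficient matrix (default 0).
#' @param noise_sd residual standard deviation (> 0 unless exactly 0 for
#'   noiseless checks).
#' @param seed integer RNG seed.
#' @return a log10-scale [protein_matrix()] with all wells of role "sample".
#' @export
simulate_proteins <- function(panel, manifest, covariates = NULL,
                              gamma = NULL, noise_sd = 1, seed = 1) {
  set.seed(as.integer(seed))
  D <- panel$dosages
  n <- nrow(D)
  proteins <- manifest$cis$protein
  P <- matrix(0, n, length(proteins),
              dimnames = list(rownames(D), proteins))
  eff <- rbind(manifest$cis,
               manifest$trans[, c("protein", "variant_id", "beta")])
  miss <- setdiff(eff$variant_id, colnames(D))
  if (length(miss))
    stop("manifest references variants absent from the panel: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(eff))) {
    p <- eff$protein[i]
    P[, p] <- P[, p] + eff$beta[i] * D[, eff$variant_id[i]]
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(gamma)) gamma <- matrix(0, ncol(covariates), length(proteins))
    P <- P + covariates %*% gamma
  }
  P <- P + matrix(stats::rnorm(length(P), sd = noise_sd), nrow(P))
  smeta <- data.frame(sample_id = rownames(D), role = "sample", plate = NA,
                      stringsAsFactors = FALSE)
  ameta <- data.frame(analyte_id = proteins, protein = proteins,
                      gene_id = manifest$genes$gene_id,
                      stringsAsFactors = FALSE)
  protein_matrix(P, smeta, ameta, log10 = TRUE)
}

#' Per-variant marginal GWAS of one quantitative trait
#'
#' Simple-regression summary statistics (beta, SE, two-sided p from the t
#' reference with n - 2 df, EAF, N) of `y` on each dosage column.
#'
#' @param panel a [genotype_panel()].
#' @param y numeric phenotype vector aligned with the panel's samples.
#' @return data.frame in the summary-statistics dialect: `variant_id`,
#'   `chrom`, `pos`, `ea`, `nea`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @export
marginal_gwas <- function(panel, y) {
  D <- panel$dosages
  stop_if_not(length(y) == nrow(D), "y must align with panel samples")
  n <- nrow(D)
  yc <- y - mean(y)
  Dc <- scale(D, center = TRUE, scale = FALSE)
  sxx <- colSums(Dc^2)
  stop_if_not(all(sxx > 0), "monomorphic variant in panel")
  beta <- as.vector(crossprod(Dc, yc)) / sxx
  rss <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  tt <- beta / se
  data.frame(variant_id = panel$variant_meta$variant_id,
             chrom = panel$variant_meta$chrom,
             pos = panel$variant_meta$pos,
             ea = panel$variant_meta$ea, nea = panel$variant_meta$nea,
             eaf = colMeans(D) / 2,
             beta = beta, se = se,
             pval = 2 * stats::pt(-abs(tt), df = n - 2),
             n = n, stringsAsFactors = FALSE)
}

#' Simulate outcome phenotypes and their GWAS summary statistics
#'
#' Outcomes follow y = proteins \%*\% theta + direct variant effects + noise;
#' marginal per-variant summary statistics are then emitted for every panel
#' variant, emulating an external outcome GWAS.
#'
#' @param panel a [genotype_panel()].
#' @param proteins a [protein_matrix()] from [simulate_proteins()].
#' @param manifest the `truth_manifest` holding `theta` and `direct`.
#' @param outcome_noise_sd residual SD of the outcomes (default 1).
#' @param seed integer RNG seed.
#' @return named list (one element per outcome) of summary-statistics
#'   data.frames as produced by [marginal_gwas()]; the simulated phenotype
#'   vectors are attached as `attr(, "phenotypes")`.
#' @export
simulate_outcome_gwas <- function(panel, proteins, manifest,
                                  outcome_noise_sd = 1, seed = 1) {
  set.seed(as.integer(seed))
  P <- sample_values(proteins)
  theta <- manifest$theta
  stop_if_not(all(rownames(theta) %in% colnames(P)),
              "theta must be defined for all proteins")
  n <- nrow(P)
  Y <- P[, rownames(theta), drop = FALSE] %*% theta
  if (!is.null(manifest$direct)) {
    for (i in seq_len(nrow(manifest$direct))) {
      o <- manifest$direct$outcome[i]
      Y[, o] <- Y[, o] +
        manifest$direct$beta[i] * panel$dosages[, manifest$direct$variant_id[i]]
    }
  }
  Y <- Y + matrix(stats::rnorm(length(Y), sd = outcome_noise_sd), n)
  out <- lapply(colnames(theta), function(o) marginal_gwas(panel, Y[, o]))
  names(out) <- colnames(theta)
  attr(out, "phenotypes") <- Y
  out
}

#' Generate raw proteomic plates with injected QC defects
#'
#' Converts a clean log10-scale protein matrix to the raw
#' relative-fluorescence scale, attaches per-plate calibrator (8 wells) and
#' buffer (4 wells) metadata, and injects requested defects. Injected defects
#' are recorded in a ledger (`attr(, "defect_ledger")`) so QC tests can
#' assert exact recovery.
#'
#' Defect types: `"lod"` (a fraction of samples pushed below the detection
#' limit), `"cv"` (calibrator coefficient of variation set above the 0.15
#' threshold), `"scale"` (one plate's calibrators rescaled so the
#' scale-factor difference exceeds 0.5), `"iqr"` (a fraction of samples
#' shifted far outside the 1.5 IQR fence), `"sample"` (one sample made an
#' outlier in a fraction of analytes).
#'
#' @param clean log10-scale [protein_matrix()] of study samples.
#' @param failures list of defect specs, each a list with `type` and an
#'   `analyte` (for analyte defects) or `sample` (for sample defects), plus
#'   optional `fraction` (default 0.2) or `cv` (default 0.30).
#' @param seed integer RNG seed.
#' @param n_plates number of plates samples are split over (default 3).
#' @param calib_cv calibrator coefficient of variation for clean analytes
#'   (default 0.05, well under the 0.15 failure threshold).
#' @return raw-scale [protein_matrix()] including calibrator and buffer
#'   wells, with the defect ledger attached.
#' @export
make_raw_proteomics <- function(clean, failures = list(), seed = 1,
                                n_plates = 3, calib_cv = 0.05) {
  set.seed(as.integer(seed))
  stop_if_not(inherits(clean, "protein_matrix") && clean$log10,
              "clean must be a log10-scale protein_matrix")
  V <- sample_values(clean)
  # shift to a positive RFU-like scale before exponentiating
  raw <- 10^(V + 3)
  n <- nrow(raw); m <- ncol(raw)
  analytes <- colnames(raw)
  keyed <- vapply(failures, function(f) paste(f$type, f$analyte %||% f$sample),
                  character(1))
  if (anyDuplicated(keyed))
    stop("overlapping contradictory defect specs", call. = FALSE)
  for (f in failures) {
    if (f$type %in% c("lod", "cv", "scale", "iqr"))
      stop_if_not(f$analyte %in% analytes,
                  paste("unknown analyte", f$analyte))
    if (f$type == "sample")
      stop_if_not(f$sample %in% rownames(raw),
                  paste("unknown sample", f$sample))
  }
  plate <- rep_len(sprintf("plate%02d", seq_len(n_plates)), n)

  # per-analyte reference level for calibrators; background for buffers
  ref <- apply(raw, 2, stats::median)
  buffer_mean <- apply(raw, 2, min) / 100
  calib <- list(); buff <- list(); cmeta <- list(); bmeta <- list()
  for (p in seq_len(n_plates)) {
    pl <- sprintf("plate%02d", p)
    cw <- sapply(seq_len(m), function(j)
      exact_cv_sample(8, ref[j], calib_cv))
    colnames(cw) <- analytes
    rownames(cw) <- sprintf("%s_cal%d", pl, seq_len(8))
    bw <- sapply(seq_len(m), function(j)
      abs(stats::rnorm(4, buffer_mean[j], buffer_mean[j] * 0.1)) + 1e-6)
    colnames(bw) <- analytes
    rownames(bw) <- sprintf("%s_buf%d", pl, seq_len(4))
    calib[[p]] <- cw; buff[[p]] <- bw
    cmeta[[p]] <- data.frame(sample_id = rownames(cw), role = "calibrator",
                             plate = pl, stringsAsFactors = FALSE)
    bmeta[[p]] <- data.frame(sample_id = rownames(bw), role = "buffer",
                             plate = pl, stringsAsFactors = FALSE)
  }
  calib <- do.call(rbind, calib); buff <- do.call(rbind, buff)

  ledger <- data.frame(id = character(0), type = character(0),
                       stringsAsFactors = FALSE)
  for (f in failures) {
    frac <- f$fraction %||% 0.2
    switch(
      f$type,
      lod = {
        lod <- mean(buff[, f$analyte]) + 2 * stats::sd(buff[, f$analyte])
        idx <- sample(n, ceiling(frac * n))
        raw[idx, f$analyte] <- lod * 0.5
      },
      cv = {
        bad_cv <- f$cv %||% 0.30
        for (p in seq_len(n_plates)) {
          rows <- grep(sprintf("plate%02d_cal", p), rownames(calib))
          calib[rows, f$analyte] <-
            exact_cv_sample(length(rows), ref[f$analyte], bad_cv)
        }
      },
      scale = {
        rows <- grep("plate01_cal", rownames(calib))
        calib[rows, f$analyte] <- calib[rows, f$analyte] * 3
      },
      iqr = {
        idx <- sample(n, ceiling(frac * n))
        raw[idx, f$analyte] <- raw[idx, f$analyte] * 1e5
      },
      sample = {
        idx <- sample(m, ceiling(frac * m))
        raw[f$sample, idx] <- raw[f$sample, idx] * 1e5
      },
      stop("unknown defect type: ", f$type, call. = FALSE))
    ledger <- rbind(ledger, data.frame(id = f$analyte %||% f$sample,
                                       type = f$type,
                                       stringsAsFactors = FALSE))
  }

  values <- rbind(raw, calib, buff)
  smeta <- rbind(
    data.frame(sample_id = rownames(raw), role = "sample", plate = plate,
               stringsAsFactors = FALSE),
    do.call(rbind, cmeta), do.call(rbind, bmeta))
  out <- protein_matrix(values, smeta, clean$analyte_meta, log10 = FALSE)
  attr(out, "defect_ledger") <- ledger
  out
}

# n positive draws with sample sd / mean equal to cv exactly
exact_cv_sample <- function(n, mean, cv) {
  z <- stats::rnorm(n)
  z <- as.vector(scale(z))          # mean 0, sample sd 1
  pmax(mean * (1 + cv * z), mean * 1e-3)
}
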