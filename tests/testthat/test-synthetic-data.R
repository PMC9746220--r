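test_that("genotype simulation is deterministic and respects MAF targets", {
  blocks <- list(list(n_variants = 5, rho = 0.3, maf = c(0.1, 0.4)),
                 list(n_variants = 3, rho = 0, maf = c(0.2, 0.5)))
  p1 <- simulate_genotypes(600, blocks, seed = 5)
  p2 <- simulate_genotypes(600, blocks, seed = 5)
  expect_identical(p1$dosages, p2$dosages)
  expect_identical(p1$variant_meta, p2$variant_meta)

  realized <- colMeans(p1$dosages) / 2
  expect_true(all(abs(realized - p1$variant_meta$maf) < 0.05))
  # positions strictly increasing per chromosome by construction
  expect_true(all(tapply(p1$variant_meta$pos, p1$variant_meta$chrom,
                         function(x) all(diff(x) > 0))))
  expect_error(simulate_genotypes(600, list(list(n_variants = 0, rho = 0,
                                                 maf = c(0.1, 0.2))), 1),
               "positive")
  expect_error(simulate_genotypes(600, list(list(n_variants = 2, rho = 0,
                                                 maf = c(0.1, 0.7))), 1),
               "MAF")
})

test_that("copula LD structure matches its analytic correlation", {
  # independent block: all pairwise |r| small
  p0 <- simulate_genotypes(1000, list(list(n_variants = 6, rho = 0,
                                           maf = c(0.2, 0.5))), seed = 9)
  cc <- stats::cor(p0$dosages)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.1))

  # strong AR(1) block: the generator calibrates the latent correlation so
  # the adjacent dosage correlation equals the requested rho (and adjacent
  # r^2 ~ rho^2 = 0.81 clears 0.5); verified against the requested value
  # and against the thresholded-bivariate-normal oracle of the calibration
  # MAFs kept near 0.5 so the Frechet bound of each pair admits r = 0.9
  p9 <- simulate_genotypes(2000, list(list(n_variants = 5, rho = 0.9,
                                           maf = c(0.48, 0.5))), seed = 10)
  maf <- p9$variant_meta$maf
  for (j in 1:4) {
    r_emp <- stats::cor(p9$dosages[, j], p9$dosages[, j + 1])
    expect_lt(abs(r_emp - 0.9), 0.05)
    expect_gt(r_emp^2, 0.5)
    # oracle route: invert the attenuation independently and confirm the
    # latent value reproduces the requested indicator correlation
    lat <- uniroot(function(l)
      copula_allele_cor(maf[j], maf[j + 1], l) - 0.9,
      lower = 0.9, upper = 0.9999, tol = 1e-7)$root
    expect_equal(copula_allele_cor(maf[j], maf[j + 1], lat), 0.9,
                 tolerance = 1e-5)
  }

  # cross-block independence
  p2b <- simulate_genotypes(800, rep(list(list(n_variants = 3, rho = 0.8,
                                               maf = c(0.2, 0.5))), 2),
                            seed = 12)
  cross <- stats::cor(p2b$dosages[, 1:3], p2b$dosages[, 4:6])
  expect_true(all(abs(cross) < 0.1))
})

test_that("protein simulation follows the linear generative model", {
  panel <- fixture_panel(n = 2000, nb = 2, nv = 3, seed = 21)
  # pure noise: variance ~ noise_sd^2
  man0 <- make_truth_manifest(panel, n_proteins = 2, b_cis = 0, seed = 3)
  pr0 <- simulate_proteins(panel, man0, noise_sd = 1, seed = 4)
  v <- apply(sample_values(pr0), 2, stats::var)
  expect_true(all(abs(v - 1) < 0.15))

  # noiseless cis effect: protein = b * dosage takes exactly 3 values
  man1 <- make_truth_manifest(panel, n_proteins = 1, b_cis = 1, seed = 5)
  pr1 <- simulate_proteins(panel, man1, noise_sd = 0, seed = 6)
  expect_identical(sort(unique(sample_values(pr1)[, 1])), c(0, 1, 2))

  # OLS on the causal dosage recovers b_cis within 3 SE (lm oracle)
  man2 <- make_truth_manifest(panel, n_proteins = 1, b_cis = 0.5, seed = 7)
  pr2 <- simulate_proteins(panel, man2, noise_sd = 1, seed = 8)
  d <- panel$dosages[, man2$cis$variant_id[1]]
  o <- ols_oracle(sample_values(pr2)[, 1], d)
  expect_lt(abs(o$beta - 0.5), 3 * o$se)

  # unknown variant id errors
  bad <- man2; bad$cis$variant_id <- "nope"
  expect_error(simulate_proteins(panel, bad, seed = 9), "absent")
})

test_that("outcome GWAS is calibrated under the null and path-traces under
           a causal effect", {
  panel <- fixture_panel(n = 1500, nb = 4, nv = 5, rho = 0, seed = 31)
  # global null: ~5% of marginal p-values below 0.05
  man0 <- make_truth_manifest(panel, n_proteins = 4, b_cis = 0.5, seed = 1)
  pr <- simulate_proteins(panel, man0, seed = 2)
  gw0 <- simulate_outcome_gwas(panel, pr, man0, seed = 3)
  expect_lt(abs(mean(gw0[[1]]$pval < 0.05) - 0.05), 0.07)

  # theta = 0.4 through b_cis = 0.5: marginal outcome beta ~ 0.2 at the
  # cis variant (path-tracing oracle), within 3 SE
  th <- matrix(c(0.4, 0, 0, 0), 4, 1)
  man1 <- make_truth_manifest(panel, n_proteins = 4, b_cis = 0.5,
                              theta = th, seed = 1)
  pr1 <- simulate_proteins(panel, man1, seed = 2)
  gw1 <- simulate_outcome_gwas(panel, pr1, man1, seed = 3)
  cisv <- man1$cis$variant_id[1]
  row <- gw1[[1]][gw1[[1]]$variant_id == cisv, ]
  expect_lt(abs(row$beta - 0.4 * 0.5), 3 * row$se)

  # determinism
  gw2 <- simulate_outcome_gwas(panel, pr1, man1, seed = 3)
  expect_identical(gw1[[1]], gw2[[1]])
})

test_that("summary statistics and protein matrices round-trip through TSV", {
  panel <- fixture_panel(n = 60, nb = 1, nv = 3, seed = 45)
  gw <- marginal_gwas(panel, rnorm(60))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(gw, f)
  back <- read_sumstats(f)
  expect_equal(back$beta, gw$beta, tolerance = 1e-12)
  expect_identical(back$variant_id, gw$variant_id)
  expect_error(write_sumstats(gw[, -1], f), "missing columns")

  man <- make_truth_manifest(panel, n_proteins = 2, seed = 1)
  pm <- simulate_proteins(panel, man, seed = 2)
  fv <- withr::local_tempfile(fileext = ".tsv")
  fm <- withr::local_tempfile(fileext = ".tsv")
  write_protein_matrix(pm, fv, fm)
  pm2 <- read_protein_matrix(fv, fm, log10 = TRUE)
  expect_equal(unname(pm2$values), unname(pm$values), tolerance = 1e-10)
  expect_identical(pm2$sample_meta$role, pm$sample_meta$role)
})

test_that("raw-plate generator records defects in its ledger", {
  panel <- fixture_panel(n = 200, nb = 2, nv = 3, seed = 41)
  man <- make_truth_manifest(panel, n_proteins = 6, seed = 1)
  clean <- simulate_proteins(panel, man, noise_sd = 0.3, seed = 2)
  raw <- make_raw_proteomics(
    clean,
    failures = list(list(type = "lod", analyte = "prot001"),
                    list(type = "cv", analyte = "prot002", cv = 0.30)),
    seed = 3)
  led <- attr(raw, "defect_ledger")
  expect_setequal(led$id, c("prot001", "prot002"))
  expect_setequal(led$type, c("lod", "cv"))
  # per-plate well design: 8 calibrators + 4 buffers on each plate
  tab <- table(raw$sample_meta$role, raw$sample_meta$plate)
  expect_true(all(tab["calibrator", ] == 8))
  expect_true(all(tab["buffer", ] == 4))

  expect_error(make_raw_proteomics(
    clean, failures = list(list(type = "lod", analyte = "prot001"),
                           list(type = "lod", analyte = "prot001")),
    seed = 3), "contradictory")
  expect_error(make_raw_proteomics(
    clean, failures = list(list(type = "lod", analyte = "zzz")), seed = 3),
    "unknown")
})
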