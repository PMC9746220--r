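exposure_row <- function(id = "v1", ea = "A", nea = "G", eaf = 0.3,
                         beta = 0.5, se = 0.05, n = 800, chrom = 1,
                         pos = 1000) {
  data.frame(variant_id = id, chrom = chrom, pos = pos, ea = ea, nea = nea,
             eaf = eaf, beta = beta, se = se, n = n, stringsAsFactors = FALSE)
}

test_that("harmonization handles swaps, strand flips and palindromes", {
  exp1 <- exposure_row(ea = "A", nea = "G", eaf = 0.3, beta = 0.5)
  # swapped alleles: outcome beta sign-flipped, EAF reflected
  out_sw <- exposure_row(ea = "G", nea = "A", eaf = 0.7, beta = 0.3)
  h <- harmonize(exp1, out_sw)
  expect_true(h$kept)
  expect_equal(h$beta_out, -0.3)
  expect_equal(h$eaf_out, 0.3)
  expect_equal(h$action, "flip")

  # strand complement (A/G vs T/C): matched, sign preserved
  out_st <- exposure_row(ea = "T", nea = "C", eaf = 0.3, beta = 0.3)
  h2 <- harmonize(exp1, out_st)
  expect_equal(h2$beta_out, 0.3)
  expect_equal(h2$action, "strand_flip")

  # palindromic with both EAF at 0.5: ambiguous, dropped
  expA <- exposure_row(ea = "A", nea = "T", eaf = 0.5)
  outA <- exposure_row(ea = "A", nea = "T", eaf = 0.5, beta = 0.2)
  h3 <- harmonize(expA, outA)
  expect_false(h3$kept)
  expect_equal(h3$action, "drop_incompatible")

  # palindromic, informative EAFs on opposite sides: sign flip
  expB <- exposure_row(ea = "A", nea = "T", eaf = 0.2)
  outB <- exposure_row(ea = "A", nea = "T", eaf = 0.8, beta = 0.2)
  h4 <- harmonize(expB, outB)
  expect_true(h4$kept)
  expect_equal(h4$beta_out, -0.2)

  # incompatible alleles dropped; missing variant dropped with reason
  out_bad <- exposure_row(ea = "A", nea = "C", beta = 0.2)
  expect_false(harmonize(exp1, out_bad)$kept)
  expect_equal(harmonize(exp1, out_bad[0, ])$action, "drop_missing")

  # involution: re-harmonizing the already-aligned outcome is a no-op
  h5 <- harmonize(exp1, out_sw)
  aligned_outcome <- data.frame(
    variant_id = h5$variant_id, chrom = 1, pos = 1000, ea = h5$ea,
    nea = h5$nea, eaf = h5$eaf_out, beta = h5$beta_out, se = h5$se_out,
    n = h5$n_out, stringsAsFactors = FALSE)
  h6 <- harmonize(exp1, aligned_outcome)
  expect_equal(h6$action, "none")
  expect_equal(h6$beta_out, h5$beta_out)
  expect_equal(h6$eaf_out, h5$eaf_out)
})

test_that("Wald ratio and IVW match their closed forms and each other", {
  w <- wald_ratio(0.5, 0.05, 0.1, 0.02)
  expect_equal(w$beta_mr, 0.2)
  expect_equal(w$se_mr, 0.04)
  w0 <- wald_ratio(0.5, 0.05, 0, 0.02)
  expect_equal(w0$beta_mr, 0)
  expect_equal(w0$p_mr, 1)
  expect_error(wald_ratio(0, 0.05, 0.1, 0.02), "nonzero")

  # two equal-precision ratios average symmetrically
  pairs <- data.frame(beta_exp = c(1, 1), beta_out = c(0.2, 0.4),
                      se_out = c(0.1, 0.1), kept = TRUE)
  expect_equal(ivw(pairs)$beta_mr, 0.3, tolerance = 1e-12)

  # IVW at n = 1 routes to the identical Wald estimate
  p1 <- data.frame(beta_exp = 0.5, se_exp = 0.05, beta_out = 0.1,
                   se_out = 0.02, kept = TRUE)
  expect_error(ivw(p1), ">= 2")
  expect_equal(wald_ratio(p1$beta_exp, p1$se_exp, p1$beta_out,
                          p1$se_out)$beta_mr, 0.2)

  # random 5-IV sets match the zero-intercept weighted-regression oracle
  set.seed(21)
  for (i in 1:20) {
    pr <- data.frame(beta_exp = runif(5, 0.2, 1),
                     beta_out = rnorm(5, 0.1, 0.05),
                     se_out = runif(5, 0.01, 0.1), kept = TRUE)
    est <- ivw(pr)
    o <- ivw_oracle(pr$beta_exp, pr$beta_out, pr$se_out)
    expect_equal(est$beta_mr, o$beta, tolerance = 1e-10)
    expect_equal(est$se_mr, o$se, tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the step-up procedure per scope", {
  rec <- data.frame(p_mr = 0.03)
  expect_equal(fdr_adjust(rec, scope = character(0))$fdr_q, 0.03)

  rec4 <- data.frame(p_mr = c(0.001, 0.01, 0.02, 0.8))
  q <- fdr_adjust(rec4, scope = character(0))$fdr_q
  expect_equal(q, c(0.004, 0.02, 4 * 0.02 / 3, 0.8), tolerance = 1e-12)
  expect_equal(q, bh_oracle(rec4$p_mr), tolerance = 1e-12)
  expect_true(all(diff(q[order(rec4$p_mr)]) >= 0))

  expect_equal(fdr_adjust(data.frame(p_mr = rep(1, 5)),
                          scope = character(0))$fdr_q, rep(1, 5))

  # grouped scopes adjust independently
  rec_g <- data.frame(p_mr = c(0.01, 0.04, 0.01, 0.04),
                      tissue = c("csf", "csf", "plasma", "plasma"),
                      workflow = "a")
  qg <- fdr_adjust(rec_g)$fdr_q
  expect_equal(qg[1:2], bh_oracle(c(0.01, 0.04)), tolerance = 1e-12)

  set.seed(31)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))
    expect_equal(fdr_adjust(data.frame(p_mr = p),
                            scope = character(0))$fdr_q,
                 bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("Steiger filter compares explained variances via Fisher z", {
  # craft t so that r2 is exact: t^2 = r2 (n-2) / (1 - r2)
  t_for <- function(r2, n) sqrt(r2 * (n - 2) / (1 - r2))
  n <- 1000
  pairs <- data.frame(beta_exp = t_for(0.04, n) * 0.01, se_exp = 0.01,
                      beta_out = t_for(4e-4, n) * 0.02, se_out = 0.02,
                      kept = TRUE)
  s <- steiger_filter(pairs, n, n)
  expect_true(s$steiger_correct)
  expect_equal(s$r2_exp, 0.04, tolerance = 1e-12)
  expect_equal(s$r2_out, 4e-4, tolerance = 1e-12)
  z_oracle <- (atanh(0.2) - atanh(0.02)) / sqrt(2 / (n - 3))
  expect_equal(s$steiger_p, 2 * pnorm(-abs(z_oracle)), tolerance = 1e-12)
  expect_lt(s$steiger_p, 1e-4)

  # equal variance explained: not correct (strict), p = 1
  pairs_eq <- data.frame(beta_exp = t_for(0.02, n) * 0.01, se_exp = 0.01,
                         beta_out = t_for(0.02, n) * 0.01, se_out = 0.01,
                         kept = TRUE)
  s2 <- steiger_filter(pairs_eq, n, n)
  expect_false(s2$steiger_correct)
  expect_equal(s2$steiger_p, 1, tolerance = 1e-12)
  expect_error(steiger_filter(pairs, 3, n), "exceed 3")
})

test_that("Wald MR recovers the simulated causal effect", {
  sim <- simulate_mr_pair(n = 2000, b_cis = 0.5, theta = 0.3, seed = 41)
  h <- harmonize(sim$exposure, sim$outcome)
  est <- wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
  expect_lt(abs(est$beta_mr - 0.3), 3 * est$se_mr)
})

test_that("run_workflow composes the pipeline and respects the truth", {
  blocks <- rep(list(list(n_variants = 15, rho = 0.4, maf = c(0.1, 0.5))), 8)
  panel <- simulate_genotypes(600, blocks, seed = 61)
  th <- matrix(0, 8, 1); th[1, 1] <- 0.5
  man <- make_truth_manifest(panel, n_proteins = 8, b_cis = 0.6,
                             theta = th, seed = 62)
  pr <- simulate_proteins(panel, man, noise_sd = 0.6, seed = 63)
  gw <- simulate_outcome_gwas(panel, pr, man, seed = 64)
  rec <- run_workflow(list(panel = panel, proteins = pr, outcomes = gw,
                           genes = man$genes, tissue = "csf",
                           workflow = "both"))
  causal <- rec[rec$protein == "prot001" & rec$workflow == "b", ]
  expect_equal(nrow(causal), 1)
  expect_true(causal$significant)
  expect_gt(causal$pp_h4, 0.8)
  expect_lt(abs(causal$beta_mr - 0.5), 4 * causal$se_mr)
  expect_true(all(rec$method[rec$n_ivs == 1] == "wald"))
  expect_true(all(rec$method[rec$n_ivs > 1] == "ivw"))
  expect_true(all(rec$iv_source %in% c("cis-only", "trans-additional")))
  # null proteins: none besides the causal one called significant
  expect_false(any(rec$significant[rec$protein != "prot001"]))
})
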