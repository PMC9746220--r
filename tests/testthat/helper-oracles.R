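# Independent oracles used across the suite. Each is deliberately written
# from first principles, not by calling the code path it checks.

# per-variant OLS slope/SE/p via lm() on the full design, one pair at a time
ols_oracle <- function(y, x, covariates = NULL) {
  dat <- data.frame(y = y, x = x)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    colnames(covariates) <- paste0("c", seq_len(ncol(covariates)))
    dat <- cbind(dat, covariates)
  }
  fit <- stats::lm(y ~ ., data = dat)
  s <- summary(fit)$coefficients["x", ]
  list(beta = unname(s[1]), se = unname(s[2]), pval = unname(s[4]))
}

# fixed-effect weighted least squares of a constant mean
wls_oracle <- function(beta, se) {
  fit <- stats::lm(beta ~ 1, weights = 1 / se^2)
  s <- summary(fit)$coefficients[1, ]
  # lm rescales the residual variance; the fixed-effect SE is the
  # weight-only expression
  list(beta = unname(s[1]), se = sqrt(1 / sum(1 / se^2)))
}

# zero-intercept weighted regression oracle for IVW
ivw_oracle <- function(beta_exp, beta_out, se_out) {
  fit <- stats::lm(beta_out ~ 0 + beta_exp, weights = 1 / se_out^2)
  b <- unname(coef(fit)[1])
  s <- sqrt(1 / sum(beta_exp^2 / se_out^2))
  list(beta = b, se = s)
}

# Benjamini-Hochberg step-up by direct enumeration of the definition:
# q_(i) = min_{j >= i} m p_(j) / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# five-hypothesis colocalization masses by explicit pair enumeration on
# linear-scale Bayes factors (scaled by the max log ABF for stability)
coloc_oracle <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  m <- length(l1)
  c1 <- max(l1); c2 <- max(l2)
  b1 <- exp(l1 - c1); b2 <- exp(l2 - c2)
  s1 <- sum(b1); s2 <- sum(b2)
  s12 <- sum(b1 * b2)
  cross <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) cross <- cross + b1[i] * b2[j]
  }
  # all masses expressed relative to exp(c1 + c2)
  h0 <- exp(-c1 - c2)
  h1 <- p1 * s1 * exp(-c2)
  h2 <- p2 * s2 * exp(-c1)
  h3 <- p1 * p2 * cross
  h4 <- p12 * s12
  tot <- h0 + h1 + h2 + h3 + h4
  c(PP.H0 = h0, PP.H1 = h1, PP.H2 = h2, PP.H3 = h3, PP.H4 = h4) / tot
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# P(Z1 > t1, Z2 > t2) for standard bivariate normal with correlation rho,
# by one-dimensional quadrature over the conditional distribution
bvn_upper_tail <- function(t1, t2, rho) {
  f <- function(z) stats::dnorm(z) *
    stats::pnorm((rho * z - t2) / sqrt(1 - rho^2))
  stats::integrate(f, t1, Inf, rel.tol = 1e-10)$value
}

# analytic correlation of the two thresholded-allele indicators under the
# Gaussian copula (one haplotype); dosage correlation equals it
copula_allele_cor <- function(maf1, maf2, rho) {
  t1 <- stats::qnorm(1 - maf1); t2 <- stats::qnorm(1 - maf2)
  p11 <- bvn_upper_tail(t1, t2, rho)
  (p11 - maf1 * maf2) / sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}
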