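# Single-causal-variant colocalization via Wakefield approximate Bayes
# factors over a +/- 500 kb window, with the averaged-PP.H4 rule for
# multi-instrument proteins.

#' Wakefield log approximate Bayes factor
#'
#' For an association with estimate `beta`, standard error `se` and a
#' N(0, prior_sd^2) prior on the true effect: with z = beta/se, V = se^2,
#' W = prior_sd^2 and r = W/(V+W),
#' log ABF = 0.5 log(1 - r) + r z^2 / 2.
#'
#' @param beta,se association estimate and standard error (se > 0).
#' @param prior_sd prior effect standard deviation (> 0); 0.15 is the
#'   conventional default for quantitative traits, 0.2 for log-odds.
#' @return numeric vector of log ABFs.
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.15) {
  stop_if_not(all(se > 0), "standard errors must be positive")
  stop_if_not(all(prior_sd > 0), "prior_sd must be positive")
  z2 <- (beta / se)^2
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  0.5 * log1p(-r) + r * z2 / 2
}

#' ABF colocalization of two traits over a shared region
#'
#' Computes per-variant log ABFs for both traits, then the posterior
#' probabilities of the five hypotheses (H0 no association; H1/H2 one trait
#' only; H3 two distinct causal variants; H4 one shared causal variant)
#' from the unnormalized masses (1, p1 S1, p2 S2, p1 p2 (S1 S2 - S12),
#' p12 S12) where S1 = sum(ABF1), S2 = sum(ABF2), S12 = sum(ABF1 * ABF2).
#' All sums are taken in log space.
#'
#' @param exposure,outcome summary-statistics data.frames for the window
#'   (columns `variant_id`, `beta`, `se`, and `chrom`/`pos` if positional
#'   matching is wanted); they are intersected on chromosome+position when
#'   available, else on variant id.
#' @param priors per-variant prior probabilities `c(p1, p2, p12)`
#'   (default 1e-4, 1e-4, 1e-5).
#' @param prior_sd length-2 prior effect SDs for the two traits
#'   (default both 0.15).
#' @return list of class `coloc_result`: `n_variants`, `pp` (named PP.H0 ..
#'   PP.H4, summing to 1), `priors`, `labf` (per-variant log ABFs).
#' @export
coloc_abf <- function(exposure, outcome,
                      priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                      prior_sd = c(0.15, 0.15)) {
  key <- function(d) {
    if (all(c("chrom", "pos") %in% names(d))) paste(d$chrom, d$pos)
    else d$variant_id
  }
  ke <- key(exposure); ko <- key(outcome)
  shared <- intersect(ke, ko)
  if (length(shared) == 0L)
    stop("no shared variants between the two windows", call. = FALSE)
  e <- exposure[match(shared, ke), , drop = FALSE]
  o <- outcome[match(shared, ko), , drop = FALSE]
  l1 <- wakefield_abf(e$beta, e$se, prior_sd[1])
  l2 <- wakefield_abf(o$beta, o$se, prior_sd[2])
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lp <- log(priors)
  lm <- c(H0 = 0,
          H1 = lp[[1]] + ls1,
          H2 = lp[[2]] + ls2,
          H3 = lp[[1]] + lp[[2]] + logdiffexp(ls1 + ls2, ls12),
          H4 = lp[[3]] + ls12)
  pp <- exp(lm - logsumexp(lm))
  names(pp) <- paste0("PP.", names(lm))
  structure(list(n_variants = length(shared), pp = pp, priors = priors,
                 prior_sd = prior_sd,
                 labf = data.frame(variant_id = e$variant_id,
                                   labf_exposure = l1, labf_outcome = l2,
                                   stringsAsFactors = FALSE)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("coloc_result over", x$n_variants, "variants:\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' Average PP.H4 across a protein's instrument-centered windows
#'
#' With several MR instruments per protein, colocalization is run once per
#' instrument-centered window and the arithmetic mean PP.H4 is reported;
#' PP.H4 > 0.80 (strict) defines strong colocalization.
#'
#' @param results list of `coloc_result` objects, or a numeric vector of
#'   PP.H4 values.
#' @return scalar averaged PP.H4.
#' @export
combine_pph4 <- function(results) {
  if (is.numeric(results)) {
    stop_if_not(length(results) >= 1, "empty PP.H4 input")
    return(mean(results))
  }
  stop_if_not(length(results) >= 1, "empty result list")
  mean(vapply(results, function(r) r$pp[["PP.H4"]], numeric(1)))
}
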