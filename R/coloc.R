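# Colocalization of two association signals (3'aQTL and GWAS) at one locus
# under the single-causal-variant assumption: per-variant approximate Bayes
# factors, then the five-hypothesis posterior decomposition
# (H0 none / H1 trait-1 only / H2 trait-2 only / H3 two distinct causal
# variants / H4 one shared causal variant). All accumulation is in log
# space with log-sum-exp; the H3 cross-term uses a stable complement.

#' Per-variant log approximate Bayes factor
#'
#' Wakefield's single-variant ABF: with shrinkage factor
#' `W^2 / (W^2 + V)` (call it rho), `lABF = 0.5 * (log(1 - rho) +
#' rho * z^2)`. `V` is the squared standard
#' error; for a quantitative trait summarised by (z, n, maf) it is
#' approximated as `1 / (2 n f (1 - f))`.
#'
#' @param z association z-score(s).
#' @param V sampling variance(s), strictly positive; recycled.
#' @param W prior SD of the effect (0.15 for quantitative traits, 0.2 on
#'   the log-odds scale for case-control, by convention).
#' @return numeric vector of log ABFs.
#' @export
log_abf <- function(z, V, W = 0.15) {
  if (any(V <= 0)) stop("V must be > 0")
  r <- W^2 / (W^2 + V)
  0.5 * (log(1 - r) + r * z^2)
}

#' Sampling variance from z, n and allele frequency (quantitative trait)
#' @param n sample size; @param maf allele frequency.
#' @return approximate squared SE of the standardised effect.
#' @export
approx_var_quant <- function(n, maf) 1 / (2 * n * maf * (1 - maf))

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Five-hypothesis colocalization posteriors
#'
#' Given per-variant log ABFs for the two traits over the same Q variants,
#' forms the unnormalised log hypothesis weights
#' `S0 = 0`,
#' `S1 = log p1 + lse(l1)`, `S2 = log p2 + lse(l2)`,
#' `S3 = log p1 + log p2 + log( sum_{i != j} exp(l1_i + l2_j) )` (computed
#' as the stable complement of the diagonal),
#' `S4 = log p12 + lse(l1 + l2)`,
#' and returns their softmax. With a single variant H3 has no
#' configuration; PP3 is 0 by convention.
#'
#' @param labf1,labf2 equal-length log-ABF vectors.
#' @param p1,p2,p12 per-variant prior probabilities (trait-1 only, trait-2
#'   only, shared); defaults 1e-4, 1e-4, 1e-5.
#' @return an object of class `coloc_result`: pp (named PP0..PP4),
#'   n_variants, priors.
#' @export
coloc_posteriors <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4,
                             p12 = 1e-5) {
  Q <- length(labf1)
  stopifnot(Q >= 1, length(labf2) == Q)
  if (any(c(p1, p2, p12) <= 0) || p1 + p2 + p12 >= 1)
    stop("priors must be positive with p1 + p2 + p12 < 1")
  l1 <- logsumexp(labf1)
  l2 <- logsumexp(labf2)
  lsum <- logsumexp(labf1 + labf2)      # diagonal (shared-variant) term
  S0 <- 0
  S1 <- log(p1) + l1
  S2 <- log(p2) + l2
  if (Q == 1) {
    S3 <- -Inf
  } else {
    # log( exp(l1 + l2) - exp(lsum) ), stable: l1 + l2 >= lsum always
    diff <- lsum - (l1 + l2)
    S3 <- log(p1) + log(p2) + l1 + l2 +
      if (diff >= 0) -Inf else log1p(-exp(diff))
  }
  S4 <- log(p12) + lsum
  S <- c(S0, S1, S2, S3, S4)
  pp <- exp(S - logsumexp(S))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp, n_variants = Q,
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result over %d variants:\n", x$n_variants))
  print(round(x$pp, 4))
  cat(sprintf("  colocalized (PP4 >= 0.5): %s\n",
              classify_coloc(x)))
  invisible(x)
}

#' Colocalization decision rule
#'
#' Flags a locus as colocalized when `PP4 >= threshold` (the boundary value
#' itself is flagged).
#'
#' @param result a `coloc_result`.
#' @param threshold decision threshold (default 0.5).
#' @return logical flag.
#' @export
classify_coloc <- function(result, threshold = 0.5) {
  stopifnot(inherits(result, "coloc_result"))
  unname(result$pp["PP4"] >= threshold)
}

#' Colocalize two harmonized summary-statistic sets over one locus
#'
#' Convenience wrapper: joins two sumstats tables on variant id (alleles
#' must already be harmonized to one orientation), computes per-trait log
#' ABFs from (z, n, maf) or (beta, se), and runs the posterior
#' decomposition. The input mode used per trait is recorded in the result.
#'
#' @param ss1,ss2 data.frames with columns snp, z, n (plus maf) or
#'   snp, beta, se.
#' @param maf named MAF vector (used for traits supplied as z, n).
#' @param W1,W2 per-trait prior effect SDs.
#' @param p1,p2,p12 priors.
#' @return a `coloc_result` with attribute `input_mode`.
#' @export
coloc_sumstats <- function(ss1, ss2, maf = NULL, W1 = 0.15, W2 = 0.15,
                           p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  common <- intersect(ss1$snp, ss2$snp)
  if (!length(common)) stop("no shared variants between the two traits")
  labf_one <- function(ss, W) {
    ss <- ss[match(common, ss$snp), , drop = FALSE]
    if (all(c("beta", "se") %in% names(ss))) {
      list(labf = log_abf(ss$beta / ss$se, ss$se^2, W), mode = "beta_se")
    } else {
      if (is.null(maf)) stop("maf needed for z/n input")
      V <- approx_var_quant(ss$n, maf[common])
      list(labf = log_abf(ss$z, V, W), mode = "z_n")
    }
  }
  a <- labf_one(ss1, W1); b <- labf_one(ss2, W2)
  res <- coloc_posteriors(a$labf, b$labf, p1, p2, p12)
  attr(res, "input_mode") <- c(trait1 = a$mode, trait2 = b$mode)
  res
}
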