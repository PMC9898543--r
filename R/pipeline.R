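# In-memory pipeline composition: from a simulated study straight through
# phenotype preparation, weight training, the summary-statistic scan,
# conditional analysis, and colocalization of the top gene. This is the
# positive-control harness the package's own validation runs on, and a
# worked example of how the stages plug together on real inputs.

#' Run the pipeline end to end on one simulated study
#'
#' Simulates a reference panel plus mediated GWAS summary statistics
#' ([sim_study()]), prepares phenotypes (inverse-normal transform and
#' centring; no known covariates exist in the simulation), trains one
#' weight model per gene, scans all models against the GWAS, and for the
#' designated causal gene computes the conditional residual GWAS signal
#' and the colocalization posteriors (3'aQTL marginal z-scores from the
#' panel vs GWAS z-scores).
#'
#' @param seed master seed for the run.
#' @param n_genes,n_samples,n_cis_variants,alpha,beta,noise_sd,ld_rho,n_gwas
#'   study conditions, passed to [sim_study()].
#' @param gate_p heritability gate for training.
#' @return list: `scan` (a `twas_scan`), `causal_id`, `causal_is_top`
#'   (did the causal gene attain the scan-wide max |Z|), `causal_q`,
#'   `pp4`, `max_abs_z_raw`, `max_abs_z_conditional` (locus max before and
#'   after conditioning), `n_trained`.
#' @export
run_end_to_end <- function(seed, n_genes = 50, n_samples = 500,
                           n_cis_variants = 30, alpha = 0.1, beta = 0.08,
                           noise_sd = 0.08, ld_rho = 0.5, n_gwas = 5e4,
                           gate_p = 0.05) {
  study <- sim_study(n_genes = n_genes, n_samples = n_samples,
                     n_cis_variants = n_cis_variants, causal_gene = 1,
                     beta = beta, alpha = alpha, noise_sd = noise_sd,
                     ld_rho = ld_rho, n_gwas = n_gwas, seed = seed)
  resid <- t(apply(study$pdui, 1, inverse_normal_transform))
  resid <- resid - rowMeans(resid)

  models <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    models[[g]] <- train_weight_model(
      resid[g, ], study$genotypes[[g]]$dosages,
      variants = study$genotypes[[g]]$variants,
      seed = derive_seed(seed, paste0("train", g)),
      gate_p = gate_p, transcript_id = study$truth$gene_id[g])
  }
  scan <- twas_scan(models, study$sumstats, study$genotypes)

  causal_id <- study$truth$gene_id[1]
  res <- scan$results
  causal_row <- match(causal_id, res$transcript_id)
  causal_is_top <- !is.na(causal_row) &&
    abs(res$Z[causal_row]) == max(abs(res$Z))
  causal_q <- if (is.na(causal_row)) NA_real_ else res$q[causal_row]

  pp4 <- NA_real_; zmax_raw <- NA_real_; zmax_cond <- NA_real_
  if (!inherits(models[[1]], "gated_out")) {
    h <- harmonize(study$sumstats[[1]], models[[1]], study$genotypes[[1]])
    if (!is_skipped(h)) {
      tz <- twas_z(h$w, h$z, h$Sigma)
      if (!is_skipped(tz)) {
        cz <- conditional_z(h$z, h$w, h$Sigma, tz$Z)
        zmax_raw <- max(abs(cz$z_raw))
        zmax_cond <- max(abs(cz$z_conditional))
      }
      G1 <- study$genotypes[[1]]
      aqtl_z <- vapply(seq_len(ncol(G1$dosages)), function(j) {
        a <- marginal_assoc(resid[1, ], G1$dosages[, j])
        if (is.null(a)) 0 else a$t
      }, numeric(1))
      maf <- stats::setNames(G1$variants$maf, G1$variants$id)
      cres <- coloc_sumstats(
        data.frame(snp = G1$variants$id, z = aqtl_z, n = n_samples),
        data.frame(snp = study$sumstats[[1]]$snp,
                   z = study$sumstats[[1]]$z, n = n_gwas),
        maf = maf)
      pp4 <- unname(cres$pp["PP4"])
    }
  }
  list(scan = scan, causal_id = causal_id, causal_is_top = causal_is_top,
       causal_q = causal_q, pp4 = pp4, max_abs_z_raw = zmax_raw,
       max_abs_z_conditional = zmax_cond,
       n_trained = sum(!vapply(models, inherits, logical(1), "gated_out")))
}
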