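# Synthetic-data generators: genotypes with local LD, PDUI phenotypes with
# cis genetic effects, two-segment coverage profiles, and GWAS summary
# statistics. These emulate the statistical structure every downstream stage
# assumes, so the pipeline is testable end to end without cohort access.

#' Simulate a dosage-coded genotype matrix with local LD
#'
#' Haplotypes are drawn under a first-order Markov copying model: each site
#' carries a latent uniform that is copied from its left neighbour with
#' probability `ld_rho` and redrawn otherwise, then thresholded at the site's
#' allele frequency. When adjacent sites share an allele frequency the
#' adjacent-haplotype correlation equals `ld_rho` exactly in expectation;
#' unequal frequencies cap the achievable correlation (Frechet bounds).
#' Two independent haplotypes are summed into dosages in \{0, 1, 2\}.
#'
#' @param n_individuals number of individuals (rows).
#' @param n_variants number of variants (columns).
#' @param maf_range length-2 numeric, minor-allele-frequency range in
#'   `(0, 0.5]`; per-site frequencies are drawn uniformly within it.
#' @param ld_rho neighbour copying probability in `[0, 1)`.
#' @param seed integer seed; the run is fully reproducible given it.
#' @param chrom chromosome label for all variants.
#' @param pos_start first variant position (1-based).
#' @param pos_step spacing between consecutive variant positions (bp).
#' @param frac_ambiguous fraction of variants assigned strand-ambiguous
#'   (A/T or C/G) allele pairs, for harmonisation tests.
#' @param frac_indel fraction of variants assigned an indel alt allele.
#' @param id_prefix prefix for variant ids (keeps ids unique when several
#'   panels are merged).
#' @return an object of class `genotype_matrix`: a list with `dosages`
#'   (individuals x variants integer matrix, column names = variant ids) and
#'   `variants` (data.frame: chrom, pos, id, ref, alt, maf with the realised
#'   minor-allele frequency), plus the seed as an attribute.
#' @export
sim_genotypes <- function(n_individuals, n_variants,
                          maf_range = c(0.05, 0.5), ld_rho = 0, seed,
                          chrom = "1", pos_start = 1e5L, pos_step = 1000L,
                          frac_ambiguous = 0, frac_indel = 0,
                          id_prefix = "rs") {
  check_scalar(n_individuals, "n_individuals", lower = 2)
  check_scalar(n_variants, "n_variants", lower = 1)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must satisfy 0 < low <= high <= 0.5")
  check_scalar(ld_rho, "ld_rho", lower = 0, upper = 1, strict_upper = TRUE)
  set.seed(seed)

  f <- stats::runif(n_variants, maf_range[1], maf_range[2])
  draw_haplotypes <- function() {
    u <- matrix(stats::runif(n_individuals * n_variants), n_individuals)
    if (ld_rho > 0 && n_variants > 1) {
      copy <- matrix(stats::runif(n_individuals * n_variants), n_individuals) < ld_rho
      for (j in 2:n_variants) {
        cj <- copy[, j]
        u[cj, j] <- u[cj, j - 1]
      }
    }
    sweep(u, 2, f, "<") * 1L
  }
  dos <- draw_haplotypes() + draw_haplotypes()

  # guarantee polymorphism: a monomorphic column gets one heterozygote
  mono <- which(apply(dos, 2, function(x) length(unique(x)) == 1L))
  for (j in mono) {
    i <- sample.int(n_individuals, 1)
    dos[i, j] <- if (dos[i, j] == 0) 1L else dos[i, j] - 1L
  }

  n_amb <- round(frac_ambiguous * n_variants)
  n_ind <- round(frac_indel * n_variants)
  kind <- rep("snp", n_variants)
  if (n_amb + n_ind > 0) {
    pick <- sample.int(n_variants, n_amb + n_ind)
    kind[pick[seq_len(n_amb)]] <- "ambiguous"
    if (n_ind > 0) kind[pick[n_amb + seq_len(n_ind)]] <- "indel"
  }
  ref <- alt <- character(n_variants)
  for (j in seq_len(n_variants)) {
    if (kind[j] == "ambiguous") {
      ref[j] <- sample(c("A", "C"), 1)
      alt[j] <- c(A = "T", C = "G")[[ref[j]]]
    } else if (kind[j] == "indel") {
      ref[j] <- paste0(sample(c("A", "C", "G", "T"), 1), "C")
      alt[j] <- substr(ref[j], 1, 1)
    } else {
      ref[j] <- sample(c("A", "C", "G", "T"), 1)
      # transition partner: never strand-ambiguous
      alt[j] <- c(A = "G", G = "A", C = "T", T = "C")[[ref[j]]]
    }
  }

  af <- colMeans(dos) / 2
  ids <- sprintf("%s%06d", id_prefix, seq_len(n_variants))
  dimnames(dos) <- list(sprintf("ind%04d", seq_len(n_individuals)), ids)
  variants <- data.frame(
    chrom = normalize_chrom(rep(chrom, n_variants)),
    pos = pos_start + pos_step * (seq_len(n_variants) - 1L),
    id = ids, ref = ref, alt = alt,
    maf = pmin(af, 1 - af), af_alt = af,
    stringsAsFactors = FALSE)
  structure(list(dosages = dos, variants = variants),
            class = "genotype_matrix", seed = seed)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants (%s:%d-%d)\n",
              nrow(x$dosages), ncol(x$dosages), x$variants$chrom[1],
              min(x$variants$pos), max(x$variants$pos)))
  cat(sprintf("  MAF range %.3f-%.3f; seed %s\n",
              min(x$variants$maf), max(x$variants$maf),
              format(attr(x, "seed"))))
  invisible(x)
}

#' Ground-truth parameter set for a simulated study
#'
#' Records, per gene, the causal cis variants, their effect sizes on PDUI
#' (PDUI units per alt allele), the true coverage breakpoint, the baseline
#' PDUI, the trait-mediation coefficient alpha (trait SD per PDUI SD), and
#' the phenotype noise SD — the quantities parameter-recovery tests check
#' against.
#'
#' @param causal list (one integer vector per gene) of causal variant
#'   column indices.
#' @param beta list of effect-size vectors conformable with `causal`.
#' @param breakpoint integer vector, true proximal poly(A) site offset in nt
#'   from the UTR 5' end, strictly inside the UTR.
#' @param utr_length integer vector of UTR lengths (nt).
#' @param baseline numeric vector of baseline PDUI values in `[0, 1]`.
#' @param alpha per-gene trait-mediation coefficient (0 = not mediating).
#' @param noise_sd per-gene phenotype noise SD (>= 0).
#' @param seed integer seed recorded in every derived output.
#' @return an object of class `sim_truth`.
#' @export
sim_truth <- function(causal, beta, breakpoint, utr_length, baseline,
                      alpha = 0, noise_sd = 0.1, seed) {
  n_genes <- length(causal)
  stopifnot(length(beta) == n_genes)
  breakpoint <- rep_len(breakpoint, n_genes)
  utr_length <- rep_len(utr_length, n_genes)
  baseline <- rep_len(baseline, n_genes)
  alpha <- rep_len(alpha, n_genes)
  noise_sd <- rep_len(noise_sd, n_genes)
  if (any(baseline < 0 | baseline > 1)) stop("baseline PDUI outside [0,1]")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  if (any(breakpoint <= 0 | breakpoint >= utr_length))
    stop("breakpoint must be strictly inside the UTR")
  for (g in seq_len(n_genes))
    if (length(beta[[g]]) != length(causal[[g]]))
      stop("beta and causal lengths differ for gene ", g)
  structure(list(causal = causal, beta = beta, breakpoint = breakpoint,
                 utr_length = utr_length, baseline = baseline,
                 alpha = alpha, noise_sd = noise_sd, seed = seed,
                 gene_id = sprintf("gene%03d", seq_len(n_genes))),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d genes, %d mediating trait (alpha != 0), seed %s\n",
              length(x$causal), sum(x$alpha != 0), format(x$seed)))
  invisible(x)
}

#' Simulate PDUI phenotypes from genotypes and ground truth
#'
#' Per gene g and individual i the PDUI is the gene's baseline plus the sum
#' of causal dosages times their effects, plus optional covariate terms and
#' Gaussian noise, clipped to the unit interval after noise (a usage
#' fraction cannot leave it).
#'
#' @param G a `genotype_matrix`.
#' @param truth a `sim_truth`.
#' @param covariate_effects optional list with `X` (samples x p covariate
#'   matrix) and `B` (genes x p effect matrix) added before noise.
#' @param seed integer seed for the noise draws.
#' @return genes x samples numeric matrix of PDUI values in `[0, 1]`, with
#'   the seed as attribute.
#' @export
sim_pdui <- function(G, truth, covariate_effects = NULL, seed) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(truth, "sim_truth"))
  dos <- G$dosages
  n <- nrow(dos); n_genes <- length(truth$causal)
  set.seed(seed)
  out <- matrix(NA_real_, n_genes, n,
                dimnames = list(truth$gene_id, rownames(dos)))
  for (g in seq_len(n_genes)) {
    idx <- truth$causal[[g]]
    if (length(idx) && (any(idx < 1) || any(idx > ncol(dos))))
      stop("causal index out of range for gene ", g)
    y <- rep(truth$baseline[g], n)
    if (length(idx))
      y <- y + as.vector(dos[, idx, drop = FALSE] %*% truth$beta[[g]])
    if (!is.null(covariate_effects))
      y <- y + as.vector(covariate_effects$X %*% covariate_effects$B[g, ])
    if (truth$noise_sd[g] > 0)
      y <- y + stats::rnorm(n, 0, truth$noise_sd[g])
    out[g, ] <- clip01(y)
  }
  attr(out, "seed") <- seed
  out
}

#' Simulate a two-segment 3'UTR coverage profile
#'
#' Expected per-base depth equals `mean_depth` upstream of the proximal
#' poly(A) site and `mean_depth * pdui_value` downstream (only the distal
#' fraction of transcripts reads through the proximal site). Counts are drawn
#' negative-binomial with `Var = mu + dispersion * mu^2`; `dispersion = 0`
#' returns the deterministic expectation (an exact noiseless fixture, not a
#' Poisson draw).
#'
#' @param pdui_value distal usage fraction in `[0, 1]`.
#' @param utr_length UTR length (nt).
#' @param breakpoint proximal site offset in nt, strictly inside the UTR.
#' @param mean_depth expected depth on the proximal segment (> 0).
#' @param dispersion negative-binomial dispersion (>= 0).
#' @param seed integer seed.
#' @param sample_id sample label carried on the profile.
#' @return a `coverage_profile`: list with `sample_id`, `values` (length
#'   `utr_length`, 5'->3'), and `total_depth_factor` (1 for simulated data).
#' @export
sim_coverage <- function(pdui_value, utr_length, breakpoint, mean_depth,
                         dispersion = 0, seed = 1L, sample_id = "sim") {
  check_scalar(pdui_value, "pdui_value", 0, 1)
  check_scalar(mean_depth, "mean_depth", 0, strict_lower = TRUE)
  check_scalar(dispersion, "dispersion", 0)
  if (breakpoint <= 0 || breakpoint >= utr_length)
    stop("breakpoint (", breakpoint, ") must lie strictly inside the UTR (0, ",
         utr_length, ")")
  mu <- c(rep(mean_depth, breakpoint),
          rep(mean_depth * pdui_value, utr_length - breakpoint))
  if (dispersion == 0) {
    values <- mu
  } else {
    set.seed(seed)
    values <- stats::rnbinom(utr_length, mu = mu, size = 1 / dispersion)
  }
  structure(list(sample_id = sample_id, values = as.numeric(values),
                 total_depth_factor = 1),
            class = "coverage_profile", seed = seed)
}

#' Simulate GWAS summary statistics under an LD panel
#'
#' Draws z-scores from the standard summary-statistic model
#' `z ~ MVN(sqrt(n_gwas) * Sigma %*% gamma, Sigma)` where `gamma` holds
#' per-SNP effects on the standardised-genotype scale. In mediated mode the
#' trait acts on SNPs only through PDUI: `gamma = alpha * w` with `w` a
#' PDUI prediction-weight vector, which makes the end-to-end positive
#' control internally consistent with the TWAS estimand.
#'
#' @param ld a `genotype_matrix` (LD computed from dosages) or a correlation
#'   matrix.
#' @param snp_effects optional per-SNP effect vector `gamma`.
#' @param weights,alpha mediated mode: `gamma = alpha * weights`.
#' @param n_gwas GWAS sample size (> 0).
#' @param seed integer seed.
#' @param variants optional variant table (required when `ld` is a plain
#'   matrix); alleles are copied from the panel.
#' @return a `gwas_sumstats` data.frame with columns snp, a1 (effect = alt
#'   allele), a2, z, n; seed as attribute.
#' @export
sim_gwas <- function(ld, snp_effects = NULL, weights = NULL, alpha = NULL,
                     n_gwas, seed, variants = NULL) {
  check_scalar(n_gwas, "n_gwas", 0, strict_lower = TRUE)
  if (inherits(ld, "genotype_matrix")) {
    variants <- ld$variants
    Sigma <- stats::cor(ld$dosages)
  } else {
    Sigma <- as.matrix(ld)
    if (is.null(variants))
      variants <- data.frame(id = paste0("snp", seq_len(nrow(Sigma))),
                             ref = "A", alt = "G",
                             stringsAsFactors = FALSE)
  }
  m <- nrow(Sigma)
  if (is.null(snp_effects)) {
    if (is.null(weights) || is.null(alpha)) {
      gamma <- rep(0, m)
    } else {
      stopifnot(length(weights) == m)
      gamma <- alpha * weights
    }
  } else {
    stopifnot(length(snp_effects) == m)
    gamma <- snp_effects
  }
  mu <- sqrt(n_gwas) * as.vector(Sigma %*% gamma)
  Sig <- Sigma
  ok <- !inherits(try(chol(Sig), silent = TRUE), "try-error")
  if (!ok) {  # finite-panel estimate can be singular; shrink once
    Sig <- 0.95 * Sigma + 0.05 * diag(m)
    if (inherits(try(chol(Sig), silent = TRUE), "try-error"))
      stop("LD matrix not positive definite even after shrinkage")
  }
  set.seed(seed)
  z <- as.vector(MASS::mvrnorm(1, mu = mu, Sigma = Sig))
  out <- data.frame(snp = variants$id, a1 = variants$alt, a2 = variants$ref,
                    z = z, n = n_gwas, stringsAsFactors = FALSE)
  class(out) <- c("gwas_sumstats", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' Simulate a coherent multi-gene study
#'
#' Builds everything one run of the pipeline consumes: a genotype panel, a
#' per-gene truth record, PDUI phenotypes, per-gene UTR layouts, and
#' (optionally) mediated GWAS summary statistics. Genes are laid out on
#' separate chromosomes so cis windows never overlap; each gene gets its own
#' block of cis variants.
#'
#' @param n_genes number of genes.
#' @param n_samples reference-panel size.
#' @param n_cis_variants cis variants per gene.
#' @param causal_gene index of the single trait-mediating gene (0 = none).
#' @param beta causal-variant effect on PDUI (PDUI units per alt allele).
#' @param alpha trait-mediation coefficient of the causal gene.
#' @param noise_sd PDUI noise SD.
#' @param ld_rho neighbour LD of the panel.
#' @param maf_range panel MAF range.
#' @param n_gwas GWAS sample size for the mediated summary statistics.
#' @param utr_length,breakpoint,depth coverage-layout parameters.
#' @param baseline baseline PDUI.
#' @param seed master seed; stage seeds are derived from it.
#' @return a list: `genotypes` (per-gene list of `genotype_matrix`), `truth`,
#'   `pdui` (genes x samples), `regions` (per-gene UTR layout data.frame),
#'   `sumstats` (per-gene list, only if `n_gwas > 0`), `weights_true`
#'   (standardised-scale causal weights used for mediation).
#' @export
sim_study <- function(n_genes = 10, n_samples = 200, n_cis_variants = 30,
                      causal_gene = 1, beta = 0.08, alpha = 0,
                      noise_sd = 0.08, ld_rho = 0.5,
                      maf_range = c(0.1, 0.5), n_gwas = 0,
                      utr_length = 600L, breakpoint = 250L, depth = 50,
                      baseline = 0.5, seed = 1L) {
  genotypes <- vector("list", n_genes)
  causal <- vector("list", n_genes)
  betas <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    genotypes[[g]] <- sim_genotypes(
      n_samples, n_cis_variants, maf_range = maf_range, ld_rho = ld_rho,
      seed = derive_seed(seed, paste0("geno", g)),
      chrom = as.character(g), pos_start = 2e6L, pos_step = 2000L,
      id_prefix = sprintf("rs%d_", g))
    causal[[g]] <- sample_causal_index(n_cis_variants,
                                       derive_seed(seed, paste0("causal", g)))
    betas[[g]] <- beta
  }
  alpha_vec <- rep(0, n_genes)
  if (causal_gene >= 1) alpha_vec[causal_gene] <- alpha
  truth <- sim_truth(causal, betas, breakpoint = breakpoint,
                     utr_length = utr_length, baseline = baseline,
                     alpha = alpha_vec, noise_sd = noise_sd, seed = seed)

  pdui <- matrix(NA_real_, n_genes, n_samples,
                 dimnames = list(truth$gene_id,
                                 rownames(genotypes[[1]]$dosages)))
  for (g in seq_len(n_genes)) {
    one <- sim_truth(list(truth$causal[[g]]), list(truth$beta[[g]]),
                     breakpoint, utr_length, baseline,
                     noise_sd = noise_sd, seed = seed)
    pdui[g, ] <- sim_pdui(genotypes[[g]], one,
                          seed = derive_seed(seed, paste0("pdui", g)))[1, ]
  }

  # UTR layout: gene g occupies [1e6, 1e6 + utr_length) on chromosome g
  regions <- data.frame(
    chrom = as.character(seq_len(n_genes)),
    utr_start = 1e6L, utr_end = 1e6L + utr_length, strand = "+",
    gene_id = truth$gene_id,
    transcript_id = paste0(truth$gene_id, ".t1"),
    stringsAsFactors = FALSE)

  sumstats <- NULL
  weights_true <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    w <- rep(0, n_cis_variants)
    f <- genotypes[[g]]$variants$af_alt
    # standardised-scale weight of the causal variant
    w[truth$causal[[g]]] <- truth$beta[[g]] *
      sqrt(2 * f[truth$causal[[g]]] * (1 - f[truth$causal[[g]]]))
    weights_true[[g]] <- w
  }
  if (n_gwas > 0) {
    sumstats <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      sd_y <- stats::sd(pdui[g, ])
      w_std <- if (sd_y > 0) weights_true[[g]] / sd_y else weights_true[[g]]
      sumstats[[g]] <- sim_gwas(
        genotypes[[g]], weights = w_std, alpha = alpha_vec[g],
        n_gwas = n_gwas, seed = derive_seed(seed, paste0("gwas", g)))
    }
  }
  list(genotypes = genotypes, truth = truth, pdui = pdui, regions = regions,
       sumstats = sumstats, weights_true = weights_true, seed = seed)
}

sample_causal_index <- function(m, seed) {
  set.seed(seed)
  # keep the causal variant away from the edges so LD neighbours exist
  sample(seq(max(1, m %/% 4), min(m, 3 * m %/% 4)), 1)
}
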