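# cis-3'aQTL mapping: per-SNP simple linear regression of residualized PDUI
# within 1 Mbp of the 3'UTR, gene-level permutation empirical p-values
# (phenotype shuffling; covariates were removed upstream), Storey/BH FDR,
# and QQ-annotation / enrichment diagnostics for GWAS overlap.

#' Enumerate cis gene-variant pairs
#'
#' A pair is included iff the variant lies within
#' `[utr_start - window, utr_end + window]` (closed interval) on the same
#' chromosome.
#'
#' @param regions a [extract_utr_regions()]-style table (needs chrom,
#'   start/utr_start, end/utr_end, transcript_id).
#' @param variants variant table with chrom, pos (1-based), id.
#' @param window cis window in bp (default 1 Mbp).
#' @return data.frame with columns transcript_id, variant_id, region_row,
#'   variant_row.
#' @export
cis_pairs <- function(regions, variants, window = 1e6) {
  rs <- regions$utr_start %||% regions$start
  re <- regions$utr_end %||% regions$end
  out <- lapply(seq_len(nrow(regions)), function(r) {
    hit <- which(variants$chrom == regions$chrom[r] &
                 variants$pos >= rs[r] - window &
                 variants$pos <= re[r] + window)
    if (!length(hit)) return(NULL)
    data.frame(transcript_id = regions$transcript_id[r],
               variant_id = variants$id[hit],
               region_row = r, variant_row = hit,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), variant_id = character(),
                      region_row = integer(), variant_row = integer())
  rownames(out) <- NULL
  out
}

#' Single-SNP association of a residualized phenotype
#'
#' Simple linear regression of the phenotype on the dosage; two-sided
#' t-test with `n - 2` degrees of freedom. Pairs with a missing phenotype
#' or dosage are dropped listwise.
#'
#' @param phenotype residualized phenotype vector.
#' @param dosage dosage vector (same length).
#' @return one-row data.frame: beta, se, t, p, n; or `NULL` (with a message)
#'   if the dosage is monomorphic after missingness.
#' @export
marginal_assoc <- function(phenotype, dosage) {
  keep <- !is.na(phenotype) & !is.na(dosage)
  y <- phenotype[keep]; g <- dosage[keep]
  n <- length(y)
  if (n < 3 || stats::var(g) == 0) {
    message("marginal_assoc: monomorphic or underpowered dosage, skipped")
    return(NULL)
  }
  gx <- g - mean(g); yx <- y - mean(y)
  sxx <- sum(gx^2)
  beta <- sum(gx * yx) / sxx
  rss <- sum((yx - beta * gx)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  data.frame(beta = beta, se = se, t = t, p = p, n = n)
}

#' Gene-level permutation empirical p-value
#'
#' The observed statistic is the minimum nominal p across the gene's cis
#' variants. Each permutation round shuffles the residualized phenotype
#' (covariates were removed once upstream, so no per-round refitting) and
#' recomputes the minimum p. The empirical p is
#' `(1 + #\{perm min-p <= observed\}) / (n_perm + 1)`, which can never be 0
#' and never exceeds 1.
#'
#' @param phenotype residualized phenotype vector (no NAs for the
#'   permutation pass; drop or impute upstream).
#' @param dosages samples x variants cis dosage matrix.
#' @param n_perm permutation rounds (default 1000).
#' @param seed integer seed.
#' @return a list of class `gene_aqtl_summary`: lead_variant, min_p, beta,
#'   empirical_p, n_perm.
#' @export
gene_empirical_p <- function(phenotype, dosages, n_perm = 1000, seed = 1L) {
  dosages <- as.matrix(dosages)
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  X <- standardize_dosages(dosages[keep, , drop = FALSE])
  poly <- apply(X, 2, stats::sd) > 0
  if (!any(poly)) stop("no polymorphic cis variant for this gene")
  X <- X[, poly, drop = FALSE]
  n <- length(y)

  ys <- (y - mean(y)) / stats::sd(y)
  r_obs <- as.vector(crossprod(X, ys)) / (n - 1) /
    apply(X, 2, stats::sd)
  t_obs <- r_obs * sqrt((n - 2) / pmax(1 - r_obs^2, 1e-300))
  p_obs <- 2 * stats::pt(abs(t_obs), df = n - 2, lower.tail = FALSE)
  min_p <- min(p_obs)
  lead <- which.min(p_obs)

  set.seed(seed)
  Xs <- scale(X)                       # centred, unit-sd columns
  Yp <- vapply(seq_len(n_perm), function(b) ys[sample.int(n)],
               numeric(n))             # permuted phenotype, mean 0, sd 1
  perm_max_absr <- apply(abs(crossprod(Xs, Yp)) / (n - 1), 2, max)
  r_min_p <- abs(r_obs[lead])          # max |r| <-> min p (common df)
  emp_p <- (1 + sum(perm_max_absr >= r_min_p)) / (n_perm + 1)
  structure(list(lead_variant = colnames(dosages)[poly][lead],
                 min_p = min_p, beta = r_obs[lead],
                 empirical_p = emp_p, n_perm = n_perm, seed = seed),
            class = "gene_aqtl_summary")
}

#' @export
print.gene_aqtl_summary <- function(x, ...) {
  cat(sprintf(
    "gene_aqtl_summary: lead %s, min p = %.3g, empirical p = %.3g (%d perms)\n",
    x$lead_variant, x$min_p, x$empirical_p, x$n_perm))
  invisible(x)
}

#' Storey q-values (or Benjamini-Hochberg)
#'
#' Storey's estimator with `pi0` estimated at a single `lambda = 0.5`
#' (no spline smoothing): `pi0 = min(1, mean(p > lambda) / (1 - lambda))`,
#' then the step-up `q_i = pi0 * m * p_(i) / i` with the cumulative-minimum
#' enforcement. With `pi0 = 1` this reduces exactly to BH, available
#' directly as `method = "bh"`.
#'
#' @param p vector of p-values in `(0, 1]`.
#' @param method `"storey"` (default) or `"bh"`.
#' @param lambda Storey tuning parameter.
#' @param pi0 optional override of the null proportion.
#' @return q-values in the input order.
#' @export
qvalues <- function(p, method = c("storey", "bh"), lambda = 0.5, pi0 = NULL) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  if (method == "bh") return(stats::p.adjust(p, "BH"))
  if (is.null(pi0)) pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  pmin(1, pi0 * stats::p.adjust(p, "BH"))
}

#' QQ annotation of GWAS p-values by SNP sets
#'
#' For each annotation set (e.g. SNPs that are 3'aQTLs at nominal
#' p < 1e-5), extracts the GWAS p-values of member SNPs, pairs the sorted
#' observed values with uniform expected quantiles, and reports the genomic
#' inflation `lambda = median(chisq) / 0.4549` of the subset.
#'
#' @param gwas data.frame with columns snp and p.
#' @param sets named list of SNP-id character vectors.
#' @param qtl_p_threshold recorded in the output metadata (the nominal
#'   threshold annotation sets are usually built at).
#' @return data.frame: set, expected, observed (both -log10), plus a
#'   `lambda` attribute (named per set). Empty intersections produce a
#'   warning and no rows.
#' @export
annotate_qq <- function(gwas, sets, qtl_p_threshold = 1e-5) {
  stopifnot(all(c("snp", "p") %in% names(gwas)))
  rows <- list(); lambdas <- numeric(0)
  for (nm in names(sets)) {
    pv <- gwas$p[gwas$snp %in% sets[[nm]]]
    pv <- pv[!is.na(pv)]
    if (!length(pv)) {
      warning("annotation set '", nm, "' has empty GWAS intersection")
      next
    }
    k <- length(pv)
    chisq <- stats::qchisq(pv, df = 1, lower.tail = FALSE)
    lambdas[nm] <- stats::median(chisq) / stats::qchisq(0.5, 1)
    rows[[nm]] <- data.frame(
      set = nm,
      expected = -log10(stats::ppoints(k)),
      observed = -log10(sort(pv)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(set = character(), expected = numeric(), observed = numeric())
  rownames(out) <- NULL
  attr(out, "lambda") <- lambdas
  attr(out, "qtl_p_threshold") <- qtl_p_threshold
  out
}

#' Annotation enrichment odds ratio (simplified GARFIELD-style)
#'
#' Tests whether GWAS-significant SNPs are enriched in an annotation set on
#' a background that is LD-pruned (greedy `r^2` pruning when a dosage
#' matrix is supplied) and stratified into MAF bins. The odds ratio is
#' Mantel-Haenszel across MAF bins with a Haldane-Anscombe 0.5 correction
#' on zero cells; the CI is a percentile bootstrap over SNPs. This is a
#' deliberately simplified enrichment control (MAF matching + LD pruning
#' only) and is labelled as such in the output.
#'
#' @param significant character vector of GWAS-significant SNP ids.
#' @param annotation character vector of annotated SNP ids.
#' @param background character vector of all candidate SNP ids (superset of
#'   both).
#' @param maf named numeric vector of MAFs over the background.
#' @param maf_bins number of MAF strata (default 5).
#' @param dosages optional samples x SNPs dosage matrix (columns named) for
#'   LD pruning.
#' @param ld_prune_r2 prune threshold (default 0.8).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return list of class `enrichment_or`: or, ci (2-vector), n_background,
#'   method = "simplified-garfield".
#' @export
enrichment_or <- function(significant, annotation, background, maf,
                          maf_bins = 5, dosages = NULL, ld_prune_r2 = 0.8,
                          n_boot = 1000, seed = 1L) {
  if (!all(significant %in% background) || !all(annotation %in% background))
    stop("background must contain both the significant and annotation sets")
  keep <- background
  if (!is.null(dosages))
    keep <- ld_prune(keep, dosages, ld_prune_r2)
  mafk <- maf[keep]
  bins <- cut(mafk, breaks = unique(stats::quantile(
    mafk, probs = seq(0, 1, length.out = maf_bins + 1))),
    include.lowest = TRUE)
  sig <- keep %in% significant
  ann <- keep %in% annotation

  or_fun <- function(idx) {
    num <- 0; den <- 0
    for (b in levels(bins)) {
      s <- idx[bins[idx] == b]
      if (!length(s)) next
      a <- sum(sig[s] & ann[s]); b2 <- sum(sig[s] & !ann[s])
      c2 <- sum(!sig[s] & ann[s]); d <- sum(!sig[s] & !ann[s])
      if (a == 0 || b2 == 0 || c2 == 0 || d == 0) {
        a <- a + 0.5; b2 <- b2 + 0.5; c2 <- c2 + 0.5; d <- d + 0.5
      }
      nt <- a + b2 + c2 + d
      num <- num + a * d / nt
      den <- den + b2 * c2 / nt
    }
    num / den
  }
  or <- or_fun(seq_along(keep))
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i)
    or_fun(sample.int(length(keep), replace = TRUE)), numeric(1))
  structure(list(or = or,
                 ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
                 n_background = length(keep),
                 method = "simplified-garfield"),
            class = "enrichment_or")
}

#' @export
print.enrichment_or <- function(x, ...) {
  cat(sprintf("enrichment_or (%s): OR = %.3f [%.3f, %.3f], %d background SNPs\n",
              x$method, x$or, x$ci[1], x$ci[2], x$n_background))
  invisible(x)
}

ld_prune <- function(ids, dosages, r2_max) {
  ids <- ids[ids %in% colnames(dosages)]
  kept <- character(0)
  for (id in ids) {
    ok <- TRUE
    for (k in kept) {
      r <- suppressWarnings(stats::cor(dosages[, id], dosages[, k],
                                       use = "complete.obs"))
      if (!is.na(r) && r^2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, id)
  }
  kept
}

#' Map cis-3'aQTLs for a set of genes
#'
#' Convenience driver: for each region, restrict to cis variants, compute
#' per-variant marginal associations and the gene-level permutation
#' empirical p, then attach q-values across genes.
#'
#' @param residuals genes x samples residualized phenotype matrix
#'   (rownames = transcript ids matching `regions$transcript_id`).
#' @param G a `genotype_matrix` covering all samples (rows match columns of
#'   `residuals`).
#' @param regions region table for the phenotype rows.
#' @param window cis window (bp).
#' @param n_perm permutation rounds.
#' @param seed master seed; per-gene seeds are derived from it.
#' @param fdr_method passed to [qvalues()].
#' @return list: `pairs` (per-pair association table), `genes` (per-gene
#'   summary with empirical_p and q).
#' @export
map_aqtl <- function(residuals, G, regions, window = 1e6, n_perm = 1000,
                     seed = 1L, fdr_method = "storey") {
  pairs <- cis_pairs(regions, G$variants, window = window)
  assoc <- list(); gene_rows <- list()
  for (tid in unique(pairs$transcript_id)) {
    sub <- pairs[pairs$transcript_id == tid, ]
    y <- residuals[tid, ]
    dos <- G$dosages[, sub$variant_row, drop = FALSE]
    recs <- lapply(seq_len(nrow(sub)), function(i) {
      r <- marginal_assoc(y, dos[, i])
      if (is.null(r)) return(NULL)
      cbind(data.frame(transcript_id = tid, variant_id = sub$variant_id[i],
                       stringsAsFactors = FALSE), r)
    })
    assoc[[tid]] <- do.call(rbind, recs)
    gsum <- gene_empirical_p(y, dos, n_perm = n_perm,
                             seed = derive_seed(seed, paste0("perm_", tid)))
    gene_rows[[tid]] <- data.frame(
      transcript_id = tid, lead_variant = gsum$lead_variant,
      min_p = gsum$min_p, empirical_p = gsum$empirical_p,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  genes$q <- qvalues(genes$empirical_p, method = fdr_method)
  rownames(genes) <- NULL
  list(pairs = do.call(rbind, assoc), genes = genes)
}
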