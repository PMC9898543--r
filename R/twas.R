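# 3'aTWAS: cis-heritability gating, penalized-regression prediction models
# of residualized PDUI (BLUP/ridge, LASSO, Elastic Net; cross-validated
# selection), harmonization of GWAS summary statistics against the model
# alleles and an LD reference, the weighted summary-statistic association
# Z = w'z / sqrt(w' S w), conditional per-SNP z-scores, and the
# weight-shuffling permutation test.

#' Estimate cis heritability of a residualized phenotype
#'
#' Single-variance-component model `y ~ N(0, s2g K + s2e I)` with
#' `K = X X' / m` from standardised, mean-imputed cis genotypes. The
#' likelihood is profiled over the total variance on the spectral
#' decomposition of K, leaving a 1-D optimization of
#' `h2 = s2g / (s2g + s2e)` on `[0, 1 - 1e-6]`. The test against `h2 = 0`
#' is a likelihood ratio referred to the boundary mixture
#' `0.5 chi2_0 + 0.5 chi2_1`.
#'
#' @param phenotype residualized phenotype vector.
#' @param dosages samples x variants cis dosage matrix.
#' @return list of class `heritability_estimate`: h2, p_lrt, s2_total,
#'   loglik, n, m.
#' @export
estimate_cis_h2 <- function(phenotype, dosages) {
  dosages <- as.matrix(dosages)
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  n <- length(y)
  if (n < 50) warning("cis-h2 estimated on n = ", n, " (< 50): unstable")
  X <- standardize_dosages(dosages[keep, , drop = FALSE])
  m <- ncol(X)
  if (m == 0) stop("no cis variants: kinship not computable")
  y <- y - mean(y)
  K <- tcrossprod(X) / m
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  ystar <- as.vector(crossprod(eig$vectors, y))

  negll <- function(h2) {
    v <- h2 * d + (1 - h2)
    s2 <- mean(ystar^2 / v)
    0.5 * (sum(log(v)) + n * log(s2) + n)
  }
  opt <- stats::optimize(negll, c(0, 1 - 1e-6), tol = 1e-8)
  ll0 <- -negll(0)
  h2 <- opt$minimum
  ll1 <- -opt$objective
  if (ll1 < ll0) { h2 <- 0; ll1 <- ll0 }
  lr <- 2 * (ll1 - ll0)
  p <- if (lr <= 0) 1 else 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  v <- h2 * d + (1 - h2)
  structure(list(h2 = h2, p_lrt = p, s2_total = mean(ystar^2 / v),
                 loglik = ll1, n = n, m = m),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("cis-h2 = %.3f (LRT p = %.3g; n = %d, m = %d variants)\n",
              x$h2, x$p_lrt, x$n, x$m))
  invisible(x)
}

#' Train a cis-SNP prediction model of residualized PDUI
#'
#' The heritability gate is evaluated first: transcripts whose cis-h2
#' likelihood-ratio p is not below `gate_p` (optionally Bonferroni-scaled
#' by `gate_n_tests`) are not trained. Three weight vectors are then fitted
#' on standardised genotypes: BLUP/ridge with the heritability-implied
#' penalty `lambda = m (1 - h2) / h2`, LASSO, and Elastic Net (mixing 0.5).
#' One seeded k-fold split is shared by all methods: it selects each
#' glmnet penalty and supplies out-of-fold predictions at the selected
#' penalty, giving each method a CV R-squared (squared correlation with
#' the phenotype, signed so anti-predictive models count as failures); the
#' best method is selected, with the deterministic tie order
#' BLUP > Elastic Net > LASSO. A transcript whose best CV R-squared is not
#' positive is gated out too.
#'
#' Weights are stored on the standardised-genotype scale with the panel
#' alleles recorded per variant, which keeps the downstream association
#' scale-free and makes harmonization explicit.
#'
#' @param phenotype residualized phenotype vector.
#' @param dosages samples x variants cis dosage matrix (columns named by
#'   variant id).
#' @param variants variant table (id, chrom, pos, ref, alt, maf) aligned
#'   with the dosage columns.
#' @param folds CV fold count (default 5).
#' @param seed integer seed (folds and glmnet paths are seeded).
#' @param gate_p heritability gate (default nominal 0.05).
#' @param gate_n_tests Bonferroni divisor for the gate (default 1 =
#'   nominal mode).
#' @param transcript_id label stored on the model.
#' @return an object of class `weight_model`, or a list of class
#'   `gated_out` (with fields transcript_id, reason, h2, p_lrt).
#' @export
train_weight_model <- function(phenotype, dosages, variants = NULL,
                               folds = 5, seed = 1L, gate_p = 0.05,
                               gate_n_tests = 1, transcript_id = "tx") {
  dosages <- as.matrix(dosages)
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  n <- length(y)
  if (n < folds) stop("fewer samples (", n, ") than folds (", folds, ")")
  X <- standardize_dosages(dosages[keep, , drop = FALSE])
  m <- ncol(X)
  h2est <- estimate_cis_h2(phenotype, dosages)
  thr <- gate_p / gate_n_tests
  if (h2est$p_lrt >= thr)
    return(structure(list(transcript_id = transcript_id,
                          reason = "h2_not_significant",
                          h2 = h2est$h2, p_lrt = h2est$p_lrt),
                     class = "gated_out"))

  h2 <- max(h2est$h2, 0.01)            # penalty floor keeps lambda finite
  yc <- y - mean(y)
  blup_fit <- function(Xtr, ytr) {
    lam <- m * (1 - h2) / h2
    solve(crossprod(Xtr) + diag(lam, ncol(Xtr)), crossprod(Xtr, ytr))
  }

  # One seeded k-fold split serves every method: cv.glmnet picks each
  # penalty on it and (keep = TRUE) returns genuinely out-of-fold
  # predictions at that penalty, the standard TWAS weight-training design.
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), n))
  preds <- matrix(NA_real_, n, 3,
                  dimnames = list(NULL, c("blup", "lasso", "enet")))
  glmnet_cv <- function(alpha) {
    cv <- glmnet::cv.glmnet(X, yc, alpha = alpha, foldid = foldid,
                            nlambda = 50, standardize = FALSE, keep = TRUE)
    i <- match(cv$lambda.min, cv$lambda)
    list(w = as.vector(stats::coef(cv, s = "lambda.min"))[-1],
         oof = cv$fit.preval[, i])
  }
  lasso <- glmnet_cv(1)
  enet <- glmnet_cv(0.5)
  preds[, "lasso"] <- lasso$oof
  preds[, "enet"] <- enet$oof
  for (f in seq_len(folds)) {
    tr <- foldid != f
    preds[!tr, "blup"] <- X[!tr, , drop = FALSE] %*%
      blup_fit(X[tr, , drop = FALSE], yc[tr])
  }
  cv_r2 <- apply(preds, 2, function(p) {
    if (stats::sd(p) == 0) return(NA_real_)
    stats::cor(p, yc)^2 * sign(stats::cor(p, yc))
  })
  if (all(is.na(cv_r2)) || max(cv_r2, na.rm = TRUE) <= 0)
    return(structure(list(transcript_id = transcript_id,
                          reason = "no_positive_cv_r2",
                          h2 = h2est$h2, p_lrt = h2est$p_lrt),
                     class = "gated_out"))
  precedence <- c(blup = 1, enet = 2, lasso = 3)
  best <- names(cv_r2)[order(-cv_r2, precedence[names(cv_r2)])][1]

  weights <- cbind(blup = as.vector(blup_fit(X, yc)),
                   lasso = lasso$w, enet = enet$w)
  rownames(weights) <- colnames(dosages)
  if (is.null(variants))
    variants <- data.frame(id = colnames(dosages), chrom = NA, pos = NA,
                           ref = "A", alt = "G", maf = colMeans(X^0) * NA)
  structure(list(transcript_id = transcript_id, variants = variants,
                 weights = weights, cv_r2 = cv_r2, selected = best,
                 h2 = h2est$h2, p_lrt = h2est$p_lrt, n = n,
                 r2_over_h2 = if (h2est$h2 > 0)
                   unname(cv_r2[best]) / h2est$h2 else NA_real_,
                 folds = folds, seed = seed),
            class = "weight_model")
}

#' @export
print.weight_model <- function(x, ...) {
  cat(sprintf("weight_model %s: %d variants, selected %s (CV R2 = %.3f)\n",
              x$transcript_id, nrow(x$weights), x$selected,
              x$cv_r2[x$selected]))
  cat(sprintf("  cis-h2 = %.3f (p = %.3g), R2/h2 = %.2f, n = %d\n",
              x$h2, x$p_lrt, x$r2_over_h2, x$n))
  invisible(x)
}

#' @export
coef.weight_model <- function(object, method = object$selected, ...) {
  stats::setNames(object$weights[, method], rownames(object$weights))
}

#' Predict PDUI from genotypes with a trained weight model
#' @param object a `weight_model`.
#' @param newdata dosage matrix with columns named by variant id.
#' @param method weight column to use (default the selected one).
#' @param ... unused.
#' @return numeric predictions (standardised-phenotype scale).
#' @export
predict.weight_model <- function(object, newdata,
                                 method = object$selected, ...) {
  ids <- rownames(object$weights)
  if (!all(ids %in% colnames(newdata)))
    stop("newdata lacks model variants: ",
         paste(setdiff(ids, colnames(newdata))[1:3], collapse = ", "))
  X <- standardize_dosages(as.matrix(newdata)[, ids, drop = FALSE])
  as.vector(X %*% object$weights[, method])
}

# Sentinel for associations that cannot be computed; carries the reason.
skipped_assoc <- function(reason)
  structure(list(reason = reason), class = "skipped_assoc")

#' Test whether a harmonization or association result was skipped
#' @param x object returned by [harmonize()] or [twas_z()].
#' @return logical; the reason string sits in `x$reason`.
#' @export
is_skipped <- function(x) inherits(x, "skipped_assoc")

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize GWAS summary statistics against a weight model and LD panel
#'
#' Drops strand-ambiguous (A/T, C/G) variants, indels, and variants with
#' panel MAF <= `maf_min`; matches the remaining variants between the
#' sumstats, the model, and the LD reference; negates z where the sumstats
#' effect/other alleles are swapped relative to the model alleles; and
#' returns the aligned `(w, z, Sigma)` triple with the LD matrix shrunk
#' toward the identity, `Sigma = (1 - theta) R + theta I`, so the
#' association denominator is positive definite with finite panels.
#' Applying the function to its own output is the identity.
#'
#' @param sumstats a `gwas_sumstats` data.frame (snp, a1, a2, z, n).
#' @param model a `weight_model`.
#' @param ld_ref `genotype_matrix` (or list with `dosages`, `variants`)
#'   supplying the LD reference; the LD source must be explicit.
#' @param maf_min MAF filter (default 0.01; variants at or below it drop).
#' @param theta LD shrinkage weight (default 0.1).
#' @param method weight column to extract.
#' @return list of class `harmonized_triple`: w, z, Sigma, variants,
#'   n_gwas, dropped (named counts per filter); or a `skipped_assoc`
#'   sentinel (see [is_skipped()]) when fewer than one variant survives.
#' @export
harmonize <- function(sumstats, model, ld_ref, maf_min = 0.01, theta = 0.1,
                      method = model$selected) {
  v <- model$variants
  w_all <- model$weights[, method]
  dropped <- c(ambiguous = 0L, indel = 0L, maf = 0L, unmatched = 0L,
               allele_mismatch = 0L)

  snp_ok <- nchar(v$ref) == 1 & nchar(v$alt) == 1 &
    v$ref %in% c("A", "C", "G", "T") & v$alt %in% c("A", "C", "G", "T")
  dropped["indel"] <- sum(!snp_ok)
  amb <- snp_ok & is_ambiguous_pair(v$ref, v$alt)
  dropped["ambiguous"] <- sum(amb)
  maf_bad <- !is.na(v$maf) & v$maf <= maf_min
  dropped["maf"] <- sum(snp_ok & !amb & maf_bad)
  keep <- snp_ok & !amb & !maf_bad

  idx_ss <- match(v$id, sumstats$snp)
  idx_ld <- match(v$id, ld_ref$variants$id)
  dropped["unmatched"] <- sum(keep & (is.na(idx_ss) | is.na(idx_ld)))
  keep <- keep & !is.na(idx_ss) & !is.na(idx_ld)

  z <- rep(NA_real_, nrow(v))
  same <- sumstats$a1[idx_ss] == v$alt & sumstats$a2[idx_ss] == v$ref
  swap <- sumstats$a1[idx_ss] == v$ref & sumstats$a2[idx_ss] == v$alt
  z[which(same)] <- sumstats$z[idx_ss[which(same)]]
  z[which(swap)] <- -sumstats$z[idx_ss[which(swap)]]
  mism <- keep & !(same %in% TRUE) & !(swap %in% TRUE)
  dropped["allele_mismatch"] <- sum(mism)
  keep <- keep & !mism

  if (sum(keep) < 1)
    return(skipped_assoc("no_surviving_variant"))
  ids <- v$id[keep]
  R <- stats::cor(ld_ref$dosages[, match(ids, ld_ref$variants$id),
                                 drop = FALSE])
  Sigma <- (1 - theta) * R + theta * diag(nrow(R))
  structure(list(w = unname(w_all[keep]), z = unname(z[keep]),
                 Sigma = Sigma, variants = v[keep, , drop = FALSE],
                 n_gwas = sumstats$n[idx_ss[keep]][1],
                 dropped = dropped, theta = theta, method = method),
            class = "harmonized_triple")
}

#' Summary-statistic TWAS association
#'
#' The standard weighted form `Z = w'z / sqrt(w' Sigma w)`, with
#' `p = 2 Phi(-|Z|)`. Invariant to rescaling `w` by a positive constant.
#'
#' @param w weight vector.
#' @param z aligned GWAS z-scores.
#' @param Sigma shrunk LD matrix.
#' @param tol denominator tolerance; below it the association is
#'   non-computable.
#' @return list: Z, p, denom; or a `skipped_assoc` sentinel with reason
#'   `"degenerate_denominator"`.
#' @export
twas_z <- function(w, z, Sigma, tol = 1e-8) {
  stopifnot(length(w) == length(z), nrow(Sigma) == length(w))
  denom2 <- as.numeric(t(w) %*% Sigma %*% w)
  if (denom2 <= tol)
    return(skipped_assoc("degenerate_denominator"))
  Z <- sum(w * z) / sqrt(denom2)
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)), denom = sqrt(denom2))
}

#' Scan all weight models against one GWAS
#'
#' Harmonizes each model, computes the association Z and p, and attaches
#' FDR q-values across the scan (Benjamini-Hochberg by default). Models
#' that cannot be tested are listed with reason codes. The scan result is
#' invariant to model ordering.
#'
#' @param models list of `weight_model`s (gated-out entries are skipped
#'   with a reason).
#' @param sumstats a `gwas_sumstats` table.
#' @param ld_ref LD reference; a single `genotype_matrix` shared by all
#'   models or a list parallel to `models`.
#' @param maf_min,theta passed to [harmonize()].
#' @param fdr_method `"bh"` (default) or `"storey"`.
#' @return an object of class `twas_scan`: `results` (data.frame:
#'   transcript_id, Z, p, q, n_snps), `skipped` (data.frame:
#'   transcript_id, reason).
#' @export
twas_scan <- function(models, sumstats, ld_ref, maf_min = 0.01, theta = 0.1,
                      fdr_method = "bh") {
  per_model_ld <- is.list(ld_ref) && !inherits(ld_ref, "genotype_matrix")
  per_model_ss <- is.list(sumstats) && !inherits(sumstats, "data.frame")
  rows <- list(); skipped <- list()
  for (i in seq_along(models)) {
    mod <- models[[i]]
    if (inherits(mod, "gated_out")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(transcript_id = mod$transcript_id, reason = mod$reason)
      next
    }
    ld <- if (per_model_ld) ld_ref[[i]] else ld_ref
    ss <- if (per_model_ss) sumstats[[i]] else sumstats
    h <- harmonize(ss, mod, ld, maf_min = maf_min, theta = theta)
    if (is_skipped(h)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(transcript_id = mod$transcript_id,
                   reason = "no_surviving_variant")
      next
    }
    tz <- twas_z(h$w, h$z, h$Sigma)
    if (is_skipped(tz)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(transcript_id = mod$transcript_id,
                   reason = "degenerate_denominator")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = mod$transcript_id, Z = tz$Z, p = tz$p,
      n_snps = length(h$w), stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows) %||%
    data.frame(transcript_id = character(), Z = numeric(), p = numeric(),
               n_snps = integer())
  if (nrow(results)) {
    ord <- order(results$transcript_id)
    results <- results[ord, , drop = FALSE]
    results$q <- qvalues(results$p, method = fdr_method)
    results <- results[order(results$p), , drop = FALSE]
    rownames(results) <- NULL
  }
  structure(list(results = results,
                 skipped = do.call(rbind, skipped) %||%
                   data.frame(transcript_id = character(),
                              reason = character())),
            class = "twas_scan")
}

#' @export
print.twas_scan <- function(x, ...) {
  cat(sprintf("twas_scan: %d tested, %d skipped, %d at q < 0.05\n",
              nrow(x$results), nrow(x$skipped), sum(x$results$q < 0.05)))
  if (nrow(x$results)) print(utils::head(x$results, 5))
  invisible(x)
}

#' Per-SNP GWAS z-scores conditional on the TWAS association
#'
#' With `c = Sigma w / sqrt(w' Sigma w)`, the conditioned score of SNP j is
#' `(z_j - c_j Z_twas) / sqrt(max(1 - c_j^2, eps))` — the GWAS signal left
#' after removing the component explained by the predicted molecular
#' phenotype, for regional plots.
#'
#' @param z aligned z-scores.
#' @param w weights.
#' @param Sigma shrunk LD matrix.
#' @param Z_twas the association Z (recomputed when `NULL`).
#' @param eps variance floor.
#' @return data.frame: z_raw, z_conditional, c.
#' @export
conditional_z <- function(z, w, Sigma, Z_twas = NULL, eps = 1e-6) {
  denom <- sqrt(as.numeric(t(w) %*% Sigma %*% w))
  if (is.null(Z_twas)) Z_twas <- sum(w * z) / denom
  cc <- as.vector(Sigma %*% w) / denom
  zc <- (z - cc * Z_twas) / sqrt(pmax(1 - cc^2, eps))
  data.frame(z_raw = z, z_conditional = zc, c = cc)
}

#' Weight-shuffling permutation p-value for a TWAS association
#'
#' Permutes the assignment of weights to variants and recomputes `|Z|` each
#' round; the empirical p is `(1 + #{|Z_perm| >= |Z_obs|}) / (n_perm + 1)`.
#' A significant permutation p indicates the association is driven by the
#' specific weight profile rather than by the locus-wide GWAS signal.
#'
#' @param w,z,Sigma harmonized triple (>= 2 variants).
#' @param n_perm rounds (default 100000).
#' @param seed integer seed.
#' @return list: p_perm, Z_obs, n_perm, degenerate (TRUE when all weights
#'   are equal, forcing p = 1).
#' @export
weight_permutation_p <- function(w, z, Sigma, n_perm = 1e5, seed = 1L) {
  m <- length(w)
  if (m < 2) stop("permutation test needs >= 2 variants")
  obs <- twas_z(w, z, Sigma)
  if (is_skipped(obs)) stop("observed association non-computable")
  degenerate <- length(unique(w)) == 1L
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    wp <- w[sample.int(m)]
    d2 <- as.numeric(t(wp) %*% Sigma %*% wp)
    if (d2 <= 1e-12) next
    if (abs(sum(wp * z)) / sqrt(d2) >= abs(obs$Z)) count <- count + 1L
  }
  list(p_perm = (1 + count) / (n_perm + 1), Z_obs = obs$Z,
       n_perm = n_perm, degenerate = degenerate)
}
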