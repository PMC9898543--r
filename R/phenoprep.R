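# Phenotype preparation: rank-based inverse-normal transform of PDUI,
# genotype principal components, hidden-factor estimation on residuals
# (a factor-analytic estimator of PEER-style hidden confounders), and
# per-gene residualisation against covariates. The fixed pipeline order is
# transform -> residualize(known + genotype PCs) -> hidden factors on the
# residuals -> residualize(hidden factors).

#' Rank-based inverse normal transform
#'
#' Non-missing values are replaced by `qnorm(rank / (n + 1))` with average
#' ranks on ties; missing values stay missing. The output depends on the
#' ranks only, so any strictly monotone transform of the input gives an
#' identical result — which is what makes it robust to the bounded
#' `[0, 1]` support of PDUI.
#'
#' @param values numeric vector, possibly with NAs.
#' @return transformed vector of the same length.
#' @export
inverse_normal_transform <- function(values) {
  obs <- !is.na(values)
  x <- values[obs]
  if (length(x) < 3) stop("need at least 3 non-missing values")
  if (length(unique(x)) == 1L)
    stop("all non-missing values identical; ranks undefined")
  out <- values
  n <- length(x)
  out[obs] <- stats::qnorm(rank(x, ties.method = "average") / (n + 1))
  out
}

#' Genotype principal components
#'
#' PCs of the individuals x standardised-dosage matrix: missing dosages are
#' mean-imputed, columns centred at `2f` and scaled by `sqrt(2 f (1 - f))`
#' with `f` the alt-allele frequency. The sign of each PC is fixed so that
#' its largest-magnitude variant loading is positive, making the output
#' reproducible across LAPACK builds.
#'
#' @param G a `genotype_matrix` or a plain dosage matrix.
#' @param k number of components (default 5, the usual ancestry adjustment).
#' @return individuals x k matrix of PC scores (columns `PC1..PCk`). If the
#'   genotype matrix has rank below `k`, the available PCs are returned with
#'   a warning.
#' @export
genotype_pcs <- function(G, k = 5) {
  dos <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  if (k >= min(dim(dos))) stop("k must be < min(n_individuals, n_variants)")
  X <- standardize_dosages(dos)
  sv <- svd(X, nu = k, nv = k)
  pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  avail <- min(k, sum(pos))
  if (avail < k)
    warning("genotype matrix rank ", sum(pos), " < k = ", k,
            "; returning ", avail, " PCs")
  scores <- sv$u[, seq_len(avail), drop = FALSE] %*%
    diag(sv$d[seq_len(avail)], avail)
  for (j in seq_len(avail)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(dos), paste0("PC", seq_len(avail)))
  scores
}

standardize_dosages <- function(dos) {
  dos <- as.matrix(dos)
  for (j in seq_len(ncol(dos))) {
    m <- is.na(dos[, j])
    if (any(m)) dos[m, j] <- mean(dos[!m, j])
  }
  f <- colMeans(dos) / 2
  sdv <- sqrt(2 * f * (1 - f))
  sdv[sdv == 0] <- 1
  sweep(sweep(dos, 2, 2 * f, "-"), 2, sdv, "/")
}

#' Hidden covariate factors from a residual phenotype matrix
#'
#' Top-k principal factors of the gene x sample residual matrix (genes
#' standardised; missing cells mean-imputed per gene for the decomposition
#' only), returned as sample-level covariates. This captures broad hidden
#' structure — batches, unmodelled technical variation — the way PEER-style
#' hidden confounder estimators are used in QTL pipelines.
#'
#' The default factor count follows the sample-size schedule commonly used
#' for expression QTL mapping: 15 below 150 samples, 30 for 150-249, 35 for
#' 250-349, and 60 from 350 up (see [default_hidden_k()]).
#'
#' @param resid_pheno genes x samples residual matrix.
#' @param k number of factors; `k = 0` returns an empty matrix.
#' @return samples x k matrix (columns `HF1..HFk`).
#' @export
hidden_factors <- function(resid_pheno, k) {
  resid_pheno <- as.matrix(resid_pheno)
  n <- ncol(resid_pheno)
  if (k >= n) stop("k must be < number of samples")
  if (k == 0)
    return(matrix(numeric(0), n, 0,
                  dimnames = list(colnames(resid_pheno), character(0))))
  Z <- t(apply(resid_pheno, 1, function(y) {
    m <- is.na(y)
    if (any(m)) y[m] <- mean(y[!m])
    s <- stats::sd(y)
    if (is.na(s) || s == 0) rep(0, length(y)) else (y - mean(y)) / s
  }))
  sv <- svd(Z, nu = k, nv = k)
  fac <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    u <- sv$u[, j]
    if (u[which.max(abs(u))] < 0) fac[, j] <- -fac[, j]
  }
  dimnames(fac) <- list(colnames(resid_pheno), paste0("HF", seq_len(k)))
  fac
}

#' Default hidden-factor count by sample size
#' @param n_samples number of samples.
#' @return integer factor count.
#' @export
default_hidden_k <- function(n_samples) {
  if (n_samples < 150) 15L
  else if (n_samples < 250) 30L
  else if (n_samples < 350) 35L
  else 60L
}

#' Residualize phenotypes against covariates
#'
#' Per gene, ordinary least-squares residuals of the phenotype on
#' `[intercept + covariates]`; rows with missing phenotype stay missing.
#' Categorical covariate columns (factors/characters) are dummy-encoded.
#' Residuals are exactly uncorrelated with every covariate column, and the
#' operation is idempotent.
#'
#' @param phenotypes genes x samples matrix (NAs allowed).
#' @param covariates samples x p matrix or data.frame; `NULL` or zero
#'   columns means intercept only (mean-centring).
#' @return residual matrix, same shape as `phenotypes`.
#' @export
residualize <- function(phenotypes, covariates = NULL) {
  phenotypes <- as.matrix(phenotypes)
  n <- ncol(phenotypes)
  X <- build_design(covariates, n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("covariate matrix rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  out <- phenotypes
  complete <- !apply(phenotypes, 1, anyNA)
  if (any(complete))
    out[complete, ] <- t(qr.resid(qrX, t(phenotypes[complete, , drop = FALSE])))
  for (g in which(!complete)) {
    obs <- !is.na(phenotypes[g, ])
    q <- qr(X[obs, , drop = FALSE])
    if (q$rank < ncol(X))
      stop("covariates rank deficient after dropping missing cells of row ", g)
    out[g, obs] <- qr.resid(q, phenotypes[g, obs])
  }
  out
}

build_design <- function(covariates, n) {
  if (is.null(covariates) || NCOL(covariates) == 0)
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  df <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (nrow(df) != n) stop("covariate rows do not match sample count")
  for (j in seq_along(df))
    if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  X <- stats::model.matrix(~ ., data = df)
  const <- apply(X[, -1, drop = FALSE], 2, function(x) stats::sd(x) == 0)
  if (any(const))
    stop("constant covariate column(s) after encoding: ",
         paste(names(const)[const], collapse = ", "))
  X
}

#' Run the full phenotype-preparation pipeline
#'
#' Fixed order: inverse-normal transform each transcript; residualize
#' against known covariates plus genotype PCs; estimate hidden factors on
#' those residuals; residualize against the hidden factors. Missing cells
#' are mean-imputed only inside the factor estimation, never in the
#' returned phenotypes.
#'
#' @param pdui a `pdui_matrix` or plain genes x samples matrix.
#' @param known_covariates samples x p table (may be `NULL`).
#' @param G optional `genotype_matrix` for genotype PCs.
#' @param n_pcs genotype PC count (default 5).
#' @param hidden_k hidden-factor count; `NULL` uses [default_hidden_k()].
#' @return list: `residuals` (genes x samples), `covariates` (assembled
#'   design), `hidden` (factor matrix), `log` (character, pipeline record).
#' @export
prep_phenotypes <- function(pdui, known_covariates = NULL, G = NULL,
                            n_pcs = 5, hidden_k = NULL) {
  values <- if (inherits(pdui, "pdui_matrix")) pdui$values else as.matrix(pdui)
  n <- ncol(values)
  if (is.null(hidden_k)) hidden_k <- min(default_hidden_k(n), n - 1L)
  ph <- t(apply(values, 1, inverse_normal_transform))
  dimnames(ph) <- dimnames(values)
  cov1 <- known_covariates
  if (!is.null(G)) {
    pcs <- genotype_pcs(G, k = n_pcs)
    cov1 <- if (is.null(cov1)) pcs else cbind(as.data.frame(cov1), pcs)
  }
  r1 <- residualize(ph, cov1)
  hid <- hidden_factors(r1, k = hidden_k)
  r2 <- if (hidden_k > 0) residualize(r1, hid) else r1
  list(residuals = r2, covariates = cov1, hidden = hid,
       log = c(sprintf("inverse_normal_transform on %d transcripts", nrow(ph)),
               sprintf("residualize: %d known/PC columns",
                       if (is.null(cov1)) 0L else NCOL(cov1)),
               sprintf("hidden_factors: k = %d", hidden_k),
               "residualize: hidden factors"))
}
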