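test_that("cis-h2: noiseless limit, null calibration, parameter recovery", {
  pan <- make_causal_panel(n = 200, m = 10, b = 1, noise = 1e-8, seed = 41)
  X <- apatwas:::standardize_dosages(pan$g$dosages)
  h <- suppressWarnings(estimate_cis_h2(X[, pan$causal], pan$g$dosages))
  expect_gt(h$h2, 0.99)                       # at the upper bound
  expect_lt(h$p_lrt, 1e-6)

  # null size of the boundary-mixture LRT
  set.seed(42)
  rej <- vapply(1:200, function(i) {
    g <- sim_genotypes(300, 30, seed = 600 + i)
    estimate_cis_h2(rnorm(300), g$dosages)$p_lrt < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02); expect_lte(mean(rej), 0.08)

  # recovery of h2 = 0.3 at n = 500, m = 200
  set.seed(43)
  h2s <- vapply(1:50, function(i) {
    g <- sim_genotypes(500, 200, seed = 700 + i)
    X <- apatwas:::standardize_dosages(g$dosages)
    b <- rnorm(200, 0, sqrt(0.3 / 200))
    y <- as.vector(X %*% b) + rnorm(500, 0, sqrt(0.7))
    estimate_cis_h2(y, g$dosages)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2s) - 0.3), 0.07)

  expect_error(estimate_cis_h2(rnorm(100),
                               matrix(nrow = 100, ncol = 0)), "no cis")
})

test_that("weight training recovers a strong causal SNP and gates out noise", {
  pan <- make_causal_panel(n = 300, m = 20, b = 0.5, noise = 0.2, seed = 44)
  m <- train_weight_model(pan$y, pan$g$dosages, variants = pan$g$variants,
                          seed = 45)
  expect_s3_class(m, "weight_model")
  expect_equal(which.max(abs(coef(m))), pan$causal, ignore_attr = TRUE)
  expect_equal(m$selected, names(which.max(m$cv_r2)))

  # same seed -> identical weights and CV R2
  m2 <- train_weight_model(pan$y, pan$g$dosages, variants = pan$g$variants,
                           seed = 45)
  expect_identical(m$weights, m2$weights)
  expect_identical(m$cv_r2, m2$cv_r2)

  # pure-noise phenotypes are gated out in >= 90% of reps
  gated <- vapply(1:50, function(i) {
    g <- sim_genotypes(150, 15, seed = 800 + i)
    set.seed(900 + i)
    inherits(train_weight_model(rnorm(150), g$dosages, seed = i),
             "gated_out")
  }, logical(1))
  expect_gte(mean(gated), 0.9)

  expect_error(train_weight_model(rnorm(3), matrix(0:2, 3, 2), folds = 5),
               "fewer samples")
})

test_that("BLUP weights approach OLS as h2 approaches 1", {
  pan <- make_causal_panel(n = 400, m = 5, causal = 3, b = 0.8,
                           noise = 1e-6, seed = 46)
  m <- suppressWarnings(
    train_weight_model(pan$y, pan$g$dosages, variants = pan$g$variants,
                       seed = 47))
  X <- apatwas:::standardize_dosages(pan$g$dosages)
  yc <- pan$y - mean(pan$y)
  ols <- solve(crossprod(X), crossprod(X, yc))
  expect_equal(unname(m$weights[, "blup"]), as.vector(ols),
               tolerance = 1e-2)
})

test_that("harmonization drops the contracted variant classes and flips z", {
  g <- sim_genotypes(100, 40, seed = 48, frac_ambiguous = 0.2,
                     frac_indel = 0.1)
  pan_y <- as.vector(apatwas:::standardize_dosages(g$dosages)[, 5]) +
    rnorm(100, 0, 0.8)
  m <- train_weight_model(pan_y, g$dosages, variants = g$variants, seed = 49)
  expect_s3_class(m, "weight_model")   # fixture is strongly heritable
  ss <- sim_gwas(g, n_gwas = 1e4, seed = 50)

  h <- harmonize(ss, m, g, maf_min = 0.01)
  expect_equal(unname(h$dropped["ambiguous"]),
               sum(apatwas:::is_ambiguous_pair(g$variants$ref,
                                               g$variants$alt)))
  expect_equal(unname(h$dropped["indel"]),
               sum(nchar(g$variants$ref) > 1 | nchar(g$variants$alt) > 1))
  expect_false(any(h$variants$maf <= 0.01))

  # swapped alleles negate z; harmonizing the already-aligned set is identity
  ss_sw <- ss
  ss_sw$a1 <- ss$a2; ss_sw$a2 <- ss$a1; ss_sw$z <- -ss$z
  h_sw <- harmonize(ss_sw, m, g)
  expect_equal(h_sw$z, h$z, tolerance = 1e-12)
  aligned <- data.frame(snp = h$variants$id, a1 = h$variants$alt,
                        a2 = h$variants$ref, z = h$z, n = 1e4)
  h2 <- harmonize(aligned, m, g)
  expect_equal(h2$z, h$z[match(h2$variants$id, h$variants$id)])

  # MAF filter: a variant at MAF 0.005 is dropped
  g2 <- g
  g2$variants$maf[1] <- 0.005
  m2 <- m; m2$variants <- g2$variants
  h3 <- harmonize(ss, m2, g2)
  expect_false(g2$variants$id[1] %in% h3$variants$id)
})

test_that("TWAS statistic: hand values, antisymmetry, scale invariance", {
  expect_equal(twas_z(1, 3.2, matrix(1))$Z, 3.2)
  expect_equal(twas_z(c(1, 1), c(2, 2), diag(2))$Z, 4 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(twas_z(c(1, -1), c(2, 2), diag(2))$Z, 0)

  set.seed(51)
  w <- rnorm(8); z <- rnorm(8)
  S <- crossprod(matrix(rnorm(64), 8)) / 8 + diag(8) * 0.5
  expect_equal(twas_z(3.7 * w, z, S)$Z, twas_z(w, z, S)$Z,
               tolerance = 1e-12)

  degenerate <- twas_z(c(0, 0), c(1, 1), diag(2))
  expect_true(is_skipped(degenerate))
  expect_equal(degenerate$reason, "degenerate_denominator")
})

test_that("summary-statistic Z matches the individual-level two-stage Z", {
  set.seed(52)
  n <- 5000
  g <- sim_genotypes(n, 25, ld_rho = 0.4, seed = 53)
  X <- apatwas:::standardize_dosages(g$dosages)
  y_mol <- as.vector(X[, 12] * sqrt(0.25)) + rnorm(n, 0, sqrt(0.75))
  m <- train_weight_model(y_mol, g$dosages, variants = g$variants, seed = 54)
  trait <- 0.05 * scale(y_mol) + rnorm(n)

  # individual level: regress the trait on model-predicted PDUI
  pred <- predict(m, g$dosages)
  z_ind <- marginal_assoc(as.vector(trait), pred)$t

  # summary level: per-SNP GWAS z-scores from the same data
  zs <- vapply(seq_len(25), function(j)
    marginal_assoc(as.vector(trait), g$dosages[, j])$t, numeric(1))
  ss <- data.frame(snp = g$variants$id, a1 = g$variants$alt,
                   a2 = g$variants$ref, z = zs, n = n)
  class(ss) <- c("gwas_sumstats", "data.frame")
  h <- harmonize(ss, m, g, theta = 0)   # same panel: no shrinkage needed
  z_sum <- twas_z(h$w, h$z, h$Sigma)$Z
  expect_lt(abs(z_sum - z_ind) / abs(z_ind), 0.1)
})

test_that("conditional z removes the modelled signal where expected", {
  expect_equal(conditional_z(3, 1, matrix(1))$z_conditional, 0,
               tolerance = 1e-9)

  # a variant orthogonal to the weights keeps its z
  S <- diag(3)
  cz <- conditional_z(c(2, 1, 1.5), c(0, 1, 1), S)
  expect_equal(cz$z_conditional[1], 2, tolerance = 1e-12)

  # mediated locus: conditioning collapses the signal
  set.seed(55)
  g <- sim_genotypes(400, 20, ld_rho = 0.5, seed = 56)
  X <- apatwas:::standardize_dosages(g$dosages)
  y <- as.vector(X[, 10] * sqrt(0.3)) + rnorm(400, 0, sqrt(0.7))
  m <- train_weight_model(y, g$dosages, variants = g$variants, seed = 57)
  w_true <- rep(0, 20); w_true[10] <- sqrt(0.3) / sd(y)
  drops <- vapply(1:10, function(i) {
    ss <- sim_gwas(g, weights = w_true, alpha = 0.1, n_gwas = 5e4,
                   seed = 1000 + i)
    h <- harmonize(ss, m, g)
    tz <- twas_z(h$w, h$z, h$Sigma)
    cz <- conditional_z(h$z, h$w, h$Sigma, tz$Z)
    max(abs(cz$z_conditional)) < qnorm(1 - 5e-8 / 2)
  }, logical(1))
  expect_gte(mean(drops), 0.8)
})

test_that("weight permutation test: invariance, floor, and planted signal", {
  S <- diag(4)
  pe <- weight_permutation_p(rep(0.3, 4), c(3, 0, 0, 0), S, n_perm = 200,
                             seed = 58)
  expect_equal(pe$p_perm, 1)              # equal weights: every perm ties
  expect_true(pe$degenerate)

  z <- c(6, 0.1, -0.2, 0.3, 0.1)
  w <- c(1, 0, 0, 0, 0)
  pp <- weight_permutation_p(w, z, diag(5), n_perm = 500, seed = 59)
  expect_equal(pp$p_perm, (1 + 96) / 501, tolerance = 0.15)  # ~ 1/5 + noise
  expect_gte(pp$p_perm, 1 / 501)

  # lead-SNP-concentrated weights vs diffuse z: permutation p near the
  # 1/m floor set by relocating the dominant weight (m = 30 here)
  set.seed(60)
  small <- vapply(1:20, function(i) {
    z <- c(5, rnorm(29, 0, 0.5))
    w <- c(1, abs(rnorm(29, 0, 0.01)))
    weight_permutation_p(w, z, diag(30), n_perm = 400,
                         seed = 1100 + i)$p_perm
  }, numeric(1))
  expect_gte(mean(small < 0.05), 0.9)
  expect_error(weight_permutation_p(1, 2, matrix(1)), ">= 2 variants")
})

test_that("the scan ranks a mediated gene first and is order invariant", {
  set.seed(61)
  study <- sim_study(n_genes = 6, n_samples = 300, causal_gene = 2,
                     alpha = 0.1, n_gwas = 5e4, seed = 62)
  resid <- t(apply(study$pdui, 1, inverse_normal_transform))
  models <- lapply(1:6, function(g) train_weight_model(
    resid[g, ], study$genotypes[[g]]$dosages,
    variants = study$genotypes[[g]]$variants,
    seed = derive_seed(62, paste0("t", g)),
    transcript_id = study$truth$gene_id[g]))
  scan <- twas_scan(models, study$sumstats, study$genotypes)
  expect_equal(scan$results$transcript_id[which.max(abs(scan$results$Z))],
               "gene002")

  ord <- c(4, 2, 6, 1, 3, 5)
  scan2 <- twas_scan(models[ord], study$sumstats[ord],
                     study$genotypes[ord])
  expect_equal(scan$results, scan2$results)
})
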