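test_that("cis pair enumeration uses a closed window on the right chromosome", {
  regions <- data.frame(chrom = "1", utr_start = 2e6, utr_end = 2e6 + 400,
                        transcript_id = "t1")
  variants <- data.frame(chrom = c("1", "1", "1", "2"),
                         pos = c(2e6 - 1e6, 2e6 - 1e6 - 1, 2.4e6 + 1e6, 2e6),
                         id = paste0("v", 1:4))
  pr <- cis_pairs(regions, variants, window = 1e6)
  expect_true("v1" %in% pr$variant_id)    # exactly window bp away: included
  expect_false("v2" %in% pr$variant_id)   # window + 1 bp: excluded
  expect_false("v4" %in% pr$variant_id)   # wrong chromosome

  # brute-force interval oracle on a random toy layout
  set.seed(31)
  regions <- data.frame(chrom = as.character(sample(1:2, 3, TRUE)),
                        utr_start = sample(1e6, 3), transcript_id = paste0("t", 1:3))
  regions$utr_end <- regions$utr_start + 500
  variants <- data.frame(chrom = as.character(sample(1:2, 10, TRUE)),
                         pos = sample(2e6, 10), id = paste0("v", 1:10))
  w <- 2e5
  pr <- cis_pairs(regions, variants, window = w)
  manual <- sum(vapply(1:3, function(r) sum(
    variants$chrom == regions$chrom[r] &
      variants$pos >= regions$utr_start[r] - w &
      variants$pos <= regions$utr_end[r] + w), numeric(1)))
  expect_equal(nrow(pr), manual)
})

test_that("marginal association matches the closed-form OLS oracle", {
  # textbook 6-point simple regression, all quantities by hand
  g <- c(0, 0, 1, 1, 2, 2)
  y <- c(0.1, 0.3, 0.5, 0.4, 0.9, 0.8)
  n <- 6
  sxx <- sum((g - mean(g))^2)
  beta <- sum((g - mean(g)) * (y - mean(y))) / sxx
  rss <- sum((y - mean(y) - beta * (g - mean(g)))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  p <- 2 * pt(abs(beta / se), df = n - 2, lower.tail = FALSE)
  rec <- marginal_assoc(y, g)
  expect_equal(rec$beta, beta, tolerance = 1e-12)
  expect_equal(rec$se, se, tolerance = 1e-12)
  expect_equal(rec$p, p, tolerance = 1e-12)

  # noiseless fit: beta exact, p -> 0
  rec0 <- marginal_assoc(0.5 * g, g)
  expect_equal(rec0$beta, 0.5, tolerance = 1e-12)
  expect_lt(rec0$p, 1e-12)

  expect_null(suppressMessages(marginal_assoc(y, rep(1, 6))))
  expect_message(marginal_assoc(y, rep(1, 6)), "monomorphic")
})

test_that("single-SNP null p-values are uniform", {
  set.seed(32)
  ps <- vapply(1:1000, function(i)
    marginal_assoc(rnorm(100), rbinom(100, 2, 0.3))$p, numeric(1))
  frac <- mean(ps < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
})

test_that("gene-level empirical p obeys the plus-one formula and determinism", {
  pan <- make_causal_panel(n = 150, m = 15, b = 0.5, noise = 0.3, seed = 33)
  s <- gene_empirical_p(pan$y, pan$g$dosages, n_perm = 500, seed = 5)
  expect_equal(s$empirical_p, 1 / 501)       # strong signal beats all perms
  expect_equal(s$lead_variant, colnames(pan$g$dosages)[pan$causal])

  s2 <- gene_empirical_p(pan$y, pan$g$dosages, n_perm = 500, seed = 5)
  expect_identical(s$empirical_p, s2$empirical_p)

  expect_gte(s$empirical_p, 1 / 501)
  expect_lte(s$empirical_p, 1)
})

test_that("q-values: hand BH, Storey/BH equivalence, order invariance", {
  expect_equal(qvalues(rep(1, 5)), rep(1, 5))
  # hand BH on p = (.01,.02,.03,.04), m = 4: all q = 0.04
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04), method = "bh"),
               rep(0.04, 4))
  p <- c(0.001, 0.2, 0.8, 0.04, 0.5)
  expect_equal(qvalues(p, pi0 = 1), qvalues(p, method = "bh"))

  ord <- sample(length(p))
  expect_equal(qvalues(p)[ord], qvalues(p[ord]))
  expect_length(qvalues(numeric(0)), 0)
  expect_error(qvalues(c(0.5, 0)), "p-values")
})

test_that("QQ annotation: control identity, null lambda, planted enrichment", {
  set.seed(34)
  gwas <- data.frame(snp = paste0("v", 1:10000), p = runif(10000))
  tab <- annotate_qq(gwas, list(all = gwas$snp))
  expect_equal(tab$observed, -log10(sort(gwas$p)))
  expect_lt(abs(attr(tab, "lambda")["all"] - 1), 0.05)

  # planted signal: annotated SNPs drawn with z ~ N(1, 1)
  z <- c(rnorm(2000, 1), rnorm(8000, 0))
  gwas2 <- data.frame(snp = paste0("v", 1:10000),
                      p = 2 * pnorm(-abs(z)))
  ann <- paste0("v", 1:2000)
  tab2 <- annotate_qq(gwas2, list(annotated = ann, control = gwas2$snp))
  obs_a <- tab2$observed[tab2$set == "annotated"]
  exp_a <- tab2$expected[tab2$set == "annotated"]
  obs_c <- tab2$observed[tab2$set == "control"]
  exp_c <- tab2$expected[tab2$set == "control"]
  qgrid <- seq(0.05, 0.95, by = 0.05)
  curve_a <- approx(exp_a, obs_a, xout = quantile(exp_a, qgrid))$y
  curve_c <- approx(exp_c, obs_c, xout = quantile(exp_a, qgrid))$y
  expect_true(all(curve_a >= curve_c))
  expect_warning(annotate_qq(gwas, list(none = "absent")), "empty")
})

test_that("enrichment odds ratio separates overlap from independence", {
  set.seed(35)
  bg <- paste0("v", 1:2000)
  maf <- setNames(runif(2000, 0.05, 0.5), bg)
  sig <- sample(bg, 200)

  # annotation identical to the significant set: OR >> 1, CI excludes 1
  r1 <- enrichment_or(sig, sig, bg, maf, n_boot = 200, seed = 1)
  expect_gt(r1$or, 1); expect_gt(r1$ci[1], 1)

  # disjoint sets: OR < 1 with the continuity correction
  r2 <- enrichment_or(sig, setdiff(bg, sig)[1:200], bg, maf,
                      n_boot = 200, seed = 1)
  expect_lt(r2$or, 1)
  expect_equal(r2$method, "simplified-garfield")

  # null coverage: independent annotation, CI covers 1 in >= 93% of reps
  hits <- vapply(1:100, function(i) {
    set.seed(100 + i)
    s <- sample(bg, 150); a <- sample(bg, 300)
    ci <- enrichment_or(s, a, bg, maf, n_boot = 120,
                        seed = 200 + i)$ci
    ci[1] <= 1 && 1 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("null genes give uniform empirical p at gene level", {
  set.seed(36)
  n_genes <- 60; n <- 120
  emp <- vapply(1:n_genes, function(g) {
    gm <- sim_genotypes(n, 10, seed = 400 + g)
    gene_empirical_p(rnorm(n), gm$dosages, n_perm = 300,
                     seed = 500 + g)$empirical_p
  }, numeric(1))
  # empirical p is discrete on the permutation grid; ties are expected
  ks <- suppressWarnings(ks.test(emp, "punif"))
  expect_gt(ks$p.value, 0.01)
})
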