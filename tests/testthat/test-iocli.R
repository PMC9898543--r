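test_that("VCF dosage reading applies the variant filter contract", {
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"))
  g <- read_vcf_dosage(vcf, maf_min = 0.01)
  counts <- attr(g, "filter_counts")
  expect_equal(unname(counts["ambiguous"]), 1L)   # A/T pair
  expect_equal(unname(counts["indel"]), 1L)       # AC -> A
  expect_equal(unname(counts["multiallelic"]), 1L)
  expect_equal(unname(counts["maf"]), 1L)         # monomorphic v_rare

  # manual-parse oracle for the surviving records
  expect_setequal(g$variants$id, c("v_snp", "v_miss"))
  expect_equal(unname(g$dosages[, "v_snp"]), c(0, 1, 2))
  expect_equal(unname(g$dosages[, "v_miss"]), c(NA_integer_, 1L, 2L))
  expect_equal(g$variants$maf[g$variants$id == "v_snp"], 0.5)
})

test_that("simulated genotypes round-trip through VCF text", {
  g <- sim_genotypes(30, 25, seed = 81, maf_range = c(0.2, 0.5))
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(g, vcf)
  expect_true(any(grepl("apatwas_seed=81", readLines(vcf))))
  back <- read_vcf_dosage(vcf, maf_min = 0)
  expect_equal(unname(back$dosages), unname(g$dosages))
  expect_equal(back$variants$pos, g$variants$pos)
})

test_that("coverage profiles round-trip through bedGraph", {
  region <- list(chrom = "3", start = 1000, end = 1400, strand = "-")
  prof <- sim_coverage(0.4, 400, 150, 60, dispersion = 0.1, seed = 82,
                       sample_id = "sA")
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(prof, region, path)
  back <- load_coverage(utils::read.table(
    path, col.names = c("chrom", "start", "end", "score"),
    colClasses = c("character", "integer", "integer", "numeric")),
    region, sample_id = "sA")
  expect_equal(back$values, prof$values)
})

test_that("BED12 writer and UTR extractor are inverse on both strands", {
  regions <- data.frame(chrom = c("1", "2"), utr_start = c(5000, 8000),
                        utr_end = c(5400, 8600), strand = c("+", "-"),
                        gene_id = c("gp", "gm"),
                        transcript_id = c("gp.t1", "gm.t1"))
  bed <- tempfile(fileext = ".bed")
  write_bed12(regions, bed)
  back <- extract_utr_regions(bed, min_seg = 100)
  expect_equal(back$start, regions$utr_start)
  expect_equal(back$end, regions$utr_end)
  expect_equal(back$strand, regions$strand)
  expect_equal(back$gene_id, regions$gene_id)
})

test_that("sumstats reading computes z, validates columns, rejects duplicates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tA2\tBETA\tSE\tN",
               "rs1\tA\tG\t0.2\t0.1\t5000",
               "rs2\tC\tT\t-0.3\t0.15\t5000"), path)
  ss <- read_sumstats(path)
  expect_equal(ss$z, c(2, -2), tolerance = 1e-12)

  writeLines(c("SNP\tA1\tA2\tZ\tN", "rs1\tA\tG\t1\t100",
               "rs1\tA\tG\t2\t100"), path)
  expect_error(read_sumstats(path), "duplicate")

  writeLines("SNP\tA1\tA2\tZ\tN", path)
  expect_warning(read_sumstats(path), "no rows")

  writeLines(c("SNP\tA1\tBETA", "rs1\tA\t0.1"), path)
  expect_error(read_sumstats(path), "A2")
})

test_that("weight files round-trip to full precision and validate schema", {
  pan <- make_causal_panel(n = 200, m = 8, causal = 4, b = 0.5,
                           noise = 0.3, seed = 83)
  m <- train_weight_model(pan$y, pan$g$dosages, variants = pan$g$variants,
                          seed = 84)
  prefix <- tempfile()
  write_weight_model(m, prefix)
  back <- read_weight_model(prefix)
  expect_identical(back$weights, m$weights)        # full float precision
  expect_equal(back$cv_r2, m$cv_r2)
  expect_equal(back$selected, m$selected)
  expect_equal(back$h2, m$h2)

  # single-variant model still writes a valid file
  one <- m
  one$weights <- m$weights[1, , drop = FALSE]
  one$variants <- m$variants[1, , drop = FALSE]
  write_weight_model(one, paste0(prefix, "_one"))
  expect_equal(nrow(read_weight_model(paste0(prefix, "_one"))$weights), 1L)

  # hand-removed allele column is a schema error
  tsv <- paste0(prefix, ".weights.tsv")
  tab <- read.delim(tsv, comment.char = "#")
  writeLines(c("# edited", capture.output(
    write.table(tab[setdiff(names(tab), "alt")], sep = "\t",
                row.names = FALSE, quote = FALSE))), tsv)
  expect_error(read_weight_model(prefix), "alt")

  # schema version mismatch is detected
  js <- paste0(prefix, ".weights.json")
  meta <- jsonlite::read_json(js)
  meta$schema_version <- "999"
  jsonlite::write_json(meta, js, auto_unbox = TRUE)
  expect_error(read_weight_model(prefix), "version mismatch")
})

test_that("chromosome dialects normalise once and never mix", {
  expect_equal(normalize_chrom(c("chr1", "chrX")), c("1", "X"))
  expect_equal(normalize_chrom(c("1", "2")), c("1", "2"))
  expect_error(normalize_chrom(c("chr1", "2")), "mixed")
})

test_that("run config round-trips and hashes stably", {
  cfg <- run_config(seed = 7, window = 1e6, permutations = 1000,
                    out = "results")
  path <- tempfile()
  write_run_config(cfg, path)
  expect_equal(read_run_config(path), cfg)
  expect_identical(config_hash(cfg), config_hash(cfg))
  expect_false(config_hash(cfg) ==
                 config_hash(run_config(seed = 8, window = 1e6)))
  expect_error(run_config(window = 1), "seed")
})

test_that("fixture directory supports the full file-based pipeline", {
  dir <- file.path(tempdir(), "fixture_e2e")
  unlink(dir, recursive = TRUE)
  study <- sim_study(n_genes = 3, n_samples = 25, n_cis_variants = 10,
                     alpha = 0.3, n_gwas = 1e4, noise_sd = 0.05, seed = 85)
  write_sim_fixture(study, dir, depth = 60, dispersion = 0)
  expect_true(file.exists(file.path(dir, "panel.vcf")))
  expect_true(file.exists(file.path(dir, "truth.json")))

  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 85)

  # quantify from the files and compare to the in-memory truth matrix
  out <- file.path(dir, "pdui.tsv")
  code <- apatwas_cli(c("quantify-apa", "--bed",
                        file.path(dir, "transcripts.bed"),
                        "--coverage-dir", dir, "--out", out))
  expect_equal(code, 0L)
  tab <- read.delim(out, comment.char = "#", check.names = FALSE)
  expect_equal(nrow(tab), 3L)
  vals <- as.matrix(tab[, rownames(study$genotypes[[1]]$dosages)])
  expect_equal(unname(vals), unname(study$pdui), tolerance = 1e-10)
  expect_equal(tab$breakpoint, rep(250, 3))
})

test_that("CLI rejects unknown input cleanly and reruns byte-identically", {
  expect_equal(apatwas_cli(c("frobnicate")), 2L)
  expect_equal(suppressMessages(
    apatwas_cli(c("simulate", "--bogus", "1"))), 1L)
  expect_equal(suppressMessages(
    apatwas_cli(c("quantify-apa", "--bed", "/nonexistent.bed",
                  "--coverage-dir", tempdir(), "--out", tempfile()))), 1L)

  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  unlink(c(d1, d2), recursive = TRUE)
  expect_equal(apatwas_cli(c("simulate", "--out", d1, "--seed", "11",
                             "--genes", "2", "--samples", "10",
                             "--n-gwas", "1000")), 0L)
  expect_equal(apatwas_cli(c("simulate", "--out", d2, "--seed", "11",
                             "--genes", "2", "--samples", "10",
                             "--n-gwas", "1000")), 0L)
  for (f in c("panel.vcf", "transcripts.bed", "gwas.sumstats.tsv",
              "truth.json", "ind0001.bedGraph")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
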