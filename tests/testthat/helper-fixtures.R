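# Small fixtures built in code and shared across test files.

# A toy panel with a single causal variant driving the phenotype.
make_causal_panel <- function(n = 300, m = 20, causal = 10, b = 0.3,
                              noise = 0.5, ld_rho = 0, seed = 42) {
  g <- sim_genotypes(n, m, ld_rho = ld_rho, seed = seed)
  set.seed(seed + 1)
  y <- b * g$dosages[, causal] + rnorm(n, 0, noise)
  list(g = g, y = as.vector(y), causal = causal, b = b)
}

# Noiseless two-segment profiles at a known breakpoint / PDUI.
make_step_profiles <- function(pduis, L = 400, bp = 200, depth = 100) {
  lapply(seq_along(pduis), function(i)
    sim_coverage(pduis[i], L, bp, depth, dispersion = 0,
                 sample_id = paste0("s", i)))
}

# Write a tiny 3-sample VCF by hand (the manual-parse oracle for readers).
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tv_snp\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tv_amb\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0",
    "1\t300\tv_indel\tAC\tA\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0",
    "1\t400\tv_rare\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0",
    "1\t500\tv_multi\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0",
    "1\t600\tv_miss\tG\tA\t.\tPASS\t.\tGT\t./.\t0/1\t1/1"),
    path)
  path
}
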