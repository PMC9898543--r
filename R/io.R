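# Readers and writers for the external formats: VCF dosages (read via
# vcfR), bedGraph and BED12 (via rtracklayer), GWAS sumstats TSV, and the
# open TSV + JSON weight-file format. Every writer stamps a provenance
# header (stage, version, seed, config hash).

#' Read dosages from a VCF
#'
#' Parses the GT field into alt-allele counts and applies the standard
#' variant filters: multi-allelic records, indels, strand-ambiguous (A/T,
#' C/G) pairs, and minor allele frequency at or below `maf_min` are
#' removed, with per-filter counts reported. Chromosome names are
#' normalised to the bare dialect.
#'
#' @param path VCF file (plain or bgzipped).
#' @param region optional list(chrom, start, end) filter (1-based positions
#'   retained when `start <= pos <= end`).
#' @param maf_min MAF filter (default 0.01; `<=` removes).
#' @param drop_indels,drop_ambiguous toggle the respective filters.
#' @return a `genotype_matrix`; attribute `filter_counts` gives removals.
#' @export
read_vcf_dosage <- function(path, region = NULL, maf_min = 0.01,
                            drop_indels = TRUE, drop_ambiguous = TRUE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- c(multiallelic = 0L, indel = 0L, ambiguous = 0L, maf = 0L,
              region = 0L)

  keep <- rep(TRUE, nrow(fix))
  multi <- grepl(",", fix$ALT)
  counts["multiallelic"] <- sum(multi); keep <- keep & !multi
  if (drop_indels) {
    ind <- nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
    counts["indel"] <- sum(ind & keep); keep <- keep & !ind
  }
  if (drop_ambiguous) {
    amb <- is_ambiguous_pair(fix$REF, fix$ALT)
    counts["ambiguous"] <- sum(amb & keep); keep <- keep & !amb
  }
  chrom <- normalize_chrom(fix$CHROM)
  pos <- as.integer(fix$POS)
  if (!is.null(region)) {
    inreg <- chrom == normalize_chrom(region$chrom) &
      pos >= region$start & pos <= region$end
    counts["region"] <- sum(!inreg & keep); keep <- keep & inreg
  }

  gt <- gt[keep, , drop = FALSE]
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  af <- rowMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  mbad <- maf <= maf_min | is.na(maf)
  counts["maf"] <- sum(mbad)
  dos <- t(dos[!mbad, , drop = FALSE])
  fixk <- fix[keep, , drop = FALSE][!mbad, , drop = FALSE]
  variants <- data.frame(chrom = normalize_chrom(fixk$CHROM),
                         pos = as.integer(fixk$POS),
                         id = fixk$ID, ref = fixk$REF, alt = fixk$ALT,
                         maf = maf[!mbad], af_alt = af[!mbad],
                         stringsAsFactors = FALSE)
  colnames(dos) <- variants$id
  structure(list(dosages = dos, variants = variants),
            class = "genotype_matrix", filter_counts = counts)
}

gt_to_dosage <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
  al <- strsplit(g, "[/|]")[[1]]
  if (any(al == ".")) return(NA_integer_)
  sum(al != "0")
}

#' Write a genotype matrix as a minimal VCFv4.2
#'
#' Plain-text emitter for simulated panels (GT field, unphased); the seed
#' and config hash travel in the header.
#'
#' @param G a `genotype_matrix`.
#' @param path output path.
#' @param seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path, seed = attr(G, "seed") %||% NA) {
  v <- G$variants
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=apatwas_%s",
            as.character(utils::packageVersion("apatwas"))),
    sprintf("##apatwas_seed=%s", format(seed, scientific = FALSE)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G$dosages)), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(j) {
    g <- G$dosages[, j]
    gts <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a coverage profile as bedGraph
#'
#' Runs of equal depth are collapsed into 0-based half-open intervals.
#' Minus-strand profiles are de-oriented back to genomic order before
#' writing.
#'
#' @param profile a `coverage_profile`.
#' @param region region layout (chrom, start, end, strand).
#' @param path output path (append supported for multi-gene files).
#' @param append append to an existing file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, region, path, append = FALSE) {
  vals <- profile$values * profile$total_depth_factor
  if (region$strand == "-") vals <- rev(vals)
  rstart <- region$utr_start %||% region$start
  r <- rle(vals)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  df <- data.frame(chrom = region$chrom,
                   start = rstart + starts,
                   end = rstart + ends,
                   score = r$values)
  df <- df[df$score != 0, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = append)
  invisible(path)
}

#' Write transcript models as BED12
#'
#' One single-exon coding transcript per region row: the CDS (thick range)
#' ends where the 3'UTR begins, so [extract_utr_regions()] recovers the
#' regions exactly.
#'
#' @param regions region table (chrom, utr_start/start, utr_end/end,
#'   strand, gene_id, transcript_id).
#' @param path output path.
#' @param cds_length length of the CDS part placed upstream of the UTR.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(regions, path, cds_length = 300L) {
  us <- regions$utr_start %||% regions$start
  ue <- regions$utr_end %||% regions$end
  rows <- vapply(seq_len(nrow(regions)), function(i) {
    if (regions$strand[i] == "+") {
      tx_start <- us[i] - cds_length; tx_end <- ue[i]
      thick <- c(tx_start, us[i])
    } else {
      tx_start <- us[i]; tx_end <- ue[i] + cds_length
      thick <- c(ue[i], tx_end)
    }
    paste(c(regions$chrom[i], tx_start, tx_end,
            paste0(regions$gene_id[i], "|", regions$transcript_id[i]),
            0, regions$strand[i], thick[1], thick[2], 0, 1,
            tx_end - tx_start, 0), collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read GWAS summary statistics from TSV
#'
#' Requires columns SNP, A1, A2 and either Z or BETA + SE (plus N); the
#' z-score is computed as `beta / se` when absent. Column-name matching is
#' case-insensitive and configurable through `col_map`. Duplicate SNP ids
#' are an error (ambiguous join key); rows with missing or non-finite z
#' are dropped and counted.
#'
#' @param path TSV file (provenance comments allowed).
#' @param col_map named character vector mapping the canonical names
#'   (snp, a1, a2, z, beta, se, n) to file columns.
#' @return a `gwas_sumstats` data.frame; attribute `n_dropped`.
#' @export
read_sumstats <- function(path, col_map = NULL) {
  df <- read_tsv_prov(path)
  names(df) <- tolower(names(df))
  if (!is.null(col_map)) {
    for (k in names(col_map)) {
      cand <- tolower(col_map[[k]])
      if (cand %in% names(df)) names(df)[names(df) == cand] <- k
    }
  }
  need <- c("snp", "a1", "a2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sumstats missing required columns: ",
                         paste(toupper(miss), collapse = ", "))
  if (!"z" %in% names(df)) {
    if (!all(c("beta", "se") %in% names(df)))
      stop("sumstats missing required columns: Z (or BETA and SE)")
    df$z <- df$beta / df$se
  }
  if (!"n" %in% names(df)) df$n <- NA_real_
  if (anyDuplicated(df$snp))
    stop("duplicate SNP id(s) in sumstats: ",
         paste(unique(df$snp[duplicated(df$snp)])[1:3], collapse = ", "))
  ok <- is.finite(df$z)
  dropped <- sum(!ok)
  if (!nrow(df)) warning("sumstats file has a header but no rows")
  out <- df[ok, c("snp", "a1", "a2", "z", "n"), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gwas_sumstats", "data.frame")
  attr(out, "n_dropped") <- dropped
  out
}

#' @rdname read_sumstats
#' @param ss a `gwas_sumstats` table; @param seed recorded in the header.
#' @export
write_sumstats <- function(ss, path, seed = attr(ss, "seed") %||% NA) {
  df <- as.data.frame(ss)[, c("snp", "a1", "a2", "z", "n")]
  names(df) <- c("SNP", "A1", "A2", "Z", "N")
  write_tsv_prov(df, path, stage = "sumstats", seed = seed)
}

weight_schema_version <- "1"

#' Write a weight model (open TSV + JSON sidecar format)
#'
#' The TSV holds one row per variant (id, chrom, pos, ref, alt, and one
#' column per method's weight, full precision); the JSON sidecar holds the
#' transcript id, h2 and its LRT p, per-method CV R-squared, selected
#' method, training n, seed, and the schema version.
#'
#' @param model a `weight_model`.
#' @param prefix output path prefix (writes `<prefix>.weights.tsv` and
#'   `<prefix>.weights.json`).
#' @return the two paths, invisibly.
#' @export
write_weight_model <- function(model, prefix) {
  stopifnot(inherits(model, "weight_model"))
  tsv <- paste0(prefix, ".weights.tsv")
  js <- paste0(prefix, ".weights.json")
  df <- data.frame(id = model$variants$id, chrom = model$variants$chrom,
                   pos = model$variants$pos, ref = model$variants$ref,
                   alt = model$variants$alt, stringsAsFactors = FALSE)
  for (mth in colnames(model$weights))
    df[[paste0("w_", mth)]] <- sprintf("%.17g", model$weights[, mth])
  write_tsv_prov(df, tsv, stage = "train-weights", seed = model$seed)
  meta <- list(schema_version = weight_schema_version,
               transcript_id = model$transcript_id,
               h2 = model$h2, p_lrt = model$p_lrt,
               cv_r2 = as.list(model$cv_r2), selected = model$selected,
               n = model$n, folds = model$folds, seed = model$seed,
               r2_over_h2 = model$r2_over_h2)
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = js))
}

#' Read a weight model written by [write_weight_model()]
#' @param prefix path prefix used when writing.
#' @return a `weight_model`.
#' @export
read_weight_model <- function(prefix) {
  tsv <- paste0(prefix, ".weights.tsv")
  js <- paste0(prefix, ".weights.json")
  if (!file.exists(tsv) || !file.exists(js))
    stop("weight files not found at prefix ", prefix)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  if (!identical(as.character(meta$schema_version), weight_schema_version))
    stop("weight schema version mismatch: expected ", weight_schema_version,
         ", found ", meta$schema_version %||% "<missing>")
  df <- read_tsv_prov(tsv)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("weight TSV missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  wcols <- grep("^w_", names(df), value = TRUE)
  if (!length(wcols)) stop("weight TSV has no w_* method columns")
  W <- as.matrix(as.data.frame(lapply(df[wcols], as.numeric)))
  colnames(W) <- sub("^w_", "", wcols)
  rownames(W) <- df$id
  cv <- unlist(meta$cv_r2)
  structure(list(transcript_id = meta$transcript_id,
                 variants = df[need],
                 weights = W, cv_r2 = cv[colnames(W)],
                 selected = meta$selected, h2 = meta$h2,
                 p_lrt = meta$p_lrt, n = meta$n,
                 r2_over_h2 = meta$r2_over_h2,
                 folds = meta$folds, seed = meta$seed),
            class = "weight_model")
}

#' Write a complete simulated fixture directory
#'
#' Emits everything the file-based pipeline reads from one [sim_study()]:
#' per-gene VCFs merged into one panel VCF, per-sample bedGraph coverage,
#' a BED12 transcript fixture, mediated GWAS sumstats (when present), and
#' a `truth.json` ground-truth record carrying the seed.
#'
#' @param study a [sim_study()] result.
#' @param dir output directory (created).
#' @param depth,dispersion coverage generation parameters.
#' @return `dir`, invisibly.
#' @export
write_sim_fixture <- function(study, dir, depth = 50, dispersion = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_genes <- length(study$genotypes)
  samples <- rownames(study$genotypes[[1]]$dosages)

  merged <- merge_genotypes(study$genotypes)
  write_vcf(merged, file.path(dir, "panel.vcf"), seed = study$seed)
  write_bed12(study$regions, file.path(dir, "transcripts.bed"))

  for (s in seq_along(samples)) {
    path <- file.path(dir, paste0(samples[s], ".bedGraph"))
    if (file.exists(path)) file.remove(path)
    for (g in seq_len(n_genes)) {
      prof <- sim_coverage(
        study$pdui[g, s], study$truth$utr_length[g],
        study$truth$breakpoint[g], depth, dispersion,
        seed = derive_seed(study$seed, paste0("cov", g, "_", s)),
        sample_id = samples[s])
      write_bedgraph(prof, as.list(study$regions[g, ]), path,
                     append = g > 1)
    }
  }
  if (!is.null(study$sumstats)) {
    ss <- do.call(rbind, lapply(study$sumstats, as.data.frame))
    class(ss) <- c("gwas_sumstats", "data.frame")
    write_sumstats(ss, file.path(dir, "gwas.sumstats.tsv"),
                   seed = study$seed)
  }
  truth <- list(seed = study$seed,
                gene_id = study$truth$gene_id,
                causal_variant = vapply(seq_len(n_genes), function(g)
                  study$genotypes[[g]]$variants$id[study$truth$causal[[g]][1]],
                  character(1)),
                beta = vapply(study$truth$beta, function(b) b[1], numeric(1)),
                breakpoint = study$truth$breakpoint,
                utr_length = study$truth$utr_length,
                baseline = study$truth$baseline,
                alpha = study$truth$alpha,
                noise_sd = study$truth$noise_sd)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

merge_genotypes <- function(glist) {
  dos <- do.call(cbind, lapply(glist, function(g) g$dosages))
  variants <- do.call(rbind, lapply(glist, function(g) g$variants))
  # make ids unique across gene blocks
  if (anyDuplicated(variants$id)) {
    variants$id <- paste0(variants$id, "_c", variants$chrom)
    colnames(dos) <- variants$id
  }
  structure(list(dosages = dos, variants = variants),
            class = "genotype_matrix", seed = attr(glist[[1]], "seed"))
}

#' Assemble and serialise a run configuration
#'
#' Flat key-value config: stage parameters, paths, master seed. Written as
#' `key = value` lines; reading it back reproduces the list exactly
#' (round-trip identity), and every stochastic stage derives its seed from
#' the master seed via [derive_seed()].
#'
#' @param ... named scalar settings; must include `seed`.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (is.null(cfg$seed)) stop("run_config requires a seed")
  structure(cfg[order(names(cfg))], class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`; @param path file path.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", format(config[[k]], scientific = FALSE)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, " = ", fixed = TRUE)
  cfg <- stats::setNames(
    lapply(kv, function(x) {
      v <- x[2]
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    }),
    vapply(kv, `[`, character(1), 1))
  do.call(run_config, cfg)
}
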