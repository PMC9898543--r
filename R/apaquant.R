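# PDUI quantification from per-base coverage. One proximal poly(A) site per
# 3'UTR is fitted jointly across samples: each candidate breakpoint P splits
# the profile into two segments, each modelled as a normal with free mean and
# variance, and the P maximising the summed profile log-likelihood is shared
# by all samples. Per-sample PDUI is the ratio of distal to proximal segment
# means, clipped to [0, 1].

#' Extract 3'UTR regions from BED12 transcript models
#'
#' The 3'UTR is the portion of the transcript downstream of the CDS on the
#' transcript strand, restricted to the last exon (plus strand:
#' `[max(thickEnd, lastExonStart), chromEnd)`; minus strand mirrored).
#' Non-coding records (zero-width thick) are skipped and counted, as are
#' UTRs shorter than `2 * min_seg` (too short to fit two segments).
#'
#' Record names of the form `"gene|transcript"` populate both ids; a bare
#' name is used for both.
#'
#' @param transcript_models path to a BED12 file, or a `GRanges` as returned
#'   by `rtracklayer::import()` with `thick` and `blocks` columns.
#' @param min_seg minimum segment length (nt) the downstream fit will use.
#' @return a data.frame of class `utr_regions` with columns chrom, start,
#'   end (0-based half-open), strand, gene_id, transcript_id, length;
#'   attributes `n_noncoding` and `n_too_short` count skipped records.
#' @export
extract_utr_regions <- function(transcript_models, min_seg = 100L) {
  gr <- if (is.character(transcript_models)) {
    rtracklayer::import(transcript_models, format = "bed")
  } else transcript_models
  thick <- S4Vectors::mcols(gr)$thick
  blocks <- S4Vectors::mcols(gr)$blocks
  if (is.null(thick) || is.null(blocks))
    stop("BED12 input required: records must carry thick (CDS) and blocks")
  nm <- S4Vectors::mcols(gr)$name
  n_noncoding <- 0L; n_too_short <- 0L
  rows <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    if (IRanges::width(thick)[i] == 0L) {        # thickStart == thickEnd
      n_noncoding <- n_noncoding + 1L
      next
    }
    chrom_start1 <- GenomicRanges::start(gr)[i]  # 1-based
    bl <- blocks[[i]]                            # exon ranges, record-relative
    ex_start1 <- chrom_start1 + IRanges::start(bl) - 1L
    ex_end1 <- chrom_start1 + IRanges::end(bl) - 1L
    strand <- as.character(GenomicRanges::strand(gr)[i])
    cds_start1 <- IRanges::start(thick)[i]
    cds_end1 <- IRanges::end(thick)[i]
    if (strand == "+") {
      last <- which.max(ex_end1)
      u_start1 <- max(cds_end1 + 1L, ex_start1[last])
      u_end1 <- ex_end1[last]
    } else if (strand == "-") {
      last <- which.min(ex_start1)
      u_start1 <- ex_start1[last]
      u_end1 <- min(cds_start1 - 1L, ex_end1[last])
    } else stop("record ", i, " has no strand; BED12 strand required")
    if (u_end1 < u_start1) { n_noncoding <- n_noncoding + 1L; next }
    len <- u_end1 - u_start1 + 1L
    if (len < 2L * min_seg) { n_too_short <- n_too_short + 1L; next }
    name <- if (!is.null(nm)) nm[i] else paste0("tx", i)
    parts <- strsplit(name, "|", fixed = TRUE)[[1]]
    rows[[i]] <- data.frame(
      chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr)[i])),
      start = u_start1 - 1L, end = u_end1, strand = strand,
      gene_id = parts[1],
      transcript_id = if (length(parts) > 1) parts[2] else parts[1],
      length = len, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), gene_id = character(), transcript_id = character(),
    length = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("utr_regions", "data.frame"),
            n_noncoding = n_noncoding, n_too_short = n_too_short)
}

#' Load a transcript-oriented coverage profile for one UTR
#'
#' Reads per-base depth over a region from a bedGraph (0-based half-open)
#' and orients it 5'->3' along the transcript: minus-strand profiles are the
#' reversed genomic slice, so position 0 of the array is always the UTR 5'
#' end. Bases absent from the bedGraph are 0.
#'
#' @param bedgraph path to a bedGraph file, a `GRanges` with a `score`
#'   column, or a data.frame with columns chrom, start, end, score.
#' @param region one row of a [extract_utr_regions()] table (or any list
#'   with chrom, start, end, strand).
#' @param sample_id label stored on the profile.
#' @param total_depth_factor sample sequencing-depth normaliser; profile
#'   values are divided by it.
#' @return a `coverage_profile`.
#' @export
load_coverage <- function(bedgraph, region, sample_id = "sample",
                          total_depth_factor = 1) {
  if (is.character(bedgraph))
    bedgraph <- rtracklayer::import(bedgraph, format = "bedGraph")
  if (inherits(bedgraph, "GRanges")) {
    bedgraph <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(bedgraph)),
      start = GenomicRanges::start(bedgraph) - 1L,  # back to 0-based
      end = GenomicRanges::end(bedgraph),
      score = S4Vectors::mcols(bedgraph)$score, stringsAsFactors = FALSE)
  }
  rchrom <- region$chrom
  bchroms <- unique(bedgraph$chrom)
  if (length(bchroms) && !(rchrom %in% bchroms)) {
    flipped <- if (grepl("^chr", rchrom)) sub("^chr", "", rchrom)
               else paste0("chr", rchrom)
    if (flipped %in% bchroms)
      stop("chromosome naming mismatch: region uses '", rchrom,
           "' but coverage uses '", flipped,
           "'; normalise one dialect before loading")
  }
  L <- region$end - region$start
  v <- numeric(L)
  sel <- bedgraph[bedgraph$chrom == rchrom &
                  bedgraph$end > region$start &
                  bedgraph$start < region$end, , drop = FALSE]
  for (k in seq_len(nrow(sel))) {
    a <- max(sel$start[k], region$start) - region$start + 1L
    b <- min(sel$end[k], region$end) - region$start
    v[a:b] <- sel$score[k]
  }
  if (region$strand == "-") v <- rev(v)
  structure(list(sample_id = sample_id,
                 values = v / total_depth_factor,
                 total_depth_factor = total_depth_factor),
            class = "coverage_profile")
}

#' Jointly fit a shared two-segment breakpoint across samples
#'
#' Every candidate breakpoint P on the grid
#' `seq(min_seg, L - min_seg, by = step)` splits each profile into a
#' proximal segment `[0, P)` and a distal segment `[P, L)`. Under the
#' default `"loglik"` objective each segment is a normal with free mean and
#' variance and P maximises the summed profile log-likelihood
#' `sum_samples [ -(n1/2) log(RSS1/n1) - (n2/2) log(RSS2/n2) ]`
#' (segment variances floored at `var_floor` so exactly-constant segments do
#' not degenerate); `"lss"` minimises the plain pooled residual sum of
#' squares instead. Objective ties break to the smallest P, so the fit is
#' deterministic.
#'
#' Samples whose region-wide mean depth is below `min_mean_cov` do not
#' contribute to the fit and get a missing PDUI; a passing sample with zero
#' proximal mean also gets a missing PDUI (the usage ratio is undefined).
#'
#' @param profiles list of `coverage_profile`s over the same region.
#' @param min_seg minimum segment length, nt.
#' @param step breakpoint-grid stride, nt.
#' @param min_mean_cov minimum mean depth over the region for a sample to
#'   enter the fit.
#' @param objective `"loglik"` (default) or `"lss"`.
#' @param var_floor variance floor for the log-likelihood objective.
#' @return an object of class `breakpoint_fit`: `P` (nt from the UTR 5'
#'   end), `samples` (data.frame: sample_id, mu_prox, mu_dist, var_prox,
#'   var_dist, pdui, used), `objective_value`, `n_samples_used`; or `NULL`
#'   if no sample passes coverage.
#' @export
fit_two_segment <- function(profiles, min_seg = 100L, step = 1L,
                            min_mean_cov = 20,
                            objective = c("loglik", "lss"),
                            var_floor = 1e-8) {
  objective <- match.arg(objective)
  stopifnot(length(profiles) >= 1)
  L <- length(profiles[[1]]$values)
  if (any(vapply(profiles, function(p) length(p$values), 0L) != L))
    stop("profiles have unequal lengths")
  if (L < 2L * min_seg)
    stop("region length ", L, " < 2 * min_seg (", 2L * min_seg, ")")
  used <- vapply(profiles, function(p) mean(p$values) >= min_mean_cov,
                 logical(1))
  if (!any(used)) return(NULL)

  P_grid <- seq.int(min_seg, L - min_seg, by = step)
  obj <- numeric(length(P_grid))
  for (p in profiles[used]) {
    v <- p$values
    cs <- cumsum(v); cs2 <- cumsum(v * v)
    n1 <- P_grid; n2 <- L - P_grid
    S1 <- cs[P_grid]; S2 <- cs[L] - S1
    rss1 <- pmax(cs2[P_grid] - S1^2 / n1, 0)
    rss2 <- pmax((cs2[L] - cs2[P_grid]) - S2^2 / n2, 0)
    obj <- obj + if (objective == "loglik") {
      -(n1 / 2) * log(pmax(rss1 / n1, var_floor)) -
        (n2 / 2) * log(pmax(rss2 / n2, var_floor))
    } else {
      -(rss1 + rss2)
    }
  }
  P <- P_grid[which.max(obj)]          # which.max takes the first: smallest P

  samples <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    v <- profiles[[i]]$values
    mu1 <- mean(v[seq_len(P)]); mu2 <- mean(v[(P + 1):L])
    pdui <- if (!used[i] || mu1 <= 0) NA_real_ else clip01(mu2 / mu1)
    data.frame(sample_id = profiles[[i]]$sample_id %||% paste0("s", i),
               mu_prox = mu1, mu_dist = mu2,
               var_prox = stats::var(v[seq_len(P)]) * (P - 1) / P,
               var_dist = stats::var(v[(P + 1):L]) * (L - P - 1) / (L - P),
               pdui = pdui, used = used[i], stringsAsFactors = FALSE)
  }))
  structure(list(P = P, samples = samples, objective_value = max(obj),
                 n_samples_used = sum(used), objective = objective),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("breakpoint_fit: P = %d nt, %d/%d samples used, %s objective\n",
              x$P, x$n_samples_used, nrow(x$samples), x$objective))
  cat(sprintf("  PDUI range %.3f-%.3f (%d missing)\n",
              suppressWarnings(min(x$samples$pdui, na.rm = TRUE)),
              suppressWarnings(max(x$samples$pdui, na.rm = TRUE)),
              sum(is.na(x$samples$pdui))))
  invisible(x)
}

#' Build the PDUI matrix over regions and samples
#'
#' Runs [fit_two_segment()] per region on the per-sample profiles and
#' assembles the transcript x sample PDUI matrix. Rows whose non-missing
#' fraction falls below `min_sample_fraction` are dropped. Output is
#' deterministic in the inputs and invariant to sample input order (up to
#' column order).
#'
#' @param profiles_by_region list (one element per region row) of lists of
#'   `coverage_profile`s, each inner list named or carrying sample ids.
#' @param regions a [extract_utr_regions()] table (rows parallel to
#'   `profiles_by_region`).
#' @param min_seg,step,min_mean_cov,objective passed to [fit_two_segment()].
#' @param min_sample_fraction minimum non-missing fraction to keep a row.
#' @return an object of class `pdui_matrix`: `values` (regions x samples),
#'   `regions` (retained region table with a `breakpoint` column),
#'   `dropped` (character vector of dropped transcript ids).
#' @export
pdui_matrix <- function(profiles_by_region, regions, min_seg = 100L,
                        step = 1L, min_mean_cov = 20,
                        objective = "loglik", min_sample_fraction = 0.5) {
  stopifnot(length(profiles_by_region) == nrow(regions))
  sample_ids <- vapply(profiles_by_region[[1]], function(p) p$sample_id,
                       character(1))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  ord <- order(sample_ids)
  sample_ids <- sample_ids[ord]

  vals <- matrix(NA_real_, nrow(regions), length(sample_ids),
                 dimnames = list(regions$transcript_id, sample_ids))
  bp <- rep(NA_integer_, nrow(regions))
  for (r in seq_len(nrow(regions))) {
    profs <- profiles_by_region[[r]]
    ids <- vapply(profs, function(p) p$sample_id, character(1))
    if (!setequal(ids, sample_ids))
      stop("region ", regions$transcript_id[r],
           " is missing coverage for some samples")
    profs <- profs[match(sample_ids, ids)]
    fit <- fit_two_segment(profs, min_seg = min_seg, step = step,
                           min_mean_cov = min_mean_cov,
                           objective = objective)
    if (is.null(fit)) next
    bp[r] <- fit$P
    vals[r, fit$samples$sample_id] <- fit$samples$pdui
  }
  keep <- rowMeans(!is.na(vals)) >= min_sample_fraction & !is.na(bp)
  regions_out <- regions[keep, , drop = FALSE]
  regions_out$breakpoint <- bp[keep]
  structure(list(values = vals[keep, , drop = FALSE],
                 regions = as.data.frame(regions_out),
                 dropped = regions$transcript_id[!keep]),
            class = "pdui_matrix")
}

#' @export
print.pdui_matrix <- function(x, ...) {
  cat(sprintf("pdui_matrix: %d transcripts x %d samples (%d dropped)\n",
              nrow(x$values), ncol(x$values), length(x$dropped)))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}
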