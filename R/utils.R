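#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules: reproducible per-stage seeds,
# a tiny stable hash for provenance headers, and argument checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed
#' deterministically from the run's master seed and the stage name, so any
#' stage can be re-run in isolation and reproduce its output exactly.
#' The derivation is a 32-bit FNV-1a hash of `"<seed>:<stage>"`, folded into
#' the positive integer range.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"sim_genotypes"`.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(stage))
  h <- fnv1a32(paste0(format(master, scientific = FALSE), ":", stage))
  as.integer(h %% (2^31 - 2)) + 1L
}

# FNV-1a over the UTF-8 bytes of a string, in double arithmetic (exact below
# 2^53, so the 32-bit folding is reliable).
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # bitwXor works on 32-bit signed ints; keep everything in [0, 2^32)
  r <- bitwXor(as.integer(a %% 2^31), as.integer(b %% 2^31))
  if (a >= 2^31) r <- r + 2^31 * (1 - 2 * (b >= 2^31))
  as.numeric(r %% 2^32)
}

#' Stable hash of a configuration list
#'
#' Serialises a flat named list as sorted `key=value` lines and hashes it;
#' used for the provenance headers every output table carries.
#'
#' @param config a named list of scalar settings.
#' @return an 8-hex-digit character hash.
#' @export
config_hash <- function(config) {
  stopifnot(is.list(config))
  keys <- sort(names(config))
  txt <- paste(vapply(keys, function(k) {
    paste0(k, "=", paste(format(config[[k]], scientific = FALSE),
                         collapse = ","))
  }, character(1)), collapse = "\n")
  h <- fnv1a32(txt)   # < 2^32, stored as double: format halves as hex
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Provenance comment block written at the top of every output table.
provenance_header <- function(stage, seed = NA, config = list()) {
  c(sprintf("# apatwas_stage: %s", stage),
    sprintf("# apatwas_version: %s",
            as.character(utils::packageVersion("apatwas"))),
    sprintf("# seed: %s", format(seed, scientific = FALSE)),
    sprintf("# config_hash: %s", config_hash(config)))
}

# Write a data.frame as TSV under a provenance header.
write_tsv_prov <- function(df, path, stage, seed = NA, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(stage, seed, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_prov <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Normalise chromosome-name dialect
#'
#' Inputs may name chromosomes `"chr1"` or `"1"`. The pipeline normalises to
#' the unprefixed dialect once at ingest; a vector mixing both dialects is an
#' error rather than a silent partial join.
#'
#' @param chrom character vector of chromosome names.
#' @return the same vector without `"chr"` prefixes.
#' @export
normalize_chrom <- function(chrom) {
  has_pre <- grepl("^chr", chrom)
  if (any(has_pre) && !all(has_pre)) {
    stop("mixed chromosome dialects in one input: both 'chr'-prefixed (e.g. ",
         chrom[has_pre][1], ") and bare (e.g. ", chrom[!has_pre][1], ")")
  }
  sub("^chr", "", chrom)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(name, " must be a single finite number")
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(name, " = ", x, " outside allowed range ",
         if (strict_lower) "(" else "[", lower, ", ", upper,
         if (strict_upper) ")" else "]")
  invisible(x)
}

clip01 <- function(x) pmin(1, pmax(0, x))
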