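#' Genotype tables
#'
#' A genotype table (`geno_tbl`) is a tibble with one row per SNP, the
#' metadata columns `chrom`, `pos`, `id`, `ref`, `alt` (alternate alleles,
#' comma-joined), and one character column per sample holding the normalized
#' diploid call. Calls are unordered allele-index pairs written `"a/b"` with
#' `a <= b` (phase is discarded: `1|0` and `0/1` are the same genotype);
#' a fully missing call is `NA`. Half-missing calls such as `./1` are resolved
#' once, at read time (see [read_vcf()]), so every downstream stage only ever
#' sees complete or fully-missing calls.
#'
#' @param x A data frame shaped as above.
#' @return `as_geno_tbl()` returns a validated `geno_tbl`;
#'   `geno_samples()` the character vector of sample IDs;
#'   `geno_calls()` the SNP-by-sample character matrix of calls;
#'   `dosage_matrix()` the SNP-by-sample numeric matrix of alternate-allele
#'   dosages (count of non-reference alleles, `NA` for missing calls).
#' @examples
#' p <- example_panel()
#' geno_samples(p$geno)[1:3]
#' dosage_matrix(p$geno)[1:3, 1:3]
#' @name geno_tbl
NULL

.geno_meta_cols <- c("chrom", "pos", "id", "ref", "alt")

#' @rdname geno_tbl
#' @export
as_geno_tbl <- function(x) {
  x <- as_tibble(x)
  missing_meta <- setdiff(.geno_meta_cols, names(x))
  if (length(missing_meta) > 0) {
    abort(paste0("genotype table lacks column(s): ",
                 paste(missing_meta, collapse = ", ")),
          class = "ldhap_format_error")
  }
  smp <- setdiff(names(x), .geno_meta_cols)
  if (length(smp) == 0) {
    abort("genotype table has zero samples", class = "ldhap_empty_error")
  }
  if (nrow(x) == 0) {
    abort("genotype table has zero variants", class = "ldhap_empty_error")
  }
  if (any(x$pos < 1)) {
    abort("SNP positions must be >= 1 (1-based VCF coordinates)",
          class = "ldhap_format_error")
  }
  key <- paste(x$chrom, x$pos, sep = ":")
  if (anyDuplicated(key)) {
    abort("duplicate (chrom, pos) pairs in genotype table",
          class = "ldhap_format_error")
  }
  ord <- order(x$chrom, x$pos)
  if (!identical(ord, seq_len(nrow(x)))) {
    abort("SNPs must be sorted by (chrom, pos); LD matrix order is defined by record order",
          class = "ldhap_format_error")
  }
  class(x) <- unique(c("geno_tbl", class(x)))
  x
}

#' @rdname geno_tbl
#' @export
geno_samples <- function(x) {
  setdiff(names(x), .geno_meta_cols)
}

#' @rdname geno_tbl
#' @export
geno_calls <- function(x) {
  smp <- geno_samples(x)
  m <- as.matrix(x[, smp, drop = FALSE])
  rownames(m) <- x$id
  m
}

#' @rdname geno_tbl
#' @export
dosage_matrix <- function(x) {
  calls <- geno_calls(x)
  d <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  ok <- !is.na(calls)
  if (any(ok)) {
    parts <- strsplit(calls[ok], "/", fixed = TRUE)
    a <- as.integer(vapply(parts, `[`, "", 1L))
    b <- as.integer(vapply(parts, `[`, "", 2L))
    d[ok] <- (a > 0L) + (b > 0L)
  }
  d
}

# Normalize raw GT tokens (one SNP's worth) to "a/b" with a <= b, or NA.
# Half-missing calls resolve per hetmiss_as: "allele" -> missing allele is the
# reference (0); "miss" -> whole call missing. n_alt bounds allele indices.
.normalize_gt <- function(tokens, n_alt, hetmiss_as, snp_label = "?") {
  out <- rep(NA_character_, length(tokens))
  tokens[tokens %in% c(".", "./.", ".|.")] <- NA_character_
  ok <- !is.na(tokens)
  if (!any(ok)) return(out)
  parts <- strsplit(tokens[ok], "[/|]")
  bad_len <- lengths(parts) != 2L
  if (any(bad_len)) {
    abort(paste0("non-diploid GT call at ", snp_label, ": ",
                 tokens[ok][bad_len][1]),
          class = "ldhap_format_error")
  }
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  half <- xor(a == ".", b == ".")
  if (hetmiss_as == "allele") {
    a[half & a == "."] <- "0"
    b[half & b == "."] <- "0"
  } else {
    a[half] <- NA_character_
    b[half] <- NA_character_
  }
  ai <- suppressWarnings(as.integer(a))
  bi <- suppressWarnings(as.integer(b))
  full <- !is.na(ai) & !is.na(bi)
  if (any(full & (pmax(ai, bi) > n_alt | pmin(ai, bi) < 0L), na.rm = TRUE)) {
    abort(paste0("allele index out of range at ", snp_label),
          class = "ldhap_format_error")
  }
  res <- rep(NA_character_, sum(ok))
  res[full] <- paste(pmin(ai[full], bi[full]), pmax(ai[full], bi[full]),
                     sep = "/")
  out[ok] <- res
  out
}
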