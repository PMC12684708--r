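#' Read a square pairwise LD (r-squared) matrix
#'
#' Reads a plain-text whitespace/tab-delimited square matrix of pairwise
#' r\eqn{^2} values, the layout written by PLINK `--r2 square` and
#' equivalents. An optional header row and/or leading ID column is
#' auto-detected: a first row or column that fails numeric parsing is treated
#' as labels and dropped. The tokens `nan`, `NaN` and `NA` (PLINK emits `nan`
#' for pairs involving a monomorphic SNP) are accepted and resolve to
#' r\eqn{^2} = 0 — no linkage evidence, i.e. maximal distance, so such SNPs
#' can never glue clusters together. After resolution the matrix is
#' symmetrized as (M + t(M))/2 when the asymmetry is at most `1e-6`
#' (larger asymmetry is an error) and the diagonal is forced to 1.
#'
#' Row/column order is defined to match the VCF record order of the paired
#' genotype table; no ID-based reordering is attempted. A dimension mismatch
#' is a hard error.
#'
#' @param path Path to the matrix file.
#' @param expected_n Required dimension (number of SNPs of the paired
#'   genotype table). Use `NULL` to skip the check.
#' @return An `n` by `n` numeric matrix of class `ld_matrix`, symmetric, with
#'   unit diagonal and entries in `[0, 1]`.
#' @seealso [compute_r2()] for computing r-squared directly from genotypes.
#' @export
read_ld_matrix <- function(path, expected_n = NULL) {
  if (!file.exists(path)) {
    abort(paste0("LD matrix file not found: ", path),
          class = "ldhap_input_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort("LD matrix file is empty", class = "ldhap_format_error")
  }
  rows <- strsplit(trimws(lines), "[ \t]+")

  is_num <- function(tok) {
    tok %in% c("nan", "NaN", "NA", "na") |
      !is.na(suppressWarnings(as.numeric(tok)))
  }
  # header row: first row entirely non-numeric (and the body parses without it)
  if (!all(is_num(rows[[1]])) ) {
    rows <- rows[-1]
  }
  if (length(rows) == 0) {
    abort("LD matrix file has no data rows", class = "ldhap_format_error")
  }
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1) {
    abort("ragged LD matrix: rows differ in length",
          class = "ldhap_format_error")
  }
  first_col <- vapply(rows, `[`, "", 1L)
  if (!all(is_num(first_col))) {
    rows <- lapply(rows, `[`, -1L)
    ncols <- ncols - 1L
  }
  bad <- unlist(rows)[!is_num(unlist(rows))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric entry in LD matrix: ", bad[1]),
          class = "ldhap_format_error")
  }
  m <- do.call(rbind, lapply(rows, function(r) suppressWarnings(as.numeric(r))))
  if (nrow(m) != ncol(m)) {
    abort(paste0("LD matrix is not square: ", nrow(m), " x ", ncol(m)),
          class = "ldhap_alignment_error")
  }
  if (!is.null(expected_n) && nrow(m) != expected_n) {
    abort(paste0("LD matrix dimension ", nrow(m),
                 " does not match the genotype table (", expected_n,
                 " SNPs); order is defined by VCF record order"),
          class = "ldhap_alignment_error")
  }
  as_ld_matrix(m)
}

#' Validate and resolve an LD matrix
#'
#' Resolves missing entries to 0, checks symmetry (tolerance `1e-6`, then
#' exact symmetrization as (M + t(M))/2), range (entries within `1e-6` of
#' `[0, 1]`, then clamped), and forces the diagonal to 1.
#'
#' @param m A square numeric matrix of r-squared values, possibly with
#'   `NA`/`NaN` entries.
#' @return A validated `ld_matrix`.
#' @export
as_ld_matrix <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || nrow(m) != ncol(m)) {
    abort("LD matrix must be a square numeric matrix",
          class = "ldhap_format_error")
  }
  m[is.na(m)] <- 0
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6) {
    abort(sprintf("LD matrix is asymmetric (max |M - t(M)| = %.3g > 1e-6)",
                  asym),
          class = "ldhap_consistency_error")
  }
  m <- (m + t(m)) / 2
  if (any(m < -1e-6) || any(m > 1 + 1e-6)) {
    abort("LD matrix entry outside [0, 1]", class = "ldhap_range_error")
  }
  m[m < 0] <- 0
  m[m > 1] <- 1
  diag(m) <- 1
  dimnames(m) <- NULL
  class(m) <- c("ld_matrix", class(m))
  m
}

#' Pairwise r-squared from alternate-allele dosages
#'
#' Convenience routine equivalent to PLINK `--r2 square` on unphased data:
#' r\eqn{^2}(i, j) is the squared Pearson correlation of the two SNPs'
#' alternate-allele dosage vectors (dosage = count of non-reference alleles,
#' 0/1/2), with missing calls excluded pairwise. Pairs involving a
#' monomorphic SNP, or with fewer than two complete observations, carry no
#' linkage evidence and resolve to r\eqn{^2} = 0.
#'
#' @param gt A [geno_tbl] with at least 2 SNPs and 2 samples.
#' @return An `ld_matrix` aligned to the SNP order of `gt`.
#' @examples
#' p <- example_panel()
#' ld <- compute_r2(p$geno)
#' ld[1:3, 1:3]
#' @export
compute_r2 <- function(gt) {
  gt <- as_geno_tbl(gt)
  if (nrow(gt) < 2L) {
    abort("compute_r2 needs at least 2 SNPs", class = "ldhap_input_error")
  }
  if (length(geno_samples(gt)) < 2L) {
    abort("compute_r2 needs at least 2 samples", class = "ldhap_input_error")
  }
  d <- t(dosage_matrix(gt))                # samples x snps
  r <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))
  r2 <- r^2
  r2[!is.finite(r2)] <- 0
  as_ld_matrix(r2)
}

# PLINK-dialect writer; used by write_fixture and tests.
# labeled = TRUE adds a header row and a leading ID column.
.write_ld_matrix <- function(m, path, ids = NULL, labeled = FALSE) {
  m <- unclass(m)
  body <- apply(m, 1L, function(r) paste(sprintf("%.12g", r), collapse = "\t"))
  if (labeled) {
    if (is.null(ids)) ids <- paste0("snp_", seq_len(nrow(m)))
    lines <- c(paste(ids, collapse = "\t"), paste(ids, body, sep = "\t"))
  } else {
    lines <- body
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
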