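#' Read diploid genotypes from a VCF file
#'
#' Parses the GT field of a VCF 4.x file into a [geno_tbl] of normalized,
#' unphased diploid calls. Half-missing calls (one allele missing, e.g.
#' `./1`) are resolved here, once: with `hetmiss_as = "allele"` the missing
#' allele is assumed to be the reference allele 0, so `./1` becomes `0/1`;
#' with `hetmiss_as = "miss"` the whole genotype is treated as missing.
#' Fully missing calls (`./.`) are always missing. Multiallelic sites are
#' retained with their alternate-allele indices. Phase separators are
#' discarded (`1|0` and `0/1` normalize to the same call).
#'
#' Records must be sorted by (chrom, pos) with no duplicate positions: the
#' row/column order of a paired LD matrix is defined to be the VCF record
#' order, so reordering is never attempted.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param hetmiss_as How to resolve half-missing calls: `"allele"` (default)
#'   or `"miss"`.
#' @return A [geno_tbl].
#' @seealso [read_ld_matrix()], [compute_r2()]
#' @examples
#' vcf <- system.file("extdata", "synthetic_panel.vcf", package = "ldhap")
#' gt <- read_vcf(vcf)
#' gt[1:3, 1:7]
#' @export
read_vcf <- function(path, hetmiss_as = c("allele", "miss")) {
  hetmiss_as <- match.arg(hetmiss_as)
  if (!file.exists(path)) {
    abort(paste0("VCF file not found: ", path), class = "ldhap_input_error")
  }
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  if (is.null(vcf@gt) || ncol(vcf@gt) < 2L) {
    abort("VCF has zero samples", class = "ldhap_empty_error")
  }
  if (nrow(vcf@fix) == 0L) {
    abort("VCF has zero variants", class = "ldhap_empty_error")
  }
  fmt <- strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)
  if (!all(vapply(fmt, function(f) "GT" %in% f, TRUE))) {
    abort("VCF FORMAT lacks a GT field on some records",
          class = "ldhap_format_error")
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {                 # single-record files drop dims
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = nrow(fix))
  }
  samples <- colnames(vcf@gt)[-1]
  n_alt <- lengths(strsplit(fix[, "ALT"], ",", fixed = TRUE))

  calls <- matrix(NA_character_, nrow(fix), length(samples),
                  dimnames = list(NULL, samples))
  for (i in seq_len(nrow(fix))) {
    calls[i, ] <- .normalize_gt(
      gt_raw[i, ], n_alt[i], hetmiss_as,
      snp_label = paste0(fix[i, "CHROM"], ":", fix[i, "POS"])
    )
  }

  out <- tibble(
    chrom = unname(fix[, "CHROM"]),
    pos   = as.integer(unname(fix[, "POS"])),
    id    = unname(ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"])),
    ref   = unname(fix[, "REF"]),
    alt   = unname(fix[, "ALT"])
  )
  out <- dplyr::bind_cols(out, as_tibble(calls))
  as_geno_tbl(out)
}
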