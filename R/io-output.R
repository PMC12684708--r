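#' Write a haplotype-variant table to disk
#'
#' Formats 1-5 are written as tab-separated text with a fixed column order,
#' `\n` line terminators and no trailing whitespace, so identical tables
#' produce byte-identical files. Format 6 is written as a syntactically
#' valid VCF 4.2 file (header lines, `#CHROM` row, haploid GT = variant
#' rank - 1, `.` for unassigned).
#'
#' @param table A `hap_table` from [haplotype_variants()] or
#'   [convert_format()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_output <- function(table, path) {
  fmt <- attr(table, "format_id")
  if (is.null(fmt)) {
    abort("table is not a hap_table (missing format id)",
          class = "ldhap_format_error")
  }
  if (fmt == 6L) {
    .write_format6_vcf(table, path)
  } else {
    con <- file(path, open = "wb")         # fixed "\n" on every platform
    on.exit(close(con))
    tbl <- as_tibble(table)
    writeLines(c(paste(names(tbl), collapse = "\t"),
                 if (nrow(tbl) > 0) {
                   do.call(paste, c(lapply(tbl, as.character), sep = "\t"))
                 }),
               con, sep = "\n")
  }
  invisible(path)
}

.write_format6_vcf <- function(table, path) {
  tbl <- as_tibble(table)
  samples <- attr(table, "samples") %||%
    setdiff(names(tbl), c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                          "FILTER", "INFO", "FORMAT"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ldhap",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Position of the block's last SNP\">",
    "##INFO=<ID=NSNPS,Number=1,Type=Integer,Description=\"Number of SNPs in the block\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid variant index (rank - 1)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- if (nrow(tbl) > 0) {
    do.call(paste, c(lapply(tbl, as.character), sep = "\t"))
  } else {
    character()
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read a written haplotype-variant table back
#'
#' Re-reads tables written by [write_output()] in formats 1-4. Block
#' metadata (chromosome/positions) is not stored in these layouts, so the
#' result can be converted among formats 1-4 but not into 5 or 6.
#'
#' @param path File path.
#' @param format The layout the file was written in, integer 1-4.
#' @return A `hap_table`.
#' @export
read_output <- function(path, format) {
  .check_format(format)
  if (format > 4L) {
    abort("read_output supports formats 1-4", class = "ldhap_format_error")
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  tbl <- switch(
    format,
    dplyr::mutate(tbl, dplyr::across(-"sample", as.integer)),     # 1
    tbl,                                                          # 2
    dplyr::mutate(tbl, variant_rank = as.integer(.data$variant_rank)), # 3
    dplyr::mutate(tbl, dplyr::across(-"sample", as.integer))      # 4
  )
  samples <- if (format %in% c(1L, 2L, 4L)) tbl$sample else unique(tbl$sample)
  .new_hap_table(tbl, format, samples, NULL)
}
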