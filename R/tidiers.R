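#' Tidy a block collection
#'
#' One row per haplotype block with its name, span, SNP count and mean
#' intra-block r-squared; the list-columns holding SNP indices and genotype
#' sub-tables are dropped.
#'
#' @param x A `hap_blocks` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hap_blocks <- function(x, ...) {
  tibble(block = x$block, chrom = x$chrom, start = x$start, end = x$end,
         n_snps = x$n_snps, mean_r2 = x$mean_r2)
}

#' Summarize a clustering run
#'
#' @param x A `hap_blocks` tibble.
#' @param ... Unused.
#' @return A one-row tibble: number of blocks, SNPs clustered, total SNPs,
#'   noise fraction and outlier SNPs pruned.
#' @export
glance.hap_blocks <- function(x, ...) {
  total <- attr(x, "n_snps_total")
  tibble(
    n_blocks = nrow(x),
    n_snps_clustered = sum(x$n_snps),
    n_snps_total = total,
    noise_fraction = attr(x, "n_noise") / total,
    n_outliers_removed = attr(x, "n_outliers_removed")
  )
}

#' Tidy a haplotype-variant table
#'
#' Returns the long/tidy view (format 3) regardless of the table's stored
#' layout: columns `haplotype`, `sample`, `variant_code`, `variant_rank`.
#'
#' @param x A `hap_table`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hap_table <- function(x, ...) {
  as_tibble(convert_format(x, 3L))
}

#' Summarize a haplotype-variant table
#'
#' @param x A `hap_table`.
#' @param ... Unused.
#' @return A one-row tibble: block count, sample count, total retained
#'   variants, mean variants per block and the fraction of zero-coded
#'   (blockwise unassigned) genotypes.
#' @export
glance.hap_table <- function(x, ...) {
  info <- attr(x, "block_info")
  long <- tidy(x)
  n_blocks <- if (!is.null(info)) nrow(info) else dplyr::n_distinct(long$haplotype)
  n_var <- if (!is.null(info)) {
    sum(lengths(info$codes))
  } else {
    nrow(dplyr::distinct(long[long$variant_rank > 0, ],
                         .data$haplotype, .data$variant_code))
  }
  tibble(
    n_blocks = n_blocks,
    n_samples = length(attr(x, "samples") %||% unique(long$sample)),
    n_variants = n_var,
    mean_variants_per_block = n_var / max(n_blocks, 1L),
    zero_coded_fraction = mean(long$variant_rank == 0L)
  )
}
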