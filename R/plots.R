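#' Plot a block collection over its LD matrix
#'
#' Heatmap of the pairwise r-squared matrix in SNP order with the detected
#' block spans outlined, the standard visual check that DBSCAN picked up the
#' high-LD squares along the diagonal.
#'
#' @param object A `hap_blocks` tibble.
#' @param ld The r-squared matrix the blocks were defined on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hap_blocks <- function(object, ld, ...) {
  ld <- as_ld_matrix(ld)
  n <- nrow(ld)
  df <- tidyr::expand_grid(j = seq_len(n), i = seq_len(n))
  df$r2 <- as.vector(unclass(ld))          # column-major: i varies fastest
  spans <- tibble(
    xmin = purrr::map_dbl(object$snp_index, min) - 0.5,
    xmax = purrr::map_dbl(object$snp_index, max) + 0.5
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$r2)) +
    ggplot2::geom_raster() +
    ggplot2::geom_rect(data = spans,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$xmin, ymax = .data$xmax),
                       inherit.aes = FALSE, fill = NA, colour = "red",
                       linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "r²") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "SNP index", y = "SNP index",
                  title = "Pairwise LD with detected haplotype blocks")
}

#' Plot haplotype-variant frequencies
#'
#' Stacked per-block bar chart of variant carrier counts (letter-coded
#' variants plus the zero-coded remainder), the quick look at how
#' multiallelic each local haplotype marker is.
#'
#' @param object A `hap_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hap_table <- function(object, ...) {
  long <- tidy(object)
  counts <- long |>
    dplyr::count(.data$haplotype, .data$variant_code, name = "carriers")
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$haplotype, y = .data$carriers,
                               fill = .data$variant_code)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "local haplotype block", y = "carriers",
                  fill = "variant",
                  title = "Haplotype-variant frequencies") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
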