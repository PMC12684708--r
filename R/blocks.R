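#' Define local haplotype blocks from an LD matrix
#'
#' Clusters SNPs into local haplotype blocks by running DBSCAN on the
#' distance d = 1 - r\eqn{^2} ([dbscan_labels()]), discarding the noise
#' group, and — unless `keep_outliers = TRUE` — pruning within-block outlier
#' SNPs ([remove_outlier_snps()]). Blocks are named
#' `hap_<firstpos>_<lastpos>` from the positions of their first and last
#' member SNPs (chromosome-qualified as `hap_<chrom>_<firstpos>_<lastpos>`
#' when the input spans more than one chromosome) and returned ordered by
#' (chrom, first position).
#'
#' @param gt A [geno_tbl]; SNP order must match `ld` row order.
#' @param ld An r-squared matrix acceptable to [as_ld_matrix()], with one
#'   row/column per SNP of `gt` in the same order.
#' @param epsilon DBSCAN neighborhood radius on 1 - r-squared. Default 0.6.
#' @param mgmin DBSCAN minimum neighborhood size. Default 30.
#' @param keep_outliers Keep within-block outlier SNPs? Default `FALSE`.
#' @return A `hap_blocks` tibble with one row per block and columns
#'   `block` (name), `chrom`, `start`, `end`, `n_snps`, `mean_r2` (mean
#'   pairwise r-squared among members), `snp_index` (list of integer indices
#'   into `gt`) and `genotypes` (list of per-block [geno_tbl] sub-tables —
#'   the method's "list of tables"). Attributes record the clustering
#'   summary used by [glance()].
#' @examples
#' p <- example_panel()
#' blocks <- define_haplotypes(p$geno, p$ld)
#' blocks[, 1:6]
#' @export
define_haplotypes <- function(gt, ld, epsilon = 0.6, mgmin = 30,
                              keep_outliers = FALSE) {
  gt <- as_geno_tbl(gt)
  ld <- as_ld_matrix(ld)
  if (nrow(ld) != nrow(gt)) {
    abort(paste0("LD matrix dimension (", nrow(ld),
                 ") does not match SNP count (", nrow(gt), ")"),
          class = "ldhap_alignment_error")
  }
  labels <- dbscan_labels(ld, epsilon = epsilon, mgmin = mgmin)
  n_noise <- sum(labels == 0L)
  idx_sets <- split(seq_len(nrow(gt)), labels)
  idx_sets <- idx_sets[names(idx_sets) != "0"]
  idx_sets <- idx_sets[lengths(idx_sets) >= 2L]      # a 1-SNP block is a SNP

  blocks <- .build_blocks(idx_sets, gt, ld)
  n_before <- sum(blocks$n_snps)
  if (!keep_outliers && nrow(blocks) > 0) {
    blocks <- remove_outlier_snps(blocks, ld)
  }
  if (nrow(blocks) == 0) {
    warn("no local haplotype blocks survive clustering; returning an empty collection")
  }
  blocks <- blocks[order(blocks$chrom, blocks$start), , drop = FALSE]
  .check_block_names(blocks$block)
  structure(
    blocks,
    n_snps_total = nrow(gt),
    n_noise = n_noise,
    n_outliers_removed = n_before - sum(blocks$n_snps),
    params = list(epsilon = epsilon, mgmin = mgmin,
                  keep_outliers = keep_outliers),
    samples = geno_samples(gt),
    class = c("hap_blocks", class(blocks))
  )
}

# assemble a hap_blocks tibble (no attributes) from index sets
.build_blocks <- function(idx_sets, gt, ld) {
  multi_chrom <- length(unique(gt$chrom)) > 1
  rows <- purrr::map(idx_sets, function(idx) {
    idx <- idx[order(gt$chrom[idx], gt$pos[idx])]
    sub <- ld[idx, idx, drop = FALSE]
    tibble(
      block = .block_name(gt$chrom[idx[1]], gt$pos[idx[1]],
                          gt$pos[idx[length(idx)]], multi_chrom),
      chrom = gt$chrom[idx[1]],
      start = gt$pos[idx[1]],
      end = gt$pos[idx[length(idx)]],
      n_snps = length(idx),
      mean_r2 = mean(sub[upper.tri(sub)]),
      snp_index = list(idx),
      genotypes = list(gt[idx, , drop = FALSE])
    )
  })
  if (length(rows) == 0) {
    return(tibble(block = character(), chrom = character(), start = integer(),
                  end = integer(), n_snps = integer(), mean_r2 = double(),
                  snp_index = list(), genotypes = list()))
  }
  dplyr::bind_rows(rows)
}

.block_name <- function(chrom, first, last, multi_chrom) {
  if (multi_chrom) {
    paste("hap", chrom, first, last, sep = "_")
  } else {
    paste("hap", first, last, sep = "_")
  }
}

.check_block_names <- function(names) {
  dup <- unique(names[duplicated(names)])
  if (length(dup) > 0) {
    abort(paste0("duplicate haplotype block name(s): ",
                 paste(dup, collapse = ", ")),
          class = "ldhap_collision_error")
  }
  invisible(names)
}

#' Prune within-block outlier SNPs
#'
#' For each member SNP i of a block, the mean intra-block LD
#' m_i = mean of r\eqn{^2}(i, j) over the other members j (the self pair is
#' excluded). SNPs whose m_i lies more than 2 sample standard deviations of
#' \{m_i\} outside the median of \{m_i\} (two-sided) are removed, in a single
#' pass — the threshold is never recomputed on the pruned block. When the
#' standard deviation is 0 nothing is removed. A block reduced below 2 SNPs
#' is discarded; survivors are renamed from their new first/last positions.
#'
#' @param blocks A `hap_blocks` tibble from [define_haplotypes()] (or built
#'   the same way).
#' @param ld The r-squared matrix the blocks were defined on.
#' @return The pruned `hap_blocks` tibble.
#' @export
remove_outlier_snps <- function(blocks, ld) {
  ld <- as_ld_matrix(ld)
  if (nrow(blocks) == 0) return(blocks)
  # chromosome-qualified names carry >= 3 underscores; keep the input's style
  multi_chrom <- length(unique(blocks$chrom)) > 1 ||
    any(stringr::str_count(blocks$block, stringr::fixed("_")) >= 3)
  kept_attrs <- attributes(blocks)
  rows <- purrr::pmap(
    list(blocks$snp_index, blocks$genotypes),
    function(idx, sub_gt) {
      keep <- .outlier_keep(idx, ld)
      if (length(keep) < 2L) return(NULL)
      pos <- sub_gt$pos[match(keep, idx)]
      sub <- ld[keep, keep, drop = FALSE]
      tibble(
        block = .block_name(sub_gt$chrom[1], min(pos), max(pos), multi_chrom),
        chrom = sub_gt$chrom[1],
        start = min(pos),
        end = max(pos),
        n_snps = length(keep),
        mean_r2 = mean(sub[upper.tri(sub)]),
        snp_index = list(keep),
        genotypes = list(sub_gt[match(keep, idx), , drop = FALSE])
      )
    }
  )
  rows <- purrr::compact(rows)
  out <- if (length(rows) == 0) blocks[0, , drop = FALSE] else dplyr::bind_rows(rows)
  for (a in setdiff(names(kept_attrs), c("names", "row.names", "class"))) {
    attr(out, a) <- kept_attrs[[a]]
  }
  class(out) <- class(blocks)
  out
}

# single-pass outlier decision; returns the kept indices (original order)
.outlier_keep <- function(idx, ld) {
  if (length(idx) < 2L) return(idx)
  sub <- ld[idx, idx, drop = FALSE]
  m <- (rowSums(sub) - 1) / (length(idx) - 1)   # exclude the self pair
  med <- median(m)
  s <- sd(m)
  if (!is.finite(s) || s == 0) return(idx)
  idx[abs(m - med) <= 2 * s]
}

#' Define haplotype blocks across several VCF/LD pairs
#'
#' Runs [define_haplotypes()] over a list of genotype-table/LD-matrix pairs
#' (e.g. one pair per chromosome) and collates the per-pair block
#' collections. All genotype tables must share the identical ordered sample
#' list.
#'
#' @param pairs A list of `list(gt = , ld = )` pairs.
#' @inheritParams define_haplotypes
#' @return A `hap_blocks` tibble, the concatenation of the per-pair results
#'   (name-collision-checked).
#' @export
define_haplotypes_globally <- function(pairs, epsilon = 0.6, mgmin = 30,
                                       keep_outliers = FALSE) {
  .check_pairs(pairs)
  results <- purrr::map(pairs, function(p) {
    define_haplotypes(p$gt, p$ld, epsilon = epsilon, mgmin = mgmin,
                      keep_outliers = keep_outliers)
  })
  collate_define_haplotypes(results)
}

.check_pairs <- function(pairs) {
  if (!is.list(pairs) || length(pairs) == 0) {
    abort("pairs must be a non-empty list of list(gt =, ld =) pairs",
          class = "ldhap_input_error")
  }
  samples <- purrr::map(pairs, function(p) geno_samples(as_geno_tbl(p$gt)))
  if (!all(vapply(samples, identical, TRUE, samples[[1]]))) {
    abort("all genotype tables must share the identical ordered sample list",
          class = "ldhap_alignment_error")
  }
  invisible(pairs)
}

#' Collate block collections
#'
#' Concatenates several [define_haplotypes()] /
#' [define_haplotypes_globally()] results (over the same sample set) into one
#' block collection, preserving input order and rejecting duplicate block
#' names.
#'
#' @param results A list of `hap_blocks` tibbles.
#' @return One `hap_blocks` tibble.
#' @export
collate_define_haplotypes <- function(results) {
  if (!is.list(results) || length(results) == 0) {
    abort("results must be a non-empty list of hap_blocks tibbles",
          class = "ldhap_input_error")
  }
  smp <- purrr::map(results, attr, "samples")
  smp <- purrr::compact(smp)
  if (length(smp) > 1 && !all(vapply(smp, identical, TRUE, smp[[1]]))) {
    abort("block collections were defined over different sample sets",
          class = "ldhap_alignment_error")
  }
  out <- dplyr::bind_rows(purrr::map(results, ~ as_tibble(.x)))
  .check_block_names(out$block)
  structure(
    out,
    n_snps_total = sum(purrr::map_dbl(results, ~ attr(.x, "n_snps_total") %||% NA_real_)),
    n_noise = sum(purrr::map_dbl(results, ~ attr(.x, "n_noise") %||% NA_real_)),
    n_outliers_removed = sum(purrr::map_dbl(results, ~ attr(.x, "n_outliers_removed") %||% NA_real_)),
    params = attr(results[[1]], "params"),
    samples = if (length(smp) > 0) smp[[1]] else NULL,
    class = c("hap_blocks", class(out))
  )
}

#' Export per-block genotype tables
#'
#' Writes one TSV per block (named `<block>.tsv`) holding the block's
#' genotype sub-table, mirroring the "list of tables" view of a block
#' collection.
#'
#' @param blocks A `hap_blocks` tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_block_tables <- function(blocks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::map2_chr(blocks$block, blocks$genotypes, function(name, g) {
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(as_tibble(g), p, na = ".")
    p
  })
  invisible(paths)
}
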