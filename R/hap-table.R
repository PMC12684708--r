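#' Haplotype-variant tables
#'
#' [haplotype_variants()] is the end-to-end pipeline: blocks are defined and
#' pruned exactly as in [define_haplotypes()], then per block the haplotype
#' variants are enumerated ([enumerate_variants()]), filtered and
#' letter-coded ([apply_min_freq()]), and the per-sample assignments are
#' assembled into one of six interchange layouts. Blocks in which no variant
#' survives the frequency filter are dropped (every sample would be 0 — an
#' uninformative marker).
#'
#' The six layouts (all tab-separated except format 6) are this package's
#' interchange contract:
#' \describe{
#'   \item{1 (default)}{wide numeric — rows = samples (`sample` column
#'     first), one column per block, cell = integer variant rank, 0 =
#'     unassigned; suits numeric GS tools (rrBLUP/BGLR-style).}
#'   \item{2}{wide letter — same shape, cells = letter codes or `"0"`.}
#'   \item{3}{long/tidy — columns `haplotype`, `sample`, `variant_code`,
#'     `variant_rank`.}
#'   \item{4}{one-hot incidence — rows = samples, one 0/1 column per
#'     (block, variant) named `<block>_<code>`; unassigned samples have an
#'     all-zero row section for that block.}
#'   \item{5}{HapMap-like — rows = blocks with columns `rs#` (block name),
#'     `alleles` (slash-joined codes), `chrom`, `pos` (first SNP position),
#'     then one letter-code column per sample; suits TASSEL/GAPIT-style
#'     loaders.}
#'   \item{6}{VCF-like — one record per block at the first SNP's position;
#'     variant codes as allele tokens (REF = code A, ALT = the rest), sample
#'     GT = variant rank - 1 as a haploid allele index, `.` for unassigned;
#'     INFO carries the block span and SNP count.}
#' }
#'
#' @param gt A [geno_tbl]; order must match `ld`.
#' @param ld An r-squared matrix acceptable to [as_ld_matrix()].
#' @param epsilon,mgmin,keep_outliers Clustering parameters, as in
#'   [define_haplotypes()].
#' @param min_freq Minimum carrier count for a variant, default 2
#'   ([apply_min_freq()]).
#' @param format Output layout, integer 1-6. Default 1.
#' @return A `hap_table`: a tibble in the requested layout carrying the
#'   format id, sample order and per-block variant dictionary as attributes.
#' @examples
#' p <- example_panel()
#' tab <- haplotype_variants(p$geno, p$ld, format = 2)
#' tab[1:4, ]
#' glance(tab)
#' @export
haplotype_variants <- function(gt, ld, epsilon = 0.6, mgmin = 30,
                               keep_outliers = FALSE, min_freq = 2,
                               format = 1) {
  .check_format(format)
  blocks <- define_haplotypes(gt, ld, epsilon = epsilon, mgmin = mgmin,
                              keep_outliers = keep_outliers)
  samples <- geno_samples(as_geno_tbl(gt))
  coded <- purrr::map2(blocks$genotypes, blocks$block, function(g, name) {
    apply_min_freq(enumerate_variants(g, block = name), min_freq = min_freq)
  })
  keep <- vapply(coded, function(v) nrow(v$dictionary) > 0, TRUE)
  .assemble_hap_table(coded[keep], blocks[keep, , drop = FALSE],
                      samples, format)
}

.check_format <- function(format) {
  if (length(format) != 1 || !format %in% 1:6) {
    abort("format must be a single integer in 1..6",
          class = "ldhap_param_error")
  }
}

# canonical long view: one row per (block, sample)
.canonical_long <- function(coded) {
  if (length(coded) == 0) {
    return(tibble(haplotype = character(), sample = character(),
                  variant_code = character(), variant_rank = integer()))
  }
  dplyr::bind_rows(purrr::map(coded, function(v) {
    tibble(haplotype = v$block,
           sample = v$assignments$sample,
           variant_code = v$assignments$code,
           variant_rank = v$assignments$rank)
  }))
}

.block_info <- function(coded, blocks) {
  tibble(
    block = blocks$block,
    chrom = blocks$chrom,
    start = blocks$start,
    end = blocks$end,
    n_snps = blocks$n_snps,
    codes = purrr::map(coded, ~ .x$dictionary$code),
    counts = purrr::map(coded, ~ .x$dictionary$count)
  )
}

.assemble_hap_table <- function(coded, blocks, samples, format) {
  long <- .canonical_long(coded)
  info <- .block_info(coded, blocks)
  .format_hap_table(long, info, samples, format)
}

.new_hap_table <- function(tbl, format, samples, block_info) {
  structure(as_tibble(tbl), format_id = as.integer(format),
            samples = samples, block_info = block_info,
            class = c("hap_table", class(as_tibble(tbl))))
}

.format_hap_table <- function(long, info, samples, format) {
  block_order <- info$block
  wide_cell <- function(value_col, fill) {
    out <- tibble(sample = samples)
    for (b in block_order) {
      rows <- long[long$haplotype == b, , drop = FALSE]
      out[[b]] <- rows[[value_col]][match(samples, rows$sample)]
      out[[b]][is.na(out[[b]])] <- fill
    }
    out
  }
  tbl <- switch(
    format,
    wide_cell("variant_rank", 0L),                               # 1
    wide_cell("variant_code", "0"),                              # 2
    {                                                            # 3
      long$haplotype <- factor(long$haplotype, levels = block_order)
      long$sample <- factor(long$sample, levels = samples)
      long <- dplyr::arrange(long, .data$haplotype, .data$sample)
      long$haplotype <- as.character(long$haplotype)
      long$sample <- as.character(long$sample)
      long
    },
    {                                                            # 4
      out <- tibble(sample = samples)
      codes <- .canonical_code_matrix(long, info, samples)
      for (i in seq_len(nrow(info))) {
        for (code in info$codes[[i]]) {
          out[[paste0(info$block[i], "_", code)]] <-
            as.integer(codes[, info$block[i]] == code)
        }
      }
      out
    },
    {                                                            # 5
      codes <- .canonical_code_matrix(long, info, samples)
      out <- tibble(
        `rs#` = info$block,
        alleles = purrr::map_chr(info$codes, paste, collapse = "/"),
        chrom = info$chrom,
        pos = info$start
      )
      for (s in samples) out[[s]] <- unname(codes[s, info$block])
      out
    },
    {                                                            # 6
      ranks <- .canonical_rank_matrix(long, info, samples)
      out <- tibble(
        CHROM = info$chrom,
        POS = info$start,
        ID = info$block,
        REF = purrr::map_chr(info$codes, 1),
        ALT = purrr::map_chr(info$codes,
                             ~ if (length(.x) > 1) paste(.x[-1], collapse = ",") else "."),
        QUAL = ".",
        FILTER = ".",
        INFO = paste0("END=", info$end, ";NSNPS=", info$n_snps),
        FORMAT = "GT"
      )
      for (s in samples) {
        r <- ranks[s, info$block]
        out[[s]] <- ifelse(r == 0L, ".", as.character(r - 1L))
      }
      out
    }
  )
  .new_hap_table(tbl, format, samples, info)
}

# samples x blocks matrices of codes / ranks from the long view
.canonical_code_matrix <- function(long, info, samples) {
  m <- matrix("0", length(samples), nrow(info),
              dimnames = list(samples, info$block))
  if (nrow(long) > 0) {
    m[cbind(long$sample, long$haplotype)] <- long$variant_code
  }
  m
}
.canonical_rank_matrix <- function(long, info, samples) {
  m <- matrix(0L, length(samples), nrow(info),
              dimnames = list(samples, info$block))
  if (nrow(long) > 0) {
    m[cbind(long$sample, long$haplotype)] <- long$variant_rank
  }
  m
}

#' Run the variants pipeline over several VCF/LD pairs
#'
#' Maps [haplotype_variants()] over a list of genotype/LD pairs sharing the
#' identical ordered sample list and collates the per-pair tables
#' ([collate_haplotype_variants()]) into one table, block columns/records in
#' input order.
#'
#' @param pairs A list of `list(gt = , ld = )` pairs.
#' @inheritParams haplotype_variants
#' @return A `hap_table`.
#' @export
haplotype_variants_global <- function(pairs, epsilon = 0.6, mgmin = 30,
                                      keep_outliers = FALSE, min_freq = 2,
                                      format = 1) {
  .check_pairs(pairs)
  tabs <- purrr::map(pairs, function(p) {
    haplotype_variants(p$gt, p$ld, epsilon = epsilon, mgmin = mgmin,
                       keep_outliers = keep_outliers, min_freq = min_freq,
                       format = format)
  })
  collate_haplotype_variants(tabs)
}

#' Collate haplotype-variant tables
#'
#' Merges several `hap_table`s of the same format over the same ordered
#' sample set into one table. Duplicate block names and mixed formats are
#' errors.
#'
#' @param tables A list of `hap_table`s.
#' @return One `hap_table`.
#' @export
collate_haplotype_variants <- function(tables) {
  if (!is.list(tables) || length(tables) == 0) {
    abort("tables must be a non-empty list of hap_table objects",
          class = "ldhap_input_error")
  }
  fmts <- purrr::map_int(tables, ~ attr(.x, "format_id") %||% NA_integer_)
  if (any(is.na(fmts))) {
    abort("every table must be a hap_table with a format id",
          class = "ldhap_format_error")
  }
  if (length(unique(fmts)) != 1) {
    abort("all tables must share the same output format",
          class = "ldhap_format_error")
  }
  smp <- purrr::map(tables, attr, "samples")
  if (!all(vapply(smp, identical, TRUE, smp[[1]]))) {
    abort("all tables must share the identical ordered sample list",
          class = "ldhap_alignment_error")
  }
  info <- dplyr::bind_rows(purrr::map(tables, attr, "block_info"))
  .check_block_names(info$block)
  fmt <- fmts[1]
  tbl <- switch(
    fmt,
    purrr::reduce(purrr::map(tables, as_tibble), dplyr::left_join,
                  by = "sample"),                                  # 1
    purrr::reduce(purrr::map(tables, as_tibble), dplyr::left_join,
                  by = "sample"),                                  # 2
    dplyr::bind_rows(purrr::map(tables, as_tibble)),               # 3
    purrr::reduce(purrr::map(tables, as_tibble), dplyr::left_join,
                  by = "sample"),                                  # 4
    dplyr::bind_rows(purrr::map(tables, as_tibble)),               # 5
    dplyr::bind_rows(purrr::map(tables, as_tibble))                # 6
  )
  .new_hap_table(tbl, fmt, smp[[1]], info)
}

#' Convert a haplotype-variant table between layouts
#'
#' Formats 1, 2 and 3 interconvert losslessly (ranks and letter codes are in
#' bijection via [letter_code()]). Conversions into 4-6 are defined;
#' conversion out of 4 recovers the assignment by per-block argmax of the
#' indicator columns (an all-zero section is "unassigned"). Conversions out
#' of formats 5 and 6 are not supported. Targets 5 and 6 need the block
#' metadata (chromosome, positions) carried on tables produced by
#' [haplotype_variants()]; a table re-read from disk without it cannot be
#' converted into those layouts.
#'
#' @param table A `hap_table`.
#' @param target Target format, integer 1-6.
#' @return A `hap_table` in the target layout.
#' @export
convert_format <- function(table, target) {
  .check_format(target)
  fmt <- attr(table, "format_id")
  if (is.null(fmt)) {
    abort("table is not a hap_table (missing format id)",
          class = "ldhap_format_error")
  }
  if (fmt == target) return(table)
  if (fmt %in% c(5L, 6L)) {
    abort("conversion out of formats 5 and 6 is not supported",
          class = "ldhap_format_error")
  }
  long <- .to_canonical_long(table)
  samples <- attr(table, "samples") %||% unique(long$sample)
  info <- attr(table, "block_info")
  if (is.null(info)) {
    if (target %in% c(5L, 6L)) {
      abort("target format needs block metadata (chrom/pos) not present on this table",
            class = "ldhap_format_error")
    }
    info <- .rebuild_block_info(long)
  }
  .format_hap_table(long, info, samples, target)
}

# minimal block_info (names + codes) when the provenance attribute is absent
.rebuild_block_info <- function(long) {
  long |>
    dplyr::filter(.data$variant_rank > 0) |>
    dplyr::distinct(.data$haplotype, .data$variant_code, .data$variant_rank) |>
    dplyr::arrange(.data$haplotype, .data$variant_rank) |>
    dplyr::group_by(block = .data$haplotype) |>
    dplyr::summarise(codes = list(.data$variant_code), .groups = "drop") |>
    dplyr::mutate(chrom = NA_character_, start = NA_integer_,
                  end = NA_integer_, n_snps = NA_integer_,
                  counts = list(NULL)) |>
    dplyr::select("block", "chrom", "start", "end", "n_snps",
                  "codes", "counts")
}

.to_canonical_long <- function(table) {
  fmt <- attr(table, "format_id")
  tbl <- as_tibble(table)
  if (fmt %in% c(1L, 2L, 4L) && ncol(tbl) == 1L) {   # zero surviving blocks
    return(tibble(haplotype = character(), sample = character(),
                  variant_code = character(), variant_rank = integer()))
  }
  switch(
    fmt,
    {                                                            # 1
      tidyr::pivot_longer(tbl, -"sample", names_to = "haplotype",
                          values_to = "variant_rank") |>
        dplyr::mutate(variant_rank = as.integer(.data$variant_rank),
                      variant_code = dplyr::if_else(
                        .data$variant_rank == 0L, "0",
                        .code_table[pmax(.data$variant_rank, 1L)])) |>
        dplyr::select("haplotype", "sample", "variant_code", "variant_rank")
    },
    {                                                            # 2
      tidyr::pivot_longer(tbl, -"sample", names_to = "haplotype",
                          values_to = "variant_code") |>
        dplyr::mutate(variant_rank = .code_rank(.data$variant_code)) |>
        dplyr::select("haplotype", "sample", "variant_code", "variant_rank")
    },
    tbl,                                                         # 3
    {                                                            # 4
      long <- tidyr::pivot_longer(tbl, -"sample", names_to = "col",
                                  values_to = "ind")
      # code is everything past the last underscore; block names contain "_"
      long$haplotype <- sub("_[^_]+$", "", long$col)
      long$variant_code <- sub("^.*_", "", long$col)
      hit <- long |>
        dplyr::filter(.data$ind == 1L) |>
        dplyr::select("haplotype", "sample", "variant_code")
      all_cells <- dplyr::distinct(long, .data$haplotype, .data$sample)
      dplyr::left_join(all_cells, hit, by = c("haplotype", "sample")) |>
        dplyr::mutate(variant_code = dplyr::coalesce(.data$variant_code, "0"),
                      variant_rank = .code_rank(.data$variant_code))
    },
    abort("conversion out of formats 5 and 6 is not supported",
          class = "ldhap_format_error")
  )
}
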