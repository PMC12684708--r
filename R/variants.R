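#' Letter codes for haplotype variants
#'
#' Maps a variant rank to its letter code: ranks 1-26 are `A`-`Z`; ranks 27
#' and up are two-letter codes in lexicographic order `AA`, `AB`, ...,
#' `ZZ`, skipping the string `NA` (reserved for missing data in downstream
#' tools). The mapping is a bijection over ranks 1..701
#' (26 singles + 676 doubles - "NA").
#'
#' @param rank Positive integer vector of variant ranks, each in 1..701.
#' @param block Optional block name used in the capacity error message.
#' @return Character vector of codes.
#' @examples
#' letter_code(c(1, 26, 27, 365, 701))
#' @export
letter_code <- function(rank, block = NULL) {
  rank <- as.integer(rank)
  if (any(is.na(rank)) || any(rank < 1L) || any(rank > .code_capacity)) {
    where <- if (is.null(block)) "" else paste0(" in block ", block)
    abort(paste0("haplotype variant rank out of the A..ZZ coding range (1..",
                 .code_capacity, ")", where),
          class = "ldhap_capacity_error")
  }
  .code_table[rank]
}

.make_code_table <- function() {
  doubles <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  doubles <- doubles[doubles != "NA"]
  c(LETTERS, doubles)
}
.code_table <- .make_code_table()
.code_capacity <- length(.code_table)   # 701

# inverse mapping: code -> rank; "0" -> 0
.code_rank <- function(code) {
  out <- match(code, .code_table)
  out[code == "0"] <- 0L
  if (any(is.na(out))) {
    abort(paste0("unknown variant code: ", code[is.na(out)][1]),
          class = "ldhap_format_error")
  }
  out
}

#' Enumerate haplotype variants within a block
#'
#' Builds each sample's variant signature — the ordered tuple of its
#' normalized diploid calls across the block's SNPs — and tabulates the
#' distinct complete signatures as haplotype variants with carrier counts.
#' Samples whose signature contains any missing call carry no variant
#' (code `"0"`) and never enter the dictionary: a missing call is not a
#' genotype, so it cannot define a combination.
#'
#' The result is pre-filter and pre-coding; [apply_min_freq()] filters rare
#' variants and assigns letter codes.
#'
#' @param block_genotypes A [geno_tbl] holding one block's SNPs (a
#'   `genotypes` list element of a `hap_blocks` tibble).
#' @param block Name of the block (carried through to outputs).
#' @return A `variant_assignment` list with elements `block`,
#'   `dictionary` (tibble: `signature`, `count`, `first_carrier`) and
#'   `assignments` (tibble: `sample`, `signature`, `NA` = no variant).
#' @export
enumerate_variants <- function(block_genotypes, block = "hap") {
  g <- as_geno_tbl(block_genotypes)
  calls <- geno_calls(g)
  complete <- colSums(is.na(calls)) == 0L
  sig <- rep(NA_character_, ncol(calls))
  sig[complete] <- apply(calls[, complete, drop = FALSE], 2L, paste,
                         collapse = ";")
  assignments <- tibble(sample = colnames(calls), signature = sig)
  dict <- assignments |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::filter(!is.na(.data$signature)) |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(count = dplyr::n(), first_carrier = min(.data$.ord),
                     .groups = "drop") |>
    dplyr::arrange(.data$first_carrier)
  structure(
    list(block = block, dictionary = dict, assignments = assignments),
    class = "variant_assignment"
  )
}

#' Filter rare variants and assign letter codes
#'
#' Removes dictionary variants carried by fewer than `min_freq` individuals
#' and zero-codes their carriers, then ranks the survivors by descending
#' carrier count (ties broken by order of first carrying sample, so ranks
#' are deterministic) and assigns [letter_code()]s by rank — `A` is always a
#' maximal-count variant, the major haplotype allele.
#'
#' @param assignment A `variant_assignment` from [enumerate_variants()].
#' @param min_freq Minimum carrier count for a variant to be retained,
#'   >= 1. Default 2.
#' @return A coded `variant_assignment`: `dictionary` gains `rank` and
#'   `code`; `assignments` gains `code` (`"0"` = no retained variant) and
#'   `rank` (0 likewise).
#' @examples
#' p <- example_panel()
#' blocks <- define_haplotypes(p$geno, p$ld)
#' va <- enumerate_variants(blocks$genotypes[[1]], blocks$block[1])
#' apply_min_freq(va, min_freq = 2)$dictionary
#' @export
apply_min_freq <- function(assignment, min_freq = 2) {
  if (!inherits(assignment, "variant_assignment")) {
    abort("assignment must come from enumerate_variants()",
          class = "ldhap_input_error")
  }
  if (min_freq < 1) {
    abort("min_freq must be >= 1", class = "ldhap_param_error")
  }
  dict <- assignment$dictionary |>
    dplyr::filter(.data$count >= min_freq) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$first_carrier) |>
    dplyr::mutate(rank = dplyr::row_number())
  dict$code <- if (nrow(dict) > 0) {
    letter_code(dict$rank, block = assignment$block)
  } else {
    character()
  }
  assignments <- assignment$assignments |>
    dplyr::left_join(dict[, c("signature", "code", "rank")],
                     by = "signature") |>
    dplyr::mutate(code = dplyr::coalesce(.data$code, "0"),
                  rank = dplyr::coalesce(.data$rank, 0L))
  structure(
    list(block = assignment$block,
         dictionary = dict[, c("signature", "count", "first_carrier",
                               "rank", "code")],
         assignments = assignments),
    class = "variant_assignment"
  )
}
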