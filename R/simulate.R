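#' Specify a planted haplotype block
#'
#' Describes one block of SNPs in high mutual LD, generated mechanistically:
#' a small set of founder haplotype-variant signatures is drawn once, each
#' sample copies one founder's diploid signature (chosen by
#' `variant_freqs`), and per-SNP corruption at `switch_rate` emulates
#' genotyping error and historical recombination, which is what decays LD in
#' real panels. Founders beyond the second are derived from an earlier
#' founder by mutating a small fraction of SNPs, the way minor haplotypes
#' arise from major ones, so intra-block LD stays high for any founder
#' count.
#'
#' @param chrom Chromosome name. Default `"chr1"`.
#' @param start_pos 1-based position of the first SNP.
#' @param n_snps Number of SNPs in the block, >= 2.
#' @param n_founder_variants Number of founder haplotype variants. Default 3.
#' @param variant_freqs Founder frequencies (summing to 1). Default: a
#'   geometric-style decay over the founders (0.5, 0.3, 0.2 for three).
#' @param switch_rate Per-sample, per-SNP probability of replacing the
#'   copied genotype with a random one. Default 0.01.
#' @param miss_rate Probability of a fully missing call (`./.`).
#'   Default 0.01.
#' @param halfmiss_rate Probability of a half-missing call (e.g. `./1`).
#'   Default 0.005.
#' @return A `block_spec` list.
#' @export
block_spec <- function(chrom = "chr1", start_pos = 1e6, n_snps = 35,
                       n_founder_variants = 3, variant_freqs = NULL,
                       switch_rate = 0.01, miss_rate = 0.01,
                       halfmiss_rate = 0.005) {
  if (n_snps < 2) abort("n_snps must be >= 2", class = "ldhap_spec_error")
  if (n_founder_variants < 1) {
    abort("n_founder_variants must be >= 1", class = "ldhap_spec_error")
  }
  if (is.null(variant_freqs)) {
    w <- 0.6^(seq_len(n_founder_variants) - 1)
    variant_freqs <- w / sum(w)
  }
  if (length(variant_freqs) != n_founder_variants ||
      abs(sum(variant_freqs) - 1) > 1e-8) {
    abort("variant_freqs must have one entry per founder and sum to 1",
          class = "ldhap_spec_error")
  }
  rates <- c(switch_rate, miss_rate, halfmiss_rate)
  if (any(rates < 0) || any(rates > 1)) {
    abort("rates must be in [0, 1]", class = "ldhap_spec_error")
  }
  structure(list(chrom = chrom, start_pos = start_pos, n_snps = n_snps,
                 n_founder_variants = n_founder_variants,
                 variant_freqs = variant_freqs, switch_rate = switch_rate,
                 miss_rate = miss_rate, halfmiss_rate = halfmiss_rate),
            class = "block_spec")
}

#' Specify a synthetic genotype panel
#'
#' @param n_samples Number of diploid individuals, >= 2. Default 100.
#' @param blocks List of [block_spec()]s with non-overlapping positions.
#' @param n_noise_snps Number of unlinked SNPs with independent
#'   Hardy-Weinberg genotypes. Default 0.
#' @param seed RNG seed; the whole panel is reproducible from it.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_samples = 100, blocks = list(), n_noise_snps = 0,
                       seed = 1) {
  if (n_samples < 2) abort("n_samples must be >= 2", class = "ldhap_spec_error")
  if (inherits(blocks, "block_spec")) blocks <- list(blocks)
  structure(list(n_samples = n_samples, blocks = blocks,
                 n_noise_snps = n_noise_snps, seed = as.integer(seed)),
            class = "panel_spec")
}

.rand_geno <- function(n) {
  # unordered diploid genotype with allele frequency 1/2
  a <- rbinom(n, 1L, 0.5)
  b <- rbinom(n, 1L, 0.5)
  paste(pmin(a, b), pmax(a, b), sep = "/")
}

#' Simulate a genotype panel with planted LD blocks
#'
#' Generates the panel described by a [panel_spec()]: founder signatures per
#' block, sample-level founder copying with corruption, independent noise
#' SNPs, then missingness, and finally the matching r-squared matrix via
#' [compute_r2()] on the calls resolved with `hetmiss_as = "allele"`. Truth
#' labels (block membership per SNP, founder variant per sample) are
#' returned for recovery checks. Fully reproducible from `spec$seed`; the
#' caller's RNG state is left untouched.
#'
#' @param spec A `panel_spec`.
#' @return A `sim_panel` list: `geno` (resolved [geno_tbl]), `ld`
#'   (`ld_matrix`), `raw` (tibble with the literal VCF call tokens, e.g.
#'   `./1`), `truth` (list of `snps` — tibble `id`, `pos`, `block`, `NA` for
#'   noise SNPs — and `founders` — tibble `sample`, `block`, `founder`) and
#'   `spec`.
#' @examples
#' sp <- panel_spec(n_samples = 50,
#'                  blocks = list(block_spec(start_pos = 1e6, n_snps = 10)),
#'                  n_noise_snps = 5, seed = 42)
#' p <- simulate_panel(sp)
#' dim(p$ld)
#' @export
simulate_panel <- function(spec) {
  if (!inherits(spec, "panel_spec")) {
    abort("spec must come from panel_spec()", class = "ldhap_spec_error")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n_smp <- spec$n_samples
  samples <- sprintf("S%03d", seq_len(n_smp))
  snp_rows <- list()
  raw_calls <- list()
  truth_snps <- list()
  truth_founders <- list()

  for (bi in seq_along(spec$blocks)) {
    bs <- spec$blocks[[bi]]
    pos <- bs$start_pos + cumsum(c(0L, sample(20:400, bs$n_snps - 1,
                                              replace = TRUE)))
    ids <- sprintf("%s_%d_s%d", bs$chrom, bs$start_pos, seq_len(bs$n_snps))
    founders <- .draw_founders(bs$n_founder_variants, bs$n_snps)
    pick <- sample(seq_len(bs$n_founder_variants), n_smp, replace = TRUE,
                   prob = bs$variant_freqs)
    calls <- founders[pick, , drop = FALSE]            # samples x snps
    if (bs$switch_rate > 0) {
      flip <- matrix(runif(n_smp * bs$n_snps) < bs$switch_rate,
                     n_smp, bs$n_snps)
      calls[flip] <- .rand_geno(sum(flip))
    }
    calls <- .apply_missing(calls, bs$miss_rate, bs$halfmiss_rate)
    block_name <- paste0("planted_", bi)
    snp_rows[[length(snp_rows) + 1]] <- tibble(
      chrom = bs$chrom, pos = as.integer(pos), id = ids, ref = "A", alt = "G"
    )
    raw_calls[[length(raw_calls) + 1]] <- t(calls)     # snps x samples
    truth_snps[[length(truth_snps) + 1]] <- tibble(
      id = ids, pos = as.integer(pos), block = block_name
    )
    truth_founders[[length(truth_founders) + 1]] <- tibble(
      sample = samples, block = block_name, founder = pick
    )
  }

  if (spec$n_noise_snps > 0) {
    base_chrom <- if (length(spec$blocks) > 0) {
      spec$blocks[[length(spec$blocks)]]$chrom
    } else {
      "chr1"
    }
    last_pos <- if (length(spec$blocks) > 0) {
      max(purrr::map_dbl(snp_rows, ~ max(.x$pos)))
    } else {
      1e6
    }
    pos <- last_pos + cumsum(sample(500:2000, spec$n_noise_snps,
                                    replace = TRUE))
    ids <- sprintf("noise_s%d", seq_len(spec$n_noise_snps))
    maf <- runif(spec$n_noise_snps, 0.1, 0.5)
    calls <- matrix("", spec$n_noise_snps, n_smp)
    for (i in seq_len(spec$n_noise_snps)) {
      a <- rbinom(n_smp, 1L, maf[i])
      b <- rbinom(n_smp, 1L, maf[i])
      calls[i, ] <- paste(pmin(a, b), pmax(a, b), sep = "/")
    }
    snp_rows[[length(snp_rows) + 1]] <- tibble(
      chrom = base_chrom, pos = as.integer(pos), id = ids, ref = "A", alt = "G"
    )
    raw_calls[[length(raw_calls) + 1]] <- calls
    truth_snps[[length(truth_snps) + 1]] <- tibble(
      id = ids, pos = as.integer(pos), block = NA_character_
    )
  }

  if (length(snp_rows) == 0) {
    abort("panel_spec describes zero SNPs", class = "ldhap_spec_error")
  }
  meta <- dplyr::bind_rows(snp_rows)
  raw <- do.call(rbind, raw_calls)
  colnames(raw) <- samples
  if (anyDuplicated(paste(meta$chrom, meta$pos))) {
    abort("block/noise SNP positions overlap", class = "ldhap_spec_error")
  }
  ord <- order(meta$chrom, meta$pos)
  meta <- meta[ord, ]
  raw <- raw[ord, , drop = FALSE]
  truth_snp_tbl <- dplyr::bind_rows(truth_snps)[ord, ]

  resolved <- raw
  for (i in seq_len(nrow(resolved))) {
    resolved[i, ] <- .normalize_gt(resolved[i, ], 1L, "allele",
                                   snp_label = meta$id[i])
  }
  geno <- as_geno_tbl(dplyr::bind_cols(meta, as_tibble(resolved)))
  ld <- compute_r2(geno)

  structure(
    list(geno = geno, ld = ld,
         raw = dplyr::bind_cols(meta, as_tibble(raw)),
         truth = list(snps = truth_snp_tbl,
                      founders = dplyr::bind_rows(truth_founders)),
         spec = spec),
    class = "sim_panel"
  )
}

# Founder diploid signatures, pairwise distinct. The first two founders are
# the two ancestral lineages: homozygous at every SNP and allele-complementary
# (breeding panels are largely inbred, and a high-LD block is in essence a
# biallelic haplotype contrast), so every SNP tags the same lineage
# bipartition and intra-block r2 is 1 before corruption. Founders 3+ derive
# from an earlier founder by mutating ~10% of SNPs, the way minor haplotype
# variants arise from major ones; they lower r2 only locally.
.draw_founders <- function(k, n_snps) {
  base_a <- ifelse(rbinom(n_snps, 1L, 0.5) == 1L, "1/1", "0/0")
  base_b <- ifelse(base_a == "0/0", "1/1", "0/0")
  founders <- matrix("", k, n_snps)
  founders[1, ] <- base_a
  if (k >= 2) founders[2, ] <- base_b
  for (f in seq_len(k)[-seq_len(min(k, 2L))]) {
    for (try in 1:50) {
      parent <- founders[sample(seq_len(f - 1), 1), ]
      n_mut <- max(1L, round(0.1 * n_snps))
      at <- sample(n_snps, n_mut)
      parent[at] <- .rand_geno(n_mut)
      key <- paste(parent, collapse = ";")
      prev <- apply(founders[seq_len(f - 1), , drop = FALSE], 1, paste,
                    collapse = ";")
      if (!key %in% prev) break
    }
    founders[f, ] <- parent
  }
  founders
}

.apply_missing <- function(calls, miss_rate, halfmiss_rate) {
  u <- matrix(runif(length(calls)), nrow(calls), ncol(calls))
  full <- u < miss_rate
  half <- !full & u < miss_rate + halfmiss_rate
  calls[full] <- "./."
  if (any(half)) {
    keep_first <- runif(sum(half)) < 0.5
    parts <- strsplit(calls[half], "/", fixed = TRUE)
    a <- vapply(parts, `[`, "", 1L)
    b <- vapply(parts, `[`, "", 2L)
    calls[half] <- ifelse(keep_first, paste0(a, "/."), paste0(".", "/", b))
  }
  calls
}

#' Write a simulated panel to VCF and LD files
#'
#' Writes the panel's raw calls (literal tokens, including half-missing
#' `./1`) as a VCF 4.2 file, the r-squared matrix in the PLINK
#' `--r2 square` dialect (label-less by default, or with a header row and
#' leading ID column), and the truth tables as TSV. [read_vcf()] /
#' [read_ld_matrix()] round-trip both files.
#'
#' @param panel A `sim_panel` from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix. Default `"panel"`.
#' @param labeled_ld Write the LD matrix with SNP-ID labels? Default
#'   `FALSE`.
#' @return A named list of paths: `vcf`, `ld`, `truth_snps`,
#'   `truth_founders`.
#' @export
write_fixture <- function(panel, dir, prefix = "panel", labeled_ld = FALSE) {
  if (!inherits(panel, "sim_panel")) {
    abort("panel must come from simulate_panel()", class = "ldhap_spec_error")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  ld_path <- file.path(dir, paste0(prefix, ".ld"))
  .write_vcf(panel$raw, vcf_path)
  .write_ld_matrix(panel$ld, ld_path, ids = panel$raw$id, labeled = labeled_ld)
  ts_path <- file.path(dir, paste0(prefix, "_truth_snps.tsv"))
  tf_path <- file.path(dir, paste0(prefix, "_truth_founders.tsv"))
  readr::write_tsv(panel$truth$snps, ts_path, na = "NA", progress = FALSE)
  readr::write_tsv(panel$truth$founders, tf_path, na = "NA", progress = FALSE)
  list(vcf = vcf_path, ld = ld_path, truth_snps = ts_path,
       truth_founders = tf_path)
}

# minimal VCF 4.2 writer over a raw-call tibble (meta cols + sample cols)
.write_vcf <- function(raw, path) {
  samples <- setdiff(names(raw), .geno_meta_cols)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ldhap_simulate_panel",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fixed <- paste(raw$chrom, raw$pos, raw$id, raw$ref, raw$alt,
                 ".", "PASS", ".", "GT", sep = "\t")
  calls <- do.call(paste, c(as.list(raw[, samples, drop = FALSE]),
                            sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, paste(fixed, calls, sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' The packaged tutorial panel
#'
#' A fixed small panel used throughout the documentation and tests: two
#' planted blocks of 35 SNPs each, 50 unlinked noise SNPs, 100 samples,
#' fixed seed. The VCF ships in `inst/extdata/synthetic_panel.vcf`
#' (synthetic data — see the methods vignette); the r-squared matrix is
#' recomputed on demand with [compute_r2()], which matches the PLINK
#' `--r2 square` values for these unphased genotypes.
#'
#' @return A list with `geno`, `ld`, `vcf` (path to the shipped file) and
#'   `spec` (the generating [panel_spec()]).
#' @examples
#' p <- example_panel()
#' nrow(p$geno)
#' @export
example_panel <- function() {
  vcf <- system.file("extdata", "synthetic_panel.vcf", package = "ldhap")
  geno <- read_vcf(vcf, hetmiss_as = "allele")
  list(geno = geno, ld = compute_r2(geno), vcf = vcf,
       spec = example_panel_spec())
}

#' @rdname example_panel
#' @export
example_panel_spec <- function() {
  panel_spec(
    n_samples = 100,
    blocks = list(
      block_spec(chrom = "chr1", start_pos = 31604185, n_snps = 35),
      block_spec(chrom = "chr1", start_pos = 33000000, n_snps = 35)
    ),
    n_noise_snps = 50,
    seed = 20260925
  )
}
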