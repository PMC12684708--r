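# Block definition, naming, outlier pruning, global/collate paths

geno_n <- function(n, n_samples = 6, ...) {
  withr::with_seed(99, {
    geno_from_dosage(matrix(sample(0:2, n * n_samples, replace = TRUE), n),
                     ...)
  })
}

test_that("blocks are named from their first and last SNP positions", {
  pos <- round(seq(31604185, 31646449, length.out = 35))
  g <- geno_n(35)
  g$pos <- as.integer(pos)
  g <- as_geno_tbl(g)
  blocks <- define_haplotypes(g, matrix(1, 35, 35))
  expect_identical(blocks$block, "hap_31604185_31646449")
  expect_identical(blocks$n_snps, 35L)
})

test_that("multi-chromosome inputs get chromosome-qualified names", {
  g1 <- geno_n(5, chrom = "chr1", start = 100L)
  g2 <- geno_n(5, chrom = "chr2", start = 100L)
  g <- as_geno_tbl(dplyr::bind_rows(g1, g2))
  ld <- block_ld(c(5, 5), inside = 1, outside = 0)
  blocks <- define_haplotypes(g, ld, epsilon = 0.5, mgmin = 3)
  expect_identical(blocks$block, c("hap_chr1_100_500", "hap_chr2_100_500"))
})

test_that("the noise group is dropped and an all-noise input warns", {
  g <- geno_n(10)
  expect_warning(
    blocks <- define_haplotypes(g, diag(10), epsilon = 0.6, mgmin = 5),
    "no local haplotype blocks"
  )
  expect_identical(nrow(blocks), 0L)
  expect_identical(glance(blocks)$noise_fraction, 1)
})

test_that("zero-dispersion blocks are never pruned", {
  g <- geno_n(6)
  blocks <- define_haplotypes(g, matrix(1, 6, 6), epsilon = 0.6, mgmin = 3)
  expect_identical(blocks$n_snps, 6L)
  expect_identical(attr(blocks, "n_outliers_removed"), 0L)
})

test_that("the constructed low-LD SNP is pruned, and kept with keep_outliers", {
  g <- geno_n(10)
  ld <- outlier_ld10()
  pruned <- define_haplotypes(g, ld, epsilon = 0.95, mgmin = 2)
  kept <- define_haplotypes(g, ld, epsilon = 0.95, mgmin = 2,
                            keep_outliers = TRUE)
  expect_identical(pruned$snp_index[[1]], 1:9)
  expect_identical(kept$snp_index[[1]], 1:10)
  # keep_outliers = TRUE gives a strict superset per matching cluster
  expect_true(all(pruned$snp_index[[1]] %in% kept$snp_index[[1]]))
  # names track the surviving span
  expect_identical(pruned$end, g$pos[9])
  expect_identical(kept$end, g$pos[10])
})

test_that("outlier pruning is single-pass: the threshold is not recomputed", {
  g <- geno_n(10)
  blocks <- define_haplotypes(g, singlepass_ld10(), epsilon = 0.95, mgmin = 2)
  # SNP 10 removed; SNP 9 would fall only to a recomputed threshold
  expect_identical(blocks$snp_index[[1]], 1:9)
})

test_that("two-member blocks are never pruned: their dispersion is zero", {
  # with two members the two per-SNP mean-LD values coincide, so s = 0 and
  # the two-sided 2-SD rule cannot flag either SNP; more generally a SNP
  # needs (m_i - med)^2 > 4 s^2 while all squared deviations from the mean
  # sum to (n - 1) s^2, so at most (n - 1) / 4 SNPs can ever be flagged and
  # pruning can never push a block below 2 survivors
  g <- geno_n(2)
  ld <- rbind(c(1, 0.3), c(0.3, 1))
  blocks <- define_haplotypes(g, ld, epsilon = 0.8, mgmin = 2,
                              keep_outliers = TRUE)
  pruned <- remove_outlier_snps(blocks, ld)
  expect_identical(pruned$snp_index, blocks$snp_index)
  expect_identical(nrow(pruned), 1L)
})

test_that("clusters reduced below 2 SNPs vanish from the collection", {
  g <- geno_n(4)
  # pair of linked SNPs plus two stragglers; with mgmin = 1 the stragglers
  # become 1-SNP clusters, which are just SNPs and must be dropped
  ld <- block_ld(c(2, 1, 1), inside = 1, outside = 0)
  blocks <- define_haplotypes(g, ld, epsilon = 0.5, mgmin = 1)
  expect_identical(nrow(blocks), 1L)
  expect_identical(blocks$n_snps, 2L)
})

test_that("define_haplotypes_globally equals per-pair runs and collates", {
  p1 <- simulate_panel(recovery_panel_spec(301))
  sp2 <- recovery_panel_spec(302)
  sp2$blocks[[1]]$start_pos <- 9e6
  sp2$blocks[[2]]$start_pos <- 13e6
  p2 <- simulate_panel(sp2)
  pairs <- list(list(gt = p1$geno, ld = p1$ld),
                list(gt = p2$geno, ld = p2$ld))

  glob <- define_haplotypes_globally(pairs)
  single <- define_haplotypes(p1$geno, p1$ld)
  both <- list(single, define_haplotypes(p2$geno, p2$ld))

  expect_identical(glob$block, c(both[[1]]$block, both[[2]]$block))
  expect_identical(nrow(glob), nrow(both[[1]]) + nrow(both[[2]]))
  expect_identical(tidy(collate_define_haplotypes(both)), tidy(glob))
  # singleton collate is the identity
  expect_identical(tidy(collate_define_haplotypes(list(single))),
                   tidy(single))
})

test_that("global/collate contracts reject bad inputs", {
  p1 <- simulate_panel(small_panel_spec(11, miss_rate = 0, halfmiss_rate = 0))
  p2 <- simulate_panel(small_panel_spec(12, miss_rate = 0, halfmiss_rate = 0))
  reordered <- p2$geno[, c(c("chrom", "pos", "id", "ref", "alt"),
                           rev(geno_samples(p2$geno)))]
  reordered <- as_geno_tbl(reordered)
  expect_error(
    define_haplotypes_globally(list(list(gt = p1$geno, ld = p1$ld),
                                    list(gt = reordered, ld = p2$ld))),
    class = "ldhap_alignment_error"
  )
  b <- define_haplotypes(p1$geno, p1$ld, epsilon = 0.9, mgmin = 2)
  expect_error(collate_define_haplotypes(list(b, b)),
               class = "ldhap_collision_error")
})

test_that("mismatched LD dimension is a hard alignment error", {
  g <- geno_n(4)
  expect_error(define_haplotypes(g, diag(5)),
               class = "ldhap_alignment_error")
})
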