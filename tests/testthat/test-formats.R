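# Output layouts, conversions and collation of haplotype-variant tables

fixture_table <- local({
  tab <- NULL
  function(format = 1) {
    if (is.null(tab)) {
      p <- example_panel()
      tab <<- haplotype_variants(p$geno, p$ld, format = 1)
    }
    convert_format(tab, format)
  }
})

test_that("format 1 is samples x blocks with integer variant ranks", {
  tab <- fixture_table(1)
  expect_identical(names(tab)[1], "sample")
  expect_identical(nrow(tab), 100L)
  info <- attr(tab, "block_info")
  expect_identical(names(tab)[-1], info$block)
  expect_true(all(vapply(tab[-1], is.integer, TRUE)))
  expect_true(all(as.matrix(tab[-1]) >= 0))
})

test_that("formats 1, 2 and 3 interconvert losslessly", {
  t1 <- fixture_table(1)
  t2 <- convert_format(t1, 2)
  t3 <- convert_format(t2, 3)
  back <- convert_format(t3, 1)
  expect_identical(bare(back), bare(t1))
  # letter codes match ranks through the coding bijection: A -> 1, 0 -> 0
  ranks <- unname(unlist(t1[1, -1]))
  codes <- unname(unlist(t2[1, -1]))
  expect_identical(codes,
                   ifelse(ranks == 0L, "0", letter_code(pmax(ranks, 1L))))
})

test_that("format 4 one-hot encodes and argmax converts back to format 1", {
  t1 <- fixture_table(1)
  t4 <- convert_format(t1, 4)
  info <- attr(t1, "block_info")
  expect_identical(names(t4)[-1],
                   unlist(purrr::map2(info$block, info$codes,
                                      ~ paste0(.x, "_", .y))))
  expect_true(all(as.matrix(t4[-1]) %in% 0:1))
  # per block at most one indicator fires per sample
  for (i in seq_len(nrow(info))) {
    cols <- paste0(info$block[i], "_", info$codes[[i]])
    expect_true(all(rowSums(t4[, cols, drop = FALSE]) <= 1))
  }
  back <- convert_format(t4, 1)
  expect_identical(bare(back)[names(t1)], bare(t1))
})

test_that("format 5 is a HapMap-like block-per-row table", {
  t5 <- fixture_table(5)
  info <- attr(t5, "block_info")
  expect_identical(names(t5)[1:4], c("rs#", "alleles", "chrom", "pos"))
  expect_identical(t5$`rs#`, info$block)
  expect_identical(t5$pos, info$start)
  expect_identical(t5$alleles,
                   vapply(info$codes, paste, "", collapse = "/"))
  expect_identical(ncol(t5), 4L + 100L)
})

test_that("format 6 writes a syntactically valid VCF that vcfR can parse", {
  t6 <- fixture_table(6)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_output(t6, path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_identical(nrow(v@fix), nrow(t6))
  expect_identical(unname(v@fix[, "ID"]), t6$ID)
  gt <- vcfR::extract.gt(v, element = "GT")
  # haploid indices: rank 1 (code A) is the REF allele, index 0
  t2 <- fixture_table(2)
  a_samples <- t2$sample[t2[[t6$ID[1]]] == "A"]
  expect_true(all(gt[1, a_samples] == "0"))
  zero_samples <- t2$sample[t2[[t6$ID[1]]] == "0"]
  expect_true(all(is.na(gt[1, zero_samples]) | gt[1, zero_samples] == "."))
})

test_that("written tables round-trip through disk (format 1)", {
  t1 <- fixture_table(1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_output(t1, path)
  back <- read_output(path, 1)
  expect_identical(bare(back), bare(t1))
  # re-read tables still interconvert among 1..4
  expect_identical(bare(convert_format(convert_format(back, 3), 1)),
                   bare(t1))
})

test_that("an empty assignment set yields a header-only sample table", {
  p <- simulate_panel(small_panel_spec(5))
  tab <- suppressWarnings(
    haplotype_variants(p$geno, p$ld, epsilon = 0.2, mgmin = 30, format = 1)
  )
  expect_identical(names(tab), "sample")
  expect_identical(nrow(tab), 8L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_output(tab, path)
  expect_identical(readLines(path)[1], "sample")
  back <- read_output(path, 1)
  expect_identical(nrow(back), 8L)
})

test_that("collation preserves blocks, rejects mixed formats and duplicates", {
  t1 <- fixture_table(1)
  info <- attr(t1, "block_info")
  # split into two single-block tables via conversion from the long layout
  long <- tidy(t1)
  halves <- purrr::map(info$block, function(b) {
    part <- long[long$haplotype == b, ]
    tab <- ldhap:::.format_hap_table(part, info[info$block == b, ],
                                     attr(t1, "samples"), 1L)
    tab
  })
  merged <- collate_haplotype_variants(halves)
  expect_identical(bare(merged), bare(t1))
  expect_identical(bare(collate_haplotype_variants(list(t1))),
                   bare(t1))
  expect_error(
    collate_haplotype_variants(list(t1, convert_format(t1, 3))),
    class = "ldhap_format_error"
  )
  expect_error(collate_haplotype_variants(list(t1, t1)),
               class = "ldhap_collision_error")
})

test_that("format validation rejects out-of-range requests", {
  p <- example_panel()
  expect_error(haplotype_variants(p$geno, p$ld, format = 7),
               class = "ldhap_param_error")
  expect_error(convert_format(fixture_table(1), 0),
               class = "ldhap_param_error")
  expect_error(convert_format(fixture_table(5), 1),
               class = "ldhap_format_error")
})
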