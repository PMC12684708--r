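# Variant enumeration, letter coding, minimum-frequency filtering

# a block genotype table with prescribed per-sample signatures:
# sig_of[s] gives which signature sample s carries; NA = inject a missing call
block_geno_from_signatures <- function(signatures, sig_of) {
  calls <- vapply(sig_of, function(k) {
    if (is.na(k)) {
      sig <- strsplit(signatures[[1]], ";")[[1]]
      sig[1] <- NA_character_
      sig
    } else {
      strsplit(signatures[[k]], ";")[[1]]
    }
  }, character(length(strsplit(signatures[[1]], ";")[[1]])))
  make_geno(calls)
}

test_that("unique complete genotype combinations become variants with counts", {
  g <- block_geno_from_signatures(
    list("0/0;0/1", "1/1;0/1"),
    c(1, 1, 2)
  )
  va <- enumerate_variants(g, block = "hap_x")
  expect_identical(nrow(va$dictionary), 2L)
  expect_identical(sort(va$dictionary$count, decreasing = TRUE), c(2L, 1L))
  # two identical samples share a signature
  expect_identical(va$assignments$signature[1], va$assignments$signature[2])
})

test_that("samples with any missing call carry no variant and stay out of the dictionary", {
  g <- block_geno_from_signatures(
    list("0/0;0/1", "1/1;0/1"),
    c(1, 1, NA)
  )
  va <- apply_min_freq(enumerate_variants(g, "hap_x"), min_freq = 1)
  expect_identical(va$assignments$code, c("A", "A", "0"))
  expect_identical(nrow(va$dictionary), 1L)
})

test_that("letter codes map ranks as A..Z then AA..ZZ skipping NA", {
  expect_identical(letter_code(1), "A")
  expect_identical(letter_code(26), "Z")
  expect_identical(letter_code(27), "AA")
  # the two-letter sequence reaches "NA" at rank 365; it is skipped
  expect_identical(letter_code(364), "MZ")
  expect_identical(letter_code(365), "NB")
  expect_identical(letter_code(701), "ZZ")
  codes <- letter_code(1:701)
  expect_identical(anyDuplicated(codes), 0L)
  expect_false("NA" %in% codes)
  expect_error(letter_code(702, block = "hap_x"),
               class = "ldhap_capacity_error")
  expect_error(letter_code(0), class = "ldhap_capacity_error")
})

test_that("two-letter codes follow the programmatic enumeration oracle", {
  oracle <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  oracle <- oracle[oracle != "NA"]
  expect_identical(letter_code(27:701), oracle)
})

test_that("minFreq removes rare variants, zero-codes carriers, ranks by count", {
  g <- block_geno_from_signatures(
    list("0/0;0/0", "1/1;1/1", "0/1;0/1"),
    c(rep(1, 5), rep(2, 3), 3)
  )
  va <- apply_min_freq(enumerate_variants(g, "hap_x"), min_freq = 2)
  expect_identical(va$dictionary$code, c("A", "B"))
  expect_identical(va$dictionary$count, c(5L, 3L))
  expect_identical(va$assignments$code[9], "0")
  expect_identical(va$assignments$rank[9], 0L)
  # min_freq = 1 keeps everything
  va1 <- apply_min_freq(enumerate_variants(g, "hap_x"), min_freq = 1)
  expect_identical(nrow(va1$dictionary), 3L)
})

test_that("count ties break by order of first carrying sample", {
  g <- block_geno_from_signatures(
    list("0/0;0/0", "1/1;1/1", "0/1;0/1", "0/0;1/1"),
    c(1, 1, 1, 1, 1, 2, 3, 2, 3, 2, 3, 4)
  )
  va <- apply_min_freq(enumerate_variants(g, "hap_x"), min_freq = 2)
  expect_identical(va$dictionary$count, c(5L, 3L, 3L))
  # signature 2 first carried by sample 6, signature 3 by sample 7
  expect_identical(va$dictionary$code, c("A", "B", "C"))
  expect_identical(va$assignments$code[6], "B")
  expect_identical(va$assignments$code[7], "C")
  expect_identical(va$assignments$code[12], "0")
})

test_that("carrier counts plus zero-coded samples always partition the panel", {
  withr::local_seed(5)
  for (r in 1:10) {
    p <- simulate_panel(small_panel_spec(400 + r))
    blocks <- suppressWarnings(
      define_haplotypes(p$geno, p$ld, epsilon = 0.9, mgmin = 3)
    )
    for (i in seq_len(nrow(blocks))) {
      va <- apply_min_freq(
        enumerate_variants(blocks$genotypes[[i]], blocks$block[i]),
        min_freq = 2
      )
      n_zero <- sum(va$assignments$code == "0")
      expect_identical(sum(va$dictionary$count) + n_zero,
                       length(geno_samples(p$geno)))
    }
  }
})

test_that("variant survival is monotone in min_freq", {
  p <- simulate_panel(small_panel_spec(77))
  blocks <- suppressWarnings(
    define_haplotypes(p$geno, p$ld, epsilon = 0.9, mgmin = 3)
  )
  va <- enumerate_variants(blocks$genotypes[[1]], blocks$block[1])
  prev <- NULL
  for (mf in 1:5) {
    dict <- apply_min_freq(va, min_freq = mf)$dictionary
    if (!is.null(prev)) {
      expect_true(all(dict$signature %in% prev$signature))
      expect_lte(nrow(dict), nrow(prev))
    }
    prev <- dict
  }
})
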