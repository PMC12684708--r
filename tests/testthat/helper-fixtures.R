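# Shared builders for tests: tiny genotype tables, random LD matrices, the
# constructed outlier blocks, and an independent reference DBSCAN.

# strip classes and provenance attributes; compare table contents only
bare <- function(x) {
  x <- as.data.frame(x)
  at <- attributes(x)
  attributes(x) <- at[intersect(names(at), c("names", "row.names"))]
  class(x) <- "data.frame"
  x
}

make_geno <- function(calls, pos = NULL, chrom = "chr1", start = 1000L) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(pos)) pos <- start + (seq_len(n) - 1L) * 100L
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("S%02d", seq_len(ncol(calls)))
  }
  as_geno_tbl(dplyr::bind_cols(
    tibble::tibble(chrom = chrom, pos = as.integer(pos),
                   id = sprintf("snp%d", seq_len(n)), ref = "A", alt = "G"),
    tibble::as_tibble(calls)
  ))
}

# snps x samples matrix of 0/1/2 dosages -> geno_tbl
geno_from_dosage <- function(d, ...) {
  d <- as.matrix(d)
  make_geno(matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d), ncol(d)), ...)
}

random_ld <- function(n) {
  m <- matrix(runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# block-structured LD: groups get r2 `inside` among themselves, `outside`
# elsewhere
block_ld <- function(sizes, inside = 1, outside = 0) {
  n <- sum(sizes)
  m <- matrix(outside, n, n)
  at <- cumsum(c(0, sizes))
  for (g in seq_along(sizes)) {
    idx <- (at[g] + 1):at[g + 1]
    m[idx, idx] <- inside
  }
  diag(m) <- 1
  m
}

# 10-SNP outlier fixture: SNPs 1..9 mutually at 0.95, SNP 10 at 0.1 to all.
# Hand computation: m_i = (8*0.95 + 0.1)/9 = 0.8556 for i in 1..9,
# m_10 = 0.1; median = 0.8556, sample SD = 0.2390, threshold 2s = 0.4779;
# only |m_10 - med| = 0.7556 crosses it.
outlier_ld10 <- function() {
  m <- matrix(0.1, 10, 10)
  m[1:9, 1:9] <- 0.95
  diag(m) <- 1
  m
}

# single-pass fixture: 8 SNPs at 0.9 mutually, SNP 9 links at 0.6, SNP 10 at
# 0.1. Pass one removes only SNP 10 (2s = 0.4044, |m_9 - med| = 0.2333 under
# it); recomputing on the pruned block would also remove SNP 9 (new 2s =
# 0.1750 < 0.2625), so SNP 9 kept proves the rule is applied exactly once.
singlepass_ld10 <- function() {
  m <- matrix(0.1, 10, 10)
  m[1:8, 1:8] <- 0.9
  m[9, 1:8] <- m[1:8, 9] <- 0.6
  diag(m) <- 1
  m
}

# Independent reference DBSCAN (textbook seed-expansion formulation) on the
# distance 1 - r2; border points join the first cluster that reaches them.
naive_dbscan <- function(ld, eps, minpts) {
  d <- 1 - ld
  n <- nrow(d)
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  cl <- 0L
  for (p in seq_len(n)) {
    if (visited[p]) next
    visited[p] <- TRUE
    nb <- which(d[p, ] <= eps)
    if (length(nb) < minpts) next
    cl <- cl + 1L
    labels[p] <- cl
    seeds <- setdiff(nb, p)
    while (length(seeds) > 0) {
      q <- seeds[1]
      seeds <- seeds[-1]
      if (!visited[q]) {
        visited[q] <- TRUE
        nbq <- which(d[q, ] <= eps)
        if (length(nbq) >= minpts) seeds <- c(seeds, setdiff(nbq, q))
      }
      if (labels[q] == 0L) labels[q] <- cl
    }
  }
  labels
}

# canonical partition: clusters sorted by smallest member, noise one set
canonical_partition <- function(labels) {
  sets <- split(seq_along(labels), labels)
  noise <- unname(sets[names(sets) == "0"])
  clusters <- unname(sets[names(sets) != "0"])
  clusters <- clusters[order(vapply(clusters, min, 1L))]
  list(noise = noise, clusters = clusters)
}

# independent resolution oracle for raw VCF GT tokens
resolve_tokens <- function(tokens, mode) {
  vapply(tokens, function(tok) {
    parts <- strsplit(tok, "[/|]")[[1]]
    if (all(parts == ".")) return(NA_character_)
    if (any(parts == ".")) {
      if (mode == "miss") return(NA_character_)
      parts[parts == "."] <- "0"
    }
    ab <- sort(as.integer(parts))
    paste(ab[1], ab[2], sep = "/")
  }, "", USE.NAMES = FALSE)
}

# small random panel spec for IO round-trip checks
small_panel_spec <- function(seed, miss_rate = 0.05, halfmiss_rate = 0.05) {
  panel_spec(
    n_samples = 8,
    blocks = list(block_spec(start_pos = 1e5, n_snps = 6,
                             miss_rate = miss_rate,
                             halfmiss_rate = halfmiss_rate)),
    n_noise_snps = 4,
    seed = seed
  )
}

# recovery panel matching the planted-block recovery premise: two clean
# founder variants per block (every SNP tags the same contrast), switch
# noise at 2%
recovery_panel_spec <- function(seed, switch_rate = 0.02) {
  panel_spec(
    n_samples = 100,
    blocks = list(
      block_spec(start_pos = 1e6, n_snps = 35, n_founder_variants = 2,
                 switch_rate = switch_rate, miss_rate = 0,
                 halfmiss_rate = 0),
      block_spec(start_pos = 5e6, n_snps = 35, n_founder_variants = 2,
                 switch_rate = switch_rate, miss_rate = 0, halfmiss_rate = 0)
    ),
    n_noise_snps = 50,
    seed = seed
  )
}

blocks_match_truth <- function(blocks, panel) {
  truth <- split(panel$truth$snps$id, panel$truth$snps$block)
  got <- lapply(blocks$genotypes, function(g) g$id)
  length(got) == length(truth) &&
    setequal(vapply(got, paste, "", collapse = ","),
             vapply(truth, paste, "", collapse = ","))
}
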