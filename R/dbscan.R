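#' DBSCAN labels on an LD-derived distance matrix
#'
#' Classical DBSCAN on the precomputed distance d(i, j) = 1 - r\eqn{^2}(i, j),
#' the standard LD-to-distance mapping, so `epsilon = 0.6` means "neighbors
#' share r-squared of at least 0.4". A SNP is a core point iff its
#' epsilon-neighborhood (d <= epsilon, the SNP counting itself) holds at least
#' `mgmin` SNPs; clusters are the maximal density-connected sets; non-core
#' SNPs unreachable from any core are noise.
#'
#' Labeling is deterministic and independent of traversal order: border SNPs
#' reachable from several clusters join the lowest-labeled one, and final
#' labels are renumbered 1..K by ascending index of each cluster's first
#' member SNP.
#'
#' @param ld An [as_ld_matrix()]-valid r-squared matrix.
#' @param epsilon Neighborhood radius on d = 1 - r-squared, in (0, 1].
#'   Default 0.6.
#' @param mgmin Minimum neighborhood size (DBSCAN minPts), >= 1. Default 30.
#' @return An integer vector of per-SNP labels: 1..K for cluster members,
#'   0 for noise.
#' @examples
#' ld <- as_ld_matrix(matrix(1, 3, 3))
#' dbscan_labels(ld, epsilon = 0.6, mgmin = 2)
#' @export
dbscan_labels <- function(ld, epsilon = 0.6, mgmin = 30) {
  ld <- as_ld_matrix(ld)
  if (!(epsilon > 0 && epsilon <= 1)) {
    abort("epsilon must be in (0, 1]", class = "ldhap_param_error")
  }
  if (mgmin < 1) {
    abort("mgmin must be >= 1", class = "ldhap_param_error")
  }
  n <- nrow(ld)
  adj <- (1 - ld) <= epsilon            # includes self: d(i, i) = 0
  core <- rowSums(adj) >= mgmin

  labels <- integer(n)                  # 0 = noise / unassigned
  next_label <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    next_label <- next_label + 1L
    labels[i] <- next_label
    queue <- i
    while (length(queue) > 0) {
      p <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[p, ] & core & labels == 0L)
      labels[nb] <- next_label
      queue <- c(queue, nb)
    }
  }
  # border points: non-core with >= 1 core neighbor; lowest label wins
  for (i in which(!core)) {
    nb_labels <- labels[adj[i, ] & core]
    if (length(nb_labels) > 0) labels[i] <- min(nb_labels)
  }
  .renumber_labels(labels)
}

# renumber cluster labels 1..K by ascending index of first member; noise = 0
.renumber_labels <- function(labels) {
  firsts <- vapply(unique(labels[labels != 0L]),
                   function(l) which(labels == l)[1], 1L)
  if (length(firsts) == 0) return(labels)
  old <- unique(labels[labels != 0L])[order(firsts)]
  out <- integer(length(labels))
  for (k in seq_along(old)) out[labels == old[k]] <- k
  out
}
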