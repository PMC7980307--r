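# Shared fixture builders. Everything is generated in code; no data files.

# small alignment from explicit sequences
aln_fixture <- function(seqs, ids = sprintf("s%02d", seq_along(seqs)),
                        partitions = list()) {
  seq_alignment(ids, seqs, partitions)
}

# an alignment forced to have `hap` haplotypes among `n` sequences by
# duplicating the first haplotype: one haplotype gets n - hap + 1 copies
# only when hap < n. Here we need the Table-2-style configuration with one
# duplicated haplotype and the rest singletons: n sequences, hap = n - 1.
forced_hap_config <- function(n, hap, L = 40) {
  stopifnot(hap <= n)
  bases <- c("A", "C", "G", "T")
  base_seq <- strrep("A", L)
  uniq <- vapply(seq_len(hap), function(h) {
    s <- strsplit(base_seq, "")[[1]]
    # give haplotype h a unique combination of substitutions
    s[(h %% L) + 1] <- bases[(h %% 3) + 2]
    s[((2 * h) %% L) + 1] <- bases[((h + 1) %% 3) + 2]
    paste(s, collapse = "")
  }, "")
  stopifnot(!anyDuplicated(uniq))
  seqs <- c(uniq, rep(uniq[1], n - hap))
  aln_fixture(seqs)
}

# genotype matrix from a compact list: calls[[ind]][[locus]] = c(a1, a2)
gt_fixture <- function(calls, ids = NULL, loci = NULL) {
  n <- length(calls)
  L <- length(calls[[1]])
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(n))
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(L))
  arr <- array(NA_integer_, c(n, L, 2))
  for (i in seq_len(n)) {
    for (l in seq_len(L)) {
      g <- calls[[i]][[l]]
      if (!is.null(g) && !anyNA(g)) arr[i, l, ] <- as.integer(g)
    }
  }
  genotype_matrix(arr, ids, loci)
}

# random diploid genotypes from given allele frequencies (HWE)
random_gt <- function(n, freqs_by_locus, seed) {
  set.seed(seed)
  L <- length(freqs_by_locus)
  arr <- array(NA_integer_, c(n, L, 2))
  for (l in seq_len(L)) {
    f <- freqs_by_locus[[l]]
    sizes <- as.integer(names(f))
    arr[, l, 1] <- sizes[sample.int(length(sizes), n, replace = TRUE, prob = f)]
    arr[, l, 2] <- sizes[sample.int(length(sizes), n, replace = TRUE, prob = f)]
  }
  genotype_matrix(arr, sprintf("i%03d", seq_len(n)),
                  sprintf("L%02d", seq_len(L)))
}

# small raster fixture
raster_fixture <- function(values, cellsize = 1) {
  raster_grid(values, cellsize = cellsize)
}

# dense effective-resistance oracle via Laplacian pseudo-inverse
resistance_oracle <- function(resist, nodes, connectivity = 8) {
  g <- skyisland:::resistance_graph(resist, connectivity)
  L <- as.matrix(g$L)
  Lp <- MASS::ginv(L)
  ids <- g$index[cbind(nodes$row, nodes$col)]
  k <- length(ids)
  out <- matrix(0, k, k, dimnames = list(nodes$label, nodes$label))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      i <- ids[a]; j <- ids[b]
      out[a, b] <- Lp[i, i] + Lp[j, j] - 2 * Lp[i, j]
    }
  }
  out
}

# random positive resistance surface
random_surface <- function(nr, nc, seed, max_cost = 50) {
  set.seed(seed)
  raster_grid(matrix(stats::runif(nr * nc, 1, max_cost), nr, nc))
}

# symmetric random pairwise matrix with zero diagonal
random_pairwise <- function(k, seed, labels = paste0("P", seq_len(k)),
                            statistic = "test") {
  set.seed(seed)
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  v <- stats::runif(k * (k - 1) / 2, 0.05, 1)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  pairwise_matrix(m, statistic)
}
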