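#' Aligned haploid sequences with optional partitions
#'
#' A `seq_alignment` holds equal-length nucleotide sequences (one per
#' individual) over the alphabet `A,C,G,T,N,-`, together with named
#' partitions (1-based, inclusive ranges) such as a protein-coding fragment
#' and a hyper-variable control-region fragment concatenated into one
#' sequence per individual.
#'
#' @param ids character vector of individual labels (unique).
#' @param seqs character vector of sequences, same length as `ids`, all of
#'   equal nucleotide length.
#' @param partitions named list of integer pairs `c(start, end)`; ranges must
#'   be disjoint and within the alignment length. May be empty.
#' @return An object of class `seq_alignment`: a list with elements `ids`,
#'   `mat` (character matrix, individuals x sites) and `partitions`.
#' @export
seq_alignment <- function(ids, seqs, partitions = list()) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("sequences are not aligned: lengths ", paste(unique(lens), collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  if (is.null(mat)) mat <- matrix(character(0), 0, 0)
  rownames(mat) <- ids
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad) > 0) {
    # tolerate IUPAC ambiguity codes by mapping them to N
    mat[mat %in% bad] <- "N"
  }
  L <- ncol(mat)
  if (length(partitions)) {
    if (is.null(names(partitions)) || any(!nzchar(names(partitions)))) {
      stop("partitions must be named")
    }
    covered <- integer(0)
    for (p in partitions) {
      if (length(p) != 2L || p[1] > p[2] || p[1] < 1L || p[2] > L) {
        stop("partition range out of bounds")
      }
      rng <- seq.int(p[1], p[2])
      if (any(rng %in% covered)) stop("partitions overlap")
      covered <- c(covered, rng)
    }
  }
  structure(list(ids = ids, mat = mat, partitions = partitions),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("seq_alignment: %d sequences x %d sites", length(x$ids), ncol(x$mat)))
  if (length(x$partitions)) {
    cat("; partitions:", paste(sprintf("%s[%d-%d]", names(x$partitions),
        vapply(x$partitions, `[`, 1L, 1L), vapply(x$partitions, `[`, 1L, 2L)),
        collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Number of sequences / subset of an alignment
#' @param aln a [seq_alignment()].
#' @param who character vector of ids or logical/integer index.
#' @return `aln_subset` returns a new `seq_alignment` restricted to `who`,
#'   keeping partitions.
#' @export
aln_subset <- function(aln, who) {
  stopifnot(inherits(aln, "seq_alignment"))
  if (is.character(who)) {
    idx <- match(who, aln$ids)
    if (anyNA(idx)) stop("unknown ids: ", paste(who[is.na(idx)], collapse = ", "))
  } else {
    idx <- seq_along(aln$ids)[who]
  }
  seq_alignment(aln$ids[idx],
                apply(aln$mat[idx, , drop = FALSE], 1, paste, collapse = ""),
                aln$partitions)
}

slice_partition <- function(aln, scope) {
  if (is.null(scope) || identical(scope, "full")) return(aln$mat)
  p <- aln$partitions[[scope]]
  if (is.null(p)) stop("unknown partition: ", scope)
  aln$mat[, seq.int(p[1], p[2]), drop = FALSE]
}

#' Collapse aligned sequences into haplotypes
#'
#' Identical sequences share a haplotype. By default any difference,
#' including an `N` or gap against a called base, separates haplotypes
#' (an `N` mismatches everything, matching the conservative convention of
#' sequence-collapsing tools). With `ambiguous_merge = TRUE`, sequences
#' differing only at sites where at least one of the pair is `N`/`-` are
#' merged greedily in input order.
#'
#' @param aln a [seq_alignment()].
#' @param scope `"full"` (default) or the name of a partition.
#' @param ambiguous_merge logical; merge sequences that differ only at
#'   ambiguous (`N`/`-`) sites. Default `FALSE`.
#' @return A data frame with one row per haplotype: `haplotype` (label),
#'   `count`, and `members` (comma-separated individual ids), ordered by
#'   first appearance. Attribute `assignment` maps each id to its haplotype.
#' @export
collapse_haplotypes <- function(aln, scope = "full", ambiguous_merge = FALSE) {
  stopifnot(inherits(aln, "seq_alignment"))
  m <- slice_partition(aln, scope)
  n <- nrow(m)
  if (n == 0L) stop("empty alignment")
  if (!ambiguous_merge) {
    keys <- apply(m, 1, paste, collapse = "")
    hap <- match(keys, unique(keys))
  } else {
    hap <- integer(n)
    reps <- list()  # representative row index per haplotype
    for (i in seq_len(n)) {
      found <- 0L
      for (h in seq_along(reps)) {
        r <- m[reps[[h]], ]
        s <- m[i, ]
        amb <- r %in% c("N", "-") | s %in% c("N", "-")
        if (all(r[!amb] == s[!amb])) { found <- h; break }
      }
      if (found == 0L) { reps[[length(reps) + 1L]] <- i; found <- length(reps) }
      hap[i] <- found
    }
  }
  labs <- sprintf("H%02d", seq_len(max(hap)))
  assignment <- stats::setNames(labs[hap], aln$ids)
  out <- data.frame(
    haplotype = labs,
    count = as.integer(tabulate(hap)),
    members = vapply(seq_len(max(hap)),
                     function(h) paste(aln$ids[hap == h], collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  attr(out, "assignment") <- assignment
  out
}

# pairwise difference counts with pairwise deletion of N/- sites.
# Returns list(diff = matrix of differing-site counts, valid = matrix of
# compared-site counts), n x n, individuals in row order.
pairwise_site_diffs <- function(m) {
  n <- nrow(m)
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  diffm <- matrix(0, n, n)
  valid <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      comp <- ok[i, ] & ok[j, ]
      valid[i, j] <- valid[j, i] <- sum(comp)
      diffm[i, j] <- diffm[j, i] <- sum(m[i, comp] != m[j, comp])
    }
  }
  list(diff = diffm, valid = valid)
}

#' Mitochondrial diversity: haplotype count, haplotype and nucleotide diversity
#'
#' Haplotype (gene) diversity uses Nei's unbiased estimator
#' \eqn{Hd = n(1 - \sum p_i^2)/(n - 1)} over haplotype frequencies.
#' Nucleotide diversity \eqn{\pi} is the mean pairwise proportion of
#' differing sites, with pairwise deletion of gaps and `N`s.
#'
#' @param aln a [seq_alignment()] holding the sequences of one population.
#' @param scope `"full"` or a partition name.
#' @return list with `Hap` (number of haplotypes), `Hd`, `Pi`, and `n`.
#' @export
mtdna_diversity <- function(aln, scope = "full") {
  stopifnot(inherits(aln, "seq_alignment"))
  n <- length(aln$ids)
  if (n < 2L) stop("need at least 2 sequences for diversity")
  haps <- collapse_haplotypes(aln, scope)
  p <- haps$count / n
  hd <- n * (1 - sum(p^2)) / (n - 1)
  m <- slice_partition(aln, scope)
  pw <- pairwise_site_diffs(m)
  ut <- upper.tri(pw$diff)
  prop <- ifelse(pw$valid[ut] > 0, pw$diff[ut] / pw$valid[ut], NA_real_)
  pi <- mean(prop, na.rm = TRUE)
  list(Hap = nrow(haps), Hd = hd, Pi = pi, n = n)
}

#' Between-population sequence divergence and differentiation
#'
#' Computes Dxy (mean between-population pairwise difference per site,
#' pairwise deletion) and Hudson's \eqn{F_{ST} = 1 - \bar\pi_w/\pi_b}
#' where \eqn{\bar\pi_w} is the simple mean of the two within-population
#' nucleotide diversities.
#'
#' @param aln a [seq_alignment()].
#' @param popmap a [pop_map()] covering all sequenced individuals.
#' @param scope `"full"` or a partition name.
#' @return list of two [pairwise_matrix()] objects, `dxy` and `fst`.
#'   Populations with fewer than 2 sequences are excluded with a warning.
#' @export
mtdna_divergence <- function(aln, popmap, scope = "full") {
  stopifnot(inherits(aln, "seq_alignment"))
  pops <- popmap_lookup(popmap, aln$ids)
  tab <- table(pops)
  keep <- names(tab)[tab >= 2L]
  if (length(keep) < length(tab)) {
    warning("excluding populations with <2 sequences: ",
            paste(setdiff(names(tab), keep), collapse = ", "))
  }
  if (length(keep) < 2L) stop("need >=2 populations with >=2 sequences")
  m <- slice_partition(aln, scope)
  pw <- pairwise_site_diffs(m)
  prop <- matrix(NA_real_, nrow(m), nrow(m))
  nz <- pw$valid > 0
  prop[nz] <- pw$diff[nz] / pw$valid[nz]
  k <- length(keep)
  dxy <- fst <- matrix(0, k, k, dimnames = list(keep, keep))
  piw <- vapply(keep, function(p) {
    idx <- which(pops == p)
    mean(prop[idx, idx][upper.tri(diag(length(idx)))], na.rm = TRUE)
  }, 0)
  for (a in seq_len(k - 1)) {
    for (b in seq.int(a + 1, k)) {
      ia <- which(pops == keep[a]); ib <- which(pops == keep[b])
      pib <- mean(prop[ia, ib], na.rm = TRUE)
      dxy[a, b] <- dxy[b, a] <- pib
      fst[a, b] <- fst[b, a] <-
        if (pib > 0) 1 - mean(c(piw[a], piw[b])) / pib else 0
    }
  }
  list(dxy = pairwise_matrix(dxy, "Dxy"),
       fst = pairwise_matrix(fst, "Hudson_FST"))
}
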