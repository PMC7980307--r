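#' Diploid microsatellite genotype matrix
#'
#' Stores allele-size calls as an integer array `individuals x loci x 2`.
#' Missing genotypes are `NA` at both slots; allele sizes must be positive
#' integers (`0` is reserved for missing in Genepop files and never stored
#' as data).
#'
#' @param calls integer array `n x L x 2`, or a list with that shape.
#' @param ids individual labels (length n).
#' @param loci locus labels (length L).
#' @return `genotype_matrix` object.
#' @export
genotype_matrix <- function(calls, ids, loci) {
  calls <- array(as.integer(calls), dim = dim(calls))
  if (length(dim(calls)) != 3L || dim(calls)[3] != 2L) {
    stop("calls must be an n x L x 2 integer array")
  }
  if (dim(calls)[1] != length(ids) || dim(calls)[2] != length(loci)) {
    stop("dimensions do not match ids/loci")
  }
  if (any(calls <= 0L, na.rm = TRUE)) stop("allele sizes must be positive integers")
  half <- is.na(calls[, , 1, drop = FALSE]) != is.na(calls[, , 2, drop = FALSE])
  if (any(half)) stop("half-missing genotype calls are not allowed")
  dimnames(calls) <- list(as.character(ids), as.character(loci), NULL)
  structure(list(calls = calls, ids = as.character(ids),
                 loci = as.character(loci)), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$calls[, , 1]))
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
              length(x$ids), length(x$loci), 100 * miss))
  invisible(x)
}

#' Subset a genotype matrix by individuals
#' @param gt a [genotype_matrix()].
#' @param who ids or index.
#' @export
gt_subset <- function(gt, who) {
  stopifnot(inherits(gt, "genotype_matrix"))
  if (is.character(who)) {
    idx <- match(who, gt$ids)
    if (anyNA(idx)) stop("unknown ids")
  } else idx <- seq_along(gt$ids)[who]
  genotype_matrix(gt$calls[idx, , , drop = FALSE], gt$ids[idx], gt$loci)
}

#' Individual-to-population map
#'
#' @param individual character vector of individual labels.
#' @param population character vector of population labels, same length.
#' @return named character vector (`pop_map`), names are individuals.
#' @export
pop_map <- function(individual, population) {
  if (length(individual) != length(population)) stop("length mismatch")
  if (anyDuplicated(individual)) stop("duplicate individuals in popmap")
  structure(stats::setNames(as.character(population), as.character(individual)),
            class = "pop_map")
}

popmap_lookup <- function(popmap, ids) {
  pops <- unname(popmap[ids])
  if (anyNA(pops)) {
    stop("individuals missing from popmap: ",
         paste(ids[is.na(pops)], collapse = ", "))
  }
  pops
}

#' Read / write a popmap CSV (`individual,population`)
#' @param path file path.
#' @export
read_popmap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("individual", "population") %in% names(df))) {
    stop("popmap CSV must have columns individual,population")
  }
  pop_map(df$individual, df$population)
}

#' @rdname read_popmap
#' @param popmap a [pop_map()].
#' @export
write_popmap <- function(popmap, path) {
  utils::write.csv(data.frame(individual = names(popmap),
                              population = unname(unclass(popmap))),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Symmetric pairwise matrix with a named statistic
#'
#' @param m symmetric numeric matrix with dimnames (population labels).
#' @param statistic name of the distance/statistic stored.
#' @return `pairwise_matrix` object (a matrix with attributes).
#' @export
pairwise_matrix <- function(m, statistic) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("not square")
  if (is.null(rownames(m))) stop("pairwise_matrix needs labelled rows")
  fin <- is.finite(m)
  if (any(abs(m[fin] - t(m)[t(fin) & fin]) > 1e-8, na.rm = TRUE)) {
    stop("matrix not symmetric")
  }
  structure(m, statistic = statistic, class = c("pairwise_matrix", "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("pairwise_matrix [", attr(x, "statistic"), "]\n", sep = "")
  print(unclass(x)[,])
  invisible(x)
}

#' Lower-triangle vectorization of a pairwise matrix
#' @param m a [pairwise_matrix()] or plain symmetric matrix.
#' @return numeric vector, pairs in column-major lower-triangle order.
#' @export
lower_vec <- function(m) {
  m <- as.matrix(m)
  m[lower.tri(m)]
}

#' Read / write square matrix CSV with the statistic name in a comment header
#'
#' The first line is `# statistic: <name>`; then a square CSV with row and
#' column labels.
#' @param path file path.
#' @export
read_matrix_csv <- function(path) {
  first <- readLines(path, n = 1L)
  stat <- sub("^#\\s*statistic:\\s*", "", first)
  df <- utils::read.csv(path, skip = 1L, row.names = 1L, check.names = FALSE)
  pairwise_matrix(as.matrix(df), stat)
}

#' @rdname read_matrix_csv
#' @param m a [pairwise_matrix()].
#' @export
write_matrix_csv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# statistic: ", attr(m, "statistic")), con)
  utils::write.csv(as.data.frame(unclass(m)[,]), con, quote = FALSE)
  invisible(path)
}

#' Read a Genepop file (4-digit allele codes)
#'
#' Parses the widely used Genepop dialect: a title line, locus names (one
#' per line or comma-separated), `POP` blocks, and per-individual lines
#' `id ,  060006200802...` with 4-digit codes per allele (`0000` = missing).
#'
#' @param path file path.
#' @return list with `gt` (a [genotype_matrix()]) and `popmap`
#'   (a [pop_map()]); population labels are `pop1..popK` unless every
#'   individual id carries a `pop_` prefix.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a genepop file: too short")
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[-1L]
  popidx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(popidx) == 0L) stop("no POP blocks found")
  locus_lines <- body[seq_len(popidx[1] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  nloc <- length(loci)
  ids <- character(0); pops <- character(0)
  rows <- list()
  popno <- 0L
  i <- popidx[1]
  while (i <= length(body)) {
    if (grepl("^\\s*pop\\s*$", body[i], ignore.case = TRUE)) {
      popno <- popno + 1L
      i <- i + 1L
      next
    }
    ln <- body[i]
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L) stop("malformed genepop line ", i + 1L, ": ", ln)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(codes) != nloc) {
      stop("line ", i + 1L, ": expected ", nloc, " loci, got ", length(codes))
    }
    if (any(nchar(codes) != 8L)) {
      stop("line ", i + 1L, ": allele codes must be 8 digits (4 per allele)")
    }
    a1 <- as.integer(substr(codes, 1L, 4L))
    a2 <- as.integer(substr(codes, 5L, 8L))
    a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    ids <- c(ids, id); pops <- c(pops, paste0("pop", popno))
    rows[[length(rows) + 1L]] <- cbind(a1, a2)
    i <- i + 1L
  }
  n <- length(ids)
  calls <- array(NA_integer_, c(n, nloc, 2L))
  for (k in seq_len(n)) {
    calls[k, , 1] <- rows[[k]][, 1]
    calls[k, , 2] <- rows[[k]][, 2]
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  list(gt = genotype_matrix(calls, ids, loci), popmap = pop_map(ids, pops))
}

#' Write a Genepop file (4-digit allele codes)
#' @param gt a [genotype_matrix()].
#' @param popmap a [pop_map()]; individuals are written in population blocks.
#' @param path output file path.
#' @param title first line of the file.
#' @export
write_genepop <- function(gt, popmap, path, title = "skyisland genepop export") {
  pops <- popmap_lookup(popmap, gt$ids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(gt$loci, con)
  for (p in unique(pops)) {
    writeLines("POP", con)
    for (i in which(pops == p)) {
      a1 <- gt$calls[i, , 1]; a2 <- gt$calls[i, , 2]
      a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
      codes <- sprintf("%04d%04d", a1, a2)
      writeLines(paste0(gt$ids[i], " ,  ", paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read / write FASTA alignments
#'
#' Thin wrappers around `seqinr` with 60-column wrapping on output.
#' @param path file path.
#' @param partitions optional named partition list forwarded to
#'   [seq_alignment()].
#' @export
read_fasta <- function(path, partitions = list()) {
  sq <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  seq_alignment(names(sq), toupper(vapply(sq, `[`, "", 1L)), partitions)
}

#' @rdname read_fasta
#' @param aln a [seq_alignment()].
#' @export
write_fasta <- function(aln, path) {
  seqs <- lapply(seq_along(aln$ids), function(i) aln$mat[i, ])
  seqinr::write.fasta(seqs, names = aln$ids, file.out = path, nbchar = 60)
  invisible(path)
}
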