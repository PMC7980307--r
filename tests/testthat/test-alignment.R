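test_that("alignment construction enforces equal lengths and partitions", {
  expect_error(seq_alignment(c("a", "b"), c("ACGT", "ACG")), "aligned")
  expect_error(seq_alignment("a", "ACGT", list(p1 = c(1, 5))), "out of bounds")
  expect_error(seq_alignment("a", "ACGTAC",
                             list(p1 = c(1, 4), p2 = c(3, 6))), "overlap")
  aln <- seq_alignment(c("a", "b"), c("ACGTAC", "ACGTAA"),
                       list(p1 = c(1, 3), p2 = c(4, 6)))
  expect_identical(dim(aln$mat), c(2L, 6L))
})

test_that("identical sequences collapse to one haplotype; pairs to two", {
  aln <- aln_fixture(rep("ACGTACGT", 5))
  h <- collapse_haplotypes(aln)
  expect_equal(nrow(h), 1L)
  expect_equal(h$count, 5L)

  aln2 <- aln_fixture(c("ACGTACGT", "ACGTACGA", "ACGTACGT", "ACGTACGA"))
  h2 <- collapse_haplotypes(aln2)
  expect_equal(nrow(h2), 2L)
  expect_equal(sort(h2$count), c(2L, 2L))
  expect_equal(sum(h2$count), 4L)
})

test_that("haplotype collapsing honours the ambiguity policy", {
  # N mismatches a called base by default, merges under ambiguous_merge
  aln <- aln_fixture(c("ACGT", "ACGN"))
  expect_equal(nrow(collapse_haplotypes(aln)), 2L)
  expect_equal(nrow(collapse_haplotypes(aln, ambiguous_merge = TRUE)), 1L)
})

test_that("haplotype collapsing respects partition scope", {
  aln <- aln_fixture(c("AAATTT", "AAATTA", "AAATTT"),
                     partitions = list(left = c(1, 3), right = c(4, 6)))
  expect_equal(nrow(collapse_haplotypes(aln, "left")), 1L)
  expect_equal(nrow(collapse_haplotypes(aln, "right")), 2L)
  expect_equal(nrow(collapse_haplotypes(aln, "full")), 2L)
})

test_that("haplotype and nucleotide diversity match closed forms", {
  # all identical -> zero diversity
  aln0 <- aln_fixture(rep("ACGTACGTAC", 4))
  d0 <- mtdna_diversity(aln0)
  expect_equal(d0$Hd, 0)
  expect_equal(d0$Pi, 0)

  # 3 sequences length 10: s1 = s2, s3 differs at 2 sites
  s <- "AAAAAAAAAA"
  s3 <- "AACCAAAAAA"
  d <- mtdna_diversity(aln_fixture(c(s, s, s3)))
  expect_equal(d$Pi, (0 + 2 + 2) / (3 * 10), tolerance = 1e-12)
  # Hd for counts (2,1): 3/2 * (1 - (4+1)/9) = 2/3
  expect_equal(d$Hd, 3 / 2 * (1 - 5 / 9), tolerance = 1e-12)

  expect_error(mtdna_diversity(aln_fixture("ACGT")), "at least 2")
})

test_that("Pi uses pairwise deletion of gaps and Ns", {
  # pair differs at 1 of 8 mutually called sites; 2 sites masked in one seq
  a <- "ACGTACGTAC"
  b <- "ACGTACGTNN"
  cc <- "ACGAACGTAC"  # differs from a at site 4
  d <- mtdna_diversity(aln_fixture(c(a, b, cc)))
  # pairs: (a,b): 0/8; (a,c): 1/10; (b,c): 1/8
  expect_equal(d$Pi, mean(c(0 / 8, 1 / 10, 1 / 8)), tolerance = 1e-12)
})

test_that("divergence matches exhaustive enumeration on a 2+2 case", {
  # pop A: a1, a2 differ at 1 site; pop B: b1, b2 differ at 1 site;
  # cross differences counted by hand over L = 10
  a1 <- "AAAAAAAAAA"
  a2 <- "CAAAAAAAAA"          # 1 diff vs a1
  b1 <- "AAAAATTTTT"          # 5 diffs vs a1, 6 vs a2
  b2 <- "AAAAATTTTA"          # 4 vs a1, 5 vs a2, 1 vs b1
  aln <- aln_fixture(c(a1, a2, b1, b2), ids = c("a1", "a2", "b1", "b2"))
  pm <- pop_map(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  dv <- mtdna_divergence(aln, pm)
  dxy_hand <- mean(c(5, 6, 4, 5)) / 10
  expect_equal(unname(dv$dxy["A", "B"]), dxy_hand, tolerance = 1e-12)
  piA <- 1 / 10; piB <- 1 / 10
  expect_equal(unname(dv$fst["A", "B"]),
               1 - mean(c(piA, piB)) / dxy_hand, tolerance = 1e-12)
})

test_that("fixed differences give Fst 1; identical pools give Fst ~ 0", {
  aln <- aln_fixture(c("AAAA", "AAAA", "TTAA", "TTAA"),
                     ids = c("a1", "a2", "b1", "b2"))
  pm <- pop_map(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  dv <- mtdna_divergence(aln, pm)
  expect_equal(unname(dv$fst["A", "B"]), 1)
  expect_equal(unname(dv$dxy["A", "B"]), 2 / 4)

  # identical haplotype pools: Fst concentrates near zero (moderate n)
  set.seed(14)
  pool <- c("AAAA", "ATAA")
  seqs <- sample(pool, 20, replace = TRUE)
  ids <- sprintf("x%02d", 1:20)
  aln2 <- aln_fixture(seqs, ids = ids)
  pm2 <- pop_map(ids, rep(c("A", "B"), each = 10))
  dv2 <- mtdna_divergence(aln2, pm2)
  expect_lt(abs(dv2$fst["A", "B"]), 0.25)
})

test_that("FASTA round-trips through 60-column files", {
  set.seed(9)
  seqs <- vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = ""), "")
  aln <- aln_fixture(seqs, ids = c("ind_a", "ind_b", "ind_c"))
  path <- tempfile(fileext = ".fasta")
  write_fasta(aln, path)
  lines <- readLines(path)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_fasta(path)
  expect_identical(back$ids, aln$ids)
  expect_identical(back$mat, aln$mat)
})
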