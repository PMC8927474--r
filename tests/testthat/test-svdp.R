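# The SV-aware dynamic program and candidate de-duplication.

test_that("a perfectly stitched query recovers the jump and full score", {
  ra <- "ACGTGCAT"; rb <- "TTAGCAGG"
  qwin <- paste0(substr(ra, 3, 8), substr(rb, 1, 5)) # "GTGCATTTAGC"
  r <- svdp_align(list(qwin = qwin, ra = ra, rb = rb))
  expect_equal(r$score_with_jump, 22) # 11 matches x 2
  expect_equal(r$qprime, 6)
  expect_equal(r$a, 8)
  expect_equal(r$b, 0)
  expect_true(r$used_jump)
})

test_that("queries explained by one piece alone do not use the jump", {
  set.seed(1)
  ra <- rand_seq(40)
  r <- svdp_align(list(qwin = ra, ra = ra, rb = rand_seq(20)))
  expect_equal(r$score_without_jump, 2 * nchar(ra))
  expect_equal(r$score_with_jump, r$score_without_jump)
  expect_false(r$used_jump)

  r1 <- svdp_align(list(qwin = "G", ra = "G", rb = "T"))
  expect_equal(r1$score_with_jump, 2)
  expect_equal(r1$qprime, 1)
  expect_error(svdp_align(list(qwin = "", ra = "A", rb = "A")))
})

test_that("svdp matches exhaustive brute force on random small instances", {
  set.seed(99)
  for (case in 1:60) {
    q <- rand_seq(sample(1:12, 1))
    ra <- rand_seq(sample(1:8, 1))
    rb <- rand_seq(sample(1:8, 1))
    got <- svdp_align(list(qwin = q, ra = ra, rb = rb))
    want <- svdp_brute(q, ra, rb)
    expect_equal(got$score_with_jump, want$score_with_jump,
                 info = paste(q, ra, rb))
    expect_equal(got$score_without_jump, want$score_without_jump,
                 info = paste(q, ra, rb))
  }
})

test_that("the free jump never hurts and tie-breaks are deterministic", {
  set.seed(5)
  for (case in 1:40) {
    inp <- list(qwin = rand_seq(sample(2:30, 1)), ra = rand_seq(sample(2:20, 1)),
                rb = rand_seq(sample(2:20, 1)))
    r <- svdp_align(inp)
    expect_gte(r$score_with_jump, r$score_without_jump)
    r2 <- svdp_align(inp)
    expect_identical(r[c("qprime", "a", "b")], r2[c("qprime", "a", "b")])
  }
})

test_that("prefix translation shifts the split point, not the score structure", {
  set.seed(8)
  ra <- rand_seq(30); rb <- rand_seq(30)
  qwin <- paste0(substr(ra, 11, 30), substr(rb, 1, 15))
  base <- svdp_align(list(qwin = qwin, ra = ra, rb = rb))
  pre <- rand_seq(6)
  shifted <- svdp_align(list(qwin = paste0(pre, qwin),
                             ra = paste0(pre, substr(ra, 11, 30)), rb = rb))
  expect_equal(shifted$qprime, base$qprime + 6)
  expect_equal(shifted$score_with_jump, base$score_with_jump + 2 * 6)
})

test_that("windows map piece offsets back to genome coordinates on both strands", {
  set.seed(21)
  genome <- Biostrings::DNAStringSet(c(chr1 = rand_seq(60000),
                                       chr2 = rand_seq(40000)))
  cand <- tibble::tibble(svtype = "DEL", chrom1 = "chr1", pos1 = 20000L,
                         chrom2 = "chr1", pos2 = 40000L, q = 3000L,
                         s = 20000L, e = 40000L, strand1 = "+", strand2 = "+",
                         jchrom1 = "chr1", jchrom2 = "chr1")
  read <- paste0(svlite:::seq_window(genome, "chr1", 17000, 20000),
                 svlite:::seq_window(genome, "chr1", 40000, 43000))
  win <- make_windows(cand, read, genome, w = 2000L, W = 10000L)
  expect_equal(nchar(win$ra), 12000L)
  expect_equal(nchar(win$rb), 12000L)
  expect_equal(nchar(win$qwin), 4000L)
  expect_equal(win$map_a(2000L), 20000L) # junction exit at s
  expect_equal(win$map_b(10000L), 40000L) # junction entry at e
  # inversion: second piece reverse-complemented, map runs backwards
  icand <- dplyr::mutate(cand, svtype = "INV", strand2 = "-", e = 40000L)
  iwin <- make_windows(icand, read, genome, w = 2000L, W = 10000L)
  # minus-strand piece: the junction entry sits W into the piece and the
  # map runs from the window top downwards
  expect_equal(iwin$map_b(10000L), 40000L)
  expect_equal(substr(iwin$rb, 1, 10),
               substr(svlite:::revcomp(
                 svlite:::seq_window(genome, "chr1", 38000, 50000)), 1, 10))
  # window entirely outside the contig is degenerate
  bad <- dplyr::mutate(cand, q = 100000L)
  expect_error(make_windows(bad, read, genome), "degenerate")
})

test_that("refinement recovers exact breakpoints from an error-free split read", {
  set.seed(31)
  genome <- Biostrings::DNAStringSet(c(chr1 = rand_seq(150000)))
  p1 <- 50000L; p2 <- 110000L
  read <- paste0(svlite:::seq_window(genome, "chr1", p1 - 3000, p1),
                 svlite:::seq_window(genome, "chr1", p2, p2 + 3000))
  cand <- tibble::tibble(svtype = "DEL", chrom1 = "chr1", pos1 = p1,
                         chrom2 = "chr1", pos2 = p2, orientation = "+-",
                         source = "split", read_ids = list("r"),
                         refined = FALSE, zygosity = NA_character_,
                         score = NA_real_, q = 3000L, s = p1, e = p2,
                         strand1 = "+", strand2 = "+", jchrom1 = "chr1",
                         jchrom2 = "chr1")
  ref <- refine_candidate(cand, read, genome)
  # junction microhomology allows a left-shift of both breakpoints; the
  # event size is exact and positions stay within the homology tract
  expect_equal(ref$pos2 - ref$pos1, p2 - p1)
  expect_lte(abs(ref$pos1 - p1), 4L)
  expect_true(ref$refined)
  # a read of pure noise is rejected by the score threshold
  expect_null(refine_candidate(cand, rand_seq(6000), genome))
  # no supporting read -> rejected
  expect_null(refine_candidate(cand, NULL, genome))
})

test_that("refinement tolerates breakpoint offsets up to the window sizes", {
  set.seed(32)
  genome <- Biostrings::DNAStringSet(c(chr1 = rand_seq(150000)))
  p1 <- 50000L; p2 <- 110000L
  read <- paste0(svlite:::seq_window(genome, "chr1", p1 - 3000, p1),
                 svlite:::seq_window(genome, "chr1", p2, p2 + 3000))
  base0 <- tibble::tibble(svtype = "DEL", chrom1 = "chr1", pos1 = p1,
                          chrom2 = "chr1", pos2 = p2, orientation = "+-",
                          source = "split", read_ids = list("r"),
                          refined = FALSE, zygosity = NA_character_,
                          score = NA_real_, q = 3000L, s = p1, e = p2,
                          strand1 = "+", strand2 = "+", jchrom1 = "chr1",
                          jchrom2 = "chr1")
  base <- refine_candidate(base0, read, genome)
  # the stitched windows extend W beyond the junction and w behind it,
  # so the prefix-side breakpoint tolerates offsets in [-W, +w] and the
  # suffix side in [-w, +W]
  cases <- list(c(-8000L, 8000L, 0L), c(-4000L, 500L, -1500L),
                c(200L, -200L, 0L), c(-9500L, 9500L, 1500L))
  for (cs in cases) {
    cand <- tibble::tibble(svtype = "DEL", chrom1 = "chr1", pos1 = p1,
                           chrom2 = "chr1", pos2 = p2, orientation = "+-",
                           source = "split", read_ids = list("r"),
                           refined = FALSE, zygosity = NA_character_,
                           score = NA_real_, q = 3000L + cs[3],
                           s = p1 + cs[1], e = p2 + cs[2], strand1 = "+",
                           strand2 = "+", jchrom1 = "chr1", jchrom2 = "chr1")
    ref <- refine_candidate(cand, read, genome)
    expect_equal(c(ref$pos1, ref$pos2), c(base$pos1, base$pos2),
                 info = paste(cs, collapse = ","))
  }
})

test_that("deduplication merges same-type candidates within tolerance", {
  base <- tibble::tibble(
    svtype = c("DEL", "DEL", "DUP"), chrom1 = "chr1",
    pos1 = c(18000L, 18010L, 18000L), chrom2 = "chr1",
    pos2 = c(118000L, 118005L, 118000L), orientation = "+-",
    source = "split", read_ids = list("r1", "r2", "r3"), refined = TRUE,
    zygosity = NA_character_, score = c(10, 20, 5), q = 0L, s = 0L, e = 0L,
    strand1 = "+", strand2 = "+", jchrom1 = "chr1", jchrom2 = "chr1")
  out <- deduplicate(base, tol = 1000L)
  expect_equal(nrow(out), 2L) # DEL pair merged, DUP kept separately
  del <- out[out$svtype == "DEL", ]
  expect_equal(del$support, 2L)
  expect_equal(del$pos1, 18010L) # highest-scoring member's breakpoints
  expect_setequal(del$read_ids[[1]], c("r1", "r2"))
  expect_equal(nrow(deduplicate(base[0, ])), 0L)
  # output sorted by position
  expect_true(all(diff(out$pos1) >= 0))
})
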