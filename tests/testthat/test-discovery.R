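# Split-read typing, gap candidates, seed anchors and supporting-read
# search.

seg_tbl <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(read_id = r[["read_id"]], q_start = as.integer(r[["q_start"]]),
                   q_end = as.integer(r[["q_end"]]), chrom = r[["chrom"]],
                   r_start = as.integer(r[["r_start"]]),
                   r_end = as.integer(r[["r_end"]]), strand = r[["strand"]],
                   mapq = 60L, is_supplementary = FALSE,
                   n_match = as.integer(r[["q_end"]]) - as.integer(r[["q_start"]]),
                   cigar = r[["cigar"]] %||% NA_character_)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("split-read geometry types deletions, duplications, inversions and breakends", {
  # prefix chr1:[10000,18000)+, suffix chr1:[118000,126000)+ -> DEL
  del <- extract_split_candidates(seg_tbl(
    list(read_id = "r", q_start = 0, q_end = 8000, chrom = "chr1",
         r_start = 10000, r_end = 18000, strand = "+"),
    list(read_id = "r", q_start = 8000, q_end = 16000, chrom = "chr1",
         r_start = 118000, r_end = 126000, strand = "+")))
  expect_equal(del$svtype, "DEL")
  expect_equal(c(del$pos1, del$pos2), c(18000L, 118000L))
  expect_equal(del$pos2 - del$pos1, 100000L)

  # strand flip -> INV
  inv <- extract_split_candidates(seg_tbl(
    list(read_id = "r", q_start = 0, q_end = 5000, chrom = "chr1",
         r_start = 10000, r_end = 15000, strand = "+"),
    list(read_id = "r", q_start = 5000, q_end = 10000, chrom = "chr1",
         r_start = 55000, r_end = 60000, strand = "-")))
  expect_equal(inv$svtype, "INV")
  expect_equal(c(inv$pos1, inv$pos2), c(15000L, 60000L))

  # cross-chromosome -> BND
  bnd <- extract_split_candidates(seg_tbl(
    list(read_id = "r", q_start = 0, q_end = 5000, chrom = "chr1",
         r_start = 10000, r_end = 15000, strand = "+"),
    list(read_id = "r", q_start = 5000, q_end = 10000, chrom = "chr5",
         r_start = 70000, r_end = 75000, strand = "+")))
  expect_equal(bnd$svtype, "BND")
  expect_equal(bnd$orientation, "+-")

  # reference-backward jump -> DUP
  dup <- extract_split_candidates(seg_tbl(
    list(read_id = "r", q_start = 0, q_end = 5000, chrom = "chr1",
         r_start = 45000, r_end = 50000, strand = "+"),
    list(read_id = "r", q_start = 5000, q_end = 10000, chrom = "chr1",
         r_start = 20000, r_end = 25000, strand = "+")))
  expect_equal(dup$svtype, "DUP")
  expect_equal(c(dup$pos1, dup$pos2), c(20000L, 50000L))
})

test_that("typing is involution-safe under read reversal", {
  fwd <- seg_tbl(
    list(read_id = "r", q_start = 0, q_end = 8000, chrom = "chr1",
         r_start = 10000, r_end = 18000, strand = "+"),
    list(read_id = "r", q_start = 8000, q_end = 16000, chrom = "chr1",
         r_start = 118000, r_end = 126000, strand = "+"))
  # the same molecule sequenced from the other strand: segment order and
  # strands flip, read coordinates mirror
  rev <- seg_tbl(
    list(read_id = "r", q_start = 0, q_end = 8000, chrom = "chr1",
         r_start = 118000, r_end = 126000, strand = "-"),
    list(read_id = "r", q_start = 8000, q_end = 16000, chrom = "chr1",
         r_start = 10000, r_end = 18000, strand = "-"))
  c1 <- extract_split_candidates(fwd)
  c2 <- extract_split_candidates(rev)
  expect_equal(c1$svtype, c2$svtype)
  expect_equal(c(c1$pos1, c1$pos2), c(c2$pos1, c2$pos2))

  # cross-chromosome pair canonicalizes identically from both strands
  bf <- extract_split_candidates(seg_tbl(
    list(read_id = "r", q_start = 0, q_end = 5000, chrom = "chr2",
         r_start = 10000, r_end = 15000, strand = "+"),
    list(read_id = "r", q_start = 5000, q_end = 10000, chrom = "chr1",
         r_start = 70000, r_end = 75000, strand = "+")))
  br <- extract_split_candidates(seg_tbl(
    list(read_id = "r", q_start = 0, q_end = 5000, chrom = "chr1",
         r_start = 70000, r_end = 75000, strand = "-"),
    list(read_id = "r", q_start = 5000, q_end = 10000, chrom = "chr2",
         r_start = 10000, r_end = 15000, strand = "-")))
  expect_equal(bf[c("chrom1", "pos1", "chrom2", "pos2", "orientation")],
               br[c("chrom1", "pos1", "chrom2", "pos2", "orientation")])
})

test_that("large unexplained read gaps (chimeras) are not paired", {
  chim <- extract_split_candidates(seg_tbl(
    list(read_id = "r", q_start = 0, q_end = 5000, chrom = "chr1",
         r_start = 10000, r_end = 15000, strand = "+"),
    list(read_id = "r", q_start = 6000, q_end = 11000, chrom = "chr1",
         r_start = 118000, r_end = 123000, strand = "+")))
  expect_equal(nrow(chim), 0L)
  # jumps below min_sv_len are not candidates either
  small <- extract_split_candidates(seg_tbl(
    list(read_id = "r", q_start = 0, q_end = 5000, chrom = "chr1",
         r_start = 10000, r_end = 15000, strand = "+"),
    list(read_id = "r", q_start = 5000, q_end = 10000, chrom = "chr1",
         r_start = 15500, r_end = 20500, strand = "+")))
  expect_equal(nrow(small), 0L)
})

test_that("long CIGAR deletion gaps become DEL candidates", {
  seg <- seg_tbl(list(read_id = "r", q_start = 0, q_end = 10000,
                      chrom = "chr1", r_start = 10000, r_end = 22000,
                      strand = "+", cigar = "5000M2000D5000M"))
  g <- extract_gap_candidates(seg)
  expect_equal(g$svtype, "DEL")
  expect_equal(c(g$pos1, g$pos2), c(15000L, 17000L))
  # below threshold -> nothing
  seg2 <- seg_tbl(list(read_id = "r", q_start = 0, q_end = 4000,
                       chrom = "chr1", r_start = 0, r_end = 4500,
                       strand = "+", cigar = "2000M500D2000M"))
  expect_equal(nrow(extract_gap_candidates(seg2)), 0L)
  # no D operations -> nothing
  seg3 <- seg_tbl(list(read_id = "r", q_start = 0, q_end = 4000,
                       chrom = "chr1", r_start = 0, r_end = 4000,
                       strand = "+", cigar = "4000M"))
  expect_equal(nrow(extract_gap_candidates(seg3)), 0L)
})

test_that("seed anchors find unique matches on both strands and mask repeats", {
  set.seed(3)
  ref <- rand_seq(600)
  read <- substr(ref, 201, 300)
  a <- seed_anchors(read, ref)
  expect_equal(nrow(a), 1L)
  expect_equal(c(a$q_start, a$q_end, a$r_start, a$r_end),
               c(0L, 100L, 200L, 300L))
  expect_gte(a$q_end - a$q_start, 100 - 15 + 1)
  # reverse-complemented read: minus strand, same reference interval
  ar <- seed_anchors(svlite:::revcomp(read), ref)
  expect_equal(ar$strand, "-")
  expect_equal(c(ar$r_start, ar$r_end), c(200L, 300L))
  expect_equal(ar$q_end - ar$q_start, ar$r_end - ar$r_start)
  # homopolymer read against homopolymer reference: repeat-masked
  expect_equal(nrow(seed_anchors(strrep("A", 60), strrep("A", 500))), 0L)
})

test_that("supporting reads need junction-consistent anchors near both breakpoints", {
  region <- tibble::tibble(chrom = "chr1", start = 100000L, end = 200000L)
  anchors <- seg_tbl(
    list(read_id = "good", q_start = 0, q_end = 4000, chrom = "chr1",
         r_start = 95000, r_end = 99000, strand = "+"),
    list(read_id = "good", q_start = 4000, q_end = 8000, chrom = "chr1",
         r_start = 201000, r_end = 205000, strand = "+"))
  sup <- find_supporting_read(region, anchors, slack = 10000L)
  expect_equal(sup$read_id, "good")
  expect_equal(sup$s, 99000L)
  expect_equal(sup$e, 201000L)

  # anchors near only one breakpoint -> none
  one_side <- anchors[1, ]
  expect_null(find_supporting_read(region, one_side, slack = 10000L))

  # two qualifying reads: larger summed anchor length wins
  anchors2 <- dplyr::bind_rows(anchors, seg_tbl(
    list(read_id = "better", q_start = 0, q_end = 6000, chrom = "chr1",
         r_start = 93000, r_end = 99000, strand = "+"),
    list(read_id = "better", q_start = 6000, q_end = 12000, chrom = "chr1",
         r_start = 201000, r_end = 207000, strand = "+")))
  expect_equal(find_supporting_read(region, anchors2, slack = 10000L)$read_id,
               "better")
})
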