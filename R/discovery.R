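# SV candidate discovery from split-read alignments and long alignment
# gaps, plus k-mer seed anchors used to link depth candidates to
# supporting reads.
#
# Junction geometry bookkeeping: for a pair of read-adjacent segments the
# read *leaves* the first segment at its reference end (plus strand) or
# start (minus strand), and *enters* the second segment at its reference
# start (plus) or end (minus). Candidates store the raw junction
# coordinates (q, s, e) plus segment strands so the refiner can rebuild
# the window geometry for reads from either strand.

seg_out_pos <- function(seg) if (seg$strand == "+") seg$r_end else seg$r_start
seg_in_pos <- function(seg) if (seg$strand == "+") seg$r_start else seg$r_end

# junction side labels: which part of the contig is retained at each
# breakend ("+" = sequence left of the position, "-" = right of it)
side_out <- function(strand) if (strand == "+") "+" else "-"
side_in <- function(strand) if (strand == "+") "-" else "+"

new_candidate <- function(svtype, chrom1, pos1, chrom2, pos2, orientation,
                          source, read_id, q, s, e, strand1, strand2,
                          jchrom1 = chrom1, jchrom2 = chrom2,
                          zygosity = NA_character_) {
  tibble(svtype = svtype, chrom1 = chrom1, pos1 = as.integer(pos1),
         chrom2 = chrom2, pos2 = as.integer(pos2), orientation = orientation,
         source = source, read_ids = list(read_id), refined = FALSE,
         zygosity = zygosity, score = NA_real_, q = as.integer(q),
         s = as.integer(s), e = as.integer(e), strand1 = strand1,
         strand2 = strand2, jchrom1 = jchrom1, jchrom2 = jchrom2)
}

empty_candidates <- function() {
  new_candidate(character(0), character(0), integer(0), character(0),
                integer(0), character(0), character(0), list(), integer(0),
                integer(0), integer(0), character(0), character(0),
                character(0))[0, ]
}

#' Extract SV candidates from split-read alignments
#'
#' For each pair of segments adjacent along the forward read (unexplained
#' gap or overlap on the read at most `read_gap_tol`; larger gaps suggest
#' chimeric reads and are not paired), the reference-side geometry types
#' the junction: same contig and strand with a reference-forward jump of
#' at least `min_sv_len` is a deletion, a reference-backward jump a
#' tandem duplication, a strand flip an inversion, and different contigs
#' a breakend (BND) pair. Candidates are canonicalized so that
#' `(chrom1, pos1) <= (chrom2, pos2)`, making typing invariant under read
#' reversal.
#'
#' @param segments alignment tibble from [read_alignments()].
#' @param min_sv_len minimum SV size (bp).
#' @param read_gap_tol maximum gap/overlap between paired segments on the
#'   read.
#' @param min_mapq segments below this mapping quality are ignored.
#' @return Candidate tibble; `q`, `s`, `e`, `strand1`, `strand2` carry the
#'   junction geometry used to seed breakpoint refinement.
#' @export
extract_split_candidates <- function(segments, min_sv_len = 1000L,
                                     read_gap_tol = 200L, min_mapq = 1L) {
  out <- list()
  segments <- segments[segments$mapq >= min_mapq, , drop = FALSE]
  multi <- names(which(table(segments$read_id) >= 2))
  segments <- segments[segments$read_id %in% multi, , drop = FALSE]
  for (seg in split(segments, segments$read_id)) {
    rid <- seg$read_id[1]
    seg <- seg[order(seg$q_start), , drop = FALSE]
    for (i in seq_len(nrow(seg) - 1)) {
      s1 <- as.list(seg[i, ]); s2 <- as.list(seg[i + 1, ])
      if (abs(s2$q_start - s1$q_end) > read_gap_tol) next
      p1 <- seg_out_pos(s1); p2 <- seg_in_pos(s2)
      cand <- NULL
      if (s1$chrom == s2$chrom && s1$strand == s2$strand) {
        jump <- if (s1$strand == "+") p2 - p1 else p1 - p2
        if (jump >= min_sv_len) {
          cand <- list(svtype = "DEL", ori = "+-")
        } else if (-jump >= min_sv_len) {
          cand <- list(svtype = "DUP", ori = "-+")
        }
      } else if (s1$chrom == s2$chrom) {
        # strand flip: inversion; both junctions of an inversion map to
        # the same (pos1, pos2) pair, so they deduplicate together
        if (abs(p2 - p1) >= min_sv_len)
          cand <- list(svtype = "INV", ori = "++")
      } else {
        cand <- list(svtype = "BND",
                     ori = paste0(side_out(s1$strand), side_in(s2$strand)))
      }
      if (is.null(cand)) next
      lo <- min(p1, p2); hi <- max(p1, p2)
      c1 <- s1$chrom; c2 <- s2$chrom; b1 <- p1; b2 <- p2; ori <- cand$ori
      if (cand$svtype == "BND" &&
          (c2 < c1 || (c2 == c1 && b2 < b1))) {
        tmp <- c1; c1 <- c2; c2 <- tmp
        tmp <- b1; b1 <- b2; b2 <- tmp
        ori <- paste0(substr(ori, 2, 2), substr(ori, 1, 1))
      }
      if (cand$svtype != "BND") { c1 <- s1$chrom; c2 <- s2$chrom; b1 <- lo; b2 <- hi }
      out[[length(out) + 1]] <- new_candidate(
        cand$svtype, c1, b1, c2, b2, ori, "split", rid,
        q = s1$q_end, s = p1, e = p2, strand1 = s1$strand,
        strand2 = s2$strand, jchrom1 = s1$chrom, jchrom2 = s2$chrom)
    }
  }
  if (length(out) == 0) return(empty_candidates())
  bind_rows(out)
}

#' Extract deletion candidates from long CIGAR deletion gaps
#'
#' Each `D` (or `N`) operation of at least `min_sv_len` bp inside an
#' alignment becomes a deletion candidate; long insertions are out of
#' scope and ignored.
#'
#' @param segments alignment tibble from [read_alignments()] (needs
#'   `cigar`).
#' @param min_sv_len minimum deletion size (bp).
#' @return Candidate tibble.
#' @export
extract_gap_candidates <- function(segments, min_sv_len = 1000L) {
  out <- list()
  # cheap prefilter: a qualifying D/N operation has >= 4 digits at 1 kbp
  digits <- max(4L, nchar(as.character(min_sv_len)))
  maybe <- !is.na(segments$cigar) &
    grepl(paste0("[0-9]{", digits, ",}[DN]"), segments$cigar)
  segments <- segments[maybe, , drop = FALSE]
  for (i in seq_len(nrow(segments))) {
    seg <- as.list(segments[i, ])
    if (is.na(seg$cigar) || seg$cigar == "*") next
    ops <- GenomicAlignments::explodeCigarOps(seg$cigar)[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(seg$cigar)[[1]]
    if (!any(ops %in% c("D", "N") & lens >= min_sv_len)) next
    rpos <- seg$r_start
    qoff <- 0L
    for (j in seq_along(ops)) {
      if (ops[j] %in% c("D", "N")) {
        if (lens[j] >= min_sv_len) {
          # read offset of the junction on the forward read
          qj <- if (seg$strand == "+") seg$q_start + qoff else seg$q_end - qoff
          st <- seg$strand
          s <- if (st == "+") rpos else rpos + lens[j]
          e <- if (st == "+") rpos + lens[j] else rpos
          out[[length(out) + 1]] <- new_candidate(
            "DEL", seg$chrom, rpos, seg$chrom, rpos + lens[j], "+-",
            "gap", seg$read_id, q = qj, s = s, e = e, strand1 = st,
            strand2 = st)
        }
        rpos <- rpos + lens[j]
      } else if (ops[j] %in% c("M", "=", "X")) {
        rpos <- rpos + lens[j]
        qoff <- qoff + lens[j]
      } else if (ops[j] == "I") {
        qoff <- qoff + lens[j]
      }
    }
  }
  if (length(out) == 0) return(empty_candidates())
  bind_rows(out)
}

#' Exact k-mer anchors between a read and a reference
#'
#' Finds exact k-mer matches on both strands, discards reference k-mers
#' occurring more than `max_occ` times (repeat masking), and merges
#' adjacent co-linear matches into maximal anchors. Anchor read
#' coordinates are reported on the forward read for both strands, so
#' `q_end - q_start == r_end - r_start` always holds.
#'
#' @param read read sequence (character).
#' @param reference [Biostrings::DNAStringSet] or single character string.
#' @param k k-mer size (>= 11).
#' @param max_occ repeat-occurrence cutoff.
#' @return Tibble with `chrom`, `q_start`, `q_end`, `r_start`, `r_end`,
#'   `strand`.
#' @export
seed_anchors <- function(read, reference, k = 15L, max_occ = 50L) {
  stopifnot(k >= 11)
  if (is.character(reference)) reference <- Biostrings::DNAStringSet(c(ref = reference))
  out <- purrr::map_dfr(names(reference), function(cn) {
    df <- .scan_anchors_core(toupper(read), as.character(reference[[cn]]),
                             as.integer(k), as.integer(max_occ))
    if (nrow(df) == 0) return(NULL)
    mutate(as_tibble(df), chrom = cn, .before = 1)
  })
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), q_start = integer(), q_end = integer(),
                  r_start = integer(), r_end = integer(), strand = character()))
  }
  arrange(out, .data$chrom, .data$r_start)
}

#' Find a read supporting a depth candidate's rough breakpoints
#'
#' Searches for one read carrying an anchor ending within `slack` bp of
#' the rough start breakpoint and a distinct same-strand anchor starting
#' within `slack` bp of the rough end breakpoint, in a read order
#' consistent with a junction. Ties between qualifying reads are broken
#' by maximal total anchor length.
#'
#' @param region one depth-candidate row (`chrom`, `start`, `end`).
#' @param anchors anchor tibble with a `read_id` column; alignment
#'   segments from [read_alignments()] qualify directly.
#' @param slack search slack in bp around each rough breakpoint
#'   (defaults to the large refinement window).
#' @return A list `(read_id, q, s, e, strand1, strand2)` seeding
#'   refinement, or `NULL` if no read qualifies.
#' @export
find_supporting_read <- function(region, anchors, slack = 10000L) {
  a <- anchors[anchors$chrom == region$chrom, , drop = FALSE]
  if (nrow(a) == 0) return(NULL)
  out_pos <- ifelse(a$strand == "+", a$r_end, a$r_start)
  in_pos <- ifelse(a$strand == "+", a$r_start, a$r_end)
  near_start <- abs(a$r_end - region$start) <= slack
  near_end <- abs(a$r_start - region$end) <= slack
  best <- NULL
  for (rid in unique(a$read_id[near_start & ave_has(a$read_id, near_end)])) {
    ia <- which(a$read_id == rid & near_start)
    ib <- which(a$read_id == rid & near_end)
    if (length(ia) == 0 || length(ib) == 0) next
    hit <- NULL
    for (x in ia) for (y in ib) {
      if (x == y || a$strand[x] != a$strand[y]) next
      if (a$strand[x] == "+" && a$q_end[x] <= a$q_start[y] + 200L) {
        hit <- list(first = x, second = y)
      } else if (a$strand[x] == "-" && a$q_end[y] <= a$q_start[x] + 200L) {
        hit <- list(first = y, second = x)
      }
    }
    if (is.null(hit)) next
    tot <- sum(a$q_end[unique(c(ia, ib))] - a$q_start[unique(c(ia, ib))])
    if (is.null(best) || tot > best$tot) {
      f <- hit$first; s <- hit$second
      best <- list(read_id = rid, q = a$q_end[f], s = out_pos[f],
                   e = in_pos[s], strand1 = a$strand[f],
                   strand2 = a$strand[s], tot = tot)
    }
  }
  if (is.null(best)) return(NULL)
  best[c("read_id", "q", "s", "e", "strand1", "strand2")]
}

# reads having any TRUE flag among their rows
ave_has <- function(ids, flag) {
  hit <- unique(ids[flag])
  ids %in% hit
}
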