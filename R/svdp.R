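# SV-aware dynamic programming: align a read window against two stitched
# reference windows allowing at most one unpenalized jump, map the jump
# back to genome coordinates, and de-duplicate refined candidates.
#
# The window geometry follows the junction bookkeeping in discovery.R: a
# candidate carries (q, s, e, strand1, strand2) where q is the junction
# offset on the forward read, s the junction-exit reference coordinate on
# the prefix side and e the junction-entry coordinate on the suffix side.

#' Build the SV-DP input windows for a candidate
#'
#' Extracts the read window `Q[q-w .. q+w)` and the two reference pieces
#' `R[s-w .. s+W)` and `R[e-W .. e+w)` (mirrored and reverse-complemented
#' for minus-strand junction sides; inversions naturally get their second
#' piece from the opposite strand, breakends draw the pieces from
#' different contigs). All windows are clipped at sequence bounds and
#' carry invertible offset-to-genome maps.
#'
#' @param candidate one candidate row (needs `chrom1`, `chrom2`, `q`, `s`,
#'   `e`, `strand1`, `strand2`).
#' @param read read sequence (character, forward orientation).
#' @param genome reference [Biostrings::DNAStringSet].
#' @param w small window half-size (read side), default 2 kbp.
#' @param W large window size (reference side), default 10 kbp.
#' @return List with `qwin`, `ra`, `rb` (character sequences) and map
#'   parameters `map_a`, `map_b` (functions from piece offset to genome
#'   position).
#' @export
make_windows <- function(candidate, read, genome, w = 2000L, W = 10000L) {
  cd <- as.list(candidate)
  if (is.null(cd$jchrom1) || is.na(cd$jchrom1)) cd$jchrom1 <- cd$chrom1
  if (is.null(cd$jchrom2) || is.na(cd$jchrom2)) cd$jchrom2 <- cd$chrom2
  q0 <- max(0L, cd$q - w)
  qwin <- substr(read, q0 + 1L, min(nchar(read), cd$q + w))
  len1 <- contig_length(genome, cd$jchrom1)
  len2 <- contig_length(genome, cd$jchrom2)
  if (cd$strand1 == "+") {
    a_lo <- max(0L, cd$s - w); a_hi <- min(len1, cd$s + W)
    ra <- seq_window(genome, cd$jchrom1, a_lo, a_hi)
    map_a <- local({ lo <- a_lo; function(a) lo + a })
  } else {
    a_lo <- max(0L, cd$s - W); a_hi <- min(len1, cd$s + w)
    ra <- revcomp(seq_window(genome, cd$jchrom1, a_lo, a_hi))
    map_a <- local({ hi <- a_hi; function(a) hi - a })
  }
  if (cd$strand2 == "+") {
    b_lo <- max(0L, cd$e - W); b_hi <- min(len2, cd$e + w)
    rb <- seq_window(genome, cd$jchrom2, b_lo, b_hi)
    map_b <- local({ lo <- b_lo; function(b) lo + b })
  } else {
    b_lo <- max(0L, cd$e - w); b_hi <- min(len2, cd$e + W)
    rb <- revcomp(seq_window(genome, cd$jchrom2, b_lo, b_hi))
    map_b <- local({ hi <- b_hi; function(b) hi - b })
  }
  if (nchar(qwin) == 0 || nchar(ra) == 0 || nchar(rb) == 0)
    abort("degenerate window")
  list(qwin = qwin, ra = ra, rb = rb, map_a = map_a, map_b = map_b,
       q_offset = q0)
}

#' SV-aware alignment with one free jump
#'
#' Maximizes `F(q', a) + B(q', b) + jump_cost` over all read split points
#' `q'` and piece offsets `(a, b)`, where `F` is the best affine-gap
#' alignment score of the read-window prefix ending at RA offset `a`
#' (free start anywhere in RA) and `B` the best score of the suffix
#' starting at RB offset `b` (free end anywhere in RB). The best no-jump
#' score (the full window against either piece alone, semi-global) is
#' reported alongside. Ties are broken towards the smallest `q'`, then
#' the smallest `a`, then the smallest `b`. Time is
#' `O(|Qwin| (|RA| + |RB|))`.
#'
#' @param input window list from [make_windows()], or any list with
#'   `qwin`, `ra`, `rb`.
#' @param scoring an [sv_scoring()] scheme.
#' @return List: `score_with_jump`, `score_without_jump`, `qprime`, `a`,
#'   `b`, `used_jump` (strict score improvement over the no-jump path).
#' @export
#' @examples
#' svdp_align(list(qwin = "GTGCATTTAGC", ra = "ACGTGCAT", rb = "TTAGCAGG"))
svdp_align <- function(input, scoring = sv_scoring()) {
  if (nchar(input$qwin) == 0 || nchar(input$ra) == 0 || nchar(input$rb) == 0)
    abort("svdp_align: empty sequence")
  r <- .svdp_core(input$qwin, input$ra, input$rb, scoring$match,
                  scoring$mismatch, scoring$gap_open, scoring$gap_extend,
                  scoring$jump_cost)
  r$used_jump <- r$score_with_jump > r$score_without_jump
  r
}

#' Refine a candidate's breakpoints with SV-DP
#'
#' Builds the stitched windows around the candidate junction, runs
#' [svdp_align()], and accepts the refinement iff the jump was used and
#' the with-jump score reaches `tau * match * |Qwin|`. On acceptance the
#' breakpoints are replaced by the genome-mapped jump coordinates
#' (canonicalized so `pos1 <= pos2` for intra-contig events) and the
#' candidate is marked refined.
#'
#' @param candidate one candidate row.
#' @param read supporting read sequence, or `NULL` (rejected with reason
#'   `no_support`).
#' @param genome reference [Biostrings::DNAStringSet].
#' @param scoring an [sv_scoring()].
#' @param tau acceptance fraction of the maximum attainable score.
#' @param w,W window sizes passed to [make_windows()].
#' @return The refined candidate row, or `NULL` with attribute-free
#'   rejection (reasons are logged by the pipeline).
#' @export
refine_candidate <- function(candidate, read, genome, scoring = sv_scoring(),
                             tau = 0.6, w = 2000L, W = 10000L) {
  if (is.null(read)) return(NULL)
  win <- make_windows(candidate, read, genome, w, W)
  res <- svdp_align(win, scoring)
  if (!res$used_jump) return(NULL)
  if (res$score_with_jump < tau * scoring$match * nchar(win$qwin)) return(NULL)
  bp1 <- win$map_a(res$a)
  bp2 <- win$map_b(res$b)
  cand <- candidate
  if (cand$svtype %in% c("DEL", "DUP", "INV")) {
    cand$pos1 <- as.integer(min(bp1, bp2))
    cand$pos2 <- as.integer(max(bp1, bp2))
    if (cand$pos2 - cand$pos1 < 1L) return(NULL)
  } else if (!is.null(cand$jchrom1) && !is.na(cand$jchrom1) &&
             cand$jchrom1 != cand$chrom1) {
    # candidate was canonicalized; bp1 lives on the read-order first contig
    cand$pos1 <- as.integer(bp2)
    cand$pos2 <- as.integer(bp1)
  } else {
    cand$pos1 <- as.integer(bp1)
    cand$pos2 <- as.integer(bp2)
  }
  cand$refined <- TRUE
  cand$score <- res$score_with_jump
  cand
}

#' Merge duplicate refined candidates
#'
#' Candidates of identical type whose breakpoints both lie within `tol`
#' bp are merged; the merged candidate keeps the breakpoints of the
#' highest-scoring member and the union of supporting reads. Output is
#' sorted by `(chrom1, pos1)`.
#'
#' @param candidates refined candidate tibble.
#' @param tol breakpoint tolerance in bp.
#' @return Deduplicated candidate tibble with a `support` column.
#' @export
deduplicate <- function(candidates, tol = 1000L) {
  if (nrow(candidates) == 0) {
    return(mutate(candidates, support = integer(0)))
  }
  candidates <- arrange(candidates, .data$svtype, .data$chrom1, .data$chrom2,
                        .data$pos1, .data$pos2)
  assigned <- rep(NA_integer_, nrow(candidates))
  cluster <- 0L
  for (i in seq_len(nrow(candidates))) {
    if (!is.na(assigned[i])) next
    cluster <- cluster + 1L
    assigned[i] <- cluster
    for (j in seq_len(nrow(candidates))[-seq_len(i)]) {
      if (!is.na(assigned[j])) next
      if (candidates$svtype[j] != candidates$svtype[i]) next
      if (candidates$chrom1[j] != candidates$chrom1[i] ||
          candidates$chrom2[j] != candidates$chrom2[i]) next
      if (abs(candidates$pos1[j] - candidates$pos1[i]) <= tol &&
          abs(candidates$pos2[j] - candidates$pos2[i]) <= tol)
        assigned[j] <- cluster
    }
  }
  candidates$cluster <- assigned
  merged <- candidates |>
    group_by(.data$cluster) |>
    group_modify(function(g, key) {
      sc <- ifelse(is.na(g$score), -Inf, g$score)
      best <- which.max(sc)
      rep_row <- g[best, ]
      rep_row$read_ids <- list(unique(unlist(g$read_ids)))
      rep_row$support <- length(rep_row$read_ids[[1]])
      # depth evidence wins the zygosity hint if any member carries one
      zyg <- g$zygosity[!is.na(g$zygosity)]
      if (length(zyg) > 0) rep_row$zygosity <- zyg[1]
      if (any(g$source == "depth") && any(g$source != "depth"))
        rep_row$source <- "split+depth"
      rep_row
    }) |>
    ungroup() |>
    select(-"cluster")
  arrange(merged, .data$chrom1, .data$pos1)
}
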