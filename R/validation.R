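# Realignment-based validation: build an alternative reference carrying
# the conjectured SV, check that it attracts reads by a score margin over
# the unaltered reference, re-check supporting reads against the rest of
# the genome, and derive a phred-like QUAL from the score gains.

#' Build the alternative reference for a candidate
#'
#' Splices flanking reference sequence around the conjectured variant:
#' deletions join the two outer flanks, tandem duplications carry two
#' copies of the duplicated segment, inversions reverse-complement the
#' inner segment, and breakends join flanks from the two contigs honoring
#' the junction orientation. Flanks are clipped at contig bounds.
#'
#' @param candidate refined candidate row.
#' @param genome reference [Biostrings::DNAStringSet].
#' @param flank flank length F in bp.
#' @return List with `seq` (the alternative sequence), `junctions`
#'   (novel-adjacency offsets in alt coordinates; inversions have two),
#'   `bp_alt` (the first junction), and `ref_windows` (unaltered
#'   reference windows around each original breakpoint, the realignment
#'   baseline).
#' @export
build_alt_reference <- function(candidate, genome, flank = 5000L) {
  cd <- as.list(candidate)
  F <- as.integer(flank)
  ref_win <- function(chrom, pos) {
    seq_window(genome, chrom, pos - F, pos + F)
  }
  if (cd$svtype %in% c("DEL", "TDEL")) {
    left <- seq_window(genome, cd$chrom1, cd$pos1 - F, cd$pos1)
    right <- seq_window(genome, cd$chrom2, cd$pos2, cd$pos2 + F)
    alt <- paste0(left, right)
    junctions <- nchar(left)
  } else if (cd$svtype == "DUP") {
    left <- seq_window(genome, cd$chrom1, cd$pos1 - F, cd$pos1)
    copy <- seq_window(genome, cd$chrom1, cd$pos1, cd$pos2)
    right <- seq_window(genome, cd$chrom1, cd$pos2, cd$pos2 + F)
    alt <- paste0(left, copy, copy, right)
    junctions <- nchar(left) + nchar(copy) # the copy seam
  } else if (cd$svtype == "INV") {
    left <- seq_window(genome, cd$chrom1, cd$pos1 - F, cd$pos1)
    inner <- revcomp(seq_window(genome, cd$chrom1, cd$pos1, cd$pos2))
    right <- seq_window(genome, cd$chrom1, cd$pos2, cd$pos2 + F)
    alt <- paste0(left, inner, right)
    junctions <- c(nchar(left), nchar(left) + nchar(inner))
  } else { # BND
    ori <- if (!is.null(cd$orientation) && !is.na(cd$orientation)) cd$orientation else "+-"
    left <- if (substr(ori, 1, 1) == "+")
      seq_window(genome, cd$chrom1, cd$pos1 - F, cd$pos1)
    else revcomp(seq_window(genome, cd$chrom1, cd$pos1, cd$pos1 + F))
    right <- if (substr(ori, 2, 2) == "-")
      seq_window(genome, cd$chrom2, cd$pos2, cd$pos2 + F)
    else revcomp(seq_window(genome, cd$chrom2, cd$pos2 - F, cd$pos2))
    alt <- paste0(left, right)
    junctions <- nchar(left)
  }
  ref_windows <- list(ref_win(cd$chrom1, cd$pos1))
  if (!(cd$chrom1 == cd$chrom2 && abs(cd$pos2 - cd$pos1) < F))
    ref_windows <- c(ref_windows, list(ref_win(cd$chrom2, cd$pos2)))
  list(seq = alt, junctions = junctions, bp_alt = junctions[1],
       ref_windows = ref_windows)
}

# local sub-window of a long sequence around a junction offset
local_window <- function(seq, bp, half) {
  lo <- max(0L, bp - half)
  hi <- min(nchar(seq), bp + half)
  list(seq = substr(seq, lo + 1L, hi), bp = bp - lo)
}

# read subsequence expected to span the junction, based on its q offset
junction_read_window <- function(read, q, half = 1000L) {
  lo <- max(0L, q - half)
  hi <- min(nchar(read), q + half)
  list(seq = substr(read, lo + 1L, hi), q_lo = lo)
}

#' Validate a refined candidate by realignment
#'
#' Each candidate-associated read is realigned (its junction-proximal
#' window) against local windows of the alternative reference around
#' every novel junction and against the unaltered reference windows
#' around the original breakpoints. The read supports the alternative
#' allele iff its best alt-window score beats its best reference-window
#' score by at least `score_margin` and the alignment crosses the
#' junction by at least `cross` bp on both sides. `n_spanning` counts
#' reads whose realignment reaches the junction locus at all; the
#' candidate passes iff `n_support >= min_support` and the allele
#' frequency `n_support / n_spanning >= min_af`.
#'
#' @param candidate refined candidate row.
#' @param reads named character vector (or tibble with `id`, `seq`) of
#'   candidate-associated reads.
#' @param genome reference [Biostrings::DNAStringSet].
#' @param config an [sv_filter_config()].
#' @param scoring an [sv_scoring()].
#' @param read_hints optional tibble (`read_id`, `q`) giving the junction
#'   offset on each read; reads without a hint use their midpoint.
#' @param cross junction-crossing requirement in bp.
#' @param local_half half-width of the local alignment windows cut
#'   around each junction (subject side); alignment cost scales with it.
#' @return List of class `sv_validation`: `n_support`, `n_spanning`,
#'   `allele_frequency`, `mean_score_gain`, `score_gains`,
#'   `supporting_reads`, `features` (per-read alignment length in query
#'   and reference and matching-base estimate), `pass`, `fail_reasons`.
#' @export
validate_candidate <- function(candidate, reads, genome,
                               config = sv_filter_config(),
                               scoring = sv_scoring(), read_hints = NULL,
                               cross = 200L, local_half = 2000L) {
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$id)
  alt <- build_alt_reference(candidate, genome, config$flank)
  half <- min(config$flank, local_half)
  alt_locals <- lapply(alt$junctions, function(j) local_window(alt$seq, j, half))
  gains <- numeric(0)
  supp <- character(0)
  n_span <- 0L
  feats <- list()
  for (rid in names(reads)) {
    q_hint <- NULL
    if (!is.null(read_hints)) {
      hit <- read_hints$q[read_hints$read_id == rid]
      if (length(hit) > 0) q_hint <- hit[1]
    }
    if (is.null(q_hint) || is.na(q_hint)) q_hint <- nchar(reads[[rid]]) %/% 2L
    rw <- junction_read_window(reads[[rid]], q_hint)
    if (nchar(rw$seq) < 2L * cross) next
    best <- NULL
    for (al in alt_locals) {
      a <- .semiglobal_core(rw$seq, al$seq, scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend)
      if (is.null(best) || a$score > best$score)
        best <- c(a, list(bp = al$bp))
    }
    spans <- best$s_start <= best$bp - cross %/% 2L &&
      best$s_end >= best$bp + cross %/% 2L
    if (spans) n_span <- n_span + 1L
    crosses <- best$s_start <= best$bp - cross && best$s_end >= best$bp + cross
    ref_score <- if (crosses) max(vapply(alt$ref_windows, function(wn) {
      wl <- local_window(wn, nchar(wn) %/% 2L, half)
      .semiglobal_core(rw$seq, wl$seq, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)$score
    }, numeric(1))) else Inf
    if (crosses && best$score >= ref_score + config$score_margin) {
      gains <- c(gains, best$score - ref_score)
      supp <- c(supp, rid)
      feats[[length(feats) + 1]] <- tibble(
        read_id = rid, q_len = nchar(rw$seq),
        r_len = best$s_end - best$s_start,
        n_match_est = best$score %/% scoring$match)
    }
  }
  n_support <- length(supp)
  af <- if (n_span > 0) n_support / n_span else 0
  reasons <- character(0)
  if (n_support < config$min_support) reasons <- c(reasons, "no_support")
  if (af < config$min_af) reasons <- c(reasons, "low_af")
  structure(list(n_support = n_support, n_spanning = n_span,
                 allele_frequency = af,
                 mean_score_gain = if (n_support > 0) mean(gains) else 0,
                 score_gains = gains, supporting_reads = supp,
                 features = if (length(feats)) bind_rows(feats) else tibble(),
                 pass = length(reasons) == 0, fail_reasons = reasons),
            class = "sv_validation")
}

#' Validate a terminal deletion by read-end pileup
#'
#' A terminal deletion's single internal breakpoint leaves no junction to
#' realign across; instead, reads whose alignments stop at the breakpoint
#' constitute the evidence. A read supports the call if its alignment
#' terminates within `tol` bp of the breakpoint after covering at least
#' `cross` bp on the retained side; reads continuing at least `cross` bp
#' past the breakpoint on the reference count toward the allele-frequency
#' denominator.
#'
#' @param candidate refined TDEL candidate; `terminal_side` (`"5p"` or
#'   `"3p"`) marks which contig end is lost.
#' @param segments alignment tibble (nearby reads suffice).
#' @param config an [sv_filter_config()].
#' @param scoring an [sv_scoring()] (for the QUAL-compatible gain proxy).
#' @param tol end-clustering tolerance in bp.
#' @param cross minimum covered bases on the retained side.
#' @param min_spanning minimum number of breakpoint-covering reads for
#'   the allele frequency to carry any information; terminal calls over
#'   thinner pileups fail with reason `low_depth`.
#' @param min_af terminal allele-frequency threshold. At heterozygous
#'   truncations about half of the breakpoint-covering reads stop there
#'   (expected AF 0.5), while random read-end collisions on an intact
#'   contig sit near the end-density over the crossing depth (about
#'   0.15 at 4x with 8 kbp reads); the default is the midpoint.
#' @return An `sv_validation` list.
#' @export
validate_terminal <- function(candidate, segments, config = sv_filter_config(),
                              scoring = sv_scoring(), tol = 100L,
                              cross = 200L, min_af = 0.3,
                              min_spanning = 3L) {
  cd <- as.list(candidate)
  five_prime <- isTRUE(cd$terminal_side == "5p")
  bp <- if (five_prime) cd$pos2 else cd$pos1
  seg <- segments[segments$chrom == cd$chrom1, , drop = FALSE]
  stop_pos <- if (five_prime) seg$r_start else seg$r_end
  covered <- if (five_prime) seg$r_end - bp else bp - seg$r_start
  supp <- unique(seg$read_id[abs(stop_pos - bp) <= tol & covered >= cross])
  over <- if (five_prime) bp - seg$r_start else seg$r_end - bp
  spanning <- unique(seg$read_id[covered >= cross &
                                   (over >= cross | abs(stop_pos - bp) <= tol)])
  n_support <- length(supp)
  n_span <- length(spanning)
  af <- if (n_span > 0) n_support / n_span else 0
  reasons <- character(0)
  if (n_support < config$min_support) reasons <- c(reasons, "no_support")
  if (af < max(min_af, config$min_af)) reasons <- c(reasons, "low_af")
  if (n_span < min_spanning) reasons <- c(reasons, "low_depth")
  gains <- rep(scoring$match * cross / 2, n_support)
  structure(list(n_support = n_support, n_spanning = n_span,
                 allele_frequency = af,
                 mean_score_gain = if (n_support > 0) mean(gains) else 0,
                 score_gains = gains, supporting_reads = supp,
                 features = tibble(), pass = length(reasons) == 0,
                 fail_reasons = reasons),
            class = "sv_validation")
}

#' Cross-genome uniqueness check for supporting reads
#'
#' For each supporting read, searches the whole genome (excluding the
#' candidate's own windows) for its best alternative locus via seed
#' anchors; the read fails if that locus could score within
#' `score_margin` of its anchor-backed score at the candidate locus. The
#' candidate passes iff at least `min_support` reads survive.
#'
#' @param candidate refined candidate row.
#' @param result `sv_validation` from [validate_candidate()].
#' @param reads named character vector of read sequences.
#' @param genome reference [Biostrings::DNAStringSet].
#' @param config an [sv_filter_config()].
#' @param scoring an [sv_scoring()].
#' @param read_hints optional tibble (`read_id`, `q`) of junction offsets.
#' @param exclude_margin bp around the candidate breakpoints to exclude.
#' @return List `(pass, n_unique)`.
#' @export
cross_genome_check <- function(candidate, result, reads, genome,
                               config = sv_filter_config(),
                               scoring = sv_scoring(), read_hints = NULL,
                               exclude_margin = 20000L) {
  cd <- as.list(candidate)
  survivors <- 0L
  for (rid in result$supporting_reads) {
    rd <- reads[[rid]]
    q_hint <- NULL
    if (!is.null(read_hints)) {
      hit <- read_hints$q[read_hints$read_id == rid]
      if (length(hit) > 0) q_hint <- hit[1]
    }
    if (is.null(q_hint) || is.na(q_hint)) q_hint <- nchar(rd) %/% 2L
    rw <- junction_read_window(rd, q_hint)
    anc <- seed_anchors(rw$seq, genome)
    own <- (anc$chrom == cd$chrom1 &
              anc$r_start < cd$pos1 + exclude_margin &
              anc$r_end > cd$pos1 - exclude_margin) |
      (anc$chrom == cd$chrom2 &
         anc$r_start < cd$pos2 + exclude_margin &
         anc$r_end > cd$pos2 - exclude_margin)
    other <- anc[!own, , drop = FALSE]
    # best alternative locus: maximal anchor coverage at one locus
    alt_best <- 0
    if (nrow(other) > 0) {
      key <- paste(other$chrom, other$strand,
                   round((other$r_start - other$q_start) / 200))
      alt_best <- max(vapply(split(seq_len(nrow(other)), key), function(ii) {
        sum(other$q_end[ii] - other$q_start[ii])
      }, numeric(1)))
    }
    own_cov <- sum(anc$q_end[own] - anc$q_start[own])
    if (alt_best * scoring$match < own_cov * scoring$match - config$score_margin ||
        (alt_best == 0 && own_cov > 0))
      survivors <- survivors + 1L
  }
  list(pass = survivors >= config$min_support, n_unique = survivors)
}

#' Phred-like QUAL from validation score gains
#'
#' `QUAL = min(cap, 10 log10(1 + sum of per-read score gains))`, rounded
#' to one decimal; zero when nothing supports the call.
#'
#' @param result an `sv_validation` (or any list with `score_gains`).
#' @param config an [sv_filter_config()] (supplies the cap).
#' @return Numeric QUAL.
#' @export
#' @examples
#' compute_qual(list(score_gains = 99)) # 20
compute_qual <- function(result, config = sv_filter_config()) {
  if (length(result$score_gains) == 0) return(0)
  round(min(config$qual_cap, 10 * log10(1 + sum(result$score_gains))), 1)
}
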