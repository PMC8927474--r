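# Shared small helpers. Internal coordinates are 0-based half-open
# everywhere; conversion to 1-based happens only at VCF serialization.

#' Default alignment scoring scheme
#'
#' Match/mismatch and affine gap parameters used by the SV-aware dynamic
#' program and the validation realigner, tuned to the error profile of
#' nanopore long reads. A gap of length `L` costs `gap_open + L *
#' gap_extend`. The jump between the two stitched reference pieces (the SV
#' itself) costs `jump_cost`, zero by default so that a single SV-induced
#' gap is never penalized.
#'
#' @param match match score (positive).
#' @param mismatch mismatch penalty (non-positive).
#' @param gap_open gap opening penalty (non-positive).
#' @param gap_extend gap extension penalty (non-positive).
#' @param jump_cost cost of the one allowed jump between reference pieces.
#' @return A named list of class `sv_scoring`.
#' @export
#' @examples
#' sv_scoring()
sv_scoring <- function(match = 2L, mismatch = -4L, gap_open = -4L,
                       gap_extend = -2L, jump_cost = 0L) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 jump_cost = as.integer(jump_cost)),
            class = "sv_scoring")
}

#' Validation filter configuration
#'
#' Thresholds applied when validating refined candidates by realignment to
#' an alternative reference.
#'
#' @param min_support minimum number of reads that must support the
#'   alternative allele.
#' @param min_af minimum allele frequency (supporting / junction-spanning
#'   reads).
#' @param score_margin score-unit margin by which a read's alignment to the
#'   alternative reference must beat its alignment to the unaltered
#'   reference.
#' @param flank flank length in bp used to build alternative references.
#' @param qual_cap maximum QUAL emitted.
#' @return A named list of class `sv_filter_config`.
#' @export
sv_filter_config <- function(min_support = 2L, min_af = 0.2,
                             score_margin = 20L, flank = 5000L,
                             qual_cap = 60) {
  stopifnot(min_support >= 0, min_af >= 0, score_margin >= 0, flank >= 0,
            qual_cap >= 0)
  structure(list(min_support = as.integer(min_support), min_af = min_af,
                 score_margin = as.integer(score_margin),
                 flank = as.integer(flank), qual_cap = qual_cap),
            class = "sv_filter_config")
}

# reverse complement of a plain character string
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

contig_length <- function(genome, chrom) {
  w <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (anyNA(w)) abort(paste0("unknown contig: ", chrom[is.na(w)][1]))
  w
}

# substring on 0-based half-open coordinates, clipped to the contig
seq_window <- function(genome, chrom, start, end) {
  len <- contig_length(genome, chrom)
  start <- max(0L, as.integer(start))
  end <- min(len, as.integer(end))
  if (start >= end) return("")
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

new_sv_tbl <- function(x, class) {
  structure(as_tibble(x), class = c(class, class(as_tibble(x))))
}
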