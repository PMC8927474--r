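# Readers/writers for the standard formats the pipeline touches, and the
# CIGAR arithmetic that places alignment segments on the forward read.

#' Read a FASTA file
#'
#' Sequences are uppercased and multi-line records joined; record order is
#' preserved.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA not found: ", path))
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                error = function(e) abort(paste0("FASTA parse error in ",
                                                 path, ": ", conditionMessage(e))))
  if (length(x) == 0) abort(paste0("empty FASTA: ", path))
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) abort("duplicate contig names in FASTA")
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs a named [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(seqs, path, format = "fasta", width = 70L)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' @param reads tibble with columns `id`, `seq` and optionally `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path path to an uncompressed FASTQ file.
#' @return Tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4 != 0) abort("truncated FASTQ")
  tibble(id = sub("\\s.*$", "", sub("^@", "", ln[c(TRUE, FALSE, FALSE, FALSE)])),
         seq = toupper(ln[c(FALSE, TRUE, FALSE, FALSE)]),
         qual = ln[c(FALSE, FALSE, FALSE, TRUE)])
}

# --- CIGAR arithmetic ------------------------------------------------------

# Query-side coordinates of an alignment record on the forward read.
# Hard and soft clips both count toward q_start/q_end, so a hard-clipped
# supplementary reports the same read interval as its soft-clipped
# equivalent. For minus-strand records the clip lengths are mirrored onto
# the forward read orientation.
cigar_query_span <- function(cigar, strand) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  n <- length(cigar)
  q_start <- integer(n); q_end <- integer(n)
  r_span <- integer(n); n_aln <- integer(n)
  for (i in seq_len(n)) {
    op <- ops[[i]]; ln <- lens[[i]]
    lead <- 0L
    j <- 1L
    while (j <= length(op) && op[j] %in% c("H", "S")) { lead <- lead + ln[j]; j <- j + 1L }
    trail <- 0L
    j <- length(op)
    while (j >= 1L && op[j] %in% c("H", "S")) { trail <- trail + ln[j]; j <- j - 1L }
    qlen <- sum(ln[op %in% c("M", "I", "=", "X")])
    total <- lead + qlen + trail
    if (strand[i] == "-") { tmp <- lead; lead <- trail; trail <- tmp }
    q_start[i] <- lead
    q_end[i] <- total - trail
    r_span[i] <- sum(ln[op %in% c("M", "D", "=", "X", "N")])
    n_aln[i] <- sum(ln[op %in% c("M", "=", "X")])
  }
  tibble(q_start = q_start, q_end = q_end, r_span = r_span, n_aln = n_aln)
}

#' Read alignment segments from SAM/BAM
#'
#' Ingests primary and supplementary (flag 0x800) records, skipping
#' unmapped and secondary ones, and derives read-side coordinates from the
#' CIGAR string: hard and soft clips both count toward `q_start`/`q_end`,
#' and minus-strand records report read coordinates on the forward read
#' orientation. Segments of one read are sorted by `q_start`.
#'
#' @param path SAM or BAM file with header.
#' @return Tibble with one row per aligned segment: `read_id`, `q_start`,
#'   `q_end` (0-based half-open on the forward read), `chrom`, `r_start`,
#'   `r_end` (0-based half-open), `strand`, `mapq`, `is_supplementary`,
#'   `n_match`, `cigar`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (length(x$qname) == 0) {
    return(tibble(read_id = character(), q_start = integer(),
                  q_end = integer(), chrom = character(),
                  r_start = integer(), r_end = integer(),
                  strand = character(), mapq = integer(),
                  is_supplementary = logical(), n_match = integer(),
                  cigar = character()))
  }
  strand <- as.character(x$strand)
  sp <- cigar_query_span(x$cigar, strand)
  tibble(read_id = x$qname,
         q_start = sp$q_start, q_end = sp$q_end,
         chrom = as.character(x$rname),
         r_start = x$pos - 1L, r_end = x$pos - 1L + sp$r_span,
         strand = strand, mapq = x$mapq,
         is_supplementary = bitwAnd(x$flag, 2048L) > 0L,
         n_match = sp$n_aln, cigar = x$cigar) |>
    arrange(.data$read_id, .data$q_start)
}

# --- VCF -------------------------------------------------------------------

vcf_header <- function(contigs) {
  c("##fileformat=VCFv4.2",
    "##source=svlite",
    paste0("##contig=<ID=", names(contigs), ",length=", unname(contigs), ">"),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Tandem duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the SV\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
    "##INFO=<ID=TERMINAL,Number=0,Type=Flag,Description=\"Terminal deletion\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"Zygosity hint\">",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Evidence source\">",
    "##FILTER=<ID=no_support,Description=\"Too few supporting reads\">",
    "##FILTER=<ID=low_af,Description=\"Allele frequency below threshold\">",
    "##FILTER=<ID=multi_locus,Description=\"Reads align equally well elsewhere\">",
    "##FILTER=<ID=low_depth,Description=\"Too few breakpoint-covering reads\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

check_sv_record <- function(r, contigs) {
  ok <- TRUE
  if (r$svtype %in% c("DEL", "DUP", "INV", "TDEL")) {
    if (r$chrom1 != r$chrom2 || r$pos1 >= r$pos2) ok <- FALSE
  }
  if (!r$chrom1 %in% names(contigs) || !r$chrom2 %in% names(contigs)) ok <- FALSE
  ok
}

info_str <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, is.null, logical(1))]
  paste(vapply(names(kv), function(k) {
    if (identical(kv[[k]], TRUE)) k else paste0(k, "=", kv[[k]])
  }, character(1)), collapse = ";")
}

#' Write SV calls to VCF 4.2
#'
#' DEL/DUP/INV records use symbolic ALT alleles with `SVTYPE`, `END` and
#' `SVLEN` INFO keys; terminal deletions are serialized as `SVTYPE=DEL`
#' with the `TERMINAL` flag; translocations become paired BND records with
#' reciprocal `MATEID`. Internal 0-based half-open coordinates are
#' converted to the 1-based VCF convention here and nowhere else.
#'
#' @param calls tibble of SV calls (columns `id`, `svtype`, `chrom1`,
#'   `pos1`, `chrom2`, `pos2`, `qual`, `filter`, optionally `support`,
#'   `af`, `zygosity`, `source`, `orientation`).
#' @param genome reference [Biostrings::DNAStringSet] (for contig lines and
#'   REF bases).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, genome, path) {
  contigs <- setNames(Biostrings::width(genome), names(genome))
  lines <- vcf_header(contigs)
  body <- character(0)
  if (nrow(calls) > 0 && !"id" %in% names(calls))
    calls$id <- paste0("sv", seq_len(nrow(calls)))
  for (i in seq_len(nrow(calls))) {
    r <- as.list(calls[i, ])
    if (!check_sv_record(r, contigs))
      abort(paste0("invalid SV record: ", r$id))
    qual <- if (is.null(r$qual) || is.na(r$qual)) "." else format(r$qual, nsmall = 1)
    filt <- if (is.null(r$filter) || is.na(r$filter) || r$filter == "") "PASS" else r$filter
    common <- list(SUPPORT = r$support, ZYG = r$zygosity, SRC = r$source)
    common <- common[!vapply(common, function(x) is.null(x) || is.na(x), logical(1))]
    af <- if (!is.null(r$af) && !is.na(r$af)) sprintf("%.4g", r$af) else NULL
    if (r$svtype %in% c("DEL", "DUP", "INV", "TDEL")) {
      styp <- if (r$svtype == "TDEL") "DEL" else r$svtype
      svlen <- r$pos2 - r$pos1
      if (styp == "DEL") svlen <- -svlen
      ref <- substr(seq_window(genome, r$chrom1, r$pos1, r$pos1 + 1L), 1, 1)
      if (ref == "") ref <- "N"
      info <- do.call(info_str, c(list(SVTYPE = styp, END = r$pos2 + 1L,
                                       SVLEN = svlen, AF = af,
                                       TERMINAL = if (r$svtype == "TDEL") TRUE else NULL),
                                  common))
      body <- c(body, paste(r$chrom1, r$pos1 + 1L, r$id, ref,
                            paste0("<", styp, ">"), qual, filt, info,
                            sep = "\t"))
    } else { # BND pair
      ori <- if (!is.null(r$orientation) && !is.na(r$orientation)) r$orientation else "+-"
      b1 <- substr(seq_window(genome, r$chrom1, max(0L, r$pos1 - 1L), r$pos1), 1, 1)
      b2 <- substr(seq_window(genome, r$chrom2, r$pos2, r$pos2 + 1L), 1, 1)
      if (b1 == "") b1 <- "N"
      if (b2 == "") b2 <- "N"
      id1 <- paste0(r$id, "_1"); id2 <- paste0(r$id, "_2")
      mate2 <- paste0(r$chrom2, ":", r$pos2 + 1L)
      mate1 <- paste0(r$chrom1, ":", r$pos1)
      alt1 <- switch(ori,
                     "+-" = paste0(b1, "[", mate2, "["),
                     "++" = paste0(b1, "]", mate2, "]"),
                     "--" = paste0("[", mate2, "[", b1),
                     paste0(b1, "[", mate2, "["))
      alt2 <- switch(ori,
                     "+-" = paste0("]", mate1, "]", b2),
                     "++" = paste0(b2, "]", mate1, "]"),
                     "--" = paste0("[", mate1, "[", b2),
                     paste0("]", mate1, "]", b2))
      i1 <- do.call(info_str, c(list(SVTYPE = "BND", MATEID = id2, AF = af), common))
      i2 <- do.call(info_str, c(list(SVTYPE = "BND", MATEID = id1, AF = af), common))
      body <- c(body,
                paste(r$chrom1, r$pos1, id1, b1, alt1, qual, filt, i1, sep = "\t"),
                paste(r$chrom2, r$pos2 + 1L, id2, b2, alt2, qual, filt, i2, sep = "\t"))
    }
  }
  writeLines(c(lines, body), path)
  invisible(path)
}

parse_info <- function(info) {
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  setNames(lapply(kv, function(x) if (length(x) > 1) x[2] else TRUE),
           vapply(kv, `[`, character(1), 1))
}

#' Read SV records from a VCF written by [write_vcf()]
#'
#' Inverse of [write_vcf()]: symbolic DEL/DUP/INV records and BND pairs are
#' reassembled into the internal 0-based half-open representation, with BND
#' mates joined into a single row per translocation.
#'
#' @param path VCF path.
#' @return Tibble of SV calls.
#' @export
read_vcf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  out <- list()
  bnd_seen <- character(0)
  for (l in ln) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    info <- parse_info(f[8])
    styp <- info[["SVTYPE"]]
    qual <- suppressWarnings(as.numeric(f[6]))
    sup <- if (!is.null(info[["SUPPORT"]])) as.integer(info[["SUPPORT"]]) else NA_integer_
    af <- if (!is.null(info[["AF"]])) as.numeric(info[["AF"]]) else NA_real_
    zyg <- if (!is.null(info[["ZYG"]])) info[["ZYG"]] else NA_character_
    src <- if (!is.null(info[["SRC"]])) info[["SRC"]] else NA_character_
    if (styp %in% c("DEL", "DUP", "INV")) {
      svtype <- if (isTRUE(info[["TERMINAL"]])) "TDEL" else styp
      out[[length(out) + 1]] <- tibble(
        id = f[3], svtype = svtype, chrom1 = f[1],
        pos1 = as.integer(f[2]) - 1L, chrom2 = f[1],
        pos2 = as.integer(info[["END"]]) - 1L, qual = qual, filter = f[7],
        support = sup, af = af, zygosity = zyg, source = src,
        orientation = NA_character_)
    } else if (identical(styp, "BND")) {
      base <- sub("_[12]$", "", f[3])
      if (base %in% bnd_seen) next
      bnd_seen <- c(bnd_seen, base)
      alt <- f[5]
      ori <- if (grepl("^[ACGTN]+\\[", alt)) "+-" else
        if (grepl("^[ACGTN]+\\]", alt)) "++" else
          if (startsWith(alt, "[")) "--" else "-+"
      m <- regmatches(alt, regexec("[\\[\\]]([^\\[\\]:]+):([0-9]+)[\\[\\]]",
                                   alt, perl = TRUE))[[1]]
      out[[length(out) + 1]] <- tibble(
        id = base, svtype = "BND", chrom1 = f[1], pos1 = as.integer(f[2]),
        chrom2 = m[2], pos2 = as.integer(m[3]) - 1L, qual = qual,
        filter = f[7], support = sup, af = af, zygosity = zyg, source = src,
        orientation = ori)
    }
  }
  if (length(out) == 0) {
    return(tibble(id = character(), svtype = character(), chrom1 = character(),
                  pos1 = integer(), chrom2 = character(), pos2 = integer(),
                  qual = double(), filter = character(), support = integer(),
                  af = double(), zygosity = character(), source = character(),
                  orientation = character()))
  }
  bind_rows(out)
}

#' Write genomic intervals to BED
#'
#' @param x tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `name`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom, x$start, x$end)
  if ("name" %in% names(x)) cols <- c(cols, list(x$name))
  if ("score" %in% names(x)) cols <- c(cols, list(x$score))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}
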