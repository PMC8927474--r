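# End-to-end orchestration: candidate discovery (split reads + depth),
# supporting-read search, SV-DP breakpoint refinement, de-duplication,
# realignment validation, QUAL computation and VCF/BED output.

#' Pipeline configuration
#'
#' Collects inputs and tuning parameters for [run_pipeline()]. Inputs may
#' be file paths or in-memory objects (a [Biostrings::DNAStringSet]
#' genome, an alignment tibble, a reads tibble, a `reference_panel`).
#'
#' @param reference reference genome (FASTA path or `DNAStringSet`).
#' @param reads long reads (FASTQ path or tibble `id`, `seq`), optional
#'   when `alignments` carries sequences.
#' @param alignments SAM/BAM path or alignment tibble from
#'   [read_alignments()]; computed with minimap2 (or the built-in
#'   seed-and-extend path at toy scale) when absent.
#' @param panel reference panel (TSV path, `reference_panel`, or list of
#'   normalized `depth_profile`s).
#' @param aux_contigs optional extra contigs FASTA appended to the
#'   reference.
#' @param out_prefix output path prefix; when `NULL` nothing is written.
#' @param min_sv_len minimum SV size (bp).
#' @param L depth interval size (bp).
#' @param target_depth depth normalization target.
#' @param alpha depth-region p-value threshold.
#' @param max_gap merge gap for abnormal intervals.
#' @param w,W SV-DP window sizes.
#' @param tau SV-DP acceptance fraction.
#' @param dedup_tol breakpoint tolerance for de-duplication (bp).
#' @param telomere_margin distance from a contig end within which a depth
#'   deletion region is treated as terminal.
#' @param scoring an [sv_scoring()].
#' @param filters an [sv_filter_config()].
#' @param aligner `"auto"`, `"minimap2"` or `"internal"`.
#' @param seed RNG seed recorded in the log (the pipeline itself is
#'   deterministic).
#' @return A config list of class `sv_config`.
#' @export
sv_config <- function(reference, reads = NULL, alignments = NULL,
                      panel = NULL, aux_contigs = NULL, out_prefix = NULL,
                      min_sv_len = 1000L, L = 10000L, target_depth = 4,
                      alpha = 0.05, max_gap = 2L, w = 2000L, W = 10000L,
                      tau = 0.6, dedup_tol = 1000L,
                      telomere_margin = 500000L, scoring = sv_scoring(),
                      filters = sv_filter_config(), aligner = "auto",
                      seed = 7L) {
  structure(list(reference = reference, reads = reads,
                 alignments = alignments, panel = panel,
                 aux_contigs = aux_contigs, out_prefix = out_prefix,
                 min_sv_len = as.integer(min_sv_len), L = as.integer(L),
                 target_depth = target_depth, alpha = alpha,
                 max_gap = as.integer(max_gap), w = as.integer(w),
                 W = as.integer(W), tau = tau,
                 dedup_tol = as.integer(dedup_tol),
                 telomere_margin = as.integer(telomere_margin),
                 scoring = scoring, filters = filters, aligner = aligner,
                 seed = as.integer(seed)),
            class = "sv_config")
}

#' Align reads to a reference with minimap2
#'
#' Thin wrapper over the minimap2 executable (`map-ont` preset, one
#' thread, no secondary alignments), producing a SAM file.
#'
#' @param reads_path FASTQ path.
#' @param ref_path FASTA path.
#' @param out_sam output SAM path.
#' @return `out_sam`, invisibly.
#' @export
align_reads_minimap2 <- function(reads_path, ref_path,
                                 out_sam = tempfile(fileext = ".sam")) {
  mm2 <- Sys.which("minimap2")
  if (mm2 == "") abort("minimap2 not found on PATH")
  status <- system2(mm2, c("-a", "-x", "map-ont", "--secondary=no", "-t", "1",
                           "-Y", shQuote(ref_path), shQuote(reads_path)),
                    stdout = out_sam, stderr = FALSE)
  if (status != 0) abort("minimap2 failed")
  invisible(out_sam)
}

#' Toy-scale internal aligner from seed anchors
#'
#' Chains exact k-mer anchors into alignment segments (same contig,
#' strand and approximate diagonal). Intended for small fixtures where a
#' production aligner is unnecessary; it reports no CIGAR.
#'
#' @param reads tibble (`id`, `seq`).
#' @param genome [Biostrings::DNAStringSet].
#' @param k,max_occ anchor parameters, see [seed_anchors()].
#' @param max_anchor_gap maximum diagonal drift and anchor spacing when
#'   chaining (bp).
#' @param min_seg_len minimum chained segment length (bp).
#' @return Alignment tibble compatible with [read_alignments()] output.
#' @export
align_reads_internal <- function(reads, genome, k = 15L, max_occ = 50L,
                                 max_anchor_gap = 2000L, min_seg_len = 100L) {
  out <- list()
  for (i in seq_len(nrow(reads))) {
    anc <- seed_anchors(reads$seq[i], genome, k, max_occ)
    if (nrow(anc) == 0) next
    anc <- arrange(anc, .data$chrom, .data$strand, .data$r_start)
    key <- paste(anc$chrom, anc$strand)
    for (grp in split(seq_len(nrow(anc)), key)) {
      a <- anc[grp, , drop = FALSE]
      diag <- ifelse(a$strand == "+", a$r_start - a$q_start,
                     a$r_start + a$q_end)
      ord <- order(a$r_start)
      a <- a[ord, , drop = FALSE]; diag <- diag[ord]
      cluster <- cumsum(c(1L, (abs(diff(diag)) > max_anchor_gap) |
                            (diff(a$r_start) > max_anchor_gap * 4)))
      for (cl in split(seq_len(nrow(a)), cluster)) {
        seg <- a[cl, , drop = FALSE]
        q0 <- min(seg$q_start); q1 <- max(seg$q_end)
        if (q1 - q0 < min_seg_len) next
        out[[length(out) + 1]] <- tibble(
          read_id = reads$id[i], q_start = q0, q_end = q1,
          chrom = seg$chrom[1], r_start = min(seg$r_start),
          r_end = max(seg$r_end), strand = seg$strand[1], mapq = 60L,
          is_supplementary = FALSE,
          n_match = sum(seg$q_end - seg$q_start), cigar = NA_character_)
      }
    }
  }
  if (length(out) == 0) {
    return(read_alignments_empty())
  }
  bind_rows(out) |> arrange(.data$read_id, .data$q_start)
}

read_alignments_empty <- function() {
  tibble(read_id = character(), q_start = integer(), q_end = integer(),
         chrom = character(), r_start = integer(), r_end = integer(),
         strand = character(), mapq = integer(),
         is_supplementary = logical(), n_match = integer(),
         cigar = character())
}

# read sequences (forward orientation) from the primary records of a BAM
extract_reads_from_bam <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "strand", "seq"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (length(x$qname) == 0) return(tibble(id = character(), seq = character()))
  sq <- as.character(x$seq)
  minus <- !is.na(x$strand) & as.character(x$strand) == "-"
  sq[minus] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sq[minus])))
  tibble(id = x$qname, seq = sq) |> dplyr::distinct(.data$id, .keep_all = TRUE)
}

resolve_inputs <- function(config) {
  genome <- config$reference
  if (is.character(genome)) genome <- read_fasta(genome)
  if (!is.null(config$aux_contigs)) {
    aux <- config$aux_contigs
    if (is.character(aux)) aux <- read_fasta(aux)
    genome <- c(genome, aux)
  }
  reads <- config$reads
  if (is.character(reads)) reads <- read_fastq(reads)
  segments <- config$alignments
  if (is.character(segments)) {
    if (is.null(reads)) reads <- extract_reads_from_bam(segments)
    segments <- read_alignments(segments)
  }
  if (is.null(segments)) {
    if (is.null(reads)) abort("need reads or alignments")
    use_mm2 <- config$aligner %in% c("auto", "minimap2") &&
      Sys.which("minimap2") != ""
    if (config$aligner == "minimap2" && Sys.which("minimap2") == "")
      abort("minimap2 requested but not found")
    if (use_mm2) {
      fq <- tempfile(fileext = ".fq"); fa <- tempfile(fileext = ".fa")
      write_fastq(reads, fq)
      write_fasta(genome, fa)
      sam <- align_reads_minimap2(fq, fa)
      segments <- read_alignments(sam)
      unlink(c(fq, fa, sam))
    } else {
      segments <- align_reads_internal(reads, genome)
    }
  }
  panel <- config$panel
  if (is.character(panel)) panel <- read_panel(panel)
  if (is.list(panel) && !inherits(panel, "reference_panel") &&
      !is.null(panel[[1]]) && inherits(panel[[1]], "depth_profile"))
    panel <- build_panel(panel)
  list(genome = genome, reads = reads, segments = segments, panel = panel)
}

# junction read-offset hint for a read whose segment crosses pos
hint_for_segment <- function(seg, pos) {
  off <- pos - seg$r_start
  if (seg$strand == "+") seg$q_start + off else seg$q_end - off
}

gather_validation_reads <- function(cand, segments, reads_vec, flank) {
  near <- segments[(segments$chrom == cand$chrom1 &
                      segments$r_start < cand$pos1 + flank &
                      segments$r_end > cand$pos1 - flank) |
                     (segments$chrom == cand$chrom2 &
                        segments$r_start < cand$pos2 + flank &
                        segments$r_end > cand$pos2 - flank), , drop = FALSE]
  ids <- sort(unique(c(unlist(cand$read_ids), near$read_id)))
  ids <- ids[ids %in% names(reads_vec)]
  hints <- list()
  for (rid in ids) {
    seg <- near[near$read_id == rid, , drop = FALSE]
    q <- NA_integer_
    for (j in seq_len(nrow(seg))) {
      sj <- as.list(seg[j, ])
      if (sj$chrom == cand$chrom1 && sj$r_start <= cand$pos1 &&
          sj$r_end >= cand$pos1) {
        q <- hint_for_segment(sj, cand$pos1); break
      }
      if (sj$chrom == cand$chrom2 && sj$r_start <= cand$pos2 &&
          sj$r_end >= cand$pos2) {
        q <- hint_for_segment(sj, cand$pos2); break
      }
    }
    if (is.na(q) && nrow(seg) > 0) {
      # segment ends nearest a breakpoint: junction just beyond the end
      sj <- as.list(seg[which.max(seg$q_end - seg$q_start), ])
      q <- if (sj$strand == "+") sj$q_end else sj$q_start
    }
    hints[[length(hints) + 1]] <- tibble(read_id = rid, q = as.integer(q))
  }
  list(reads = reads_vec[ids],
       hints = if (length(hints)) bind_rows(hints) else
         tibble(read_id = character(), q = integer()))
}

# refine a terminal-deletion depth region by read-end pileup clustering
refine_terminal_candidate <- function(region, segments, genome, L,
                                      five_prime = FALSE, min_count = 2L,
                                      cluster_gap = 100L,
                                      min_sv_len = 1000L) {
  cn <- region$chrom
  clen <- contig_length(genome, cn)
  seg <- segments[segments$chrom == cn, , drop = FALSE]
  if (five_prime) {
    # rough breakpoint near the region's inner (right) edge; greedy
    # merging can overshoot by a few bridged intervals
    win_lo <- region$end - 3L * L; win_hi <- region$end + L
    ends <- seg$r_start[seg$r_start >= win_lo & seg$r_start <= win_hi &
                          seg$r_start >= min_sv_len &
                          seg$r_end - seg$r_start >= 200L]
  } else {
    win_lo <- region$start - L; win_hi <- region$start + 3L * L
    ends <- seg$r_end[seg$r_end >= win_lo & seg$r_end <= win_hi &
                        seg$r_end <= clen - min_sv_len &
                        seg$r_end - seg$r_start >= 200L]
  }
  if (length(ends) < min_count) return(NULL)
  ends <- sort(ends)
  cl <- cumsum(c(1L, diff(ends) > cluster_gap))
  sizes <- table(cl)
  big <- as.integer(names(sizes)[which.max(sizes)])
  grp <- ends[cl == big]
  if (length(grp) < min_count) return(NULL)
  bp <- as.integer(round(stats::median(grp)))
  rids <- if (five_prime) {
    seg$read_id[seg$r_start %in% grp]
  } else {
    seg$read_id[seg$r_end %in% grp]
  }
  cand <- new_candidate("TDEL",
                        chrom1 = cn,
                        pos1 = if (five_prime) 0L else bp,
                        chrom2 = cn,
                        pos2 = if (five_prime) bp else as.integer(clen),
                        orientation = NA_character_, source = "depth",
                        read_id = unique(rids), q = NA_integer_,
                        s = NA_integer_, e = NA_integer_,
                        strand1 = "+", strand2 = "+",
                        zygosity = region$zygosity)
  cand$refined <- TRUE
  cand$score <- NA_real_
  cand$terminal_side <- if (five_prime) "5p" else "3p"
  cand
}

#' Run the full SV-calling pipeline
#'
#' Executes the four-step workflow: candidate discovery from split reads
#' and alignment gaps plus depth-based candidate regions against the
#' reference panel; supporting-read search and SV-DP breakpoint
#' refinement; de-duplication; and realignment validation with QUAL
#' scoring. Calls (including validation-failed ones, annotated in
#' FILTER) are returned and optionally written as VCF and BED.
#'
#' @param config an [sv_config()].
#' @return List of class `sv_result`: `calls` (tibble), `stage_log`
#'   (tibble of candidate counts per stage), `profile`, `paths` (output
#'   files if written).
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  inp <- resolve_inputs(config)
  genome <- inp$genome
  segments <- inp$segments
  reads_vec <- if (!is.null(inp$reads)) setNames(inp$reads$seq, inp$reads$id)
  else character(0)
  log <- list()
  note <- function(stage, n) log[[length(log) + 1]] <<- tibble(stage = stage, n = n)

  # discovery: split reads + long alignment gaps
  split_cands <- extract_split_candidates(segments, config$min_sv_len)
  gap_cands <- extract_gap_candidates(segments, config$min_sv_len)
  note("split_candidates", nrow(split_cands))
  note("gap_candidates", nrow(gap_cands))

  # depth route
  depth_regs <- tibble()
  profile <- NULL
  if (!is.null(inp$panel)) {
    profile <- compute_depth_profile(segments, genome, config$L)
    if (attr(profile, "genome_mean") > 0)
      profile <- normalize_profile(profile, config$target_depth)
    depth_regs <- depth_candidates(profile, inp$panel, config$alpha,
                                   config$max_gap)
  }
  note("depth_regions", nrow(depth_regs))

  # pre-cluster junction candidates so each junction is refined once
  pool <- bind_rows(split_cands, gap_cands)
  pre <- deduplicate(pool, tol = 2 * config$dedup_tol)
  note("junctions_to_refine", nrow(pre))

  refined <- list()
  reject_log <- character(0)
  for (i in seq_len(nrow(pre))) {
    cand <- pre[i, ]
    done <- NULL
    for (rid in head(unlist(cand$read_ids), 3)) {
      if (!rid %in% names(reads_vec)) next
      done <- tryCatch(
        refine_candidate(cand, reads_vec[[rid]], genome, config$scoring,
                         config$tau, config$w, config$W),
        error = function(e) NULL)
      if (!is.null(done)) break
    }
    if (is.null(done)) reject_log <- c(reject_log, "refine_failed")
    else refined[[length(refined) + 1]] <- done
  }

  # depth regions: terminal regions by end pileup, internal via SV-DP
  for (i in seq_len(nrow(depth_regs))) {
    reg <- depth_regs[i, ]
    clen <- contig_length(genome, reg$chrom)
    near5 <- reg$start <= 2L * config$L
    near3 <- reg$end >= clen - 2L * config$L
    terminal <- reg$mode == "del" && (near5 || near3)
    if (terminal) {
      tc <- refine_terminal_candidate(reg, segments, genome, config$L,
                                      five_prime = near5 && !near3,
                                      min_sv_len = config$min_sv_len)
      if (!is.null(tc)) refined[[length(refined) + 1]] <- tc
      else reject_log <- c(reject_log, "terminal_unrefined")
      next
    }
    sup <- find_supporting_read(reg, segments, slack = config$W)
    if (is.null(sup)) { reject_log <- c(reject_log, "no_support"); next }
    if (!sup$read_id %in% names(reads_vec)) {
      reject_log <- c(reject_log, "no_read_seq"); next
    }
    cand <- new_candidate(if (reg$mode == "del") "DEL" else "DUP",
                          chrom1 = reg$chrom, pos1 = reg$start,
                          chrom2 = reg$chrom, pos2 = reg$end,
                          orientation = if (reg$mode == "del") "+-" else "-+",
                          source = "depth", read_id = sup$read_id,
                          q = sup$q, s = sup$s, e = sup$e,
                          strand1 = sup$strand1, strand2 = sup$strand2,
                          zygosity = reg$zygosity)
    done <- tryCatch(
      refine_candidate(cand, reads_vec[[sup$read_id]], genome,
                       config$scoring, config$tau, config$w, config$W),
      error = function(e) NULL)
    if (is.null(done)) reject_log <- c(reject_log, "refine_failed")
    else refined[[length(refined) + 1]] <- done
  }
  refined <- if (length(refined)) bind_rows(refined) else empty_candidates()
  if (!"terminal_side" %in% names(refined) && nrow(refined) > 0)
    refined$terminal_side <- NA_character_
  note("refined", nrow(refined))

  merged <- deduplicate(refined, config$dedup_tol)
  # a terminal depth loss explained by an unbalanced translocation
  if (nrow(merged) > 0) {
    bnd_pos <- merged |>
      filter(.data$svtype == "BND")
    drop <- logical(nrow(merged))
    for (i in which(merged$svtype == "TDEL")) {
      lo <- merged$pos1[i] - config$L
      hi <- merged$pos2[i] + config$L
      in_footprint <- any(
        (bnd_pos$chrom1 == merged$chrom1[i] & bnd_pos$pos1 >= lo &
           bnd_pos$pos1 <= hi) |
          (bnd_pos$chrom2 == merged$chrom1[i] & bnd_pos$pos2 >= lo &
             bnd_pos$pos2 <= hi))
      if (in_footprint) drop[i] <- TRUE
    }
    merged <- merged[!drop, , drop = FALSE]
  }
  note("deduplicated", nrow(merged))

  # validation
  calls <- list()
  for (i in seq_len(nrow(merged))) {
    cand <- merged[i, ]
    if (cand$svtype == "TDEL") {
      vres <- validate_terminal(cand, segments, config$filters,
                                config$scoring)
      cg_pass <- TRUE
    } else {
      vr <- gather_validation_reads(cand, segments, reads_vec,
                                    config$filters$flank)
      vres <- validate_candidate(cand, vr$reads, genome, config$filters,
                                 config$scoring, read_hints = vr$hints)
      cg_pass <- TRUE
      if (vres$pass) {
        cg <- cross_genome_check(cand, vres, vr$reads, genome,
                                 config$filters, config$scoring,
                                 read_hints = vr$hints)
        cg_pass <- cg$pass
      }
    }
    reasons <- vres$fail_reasons
    if (!cg_pass) reasons <- c(reasons, "multi_locus")
    qual <- compute_qual(vres, config$filters)
    zyg <- cand$zygosity
    if (is.na(zyg)) zyg <- if (vres$allele_frequency >= 0.8) "hom" else "het"
    calls[[length(calls) + 1]] <- tibble(
      id = sprintf("svlite_%03d", i), svtype = cand$svtype,
      chrom1 = cand$chrom1, pos1 = cand$pos1, chrom2 = cand$chrom2,
      pos2 = cand$pos2, qual = qual,
      filter = if (length(reasons) == 0) "PASS"
      else paste(reasons, collapse = ";"),
      support = max(cand$support, vres$n_support),
      af = vres$allele_frequency, zygosity = zyg, source = cand$source,
      orientation = cand$orientation,
      terminal_side = if ("terminal_side" %in% names(cand))
        cand$terminal_side else NA_character_)
  }
  calls <- if (length(calls)) bind_rows(calls) else tibble(
    id = character(), svtype = character(), chrom1 = character(),
    pos1 = integer(), chrom2 = character(), pos2 = integer(),
    qual = double(), filter = character(), support = integer(),
    af = double(), zygosity = character(), source = character(),
    orientation = character(), terminal_side = character())
  calls <- arrange(calls, .data$chrom1, .data$pos1)
  if (nrow(calls) > 0) calls$id <- sprintf("svlite_%03d", seq_len(nrow(calls)))
  note("validated_pass", sum(calls$filter == "PASS"))
  note("calls_total", nrow(calls))

  paths <- list()
  if (!is.null(config$out_prefix)) {
    paths$vcf <- paste0(config$out_prefix, ".vcf")
    write_vcf(calls, genome, paths$vcf)
    paths$bed <- paste0(config$out_prefix, ".bed")
    write_bed(tibble(chrom = calls$chrom1, start = calls$pos1,
                     end = ifelse(calls$svtype == "BND", calls$pos1 + 1L,
                                  calls$pos2),
                     name = paste0(calls$svtype, "_", calls$id)), paths$bed)
    log_path <- paste0(config$out_prefix, ".log")
    stage_log <- bind_rows(log)
    writeLines(c(paste0("# svlite seed=", config$seed),
                 paste(stage_log$stage, stage_log$n, sep = "\t")), log_path)
    paths$log <- log_path
  }
  structure(list(calls = calls, stage_log = bind_rows(log),
                 profile = profile, reject_log = reject_log,
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                 paths = paths),
            class = "sv_result")
}

#' @export
print.sv_result <- function(x, ...) {
  cat("svlite result: ", nrow(x$calls), " calls (",
      sum(x$calls$filter == "PASS"), " PASS), ",
      sprintf("%.1f s\n", x$elapsed), sep = "")
  print(x$stage_log)
  invisible(x)
}

#' Tidy pipeline calls
#'
#' @param x an `sv_result` from [run_pipeline()].
#' @param ... unused.
#' @return The calls tibble.
#' @export
tidy.sv_result <- function(x, ...) x$calls

#' One-row pipeline summary
#'
#' @param x an `sv_result`.
#' @param ... unused.
#' @return One-row tibble with call counts and runtime.
#' @export
glance.sv_result <- function(x, ...) {
  tibble(n_calls = nrow(x$calls), n_pass = sum(x$calls$filter == "PASS"),
         elapsed_s = x$elapsed)
}

#' Simulate a full synthetic case and call SVs on it
#'
#' Generates a random reference with telomere-like ends, implants SVs
#' (none for `zygosity = "none"`), simulates a reference panel and noisy
#' long reads, runs [run_pipeline()], and evaluates the calls against the
#' truth. This is the package's reproducible benchmark harness.
#'
#' @param seed RNG seed controlling every random choice.
#' @param zygosity `"het"`, `"hom"`, or `"none"` (null genome).
#' @param contig_lengths reference contig lengths (default seven contigs
#'   totalling 5 Mbp).
#' @param n_per_type SVs implanted per type.
#' @param depth target coverage.
#' @param mean_len mean read length.
#' @param err_mis,err_ins,err_del read error rates.
#' @param panel_n panel samples.
#' @param max_dist breakpoint allowance(s) for evaluation.
#' @param keep_files write outputs under this prefix when non-`NULL`.
#' @return List: `truth`, `result` (`sv_result`), `evals` (named list of
#'   `sv_eval` per allowance), `genome`.
#' @export
run_synthetic_benchmark <- function(seed = 1L, zygosity = c("het", "hom", "none"),
                                    contig_lengths = c(9e5, 8e5, 8e5, 7e5,
                                                       7e5, 6e5, 5e5),
                                    n_per_type = 2L, depth = 4,
                                    mean_len = 8000, err_mis = 0.04,
                                    err_ins = 0.02, err_del = 0.02,
                                    panel_n = 24L, max_dist = c(100L, 2000L),
                                    keep_files = NULL) {
  zygosity <- match.arg(zygosity)
  genome <- make_reference(contig_lengths, seed = seed)
  if (zygosity == "none") {
    hap1 <- genome; hap2 <- genome
    truth <- tibble(id = character(), svtype = character(),
                    chrom1 = character(), pos1 = integer(),
                    chrom2 = character(), pos2 = integer(),
                    size = integer(), zygosity = character(),
                    terminal_side = character(), orientation = character())
  } else {
    specs <- sv_spec_set(n_per_type = n_per_type, zygosity = zygosity)
    imp <- implant_svs(genome, specs, seed = seed)
    hap1 <- imp$hap1; hap2 <- imp$hap2; truth <- imp$truth
  }
  panel <- simulate_panel(genome, n = panel_n, depth = depth, seed = seed)
  sim <- simulate_reads(hap1, hap2, depth = depth, mean_len = mean_len,
                        err_mis = err_mis, err_ins = err_ins,
                        err_del = err_del, seed = seed)
  cfg <- sv_config(reference = genome, reads = sim$reads,
                   panel = panel, out_prefix = keep_files, seed = seed)
  res <- run_pipeline(cfg)
  evals <- lapply(setNames(max_dist, paste0("dist_", max_dist)), function(d) {
    match_calls(res$calls, truth, max_dist = d)
  })
  list(truth = truth, result = res, evals = evals, genome = genome)
}
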