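# Synthetic-data generator: toy reference with telomere-like repeat
# tracts, implantation of the seven SV types on one or both haplotypes,
# noisy long-read simulation with known truth, and a simulated reference
# panel of normal low-depth samples.

TELOMERE_UNIT <- "TTAGGG"

#' Build a random reference genome with telomere-like ends
#'
#' Contigs are i.i.d. random nucleotide sequence with tandem 6-mer repeat
#' tracts at both ends mimicking telomeric repetition; deterministic per
#' seed.
#'
#' @param contig_lengths named (or unnamed, `chr1..chrN`) integer vector
#'   of contig lengths; at least 50 kbp each recommended.
#' @param seed RNG seed.
#' @param telomere_tract_len length of the terminal repeat tract (bp).
#' @return A [Biostrings::DNAStringSet].
#' @export
make_reference <- function(contig_lengths, seed = 1L,
                           telomere_tract_len = 5000L) {
  set.seed(seed)
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- paste0("chr", seq_along(contig_lengths))
  tl <- as.integer(telomere_tract_len)
  tract <- substr(strrep(TELOMERE_UNIT, ceiling(tl / 6) + 1), 1, tl)
  seqs <- vapply(contig_lengths, function(len) {
    len <- as.integer(len)
    core <- len - 2L * tl
    stopifnot(core > 0)
    body <- paste(sample(c("A", "C", "G", "T"), core, replace = TRUE),
                  collapse = "")
    paste0(tract, body, revcomp(tract))
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

#' Specifications for a set of SVs to implant
#'
#' One row per SV: the seven supported types are `del_short`, `del_long`,
#' `dup`, `tdel` (terminal deletion), `inv`, `tra_balanced` and
#' `tra_unbalanced`. Sizes (not used for balanced translocations) must be
#' at least 1 kbp.
#'
#' @param n_per_type number of SVs of each type.
#' @param zygosity `"het"` or `"hom"`, recycled across rows.
#' @param size_ranges named list of `c(min, max)` size ranges per type.
#' @return Tibble with `svtype`, `size_min`, `size_max`, `zygosity`.
#' @export
sv_spec_set <- function(n_per_type = 2L, zygosity = "het",
                        size_ranges = NULL) {
  defaults <- list(del_short = c(5e4, 1e5), del_long = c(1.2e5, 3e5),
                   dup = c(5e4, 1.5e5), tdel = c(5e4, 2e5),
                   inv = c(5e4, 2e5), tra_balanced = c(NA, NA),
                   tra_unbalanced = c(5e4, 2e5))
  if (!is.null(size_ranges)) defaults[names(size_ranges)] <- size_ranges
  types <- names(defaults)
  tibble(svtype = rep(types, each = n_per_type),
         size_min = rep(vapply(defaults, `[`, numeric(1), 1), each = n_per_type),
         size_max = rep(vapply(defaults, `[`, numeric(1), 2), each = n_per_type),
         zygosity = zygosity)
}

# interval bookkeeping for non-overlapping placement
overlaps_any <- function(occ, start, end, pad) {
  if (length(occ) == 0) return(FALSE)
  any(vapply(occ, function(iv) start < iv[2] + pad && end > iv[1] - pad,
             logical(1)))
}

#' Implant SVs into a reference, producing two haplotypes and truth
#'
#' Heterozygous SVs are applied to haplotype 1 only, homozygous ones to
#' both. Terminal deletions and unbalanced translocations are anchored at
#' contig ends (one breakpoint in the telomere-like tract side);
#' placements never overlap. Truth records carry exact breakpoints in
#' reference coordinates (0-based half-open).
#'
#' @param reference [Biostrings::DNAStringSet] from [make_reference()].
#' @param specs tibble from [sv_spec_set()].
#' @param seed RNG seed.
#' @param end_margin minimum distance of internal events from contig
#'   ends.
#' @param pad minimum distance between implanted events.
#' @param max_retry placement attempts per event before shrinking the
#'   requested size.
#' @return List with `hap1`, `hap2` ([Biostrings::DNAStringSet]) and
#'   `truth` (tibble: `id`, `svtype` in DEL/DUP/INV/BND/TDEL terms,
#'   `chrom1`, `pos1`, `chrom2`, `pos2`, `size`, `zygosity`,
#'   `terminal_side`, `orientation`).
#' @export
implant_svs <- function(reference, specs, seed = 1L, end_margin = 30000L,
                        pad = 30000L, max_retry = 200L) {
  set.seed(seed + 1L)
  lens <- setNames(Biostrings::width(reference), names(reference))
  occ <- setNames(vector("list", length(lens)), names(lens))
  free_ends <- unlist(lapply(names(lens), function(cn) paste0(cn, ":", c("5p", "3p"))))
  truth <- list()
  edits <- list() # per-event edit descriptors, reference coordinates

  claim <- function(cn, start, end) {
    occ[[cn]] <<- c(occ[[cn]], list(c(start, end)))
  }
  pick_internal <- function(size) {
    for (try in seq_len(max_retry)) {
      cn <- sample(names(lens), 1, prob = as.numeric(lens))
      lo <- end_margin
      hi <- lens[[cn]] - end_margin - size
      if (hi <= lo) next
      start <- floor(runif(1, lo, hi))
      if (!overlaps_any(occ[[cn]], start, start + size, pad))
        return(list(chrom = cn, start = as.integer(start),
                    end = as.integer(start + size)))
    }
    NULL
  }
  pick_end <- function() {
    if (length(free_ends) == 0) return(NULL)
    e <- sample(free_ends, 1)
    free_ends <<- setdiff(free_ends, e)
    parts <- strsplit(e, ":", fixed = TRUE)[[1]]
    list(chrom = parts[1], side = parts[2], key = e)
  }
  unpick_end <- function(e) {
    free_ends <<- c(free_ends, e$key)
  }
  draw_size <- function(smin, smax) as.integer(floor(runif(1, smin, smax)))

  # translocations first: they claim whole contig ends
  ord <- order(match(specs$svtype, c("tra_balanced", "tra_unbalanced", "tdel",
                                     "del_long", "del_short", "dup", "inv")))
  specs <- specs[ord, , drop = FALSE]
  sv_id <- 0L
  for (i in seq_len(nrow(specs))) {
    sp <- as.list(specs[i, ])
    sv_id <- sv_id + 1L
    id <- sprintf("truth_%02d_%s", sv_id, sp$svtype)
    if (sp$svtype %in% c("del_short", "del_long", "dup", "inv")) {
      placed <- NULL
      size <- draw_size(sp$size_min, sp$size_max)
      while (is.null(placed) && size >= 1000L) {
        placed <- pick_internal(size)
        if (is.null(placed)) size <- as.integer(size * 0.7)
      }
      if (is.null(placed)) abort(paste0("cannot place ", sp$svtype))
      claim(placed$chrom, placed$start, placed$end)
      vtype <- switch(sp$svtype, del_short = "DEL", del_long = "DEL",
                      dup = "DUP", inv = "INV")
      truth[[id]] <- tibble(id = id, svtype = vtype, chrom1 = placed$chrom,
                            pos1 = placed$start, chrom2 = placed$chrom,
                            pos2 = placed$end, size = size,
                            zygosity = sp$zygosity,
                            terminal_side = NA_character_,
                            orientation = NA_character_)
      edits[[id]] <- list(type = vtype, chrom = placed$chrom,
                          start = placed$start, end = placed$end,
                          zygosity = sp$zygosity)
    } else if (sp$svtype == "tdel") {
      done <- FALSE
      for (try in seq_len(max_retry)) {
        e <- pick_end()
        if (is.null(e)) break
        size <- draw_size(sp$size_min, min(sp$size_max, lens[[e$chrom]] / 3))
        if (e$side == "3p") {
          start <- lens[[e$chrom]] - size
          if (overlaps_any(occ[[e$chrom]], start, lens[[e$chrom]], pad)) {
            unpick_end(e); next
          }
          claim(e$chrom, start, lens[[e$chrom]])
          truth[[id]] <- tibble(id = id, svtype = "TDEL", chrom1 = e$chrom,
                                pos1 = as.integer(start), chrom2 = e$chrom,
                                pos2 = lens[[e$chrom]], size = size,
                                zygosity = sp$zygosity, terminal_side = "3p",
                                orientation = NA_character_)
        } else {
          if (overlaps_any(occ[[e$chrom]], 0L, size, pad)) {
            unpick_end(e); next
          }
          claim(e$chrom, 0L, size)
          truth[[id]] <- tibble(id = id, svtype = "TDEL", chrom1 = e$chrom,
                                pos1 = 0L, chrom2 = e$chrom,
                                pos2 = as.integer(size), size = size,
                                zygosity = sp$zygosity, terminal_side = "5p",
                                orientation = NA_character_)
        }
        edits[[id]] <- list(type = "TDEL", chrom = e$chrom, side = e$side,
                            pos = if (e$side == "3p") as.integer(lens[[e$chrom]] - size)
                            else as.integer(size),
                            zygosity = sp$zygosity)
        done <- TRUE
        break
      }
      if (!done) abort("cannot place terminal deletion")
    } else if (sp$svtype == "tra_unbalanced") {
      done <- FALSE
      for (try in seq_len(max_retry)) {
        e <- pick_end() # receiving contig loses this end
        if (is.null(e)) break
        cn_a <- e$chrom
        loss <- draw_size(sp$size_min, min(sp$size_max, lens[[cn_a]] / 3))
        donors <- setdiff(names(lens), cn_a)
        cn_b <- sample(donors, 1)
        tip <- draw_size(2e4, 6e4) # subtelomeric donor tip
        if (e$side == "3p") {
          pa <- lens[[cn_a]] - loss
          pb <- lens[[cn_b]] - tip
          if (overlaps_any(occ[[cn_a]], pa, lens[[cn_a]], pad) ||
              overlaps_any(occ[[cn_b]], pb, lens[[cn_b]], pad)) {
            unpick_end(e); next
          }
          claim(cn_a, pa, lens[[cn_a]])
          claim(cn_b, pb, lens[[cn_b]])
          truth[[id]] <- tibble(id = id, svtype = "BND", chrom1 = cn_a,
                                pos1 = as.integer(pa), chrom2 = cn_b,
                                pos2 = as.integer(pb), size = loss,
                                zygosity = sp$zygosity,
                                terminal_side = "3p", orientation = "+-")
          edits[[id]] <- list(type = "TRA_UNBAL", chrom = cn_a, side = "3p",
                              pa = as.integer(pa), donor = cn_b,
                              pb = as.integer(pb), zygosity = sp$zygosity)
        } else {
          pa <- loss
          pb <- tip
          if (overlaps_any(occ[[cn_a]], 0L, pa, pad) ||
              overlaps_any(occ[[cn_b]], 0L, pb, pad)) {
            unpick_end(e); next
          }
          claim(cn_a, 0L, pa)
          claim(cn_b, 0L, pb)
          # donor prefix attached before the retained suffix
          truth[[id]] <- tibble(id = id, svtype = "BND", chrom1 = cn_b,
                                pos1 = as.integer(pb), chrom2 = cn_a,
                                pos2 = as.integer(pa), size = loss,
                                zygosity = sp$zygosity,
                                terminal_side = "5p", orientation = "+-")
          edits[[id]] <- list(type = "TRA_UNBAL", chrom = cn_a, side = "5p",
                              pa = as.integer(pa), donor = cn_b,
                              pb = as.integer(pb), zygosity = sp$zygosity)
        }
        done <- TRUE
        break
      }
      if (!done) abort("cannot place unbalanced translocation")
    } else { # tra_balanced: reciprocal 3' swap between two contigs
      done <- FALSE
      for (try in seq_len(max_retry)) {
        ends3 <- free_ends[endsWith(free_ends, ":3p")]
        if (length(ends3) < 2) break
        pick <- sample(ends3, 2)
        cn_a <- sub(":3p$", "", pick[1])
        cn_b <- sub(":3p$", "", pick[2])
        sza <- draw_size(5e4, min(2e5, lens[[cn_a]] / 3))
        szb <- draw_size(5e4, min(2e5, lens[[cn_b]] / 3))
        pa <- lens[[cn_a]] - sza
        pb <- lens[[cn_b]] - szb
        if (overlaps_any(occ[[cn_a]], pa, lens[[cn_a]], pad) ||
            overlaps_any(occ[[cn_b]], pb, lens[[cn_b]], pad)) next
        free_ends <- setdiff(free_ends, pick)
        claim(cn_a, pa, lens[[cn_a]])
        claim(cn_b, pb, lens[[cn_b]])
        truth[[id]] <- tibble(id = id, svtype = "BND", chrom1 = cn_a,
                              pos1 = as.integer(pa), chrom2 = cn_b,
                              pos2 = as.integer(pb), size = NA_integer_,
                              zygosity = sp$zygosity,
                              terminal_side = NA_character_,
                              orientation = "+-")
        # reciprocal exchange: two terminal-swap edits
        edits[[paste0(id, "_a")]] <- list(type = "TRA_UNBAL", chrom = cn_a,
                                          side = "3p", pa = as.integer(pa),
                                          donor = cn_b, pb = as.integer(pb),
                                          zygosity = sp$zygosity)
        edits[[paste0(id, "_b")]] <- list(type = "TRA_UNBAL", chrom = cn_b,
                                          side = "3p", pa = as.integer(pb),
                                          donor = cn_a, pb = as.integer(pa),
                                          zygosity = sp$zygosity)
        done <- TRUE
        break
      }
      if (!done) abort("cannot place balanced translocation")
    }
  }
  truth <- bind_rows(truth)
  hap1 <- apply_sv_edits(reference, edits, hap = 1L)
  hap2 <- apply_sv_edits(reference, edits, hap = 2L)
  list(hap1 = hap1, hap2 = hap2, truth = truth)
}

# Apply edit descriptors to the reference to build one haplotype.
# Homozygous edits apply to both haplotypes, heterozygous to hap 1 only.
apply_sv_edits <- function(reference, edits, hap = 1L) {
  edits <- Filter(function(e) hap == 1L || identical(e$zygosity, "hom"), edits)
  lens <- setNames(Biostrings::width(reference), names(reference))
  out <- as.character(reference)
  for (cn in names(out)) {
    ev <- Filter(function(e) identical(e$chrom, cn), edits)
    if (length(ev) == 0) next
    # single left-to-right pass in reference coordinates
    internal <- Filter(function(e) e$type %in% c("DEL", "DUP", "INV"), ev)
    internal <- internal[order(vapply(internal, `[[`, numeric(1), "start"))]
    lo <- 0L
    hi <- lens[[cn]]
    prefix_add <- ""
    suffix_add <- ""
    for (e in ev) {
      if (e$type == "TDEL") {
        if (e$side == "3p") hi <- e$pos else lo <- e$pos
      } else if (e$type == "TRA_UNBAL") {
        if (identical(e$side, "5p")) {
          lo <- e$pa
          prefix_add <- seq_window(reference, e$donor, 0L, e$pb)
        } else {
          hi <- e$pa
          suffix_add <- seq_window(reference, e$donor, e$pb, lens[[e$donor]])
        }
      }
    }
    pieces <- character(0)
    cur <- lo
    for (e in internal) {
      pieces <- c(pieces, seq_window(reference, cn, cur, e$start))
      if (e$type == "DUP") {
        seg <- seq_window(reference, cn, e$start, e$end)
        pieces <- c(pieces, seg, seg)
      } else if (e$type == "INV") {
        pieces <- c(pieces, revcomp(seq_window(reference, cn, e$start, e$end)))
      } # DEL emits nothing
      cur <- e$end
    }
    pieces <- c(pieces, seq_window(reference, cn, cur, hi))
    out[[cn]] <- paste0(prefix_add, paste(pieces, collapse = ""), suffix_add)
  }
  Biostrings::DNAStringSet(out)
}

#' Simulate noisy long reads from a diploid genome
#'
#' Reads are sampled uniformly from the two haplotypes (50/50), with
#' lengths from a log-normal distribution truncated at `max_len`,
#' uniformly random start positions (clipped at contig ends), random
#' strand, and i.i.d. per-base mismatch/insertion/deletion errors.
#'
#' @param hap1,hap2 haplotype [Biostrings::DNAStringSet]s.
#' @param depth target fold coverage over the diploid genome.
#' @param mean_len mean read length (bp).
#' @param sd_log log-scale standard deviation of the length distribution.
#' @param max_len maximum read length (bp).
#' @param min_len reads shorter than this after clipping are dropped.
#' @param err_mis,err_ins,err_del per-base error rates.
#' @param seed RNG seed.
#' @return List with `reads` (tibble `id`, `seq`) and `origins` (tibble
#'   `id`, `hap`, `chrom`, `start`, `end`, `strand`).
#' @export
simulate_reads <- function(hap1, hap2, depth = 4, mean_len = 8000,
                           sd_log = 0.5, max_len = 20000L, min_len = 300L,
                           err_mis = 0.04, err_ins = 0.03, err_del = 0.03,
                           seed = 1L) {
  set.seed(seed + 2L)
  haps <- list(hap1, hap2)
  hsizes <- vapply(haps, function(h) sum(Biostrings::width(h)), numeric(1))
  total_target <- depth * mean(hsizes)
  meanlog <- log(mean_len) - sd_log^2 / 2
  reads <- list()
  origins <- list()
  total <- 0
  idx <- 0L
  while (total < total_target) {
    idx <- idx + 1L
    h <- sample(1:2, 1)
    hs <- haps[[h]]
    wl <- Biostrings::width(hs)
    ci <- sample(seq_along(hs), 1, prob = wl)
    len <- min(max_len, max(min_len, round(rlnorm(1, meanlog, sd_log))))
    # fragments spanning a molecule end are truncated there, so both
    # contig ends accumulate read-boundary pileups
    start <- floor(runif(1, -len + min_len, wl[ci] - min_len))
    end <- min(wl[ci], start + len)
    start <- max(0L, start)
    if (end - start < min_len) next
    tmpl <- as.character(Biostrings::subseq(hs[[ci]], start + 1, end))
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") tmpl <- revcomp(tmpl)
    seqv <- inject_errors(tmpl, err_mis, err_ins, err_del)
    rid <- sprintf("read_%06d", idx)
    reads[[idx]] <- seqv
    origins[[idx]] <- tibble(id = rid, hap = h, chrom = names(hs)[ci],
                             start = start, end = end, strand = strand)
    total <- total + (end - start)
  }
  origins <- bind_rows(origins)
  list(reads = tibble(id = origins$id, seq = unlist(reads)),
       origins = origins)
}

# i.i.d. per-base error injection, operating on raw bytes for speed
inject_errors <- function(seq, err_mis, err_ins, err_del) {
  if (err_mis == 0 && err_ins == 0 && err_del == 0) return(seq)
  ACGT <- charToRaw("ACGT")
  r <- charToRaw(seq)
  n <- length(r)
  r <- r[runif(n) >= err_del]
  n2 <- length(r)
  if (n2 == 0) return("")
  mis <- which(runif(n2) < err_mis)
  if (length(mis) > 0) {
    sub <- sample(ACGT, length(mis), replace = TRUE)
    same <- sub == r[mis]
    while (any(same)) { # force a real substitution
      sub[same] <- sample(ACGT, sum(same), replace = TRUE)
      same <- sub == r[mis]
    }
    r[mis] <- sub
  }
  ins <- which(runif(n2) < err_ins)
  if (length(ins) > 0) {
    pos <- sort(c(seq_len(n2), ins + 0.5))
    out <- r[floor(pos)]
    out[pos != floor(pos)] <- sample(ACGT, length(ins), replace = TRUE)
    r <- out
  }
  rawToChar(r)
}

#' Simulate a reference panel of normal low-depth samples
#'
#' Per-interval depths are drawn as a shared per-interval bias factor
#' (log-normal, emulating region-specific sequencing bias) times
#' per-sample Poisson noise at the target depth, then normalized to the
#' target genome-wide mean.
#'
#' @param reference [Biostrings::DNAStringSet] (defines the binning).
#' @param n number of panel samples (>= 2).
#' @param depth nominal per-sample depth.
#' @param L interval size (bp).
#' @param bias_sd log-scale SD of the shared interval bias.
#' @param mean_len mean read length controlling count granularity.
#' @param mask_terminal intervals overlapping this many bp at either
#'   contig end get zero bias, emulating the unmappable telomeric tracts
#'   that a real panel masks ([build_panel()] then masks them via its
#'   `mu_min` rule).
#' @param seed RNG seed.
#' @return List of normalized `depth_profile`s, one per sample.
#' @export
simulate_panel <- function(reference, n = 24L, depth = 4, L = 10000L,
                           bias_sd = 0.15, mean_len = 8000,
                           mask_terminal = 5000L, seed = 1L) {
  stopifnot(n >= 2)
  set.seed(seed + 3L)
  lens <- setNames(Biostrings::width(reference), names(reference))
  grid <- purrr::map_dfr(names(lens), function(cn) {
    n_iv <- ceiling(lens[[cn]] / L)
    start <- (seq_len(n_iv) - 1L) * L
    tibble(chrom = cn, iv = seq_len(n_iv) - 1L, start = start,
           end = pmin(start + L, lens[[cn]]))
  })
  width <- grid$end - grid$start
  bias <- rlnorm(nrow(grid), 0, bias_sd)
  if (mask_terminal > 0) {
    clen <- lens[grid$chrom]
    bias[grid$start < mask_terminal | grid$end > clen - mask_terminal] <- 0
  }
  lapply(seq_len(n), function(s) {
    lam <- depth * bias * width / mean_len
    d <- rpois(nrow(grid), lam) * mean_len / width
    prof <- mutate(grid, depth = d)
    gm <- sum(prof$depth * width) / sum(width)
    prof <- structure(prof, L = as.integer(L), genome_mean = gm,
                      class = c("depth_profile", class(prof)))
    normalize_profile(prof, depth)
  })
}
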