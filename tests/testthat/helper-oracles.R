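# Independent oracles used across the suite. These deliberately use
# different algorithmic routes than the package internals: global
# Needleman-Wunsch over enumerated substrings instead of semi-global
# row-max DPs, and a regex CIGAR walker instead of the tokenizer-based
# arithmetic.

# global affine alignment score of q vs s; gap of length L costs
# gap_open + L * gap_extend
nw_affine <- function(q, s, match = 2, mismatch = -4, gap_open = -4,
                      gap_extend = -2) {
  n <- nchar(q); m <- nchar(s)
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap consuming s
  Y <- matrix(NEG, n + 1, m + 1) # gap consuming q
  M[1, 1] <- 0
  for (j in seq_len(m)) X[1, j + 1] <- gap_open + j * gap_extend
  for (i in seq_len(n)) Y[i + 1, 1] <- gap_open + i * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (qc[i] == sc[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub
      X[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             X[i + 1, j] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             Y[i, j + 1] + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# best score of fully aligning q against ANY substring of s (including
# the empty substring), by exhaustive enumeration
best_substring_score <- function(q, s, ...) {
  n <- nchar(q); m <- nchar(s)
  if (n == 0) return(0)
  best <- nw_affine(q, "", ...)
  for (a in seq_len(m)) {
    for (b in a:m) {
      best <- max(best, nw_affine(q, substr(s, a, b), ...))
    }
  }
  best
}

# brute-force SV-DP: maximize over every split q' of
# prefix-vs-RA + suffix-vs-RB + jump_cost, and the no-jump score
svdp_brute <- function(qwin, ra, rb, jump_cost = 0, ...) {
  n <- nchar(qwin)
  best <- -Inf
  for (qp in 0:n) {
    f <- best_substring_score(substr(qwin, 1, qp), ra, ...)
    b <- best_substring_score(substr(qwin, qp + 1, n), rb, ...)
    best <- max(best, f + b + jump_cost)
  }
  no_jump <- max(best_substring_score(qwin, ra, ...),
                 best_substring_score(qwin, rb, ...))
  list(score_with_jump = best, score_without_jump = no_jump)
}

# independent CIGAR walk via regex, computing forward-read coordinates
cigar_walk_oracle <- function(cigar, strand) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", m))
  ops <- sub("^[0-9]+", "", m)
  clip_lead <- 0L
  i <- 1
  while (i <= length(ops) && ops[i] %in% c("S", "H")) {
    clip_lead <- clip_lead + lens[i]; i <- i + 1
  }
  clip_trail <- 0L
  i <- length(ops)
  while (i >= 1 && ops[i] %in% c("S", "H")) {
    clip_trail <- clip_trail + lens[i]; i <- i - 1
  }
  qlen <- sum(lens[ops %in% c("M", "I", "=", "X")])
  total <- clip_lead + qlen + clip_trail
  if (strand == "-") {
    tmp <- clip_lead; clip_lead <- clip_trail; clip_trail <- tmp
  }
  list(q_start = clip_lead, q_end = total - clip_trail,
       r_span = sum(lens[ops %in% c("M", "D", "N", "=", "X")]))
}

# random CIGAR generator for property tests
random_cigar <- function() {
  ops <- c("M")
  lens <- sample(50:500, 1)
  body_ops <- sample(c("M", "I", "D"), sample(1:6, 1), replace = TRUE)
  body_lens <- sample(1:300, length(body_ops), replace = TRUE)
  # ensure alignment starts and ends with M
  ops <- c("M", body_ops, "M")
  lens <- c(sample(50:400, 1), body_lens, sample(50:400, 1))
  lead <- if (runif(1) < 0.6) sprintf("%dS", sample(1:2000, 1)) else ""
  trail <- if (runif(1) < 0.6) sprintf("%dS", sample(1:2000, 1)) else ""
  paste0(lead, paste0(lens, ops, collapse = ""), trail)
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal SAM text builder
write_test_sam <- function(path, contigs, records) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(contigs), "\tLN:", unname(contigs)))
  lines <- vapply(records, function(r) {
    paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, "*", 0, 0,
          r$seq, "*", sep = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  path
}

# small deterministic diploid fixture shared by pipeline-level tests
small_fixture <- function(seed = 5L) {
  genome <- make_reference(c(3e5, 2.5e5), seed = seed)
  specs <- tibble::tibble(svtype = c("del_short", "inv"),
                          size_min = c(5e4, 5e4), size_max = c(6e4, 6e4),
                          zygosity = "het")
  imp <- implant_svs(genome, specs, seed = seed)
  sim <- simulate_reads(imp$hap1, imp$hap2, depth = 4, mean_len = 8000,
                        err_mis = 0.04, err_ins = 0.02, err_del = 0.02,
                        seed = seed)
  panel <- simulate_panel(genome, n = 12, depth = 4, seed = seed)
  list(genome = genome, imp = imp, sim = sim, panel = panel)
}

# memo for expensive benchmark runs shared between acceptance blocks
.bench_cache <- new.env(parent = emptyenv())
bench_run <- function(seed, zygosity) {
  key <- paste0(zygosity, "_", seed)
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- run_synthetic_benchmark(seed = seed,
                                                   zygosity = zygosity)
  .bench_cache[[key]]
}
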