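# Depth profiles, panel statistics, the likelihood-ratio test and region
# merging.

toy_genome <- function(lens = c(chrA = 50000L)) {
  Biostrings::DNAStringSet(vapply(lens, function(n) rand_seq(n), "",
                                  USE.NAMES = TRUE))
}

seg_row <- function(chrom, r_start, r_end) {
  tibble::tibble(read_id = "r", q_start = 0L, q_end = r_end - r_start,
                 chrom = chrom, r_start = r_start, r_end = r_end,
                 strand = "+", mapq = 60L, is_supplementary = FALSE,
                 n_match = r_end - r_start, cigar = NA_character_)
}

test_that("interval depth counts aligned bases per interval", {
  g <- toy_genome(c(chrA = 25000L))
  empty <- seg_row("chrA", 1L, 2L)[0, ]
  p0 <- compute_depth_profile(empty, g, L = 10000L)
  expect_equal(p0$depth, c(0, 0, 0))
  # one segment exactly covering one interval
  p1 <- compute_depth_profile(seg_row("chrA", 10000L, 20000L), g, 10000L)
  expect_equal(p1$depth, c(0, 1, 0))
  # segment straddling two intervals half/half
  p2 <- compute_depth_profile(seg_row("chrA", 5000L, 15000L), g, 10000L)
  expect_equal(p2$depth, c(0.5, 0.5, 0))
  # last partial interval normalized by its true width
  p3 <- compute_depth_profile(seg_row("chrA", 20000L, 25000L), g, 10000L)
  expect_equal(p3$depth[3], 1)
})

test_that("normalization scales to the target mean and rejects empty profiles", {
  g <- toy_genome(c(chrA = 20000L))
  p <- compute_depth_profile(seg_row("chrA", 0L, 20000L), g, 10000L)
  attr(p, "genome_mean") <- 8
  p$depth <- c(8, 8)
  n <- normalize_profile(p, 4)
  expect_equal(n$depth, c(4, 4))
  expect_equal(attr(n, "genome_mean"), 4)
  p$depth <- c(0, 16)
  attr(p, "genome_mean") <- 8
  expect_equal(normalize_profile(p, 4)$depth, c(0, 8))
  attr(p, "genome_mean") <- 0
  expect_error(normalize_profile(p), "empty")
})

fake_profile <- function(depths, L = 10000L) {
  n <- length(depths)
  p <- tibble::tibble(chrom = "chrA", iv = seq_len(n) - 1L,
                      start = (seq_len(n) - 1L) * L,
                      end = seq_len(n) * L, depth = depths)
  structure(p, L = L, genome_mean = mean(depths),
            class = c("depth_profile", class(p)))
}

test_that("panel statistics use sample sd with flooring and masking", {
  p1 <- fake_profile(c(4, 3, 0.1))
  p2 <- fake_profile(c(4, 5, 0.1))
  pan <- build_panel(list(p1, p2), sigma_min = 0.3, mu_min = 0.5)
  expect_equal(pan$mu, c(4, 4, 0.1))
  # zero variance floored; {3,5} -> sd sqrt(2)
  expect_equal(pan$sigma, c(0.3, sqrt(2), 0.3))
  expect_equal(pan$mask, c(FALSE, FALSE, TRUE))
  expect_error(build_panel(list(p1, fake_profile(c(4, 4)))), "binning")
  expect_error(build_panel(list(p1)))
})

test_that("panel TSV round-trips", {
  pan <- build_panel(list(fake_profile(c(4, 3)), fake_profile(c(4, 5))))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_panel(pan, p)
  back <- read_panel(p)
  expect_equal(attr(back, "L"), attr(pan, "L"))
  expect_equal(attr(back, "n_samples"), 2L)
  expect_equal(back$mu, pan$mu)
  expect_equal(back$sigma, pan$sigma)
  expect_equal(back$mask, pan$mask)
})

test_that("interval llr matches its closed forms and the normal likelihoods", {
  # spec closed-form examples
  expect_equal(interval_llr(3, 4, 1, "del"), 0)
  expect_equal(interval_llr(2, 4, 1, "del"), 2)
  expect_equal(interval_llr(6, 4, 1, "dup"), 2)
  # closed forms against a direct two-model log-likelihood computation
  grid <- expand.grid(d = seq(0, 10, by = 0.25), mu = c(2, 4, 6),
                      sigma = c(0.3, 1, 2))
  for (mode in c("del", "dup")) {
    mu_sv <- if (mode == "del") 0.5 * grid$mu else 1.5 * grid$mu
    direct <- dnorm(grid$d, mu_sv, grid$sigma, log = TRUE) -
      dnorm(grid$d, grid$mu, grid$sigma, log = TRUE)
    closed <- if (mode == "del") {
      grid$mu * (0.75 * grid$mu - grid$d) / (2 * grid$sigma^2)
    } else {
      grid$mu * (grid$d - 1.25 * grid$mu) / (2 * grid$sigma^2)
    }
    got <- interval_llr(grid$d, grid$mu, grid$sigma, mode)
    expect_lt(max(abs(got - direct)), 1e-9)
    expect_lt(max(abs(got - closed)), 1e-9)
  }
  expect_error(interval_llr(1, 4, 0, "del"), "sigma")
})

test_that("llr is linear in d and flips sign exactly at the midpoints", {
  d <- seq(0, 8, by = 0.5)
  l <- interval_llr(d, 4, 1, "del")
  expect_equal(diff(l), rep(diff(l)[1], length(d) - 1)) # linear
  eps <- 1e-9
  expect_gt(interval_llr(3 - eps, 4, 1, "del"), 0)
  expect_lt(interval_llr(3 + eps, 4, 1, "del"), 0)
  expect_lt(interval_llr(5 - eps, 4, 1, "dup"), 0)
  expect_gt(interval_llr(5 + eps, 4, 1, "dup"), 0)
  # antisymmetry about the midpoint
  expect_equal(interval_llr(3 - 1, 4, 1, "del"),
               -interval_llr(3 + 1, 4, 1, "del"))
})

test_that("abnormality flags respect the mask and the strict inequality", {
  prof <- fake_profile(c(4, 2, 0))
  pan <- build_panel(list(fake_profile(c(4, 4, 0.1)),
                          fake_profile(c(4, 4, 0.1))))
  fl <- flag_abnormal(prof, pan, "del")
  expect_equal(fl, c(FALSE, TRUE, FALSE)) # d = mu normal; masked never abnormal
})

test_that("greedy merging bridges small gaps only", {
  prof <- fake_profile(rep(4, 6))
  # [A,A,N,A] with max_gap 2 -> one region over intervals 0..3
  r1 <- merge_abnormal(prof[1:4, ], c(TRUE, TRUE, FALSE, TRUE), "del", 2L)
  expect_equal(nrow(r1), 1L)
  expect_equal(c(r1$start_iv, r1$end_iv), c(0L, 4L))
  expect_equal(c(r1$start, r1$end), c(0L, 40000L))
  # [A,N,N,N,A] with max_gap 2 -> two singleton regions
  r2 <- merge_abnormal(prof[1:5, ], c(TRUE, FALSE, FALSE, FALSE, TRUE),
                       "del", 2L)
  expect_equal(nrow(r2), 2L)
  expect_equal(r2$start_iv, c(0L, 4L))
  # all-normal -> empty
  expect_equal(nrow(merge_abnormal(prof, rep(FALSE, 6), "del", 2L)), 0L)
})

test_that("merged regions are disjoint, sorted and cover all abnormal intervals", {
  set.seed(7)
  for (rep in 1:25) {
    n <- 60
    flags <- runif(n) < 0.3
    prof <- fake_profile(rep(4, n))
    regs <- merge_abnormal(prof, flags, "del", max_gap = 2L)
    if (nrow(regs) == 0) { expect_false(any(flags)); next }
    expect_true(all(diff(regs$start_iv) > 0))
    expect_true(all(regs$end_iv[-nrow(regs)] <= regs$start_iv[-1]))
    covered <- unlist(Map(seq, regs$start_iv, regs$end_iv - 1L))
    expect_true(all((which(flags) - 1L) %in% covered))
    # every region's first and last interval are abnormal
    expect_true(all(flags[regs$start_iv + 1L]))
    expect_true(all(flags[regs$end_iv]))
  }
})

test_that("region p-values follow the chi-square with one degree of freedom", {
  pan <- build_panel(list(fake_profile(c(4, 4, 4)), fake_profile(c(4, 4, 4))),
                     sigma_min = 1)
  reg <- tibble::tibble(chrom = "chrA", start_iv = 0L, end_iv = 3L,
                        start = 0L, end = 30000L, mode = "del")
  # three intervals each llr = 2 -> Lambda = 12
  prof <- fake_profile(c(2, 2, 2))
  pv <- region_pvalue(reg, prof, pan)
  expect_equal(pv$lambda, 12)
  expect_equal(pv$pvalue, 5.32e-4, tolerance = 0.01)
  # single interval llr = 2 -> Lambda = 4, p ~ 0.0455
  reg1 <- dplyr::mutate(reg, end_iv = 1L, end = 10000L)
  pv1 <- region_pvalue(reg1, fake_profile(c(2, 4, 4)), pan)
  expect_equal(pv1$lambda, 4)
  expect_equal(pv1$pvalue, 0.0455, tolerance = 0.01)
  # Lambda clipped at zero -> p = 1
  pv0 <- region_pvalue(reg, fake_profile(c(4.5, 4.5, 4.5)), pan)
  expect_equal(pv0$lambda, 0)
  expect_equal(pv0$pvalue, 1)
})

test_that("zygosity is classified by the nearest depth model", {
  expect_equal(classify_zygosity(0.1, 4, "del"), "hom")
  expect_equal(classify_zygosity(2.0, 4, "del"), "het") # exactly the het mean
  expect_equal(classify_zygosity(6.0, 4, "dup"), "het")
  expect_equal(classify_zygosity(7.9, 4, "dup"), "hom")
})

# depth simulation at aggregated granularity: per-interval aligned-base
# counts in 100-bp units, so interval noise is the few-percent scale at
# which rough interval-level breakpoints are meaningful
sim_depth <- function(n_iv, depth, L = 10000L, unit = 100) {
  rpois(n_iv, depth * L / unit) * unit / L
}

test_that("implanted het deletions are recovered at interval resolution", {
  set.seed(11)
  n_iv <- 200
  hits <- 0
  for (rep in 1:100) {
    panel <- lapply(1:12, function(i) fake_profile(sim_depth(n_iv, 4)))
    pan <- build_panel(panel)
    start <- sample(20:150, 1)
    len <- sample(5:12, 1)
    depths <- sim_depth(n_iv, 4)
    depths[start:(start + len - 1)] <- sim_depth(len, 2)
    prof <- fake_profile(depths)
    regs <- depth_candidates(prof, pan, alpha = 0.05)
    regs <- regs[regs$mode == "del", ]
    ok <- any(abs(regs$start_iv - (start - 1)) <= 1 &
                abs(regs$end_iv - (start + len - 1)) <= 1)
    hits <- hits + ok
  }
  expect_gte(hits, 95)
})

test_that("the null genome keeps almost no intervals in candidate regions", {
  set.seed(12)
  frac <- numeric(100)
  for (rep in 1:100) {
    n_iv <- 1000
    pan <- build_panel(lapply(1:12, function(i) fake_profile(sim_depth(n_iv, 4))))
    prof <- fake_profile(sim_depth(n_iv, 4))
    regs <- depth_candidates(prof, pan, alpha = 0.05)
    inside <- if (nrow(regs) == 0) 0 else sum(regs$end_iv - regs$start_iv)
    frac[rep] <- inside / n_iv
  }
  expect_lt(mean(frac), 0.01)
})
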