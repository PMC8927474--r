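# Read-depth CNV detection: per-interval depth profiles, a reference panel
# of normal samples, a two-model Gaussian likelihood-ratio test per
# interval, greedy merging of abnormal intervals, and a chi-square p-value
# per merged region.

#' Compute a per-interval depth profile from alignment segments
#'
#' The genome is partitioned into intervals of `L` bp (default 10 kbp) and
#' each interval's depth is the number of aligned reference bases
#' overlapping it divided by the interval width; the last partial interval
#' is normalized by its true width.
#'
#' @param segments alignment tibble from [read_alignments()] (columns
#'   `chrom`, `r_start`, `r_end`).
#' @param genome reference [Biostrings::DNAStringSet] (defines contigs and
#'   lengths).
#' @param L interval size in bp.
#' @return A tibble of class `depth_profile` with columns `chrom`, `iv`
#'   (0-based interval index), `start`, `end`, `depth`, and attributes
#'   `L` and `genome_mean`.
#' @export
compute_depth_profile <- function(segments, genome, L = 10000L) {
  stopifnot(L > 0)
  L <- as.integer(L)
  lens <- setNames(Biostrings::width(genome), names(genome))
  prof <- purrr::map_dfr(names(lens), function(cn) {
    clen <- lens[[cn]]
    seg <- segments[segments$chrom == cn, , drop = FALSE]
    cov <- .interval_coverage_core(as.integer(seg$r_start),
                                   as.integer(seg$r_end), L, clen)
    n_iv <- length(cov)
    start <- (seq_len(n_iv) - 1L) * L
    end <- pmin(start + L, clen)
    tibble(chrom = cn, iv = seq_len(n_iv) - 1L, start = start, end = end,
           depth = as.numeric(cov) / (end - start))
  })
  gm <- sum(prof$depth * (prof$end - prof$start)) / sum(prof$end - prof$start)
  structure(prof, L = L, genome_mean = gm,
            class = c("depth_profile", class(prof)))
}

#' Normalize a depth profile to a target genome-wide mean
#'
#' All interval depths are scaled by `target_depth / genome_mean` so every
#' sample is comparable at the same nominal coverage (4x by default).
#'
#' @param profile a `depth_profile`.
#' @param target_depth target genome-wide mean depth.
#' @return The rescaled `depth_profile`.
#' @export
normalize_profile <- function(profile, target_depth = 4.0) {
  gm <- attr(profile, "genome_mean")
  if (is.null(gm) || gm <= 0) abort("empty profile")
  profile$depth <- profile$depth * (target_depth / gm)
  attr(profile, "genome_mean") <- target_depth
  profile
}

#' Build a reference panel from normalized depth profiles
#'
#' Per interval, `mu` is the sample mean and `sigma` the sample standard
#' deviation (denominator n-1) across panel samples, floored at
#' `sigma_min`; intervals with `mu < mu_min` (unmappable or N-gap regions)
#' are masked and excluded from all tests.
#'
#' @param profiles list of normalized `depth_profile`s with identical
#'   binning.
#' @param sigma_min floor on the per-interval standard deviation
#'   (fold-coverage units).
#' @param mu_min minimum mean depth for an interval to stay usable.
#' @return A tibble of class `reference_panel` with columns `chrom`, `iv`,
#'   `start`, `end`, `mu`, `sigma`, `mask`, and attributes `L`,
#'   `n_samples`.
#' @export
build_panel <- function(profiles, sigma_min = 0.3, mu_min = 0.5) {
  stopifnot(length(profiles) >= 2)
  L <- attr(profiles[[1]], "L")
  key <- paste(profiles[[1]]$chrom, profiles[[1]]$iv)
  for (p in profiles[-1]) {
    if (!identical(attr(p, "L"), L) || !identical(paste(p$chrom, p$iv), key))
      abort("panel profiles have mismatched binning")
  }
  d <- do.call(cbind, lapply(profiles, `[[`, "depth"))
  mu <- rowMeans(d)
  sg <- pmax(apply(d, 1, sd), sigma_min)
  out <- tibble(chrom = profiles[[1]]$chrom, iv = profiles[[1]]$iv,
                start = profiles[[1]]$start, end = profiles[[1]]$end,
                mu = mu, sigma = sg, mask = mu < mu_min)
  structure(out, L = L, n_samples = length(profiles),
            class = c("reference_panel", class(out)))
}

#' Per-interval log-likelihood ratio between the SV and no-SV depth models
#'
#' The observed depth `d` is compared under `N(mu_sv, sigma^2)` versus
#' `N(mu, sigma^2)`, where `mu_sv = 0.5 mu` for deletions and `1.5 mu` for
#' duplications (heterozygous expectation). The ratio reduces to the closed
#' forms `mu (0.75 mu - d) / (2 sigma^2)` (del) and
#' `mu (d - 1.25 mu) / (2 sigma^2)` (dup); positive values favour the SV
#' model.
#'
#' @param d observed depth (vectorized).
#' @param mu panel mean depth.
#' @param sigma panel standard deviation (> 0).
#' @param mode `"del"` or `"dup"`.
#' @return Numeric vector of log-likelihood ratios.
#' @export
#' @examples
#' interval_llr(2, 4, 1, "del") # deletion strongly favoured
interval_llr <- function(d, mu, sigma, mode = c("del", "dup")) {
  mode <- match.arg(mode)
  if (any(sigma <= 0)) abort("sigma must be positive")
  mu_sv <- if (mode == "del") 0.5 * mu else 1.5 * mu
  ((d - mu)^2 - (d - mu_sv)^2) / (2 * sigma^2)
}

#' Flag intervals whose depth favours the SV model
#'
#' An interval is abnormal iff it is usable (unmasked) and its
#' log-likelihood ratio is strictly positive; ties go to normal.
#'
#' @param profile normalized `depth_profile` of the analyzed sample.
#' @param panel `reference_panel` with matching binning.
#' @param mode `"del"` or `"dup"`.
#' @return Logical vector along the profile rows.
#' @export
flag_abnormal <- function(profile, panel, mode = c("del", "dup")) {
  mode <- match.arg(mode)
  if (!identical(paste(profile$chrom, profile$iv), paste(panel$chrom, panel$iv)))
    abort("profile and panel binning differ")
  llr <- interval_llr(profile$depth, panel$mu, panel$sigma, mode)
  !panel$mask & llr > 0
}

#' Merge abnormal intervals into candidate regions
#'
#' Greedy left-to-right scan per contig: a run of abnormal intervals
#' absorbs subsequent abnormal intervals separated by at most `max_gap`
#' normal intervals. The region spans from its first to its last abnormal
#' interval; rough breakpoints are the bp bounds of those intervals.
#'
#' @param profile the sample `depth_profile` (supplies coordinates).
#' @param flags logical vector from [flag_abnormal()].
#' @param mode `"del"` or `"dup"` (recorded on the output).
#' @param max_gap maximum number of bridged normal intervals.
#' @return Tibble with one row per region: `chrom`, `start_iv`, `end_iv`
#'   (half-open interval indices), `start`, `end` (rough breakpoints in
#'   bp), `mode`.
#' @export
merge_abnormal <- function(profile, flags, mode = "del", max_gap = 2L) {
  out <- list()
  for (cn in unique(profile$chrom)) {
    sel <- which(profile$chrom == cn)
    f <- flags[sel]
    idx <- which(f)
    if (length(idx) == 0) next
    runs <- split(idx, cumsum(c(1L, diff(idx) > max_gap + 1L)))
    for (r in runs) {
      i0 <- min(r); i1 <- max(r)
      out[[length(out) + 1]] <- tibble(
        chrom = cn, start_iv = profile$iv[sel[i0]],
        end_iv = profile$iv[sel[i1]] + 1L,
        start = profile$start[sel[i0]], end = profile$end[sel[i1]],
        mode = mode)
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start_iv = integer(),
                  end_iv = integer(), start = integer(), end = integer(),
                  mode = character()))
  }
  bind_rows(out) |> arrange(.data$chrom, .data$start)
}

#' Chi-square p-value for a merged depth region
#'
#' The region statistic is `Lambda = 2 * max(0, sum of interval
#' log-likelihood ratios over usable intervals)`; under the null it is
#' referred to a chi-square distribution with one degree of freedom (one
#' free parameter, the copy-number state), and the upper-tail probability
#' is the region p-value.
#'
#' @param region one row of [merge_abnormal()] output.
#' @param profile the sample `depth_profile`.
#' @param panel the `reference_panel`.
#' @return List with `lambda`, `pvalue`, `mean_depth`, `mean_mu`.
#' @export
region_pvalue <- function(region, profile, panel) {
  sel <- profile$chrom == region$chrom &
    profile$iv >= region$start_iv & profile$iv < region$end_iv & !panel$mask
  llr <- interval_llr(profile$depth[sel], panel$mu[sel], panel$sigma[sel],
                      region$mode)
  lambda <- 2 * max(0, sum(llr))
  list(lambda = lambda, pvalue = pchisq(lambda, df = 1, lower.tail = FALSE),
       mean_depth = mean(profile$depth[sel]), mean_mu = mean(panel$mu[sel]))
}

#' Classify region zygosity by nearest depth model
#'
#' Deletions: homozygous iff the region mean depth is closer to 0 than to
#' `0.5 mu`; duplications: homozygous iff closer to `2 mu` than to
#' `1.5 mu`. Ties go to heterozygous.
#'
#' @param mean_depth region mean depth.
#' @param mean_mu region mean panel depth.
#' @param mode `"del"` or `"dup"`.
#' @return `"het"` or `"hom"`.
#' @export
classify_zygosity <- function(mean_depth, mean_mu, mode = c("del", "dup")) {
  mode <- match.arg(mode)
  if (mode == "del") {
    if (mean_depth < 0.25 * mean_mu) "hom" else "het"
  } else {
    if (mean_depth > 1.75 * mean_mu) "hom" else "het"
  }
}

#' Depth-based SV candidate regions
#'
#' Runs the full depth route for both modes: flag abnormal intervals,
#' merge them greedily, compute region p-values, keep regions with
#' `p <= alpha`, and attach a zygosity hint.
#'
#' @param profile normalized sample `depth_profile`.
#' @param panel `reference_panel`.
#' @param alpha significance threshold on the region p-value.
#' @param max_gap passed to [merge_abnormal()].
#' @return Tibble of kept regions with `chrom`, `start`, `end`, `mode`,
#'   `lambda`, `pvalue`, `zygosity`.
#' @export
depth_candidates <- function(profile, panel, alpha = 0.05, max_gap = 2L) {
  out <- list()
  for (mode in c("del", "dup")) {
    fl <- flag_abnormal(profile, panel, mode)
    regs <- merge_abnormal(profile, fl, mode, max_gap)
    for (i in seq_len(nrow(regs))) {
      pv <- region_pvalue(regs[i, ], profile, panel)
      if (pv$pvalue <= alpha) {
        out[[length(out) + 1]] <- mutate(
          regs[i, ], lambda = pv$lambda, pvalue = pv$pvalue,
          zygosity = classify_zygosity(pv$mean_depth, pv$mean_mu, mode))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start_iv = integer(),
                  end_iv = integer(), start = integer(), end = integer(),
                  mode = character(), lambda = double(), pvalue = double(),
                  zygosity = character()))
  }
  bind_rows(out) |> arrange(.data$chrom, .data$start)
}

#' Serialize a reference panel to TSV
#'
#' Tab-separated columns (contig, interval index, start, end, mu, sigma,
#' mask) preceded by a two-line header recording the interval size and the
#' number of panel samples.
#'
#' @param panel a `reference_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#L=", attr(panel, "L")),
               paste0("#n_samples=", attr(panel, "n_samples"))), con)
  write.table(as.data.frame(panel), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a reference panel written by [write_panel()]
#'
#' @param path panel TSV path.
#' @return A `reference_panel` tibble.
#' @export
read_panel <- function(path) {
  hd <- readLines(path, n = 2)
  L <- as.integer(sub("#L=", "", hd[1]))
  n <- as.integer(sub("#n_samples=", "", hd[2]))
  x <- as_tibble(read.table(path, header = TRUE, sep = "\t", skip = 2,
                            colClasses = c("character", "integer", "integer",
                                           "integer", "numeric", "numeric",
                                           "logical")))
  structure(x, L = L, n_samples = n,
            class = c("reference_panel", class(x)))
}
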