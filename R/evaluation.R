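# Type-aware benchmarking of called SVs against a truth set with a
# breakpoint-distance allowance.

# breakpoint distance between a call and a truth record, or NA if the
# pair is incompatible; terminal deletions only require the internal
# breakpoint when the truth's other breakpoint sits at the contig end
pair_distance <- function(call, truth, bnd_for_translocation = TRUE) {
  tt <- truth$svtype
  ct <- call$svtype
  compatible <-
    (tt == ct) ||
    (tt == "TDEL" && ct %in% c("DEL", "TDEL")) ||
    (tt == "DEL" && ct == "TDEL") ||
    (tt %in% c("BND", "TRA") && ct == "BND" && bnd_for_translocation)
  if (!compatible) return(NA_real_)
  if (tt %in% c("BND", "TRA")) {
    if (call$chrom1 == truth$chrom1 && call$chrom2 == truth$chrom2) {
      return(abs(call$pos1 - truth$pos1) + abs(call$pos2 - truth$pos2))
    }
    if (call$chrom1 == truth$chrom2 && call$chrom2 == truth$chrom1) {
      return(abs(call$pos1 - truth$pos2) + abs(call$pos2 - truth$pos1))
    }
    return(NA_real_)
  }
  if (call$chrom1 != truth$chrom1) return(NA_real_)
  if (tt == "TDEL" || ct == "TDEL") {
    side <- if (!is.null(truth$terminal_side) && !is.na(truth$terminal_side))
      truth$terminal_side else "3p"
    d <- if (side == "5p") abs(call$pos2 - truth$pos2)
    else abs(call$pos1 - truth$pos1)
    return(2 * d) # single-breakpoint distance, scaled onto the pair metric
  }
  abs(call$pos1 - truth$pos1) + abs(call$pos2 - truth$pos2)
}

# per-breakpoint worst-case distance used against max_dist
pair_max_bp_dist <- function(call, truth) {
  tt <- truth$svtype
  if (tt %in% c("BND", "TRA")) {
    d1 <- abs(call$pos1 - truth$pos1) + abs(call$pos2 - truth$pos2)
    d2 <- abs(call$pos1 - truth$pos2) + abs(call$pos2 - truth$pos1)
    if (call$chrom1 == truth$chrom1 && call$chrom2 == truth$chrom2 &&
        call$chrom1 == truth$chrom2) {
      return(min(max(abs(call$pos1 - truth$pos1), abs(call$pos2 - truth$pos2)),
                 max(abs(call$pos1 - truth$pos2), abs(call$pos2 - truth$pos1))))
    }
    if (call$chrom1 == truth$chrom1 && call$chrom2 == truth$chrom2)
      return(max(abs(call$pos1 - truth$pos1), abs(call$pos2 - truth$pos2)))
    return(max(abs(call$pos1 - truth$pos2), abs(call$pos2 - truth$pos1)))
  }
  if (tt == "TDEL" || call$svtype == "TDEL") {
    side <- if (!is.null(truth$terminal_side) && !is.na(truth$terminal_side))
      truth$terminal_side else "3p"
    return(if (side == "5p") abs(call$pos2 - truth$pos2)
           else abs(call$pos1 - truth$pos1))
  }
  max(abs(call$pos1 - truth$pos1), abs(call$pos2 - truth$pos2))
}

#' Match SV calls against a truth set
#'
#' Calls are first filtered to SVs of at least `min_size` bp (breakends
#' excepted) and supported types. A truth record is a true positive iff
#' some call of a compatible type (translocation truth may match BND
#' calls) has every breakpoint within `max_dist` bp; matching is
#' one-to-one and greedy by smallest total breakpoint distance.
#' Unmatched calls are false positives, unmatched truth records false
#' negatives.
#'
#' @param calls call tibble (from [read_vcf()] or the pipeline).
#' @param truth truth tibble (needs `svtype`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`; optional `terminal_side`).
#' @param max_dist breakpoint distance allowance in bp (100 or 2000 in
#'   the standard protocol).
#' @param min_size minimum SV size for calls to be considered.
#' @param bnd_for_translocation allow BND calls to match translocation
#'   truth records.
#' @return An object of class `sv_eval`: list with `summary` (per-type
#'   TP/FP/FN and sensitivity), `overall`, `matches`, `max_dist`.
#' @export
match_calls <- function(calls, truth, max_dist = 100L, min_size = 1000L,
                        bnd_for_translocation = TRUE) {
  keep <- calls$svtype == "BND" |
    (abs(calls$pos2 - calls$pos1) >= min_size)
  keep <- keep & calls$svtype %in% c("DEL", "DUP", "INV", "BND", "TDEL")
  calls <- calls[keep, , drop = FALSE]
  pairs <- list()
  for (ti in seq_len(nrow(truth))) {
    for (ci in seq_len(nrow(calls))) {
      d <- pair_distance(as.list(calls[ci, ]), as.list(truth[ti, ]),
                         bnd_for_translocation)
      if (is.na(d)) next
      worst <- pair_max_bp_dist(as.list(calls[ci, ]), as.list(truth[ti, ]))
      if (worst <= max_dist)
        pairs[[length(pairs) + 1]] <- tibble(truth_idx = ti, call_idx = ci,
                                             dist = d)
    }
  }
  matches <- tibble(truth_idx = integer(), call_idx = integer(),
                    dist = double())
  if (length(pairs) > 0) {
    pairs <- bind_rows(pairs) |> arrange(.data$dist)
    used_t <- logical(nrow(truth))
    used_c <- logical(nrow(calls))
    for (i in seq_len(nrow(pairs))) {
      ti <- pairs$truth_idx[i]; ci <- pairs$call_idx[i]
      if (used_t[ti] || used_c[ci]) next
      used_t[ti] <- TRUE; used_c[ci] <- TRUE
      matches <- bind_rows(matches, pairs[i, ])
    }
  }
  truth$matched <- seq_len(nrow(truth)) %in% matches$truth_idx
  calls$matched <- seq_len(nrow(calls)) %in% matches$call_idx
  per_type <- truth |>
    group_by(svtype = .data$svtype) |>
    summarise(n_truth = n(), tp = sum(.data$matched),
              fn = sum(!.data$matched), .groups = "drop") |>
    mutate(sensitivity = .data$tp / .data$n_truth)
  fp_by_type <- calls |>
    filter(!.data$matched) |>
    group_by(svtype = .data$svtype) |>
    summarise(fp = n(), .groups = "drop")
  per_type <- left_join(per_type, fp_by_type, by = "svtype") |>
    mutate(fp = ifelse(is.na(.data$fp), 0L, .data$fp))
  overall <- tibble(n_truth = nrow(truth), tp = sum(truth$matched),
                    fn = sum(!truth$matched), fp = sum(!calls$matched),
                    sensitivity = if (nrow(truth) > 0)
                      sum(truth$matched) / nrow(truth) else NA_real_)
  structure(list(summary = per_type, overall = overall, matches = matches,
                 max_dist = max_dist, n_calls = nrow(calls)),
            class = "sv_eval")
}

#' @export
print.sv_eval <- function(x, ...) {
  cat("SV evaluation (breakpoint allowance ", x$max_dist, " bp)\n", sep = "")
  cat("  truth: ", x$overall$n_truth, "  calls: ", x$n_calls,
      "  TP: ", x$overall$tp, "  FN: ", x$overall$fn,
      "  FP: ", x$overall$fp, "\n", sep = "")
  cat(sprintf("  sensitivity: %.3f\n", x$overall$sensitivity))
  print(x$summary)
  invisible(x)
}

#' Tidy per-type evaluation results
#'
#' @param x an `sv_eval` from [match_calls()].
#' @param ... unused.
#' @return Tibble with one row per SV type: TP/FP/FN and sensitivity.
#' @export
tidy.sv_eval <- function(x, ...) {
  x$summary
}

#' One-row evaluation summary
#'
#' @param x an `sv_eval` from [match_calls()].
#' @param ... unused.
#' @return One-row tibble: counts, sensitivity, the distance allowance.
#' @export
glance.sv_eval <- function(x, ...) {
  mutate(x$overall, max_dist = x$max_dist, n_calls = x$n_calls)
}

#' Write the per-type evaluation table to TSV
#'
#' @param x an `sv_eval`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_table <- function(x, path) {
  write.table(as.data.frame(tidy(x)), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
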