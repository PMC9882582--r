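#' Breakpoint score between a called and a true SV
#'
#' The arithmetic mean of the absolute start- and end-coordinate offsets,
#' `(|start' - start| + |end' - end|) / 2`. Lower is better; 0 means exact
#' breakpoints. For insertions both records carry `end == start`, so the score
#' reduces to the insertion-point distance.
#'
#' @param call,truth SV call rows (data frames with `chrom`, `start`, `end`),
#'   recycled/vectorized over equal row counts.
#' @return Numeric vector of scores.
#' @export
breakpoint_score <- function(call, truth) {
  if (!all(call$chrom == truth$chrom)) {
    abort("breakpoint score undefined across chromosomes",
          class = "quantalign_parameter_error")
  }
  (abs(call$start - truth$start) + abs(call$end - truth$end)) / 2
}

#' SV length similarity
#'
#' `min(L1, L2) / max(L1, L2)` of the two SV lengths, a symmetric value in
#' (0, 1]; 1 means identical lengths.
#'
#' @param call,truth SV call rows with a `length` column.
#' @return Numeric vector of similarities.
#' @export
length_similarity <- function(call, truth) {
  if (any(call$length <= 0) || any(truth$length <= 0)) {
    abort("SV lengths must be positive", class = "quantalign_parameter_error")
  }
  pmin(call$length, truth$length) / pmax(call$length, truth$length)
}

#' Match SV calls against a truth set
#'
#' Simplified Truvari-style matching: a call and a truth record are candidate
#' partners when they share chromosome and SV type, their breakpoint score is
#' at most `refdist` and their length similarity at least `pctsize` (0.7, the
#' Truvari default). Candidates are assigned greedily in ascending breakpoint
#' score, each record used at most once.
#'
#' @param calls,truths SV call tibbles ([extract_sv_candidates()] /
#'   [read_vcf_sv()] layout).
#' @param refdist Maximum breakpoint score for a match (bases).
#' @param pctsize Minimum length similarity.
#' @return An `sv_match`: list with `pairs` (matched call/truth index pairs
#'   and their scores), `fp` (unmatched calls), `fn` (unmatched truths) and
#'   the input sizes.
#' @export
match_calls <- function(calls, truths, refdist = 500, pctsize = 0.7) {
  nc <- nrow(calls); nt <- nrow(truths)
  pairs <- tibble(call_idx = integer(0), truth_idx = integer(0),
                  breakpoint_score = numeric(0), length_similarity = numeric(0))
  if (nc > 0L && nt > 0L) {
    cand <- inner_join(
      mutate(calls, call_idx = row_number()),
      mutate(truths, truth_idx = row_number()),
      by = c("chrom", "svtype"), suffix = c("_c", "_t"), relationship = "many-to-many")
    if (nrow(cand) > 0L) {
      cand$bs <- (abs(cand$start_c - cand$start_t) + abs(cand$end_c - cand$end_t)) / 2
      cand$ls <- pmin(cand$length_c, cand$length_t) / pmax(cand$length_c, cand$length_t)
      cand <- cand[cand$bs <= refdist & cand$ls >= pctsize, ]
      cand <- cand[order(cand$bs, cand$call_idx, cand$truth_idx), ]
      used_c <- logical(nc); used_t <- logical(nt)
      for (i in seq_len(nrow(cand))) {
        ci <- cand$call_idx[i]; ti <- cand$truth_idx[i]
        if (used_c[ci] || used_t[ti]) next
        used_c[ci] <- TRUE; used_t[ti] <- TRUE
        pairs <- bind_rows(pairs, tibble(call_idx = ci, truth_idx = ti,
                                         breakpoint_score = cand$bs[i],
                                         length_similarity = cand$ls[i]))
      }
    }
  }
  structure(list(pairs = pairs,
                 fp = if (nc > 0) calls[setdiff(seq_len(nc), pairs$call_idx), ] else calls,
                 fn = if (nt > 0) truths[setdiff(seq_len(nt), pairs$truth_idx), ] else truths,
                 n_calls = nc, n_truths = nt),
            class = "sv_match")
}

#' @export
print.sv_match <- function(x, ...) {
  cat(sprintf("<sv_match> %d calls vs %d truths: TP %d, FP %d, FN %d\n",
              x$n_calls, x$n_truths, nrow(x$pairs), nrow(x$fp), nrow(x$fn)))
  invisible(x)
}

#' Precision, recall and F1 from a match result
#'
#' Precision is the fraction of calls matched to the truth set, recall the
#' fraction of truths recovered, and F1 their harmonic mean (0 when P + R is
#' 0). An empty call set yields precision 0 with a warning.
#'
#' @param match An `sv_match` from [match_calls()].
#' @return One-row tibble: `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
prf <- function(match) {
  tp <- nrow(match$pairs); fp <- nrow(match$fp); fn <- nrow(match$fn)
  if (tp + fp == 0L) {
    warn("empty call set: precision defined as 0")
    precision <- 0
  } else precision <- tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(precision = precision, recall = recall, f1 = f1,
         tp = tp, fp = fp, fn = fn)
}

#' Union of two SV call sets
#'
#' The union model: all of `setA` plus every member of `setB` that matches no
#' member of `setA` under the [match_calls()] candidate criteria; duplicates
#' collapse to the `setA` representative. Against any fixed truth set the
#' union's recall is at least the larger of the two inputs' recalls.
#'
#' @param setA,setB SV call tibbles on one coordinate system.
#' @param refdist,pctsize Matching thresholds, as in [match_calls()].
#' @return SV call tibble.
#' @export
union_calls <- function(setA, setB, refdist = 500, pctsize = 0.7) {
  if (nrow(setB) == 0L) return(setA)
  if (nrow(setA) == 0L) return(setB)
  keep <- map_lgl(seq_len(nrow(setB)), function(i) {
    b <- setB[i, ]
    a <- setA[setA$chrom == b$chrom & setA$svtype == b$svtype, ]
    if (nrow(a) == 0L) return(TRUE)
    bs <- (abs(a$start - b$start) + abs(a$end - b$end)) / 2
    ls <- pmin(a$length, b$length) / pmax(a$length, b$length)
    !any(bs <= refdist & ls >= pctsize)
  })
  bind_rows(setA, setB[keep, ])
}

#' Drop calls overlapping excluded regions
#'
#' Removes every call whose interval overlaps any region (any-overlap rule);
#' insertion points are treated as zero-length positions and dropped when they
#' fall inside a region.
#'
#' @param calls SV call tibble.
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open), as
#'   from [read_bed()].
#' @return Filtered call tibble.
#' @export
exclude_regions <- function(calls, regions) {
  if (nrow(calls) == 0L || nrow(regions) == 0L) return(calls)
  drop <- map_lgl(seq_len(nrow(calls)), function(i) {
    r <- regions[regions$chrom == calls$chrom[i], ]
    if (nrow(r) == 0L) return(FALSE)
    s <- calls$start[i]; e <- calls$end[i]
    if (e > s) any(s < r$end & e > r$start) else any(s >= r$start & s < r$end)
  })
  calls[!drop, ]
}

#' Benchmark SV calls against a truth set
#'
#' Convenience wrapper: optional region exclusion on both sides, matching,
#' precision/recall/F1 and breakpoint-quality summaries, packaged with
#' [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()] methods.
#'
#' @param calls,truth SV call tibbles.
#' @param refdist,pctsize Matching thresholds.
#' @param exclude Optional regions tibble passed to [exclude_regions()].
#' @return An `sv_benchmark` object.
#' @export
evaluate_sv_calls <- function(calls, truth, refdist = 500, pctsize = 0.7,
                              exclude = NULL) {
  if (!is.null(exclude)) {
    calls <- exclude_regions(calls, exclude)
    truth <- exclude_regions(truth, exclude)
  }
  m <- match_calls(calls, truth, refdist, pctsize)
  structure(list(match = m, scores = prf(m), calls = calls, truth = truth,
                 refdist = refdist, pctsize = pctsize),
            class = "sv_benchmark")
}

#' @export
print.sv_benchmark <- function(x, ...) {
  s <- x$scores
  cat(sprintf("<sv_benchmark> P %.3f R %.3f F1 %.3f (TP %d FP %d FN %d)\n",
              s$precision, s$recall, s$f1, s$tp, s$fp, s$fn))
  if (nrow(x$match$pairs) > 0) {
    cat(sprintf("  mean breakpoint score %.1f, mean length similarity %.3f\n",
                mean(x$match$pairs$breakpoint_score),
                mean(x$match$pairs$length_similarity)))
  }
  invisible(x)
}

#' @export
tidy.sv_benchmark <- function(x, ...) {
  p <- x$match$pairs
  if (nrow(p) == 0L) return(p)
  bind_rows(
    mutate(p,
           chrom = x$calls$chrom[p$call_idx],
           svtype = x$calls$svtype[p$call_idx],
           call_start = x$calls$start[p$call_idx],
           truth_start = x$truth$start[p$truth_idx],
           call_length = x$calls$length[p$call_idx],
           truth_length = x$truth$length[p$truth_idx]))
}

#' @export
glance.sv_benchmark <- function(x, ...) {
  p <- x$match$pairs
  bind_rows(mutate(x$scores,
                   mean_breakpoint_score = if (nrow(p)) mean(p$breakpoint_score) else NA_real_,
                   mean_length_similarity = if (nrow(p)) mean(p$length_similarity) else NA_real_))
}

#' @export
autoplot.sv_benchmark <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$breakpoint_score,
                                  y = .data$length_similarity,
                                  colour = .data$svtype)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "breakpoint score (bases)", y = "SV length similarity")
}
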