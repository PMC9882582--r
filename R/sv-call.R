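#' Extract structural-variant candidates from alignments
#'
#' A lightweight split-read and CIGAR-based SV extractor, sufficient for
#' benchmarking the alignment stages: deletions and insertions are taken from
#' CIGAR D/I runs of at least `min_len` bases; inversions from pairs of split
#' segments of one read with opposite strands whose target intervals are
#' adjacent or overlapping (within `inv_max_gap`). Per-read evidence is then
#' clustered per locus across reads (breakpoints within `cluster_dist`) and
#' clusters below `min_support` supporting reads are dropped. This is
#' benchmarking plumbing, not a production SV caller.
#'
#' @param alignments Alignment tibble with nucleotide CIGARs (primary and
#'   supplementary segments are used; secondaries ignored).
#' @param min_len Minimum SV length (50 by the field's definition of an SV).
#' @param min_support Minimum number of distinct supporting reads per call.
#' @param cluster_dist Maximum start-position spread within one cluster.
#' @param inv_max_gap Maximum gap between opposite-strand segments of a read
#'   for an inversion candidate.
#' @param merge_run_dist Within one segment, same-type CIGAR runs closer than
#'   this are merged into one event (long indels occasionally fragment around
#'   chance matches).
#' @param source Label recorded in the `source` column.
#' @return SV call tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `svtype` (INS/DEL/INV), `length`, `support`, `source`. For insertions
#'   `end == start` and `length` is the inserted-sequence length.
#' @export
extract_sv_candidates <- function(alignments, min_len = 50L, min_support = 3L,
                                  cluster_dist = 500L, inv_max_gap = 1000L,
                                  merge_run_dist = 150L, source = "quantalign") {
  segs <- alignments[alignments$tag %in% c("primary", "supplementary"), ]
  raw <- list()
  # CIGAR-run DEL/INS; nearby runs of one type within a segment are merged,
  # since long indels occasionally fragment around chance matches
  for (i in seq_len(nrow(segs))) {
    p <- cigar_parse(segs$cigar[i])
    ref <- segs$t_start[i]
    ev <- list()
    for (j in seq_along(p$len)) {
      op <- p$op[j]; len <- p$len[j]
      if (op %in% c("M", "=", "X")) ref <- ref + len
      else if (op == "D") {
        if (len >= 20L) ev[[length(ev) + 1L]] <- c(pos = ref, len = len, ins = 0L)
        ref <- ref + len
      } else if (op == "I") {
        if (len >= 20L) ev[[length(ev) + 1L]] <- c(pos = ref, len = len, ins = 1L)
      }
    }
    if (length(ev) == 0L) next
    ev <- do.call(rbind, ev)
    for (ins in c(0L, 1L)) {
      e <- ev[ev[, "ins"] == ins, , drop = FALSE]
      if (nrow(e) == 0L) next
      gap_to_prev <- c(Inf, e[-1, "pos"] -
                         (e[-nrow(e), "pos"] + (1L - ins) * e[-nrow(e), "len"]))
      grp <- cumsum(gap_to_prev > merge_run_dist)
      for (g in unique(grp)) {
        sub <- e[grp == g, , drop = FALSE]
        len <- sum(sub[, "len"])
        if (len < min_len) next
        pos <- sub[which.max(sub[, "len"]), "pos"]
        raw[[length(raw) + 1L]] <- tibble(
          chrom = segs$target_id[i], start = as.integer(pos),
          end = as.integer(if (ins) pos else pos + len),
          svtype = if (ins) "INS" else "DEL", length = as.integer(len),
          query_id = segs$query_id[i])
      }
    }
  }
  # split-read inversions: an internal '-' segment of a read flanked by a
  # substantial '+' segment nearby on the same target; whole-read '-'
  # alignments are ordinary reverse-strand reads, not inversion evidence
  for (qid in unique(segs$query_id)) {
    rs <- segs[segs$query_id == qid, ]
    if (length(unique(rs$strand)) < 2L) next
    # the inverted block is the minority-strand part of the split read: a
    # forward read crossing an inversion is + with a - insert, a
    # reverse-strand read is - with a + insert
    cov <- vapply(c("+", "-"), function(s) {
      sum(rs$q_end[rs$strand == s] - rs$q_start[rs$strand == s])
    }, numeric(1))
    minority <- names(cov)[which.min(cov)]
    inner <- rs[rs$strand == minority, ]
    flank <- rs[rs$strand != minority & (rs$q_end - rs$q_start) >= 100L, ]
    if (nrow(flank) == 0L) next
    for (i in seq_len(nrow(inner))) {
      if (inner$q_end[i] - inner$q_start[i] > 0.9 * inner$query_len[i]) next
      near <- flank$target_id == inner$target_id[i] &
        pmax(0, pmax(flank$t_start, inner$t_start[i]) -
               pmin(flank$t_end, inner$t_end[i])) <= inv_max_gap
      if (any(near)) {
        raw[[length(raw) + 1L]] <- tibble(
          chrom = inner$target_id[i], start = inner$t_start[i],
          end = inner$t_end[i], svtype = "INV",
          length = inner$t_end[i] - inner$t_start[i], query_id = qid)
      }
    }
  }
  empty <- tibble(chrom = character(0), start = integer(0), end = integer(0),
                  svtype = character(0), length = integer(0),
                  support = integer(0), source = character(0))
  if (length(raw) == 0L) return(empty)
  raw <- list_rbind(raw)
  raw <- raw[raw$length >= min_len, ]
  if (nrow(raw) == 0L) return(empty)

  # per-locus clustering; evidence is first aggregated per read within a
  # cluster (one read, one vote) so reads with fragmented runs do not
  # outweigh clean spanning reads
  out <- raw |>
    group_by(.data$chrom, .data$svtype) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(cl = cumsum(c(TRUE, diff(.data$start) > cluster_dist))) |>
    group_by(.data$chrom, .data$svtype, .data$cl, .data$query_id) |>
    summarise(start = .data$start[which.max(.data$length)],
              end = .data$end[which.max(.data$length)] +
                sum(.data$length) - max(.data$length),
              length = sum(.data$length), .groups = "drop_last") |>
    group_by(.data$chrom, .data$svtype, .data$cl) |>
    summarise(start = as.integer(round(median(.data$start))),
              end = as.integer(round(median(.data$end))),
              length = as.integer(round(median(.data$length))),
              support = n_distinct(.data$query_id), .groups = "drop") |>
    filter(.data$support >= min_support) |>
    mutate(end = ifelse(.data$svtype == "INS", .data$start, .data$end),
           source = source) |>
    select("chrom", "start", "end", "svtype", "length", "support", "source") |>
    arrange(desc(.data$support))
  # dedupe clusters describing one event
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i] || i == 1L) next
    prev <- out[seq_len(i - 1L), ][keep[seq_len(i - 1L)], ]
    same <- prev$chrom == out$chrom[i] & prev$svtype == out$svtype[i]
    if (!any(same)) next
    p <- prev[same, ]
    bs <- (abs(p$start - out$start[i]) + abs(p$end - out$end[i])) / 2
    ls <- pmin(p$length, out$length[i]) / pmax(p$length, out$length[i])
    if (any(bs <= cluster_dist & ls >= 0.5)) keep[i] <- FALSE
  }
  arrange(out[keep, ], .data$chrom, .data$start)
}
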