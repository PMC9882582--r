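#' Well-aligned reads
#'
#' A read is well-aligned when at least 90% of its length is covered by the
#' alignment's genome span (`t_end - t_start >= 0.9 * read_length`, the
#' literal genome-span criterion) and the mapping quality is strictly greater
#' than 20.
#'
#' @param alignments Alignment tibble (needs `t_start`, `t_end`, `mapq`).
#' @param read_length Read lengths; defaults to the `query_len` column.
#' @return Logical vector, one element per alignment row.
#' @export
is_well_aligned <- function(alignments, read_length = alignments$query_len) {
  (alignments$t_end - alignments$t_start) >= 0.9 * read_length &
    alignments$mapq > 20
}

#' Normalized edit distance of an alignment
#'
#' Edit distance between the entire read and the genome slice delimited by the
#' alignment, divided by read length. The distance is always computed on
#' nucleotide sequences; for quantized alignments only the coordinates come
#' from symbol space, which is what makes the two stages comparable on one
#' scale.
#'
#' @param read Read sequence (ACGT string).
#' @param target Target (chromosome) sequence.
#' @param start,end 0-based half-open aligned interval on the target.
#' @param strand Alignment strand; for `"-"` the genome slice is
#'   reverse-complemented before the comparison.
#' @return Edit distance / read length.
#' @export
normalized_edit_distance <- function(read, target, start, end, strand = "+") {
  if (end <= start) {
    abort("empty target interval: normalized edit distance undefined",
          class = "quantalign_interval_error")
  }
  slice <- substr(target, start + 1L, end)
  if (strand == "-") slice <- seq_revcomp(slice)
  qv <- encode_dna(read)
  tv <- encode_dna(slice)
  res <- banded_global_cpp(qv, tv, max(64L, abs(length(qv) - length(tv)) + 16L),
                           length(qv) + length(tv))
  res$edit / length(qv)
}

#' Normalized alignment length
#'
#' Genome span of the alignment divided by the read length; 1 indicates a
#' contiguous full-length alignment, and deletion-spanning alignments can
#' exceed 1.
#'
#' @param start,end 0-based half-open aligned interval on the target.
#' @param read_length Read length.
#' @return `(end - start) / read_length`.
#' @export
normalized_alignment_length <- function(start, end, read_length) {
  stopifnot(read_length > 0)
  (end - start) / read_length
}

#' Ordinary least squares line
#'
#' @param xs,ys Numeric vectors (>= 2 points, `xs` not all equal).
#' @return List with `slope`, `intercept` and the underlying `lm` fit in
#'   `model`.
#' @export
regression_fit <- function(xs, ys) {
  if (length(xs) < 2L || length(xs) != length(ys)) {
    abort("need >= 2 paired points", class = "quantalign_parameter_error")
  }
  if (diff(range(xs)) == 0) {
    abort("xs are all equal: regression degenerate",
          class = "quantalign_degenerate_error")
  }
  fit <- lm(ys ~ xs)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]), model = fit)
}

#' Per-read alignment quality metrics
#'
#' Computes, for the primary alignment of each read, the normalized edit
#' distance, normalized alignment length and well-aligned flag.
#'
#' @param alignments Alignment tibble as produced by [align()] or
#'   [hybrid_align()].
#' @param reads Named character vector of read sequences.
#' @param genome Named character vector of target sequences.
#' @return Tibble with one row per read that has a primary alignment.
#' @export
alignment_metrics <- function(alignments, reads, genome) {
  prim <- alignments[alignments$tag == "primary", ]
  if (nrow(prim) == 0L) {
    return(tibble(query_id = character(0), ned = numeric(0), nal = numeric(0),
                  well_aligned = logical(0)))
  }
  tibble(
    query_id = prim$query_id,
    ned = map_dbl(seq_len(nrow(prim)), function(i) {
      normalized_edit_distance(reads[[prim$query_id[i]]],
                               genome[[prim$target_id[i]]],
                               prim$t_start[i], prim$t_end[i], prim$strand[i])
    }),
    nal = normalized_alignment_length(prim$t_start, prim$t_end, prim$query_len),
    well_aligned = is_well_aligned(prim)
  )
}

#' Compare two alignment runs over the same reads
#'
#' Pairs the per-read metrics of two alignment tables (typically the
#' nucleotide stage versus the hybrid quantized stage), fits the OLS
#' regression of the second method's normalized edit distance on the first's,
#' and summarises well-aligned percentages. A regression slope below 1 means
#' method `b` achieves smaller normalized edit distance on average.
#'
#' @param aln_a,aln_b Alignment tibbles over the same reads.
#' @param reads,genome Sequences used for the metric computation.
#' @param labels Length-2 character, names for the two methods.
#' @return An `aln_comparison` object with [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods.
#' @export
compare_alignments <- function(aln_a, aln_b, reads, genome,
                               labels = c("nucleotide", "quantized")) {
  ma <- alignment_metrics(aln_a, reads, genome)
  mb <- alignment_metrics(aln_b, reads, genome)
  paired <- inner_join(ma, mb, by = "query_id", suffix = c("_a", "_b"))
  fit <- if (nrow(paired) >= 2L && diff(range(paired$ned_a)) > 0) {
    regression_fit(paired$ned_a, paired$ned_b)
  } else NULL
  structure(list(metrics = paired, fit = fit, labels = labels,
                 n_a = nrow(ma), n_b = nrow(mb)),
            class = "aln_comparison")
}

#' @export
print.aln_comparison <- function(x, ...) {
  g <- generics::glance(x)
  cat(sprintf("<aln_comparison> %s vs %s over %d paired reads\n",
              x$labels[1], x$labels[2], g$n))
  cat(sprintf("  well-aligned: %.2f%% (%s) vs %.2f%% (%s)\n",
              g$pct_well_a, x$labels[1], g$pct_well_b, x$labels[2]))
  if (!is.na(g$slope)) {
    cat(sprintf("  normalized edit distance OLS: slope %.4f, intercept %.4f\n",
                g$slope, g$intercept))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.aln_comparison <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(term = character(0), estimate = numeric(0)))
  }
  tibble(term = c("intercept", "slope"),
         estimate = c(x$fit$intercept, x$fit$slope))
}

#' @importFrom generics glance
#' @export
glance.aln_comparison <- function(x, ...) {
  p <- x$metrics
  tibble(
    n = nrow(p),
    pct_well_a = 100 * mean(p$well_aligned_a),
    pct_well_b = 100 * mean(p$well_aligned_b),
    slope = if (is.null(x$fit)) NA_real_ else x$fit$slope,
    intercept = if (is.null(x$fit)) NA_real_ else x$fit$intercept,
    frac_b_le_a = mean(p$ned_b <= p$ned_a),
    mean_ned_a = mean(p$ned_a),
    mean_ned_b = mean(p$ned_b)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.aln_comparison <- function(object, ...) {
  p <- object$metrics
  gg <- ggplot2::ggplot(p, ggplot2::aes(x = .data$ned_a, y = .data$ned_b)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = paste("normalized edit distance,", object$labels[1]),
                  y = paste("normalized edit distance,", object$labels[2]))
  if (!is.null(object$fit)) {
    gg <- gg + ggplot2::geom_abline(slope = object$fit$slope,
                                    intercept = object$fit$intercept,
                                    colour = "firebrick")
  }
  gg
}
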