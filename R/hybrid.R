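#' Extend a region of interest
#'
#' Given a step-1 alignment of a read of length n spanning `[s, e)` on the
#' target, the quantized re-alignment window is the interval extended on both
#' sides by `b = (1 - f + 0.25) * n`, where `f = (e - s) / n` is the aligned
#' fraction. `f` is capped at 1 before the formula so deletion-inflated genome
#' spans never shrink the window: the extension always keeps its `0.25 * n`
#' floor. The window is clamped to the target.
#'
#' @param s,e 0-based half-open step-1 interval on the target.
#' @param n Read length (nucleotides).
#' @param target_length Length of the target sequence.
#' @return List with `s_q`, `e_q` (extended window), `f` and `b`.
#' @examples
#' extend_roi(5000, 6000, 1000, 100000)  # f = 1, b = 250
#' @export
extend_roi <- function(s, e, n, target_length) {
  stopifnot(s >= 0, e >= s, n > 0, e <= target_length)
  f <- min((e - s) / n, 1)
  b <- round((1 - f + 0.25) * n)
  list(s_q = max(0, s - b), e_q = min(target_length, e + b), f = f, b = b)
}

#' Find regions of interest by nucleotide pre-alignment
#'
#' Step 1 of the hybrid strategy: the read is aligned in nucleotide space and
#' every resulting placement (primary, supplementary and secondary) defines a
#' region of interest, extended per [extend_roi()]. Windows are always in
#' forward target coordinates; the step-1 strand is recorded only as a hint.
#'
#' @param read A nucleotide string.
#' @param genome Named character vector of target sequences, or a nucleotide
#'   [build_index()].
#' @param params Nucleotide-stage [align_params].
#' @return Tibble of ROIs (`target_id`, `s`, `e`, `f`, `b`, `s_q`, `e_q`,
#'   `read_length`, `strand_hint`, `score`); zero rows when the read is
#'   unmapped in step 1.
#' @export
find_rois <- function(read, genome, params = align_params()) {
  idx <- if (inherits(genome, "qa_index")) genome else build_index(genome, params)
  a <- align(read, idx, query_id = "read")
  n <- nchar(read)
  if (nrow(a) == 0L) {
    return(tibble(target_id = character(0), s = integer(0), e = integer(0),
                  f = numeric(0), b = numeric(0), s_q = integer(0),
                  e_q = integer(0), read_length = integer(0),
                  strand_hint = character(0), score = numeric(0)))
  }
  tlens <- setNames(idx$lens, idx$ids)
  ext <- pmap(list(a$t_start, a$t_end, a$target_id), function(s, e, tid) {
    extend_roi(s, e, n, tlens[[tid]])
  })
  tibble(target_id = a$target_id, s = a$t_start, e = a$t_end,
         f = map_dbl(ext, "f"), b = map_dbl(ext, "b"),
         s_q = as.integer(map_dbl(ext, "s_q")), e_q = as.integer(map_dbl(ext, "e_q")),
         read_length = n, strand_hint = a$strand, score = a$score)
}

# merge overlapping extended windows on the same target
merge_rois <- function(rois) {
  if (nrow(rois) == 0L) return(rois[, c("target_id", "s_q", "e_q")])
  rois |>
    select("target_id", "s_q", "e_q") |>
    arrange(.data$target_id, .data$s_q) |>
    group_by(.data$target_id) |>
    mutate(grp = cumsum(c(TRUE, .data$s_q[-1] > cummax(.data$e_q)[-n()]))) |>
    group_by(.data$target_id, .data$grp) |>
    summarise(s_q = min(.data$s_q), e_q = max(.data$e_q), .groups = "drop") |>
    select("target_id", "s_q", "e_q")
}

#' Map a quantized-space interval back to nucleotide coordinates
#'
#' A quantized sequence has one symbol per Q-window, so symbol interval
#' `[q_start, q_end)` covers nucleotides `[q_start, q_end + Q - 1)` of the
#' sequence it was derived from. For a window quantized in the forward
#' orientation the genome interval follows by adding the window offset; for an
#' interval on the reverse-complement-derived quantized sequence the
#' coordinates are mirrored within the window first, then widened by Q - 1.
#'
#' @param q_start,q_end 0-based half-open interval in symbol space.
#' @param window_start 0-based target offset of the quantized window.
#' @param strand `"+"` for the forward quantized window, `"-"` for an interval
#'   on the reverse-complement-derived sequence.
#' @param Q Pore-model word length.
#' @param window_qlen Quantized length of the window (required for `"-"`).
#' @return Integer vector `c(start, end)`, 0-based half-open, nucleotides.
#' @export
map_quantized_interval <- function(q_start, q_end, window_start, strand = "+",
                                   Q = 6L, window_qlen = NULL) {
  stopifnot(q_start < q_end, q_start >= 0)
  if (strand == "+") {
    c(window_start + q_start, window_start + q_end + Q - 1L)
  } else {
    if (is.null(window_qlen)) {
      abort("window_qlen is required for strand '-'", class = "quantalign_parameter_error")
    }
    if (q_end > window_qlen) {
      abort("interval outside window", class = "quantalign_bounds_error")
    }
    c(window_start + window_qlen - q_end,
      window_start + window_qlen - q_start + Q - 1L)
  }
}

#' Hybrid quantized alignment of one read
#'
#' The two-step strategy: a coarse nucleotide alignment finds regions of
#' interest, each extended window is quantized, and the quantized read plus
#' its quantized reverse complement are re-aligned to the window with the
#' k = 18 ternary engine. Quantized placements are mapped back to nucleotide
#' coordinates and the nucleotide CIGAR is re-derived by banded global
#' alignment of the implied substrings, so downstream SV callers see ordinary
#' nucleotide alignments; segments found in the reverse-complement orientation
#' carry strand "-", which is what exposes inversions. MAPQ comes from the
#' quantized-stage chain competition. If no quantized chain is found in any
#' window the step-1 alignment is returned, flagged `stage = "fallback"`.
#'
#' @param read A nucleotide string.
#' @param genome Named character vector of targets or nucleotide index.
#' @param model A [qmer_model].
#' @param cfg A `quantizer_config`.
#' @param params Nucleotide-stage [align_params] (step 1).
#' @param qparams Quantized-stage parameters, default [quantized_params()].
#' @param query_id Read identifier for the output.
#' @param max_secondary Secondary alignments kept after pooling.
#' @return Alignment tibble in nucleotide coordinates with extra columns
#'   `stage` (`"hybrid"` or `"fallback"`) and `domain`.
#' @export
hybrid_align <- function(read, genome, model, cfg, params = align_params(),
                         qparams = quantized_params(), query_id = "read",
                         max_secondary = 5L) {
  Q <- qmer_q(model)
  n <- nchar(read)
  if (n < Q + qparams$k - 1L) {
    abort("read shorter than Q + k - 1: no quantized window fits",
          class = "quantalign_length_error")
  }
  idx <- if (inherits(genome, "qa_index")) genome else build_index(genome, params)
  step1 <- align(read, idx, query_id = query_id)
  if (nrow(step1) == 0L) {
    out <- empty_alignments()
    out$stage <- character(0)
    return(out)
  }
  tlens <- setNames(idx$lens, idx$ids)
  rois <- merge_rois(find_rois_from_step1(step1, n, tlens))

  qf <- as.integer(quantize_sequence(read, model, cfg, query_id))
  qr <- as.integer(quantized_reverse_complement(read, model, cfg, query_id))
  qn <- length(qf)

  cand <- list()
  for (i in seq_len(nrow(rois))) {
    tid <- rois$target_id[i]; w0 <- rois$s_q[i]; w1 <- rois$e_q[i]
    if (w1 - w0 < Q + qparams$k - 1L) next
    win_nt <- idx$enc[[tid]][(w0 + 1L):w1]
    wq <- findInterval(qmer_currents_cpp(win_nt, current_vector(model), Q),
                       cfg$thresholds, left.open = TRUE)
    widx <- build_index(stats::setNames(list(wq), "w"), qparams)
    for (orient in c("+", "-")) {
      qsym <- if (orient == "+") qf else qr
      al <- align(qsym, widx, query_id = query_id, max_secondary = 2L)
      if (nrow(al) == 0L) next
      al$orient <- orient; al$tid <- tid; al$w0 <- w0
      cand[[length(cand) + 1L]] <- al
    }
  }
  if (length(cand) == 0L) {
    step1$stage <- "fallback"
    return(step1)
  }
  pool <- list_rbind(cand)
  # quantized coords -> nucleotide coords (query on the original read strand)
  pool <- pool |>
    mutate(nt_t_start = .data$w0 + .data$t_start,
           nt_t_end = .data$w0 + .data$t_end + Q - 1L,
           nt_q_start = ifelse(.data$orient == "+", .data$q_start,
                               n - (.data$q_end + Q - 1L)),
           nt_q_end = ifelse(.data$orient == "+", .data$q_end + Q - 1L,
                             n - .data$q_start)) |>
    arrange(desc(.data$score))

  # pooled query-coverage selection across ROIs and orientations
  accepted <- logical(nrow(pool))
  cover <- matrix(numeric(0), nrow = 0, ncol = 2)
  for (i in seq_len(nrow(pool))) {
    sp <- c(pool$nt_q_start[i], pool$nt_q_end[i])
    ov <- if (nrow(cover) > 0) {
      sum(pmax(0, pmin(cover[, 2], sp[2]) - pmax(cover[, 1], sp[1])))
    } else 0
    if (ov < 0.5 * (sp[2] - sp[1])) {
      accepted[i] <- TRUE
      cover <- rbind(cover, sp)
    }
  }
  keep <- which(accepted | cumsum(!accepted) <= max_secondary)
  pool <- pool[keep, ]
  accepted <- accepted[keep]

  genc <- idx$enc
  renc <- encode_dna(read)
  renc_rc <- rev(3L - renc)
  rows <- map(seq_len(nrow(pool)), function(i) {
    r <- pool[i, ]
    qs <- r$nt_q_start; qe <- r$nt_q_end
    ts <- r$nt_t_start; te <- min(r$nt_t_end, tlens[[r$tid]])
    tlen <- tlens[[r$tid]]
    # polish endpoints at nucleotide level: quantized symbol ends are noisy,
    # so recover the few bases the symbol-space alignment leaves behind
    qv_frame <- if (r$orient == "+") renc else renc_rc
    fs <- if (r$orient == "+") qs else n - qe   # frame coords
    fe <- if (r$orient == "+") qe else n - qs
    tv <- genc[[r$tid]]
    if (fe < n && te < tlen) {
      tail_q <- n - fe
      win <- min(tlen - te, tail_q + 50L)
      ext <- extend_align_cpp(qv_frame[(fe + 1L):n], tv[(te + 1L):(te + win)],
                              2L, -6L, -5L, 64L, 100L)
      fe <- fe + ext$q_used; te <- te + ext$t_used
    }
    if (fs > 0L && ts > 0L) {
      win <- min(ts, fs + 50L)
      ext <- extend_align_cpp(qv_frame[fs:1], tv[ts:(ts - win + 1L)],
                              2L, -6L, -5L, 64L, 100L)
      fs <- fs - ext$q_used; ts <- ts - ext$t_used
    }
    qs <- if (r$orient == "+") fs else n - fe
    qe <- if (r$orient == "+") fe else n - fs
    qvec <- qv_frame[(fs + 1L):fe]
    tvec <- tv[(ts + 1L):te]
    res <- affine_global_cpp(qvec, tvec,
                             max(128L, as.integer(0.05 * length(qvec))),
                             2L, -4L, 16L, 1L)
    # terminal deletions are artifacts of the Q-window interval widening:
    # tighten the target interval instead of charging them to the alignment
    p <- cigar_parse(res$cigar)
    edit <- res$edit
    while (length(p$op) > 0L && p$op[1] == "D") {
      ts <- ts + p$len[1]; edit <- edit - p$len[1]
      p$op <- p$op[-1]; p$len <- p$len[-1]
    }
    while (length(p$op) > 0L && p$op[length(p$op)] == "D") {
      te <- te - p$len[length(p$op)]; edit <- edit - p$len[length(p$op)]
      p$op <- p$op[-length(p$op)]; p$len <- p$len[-length(p$len)]
    }
    tibble(query_id = r$query_id, query_len = n, target_id = r$tid,
           strand = if (r$orient == "+") "+" else "-",
           q_start = qs, q_end = qe, t_start = ts, t_end = te,
           cigar = cigar_build(p$len, p$op), score = r$score, edit_dist = edit,
           n_match = res$nmatch, mapq = 0L, tag = "secondary",
           domain = "quantized", n_anchors = r$n_anchors)
  })
  out <- list_rbind(rows)
  acc_rows <- which(accepted)
  out$tag[acc_rows] <- c("primary", rep("supplementary", length(acc_rows) - 1L))
  for (r in acc_rows) {
    sp <- c(out$q_start[r], out$q_end[r])
    second <- NA_real_
    for (j in seq_len(nrow(out))) {
      if (j == r) next
      ov <- max(0, min(out$q_end[j], sp[2]) - max(out$q_start[j], sp[1]))
      if (ov >= 0.5 * (sp[2] - sp[1])) second <- max(second, out$score[j], na.rm = TRUE)
    }
    out$mapq[r] <- compute_mapq(out$score[r], second, out$n_anchors[r])
  }
  out$stage <- "hybrid"
  out
}

# ROI construction from an existing step-1 alignment table
find_rois_from_step1 <- function(step1, n, tlens) {
  ext <- pmap(list(step1$t_start, step1$t_end, step1$target_id), function(s, e, tid) {
    extend_roi(s, e, n, tlens[[tid]])
  })
  tibble(target_id = step1$target_id,
         s_q = as.integer(map_dbl(ext, "s_q")),
         e_q = as.integer(map_dbl(ext, "e_q")))
}

#' Batch hybrid alignment with SAM/PAF output
#'
#' Runs [hybrid_align()] over a read set in input order and optionally writes
#' SAM and/or PAF. Unmapped reads appear as unmapped SAM records; malformed or
#' too-short reads are skipped with a warning.
#'
#' @param reads Named character vector of read sequences, or a FASTQ/FASTA
#'   path.
#' @param genome Named character vector or FASTA path.
#' @param model A [qmer_model].
#' @param cfg A `quantizer_config`.
#' @param params,qparams Stage parameters.
#' @param out_sam,out_paf Optional output paths.
#' @return Tibble of all alignments; unmapped read ids in attribute
#'   `unmapped`.
#' @export
align_batch <- function(reads, genome, model, cfg, params = align_params(),
                        qparams = quantized_params(), out_sam = NULL, out_paf = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) read_fastq(reads) else read_fasta(reads)
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  idx <- build_index(genome, params)
  res <- vector("list", length(reads))
  unmapped <- character(0)
  for (i in seq_along(reads)) {
    id <- names(reads)[i]
    a <- tryCatch(
      hybrid_align(reads[[i]], idx, model, cfg, params, qparams, query_id = id),
      quantalign_length_error = function(e) {
        warn(sprintf("read %s skipped: %s", id, conditionMessage(e)))
        empty_alignments()
      })
    if (nrow(a) == 0L) unmapped <- c(unmapped, id) else res[[i]] <- a
  }
  out <- list_rbind(res[!vapply(res, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    out <- empty_alignments()
    out$stage <- character(0)
  }
  tlens <- setNames(idx$lens, idx$ids)
  if (!is.null(out_sam)) {
    write_sam(out, tlens, out_sam, reads = reads, unmapped = unmapped)
  }
  if (!is.null(out_paf)) write_paf(out, tlens, out_paf)
  attr(out, "unmapped") <- unmapped
  out
}
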