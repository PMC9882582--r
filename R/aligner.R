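#' Alignment engine parameters
#'
#' Parameters of the alphabet-generic minimizer seed-chain-extend engine. The
#' nucleotide stage uses minimap2-like defaults (k = 15, w = 10, canonical
#' strand-collapsed minimizers); the quantized stage uses k = 18 over the
#' ternary alphabet with forward-only minimizers, since symbol space has no
#' complement.
#'
#' @param k Minimizer k-mer length.
#' @param w Minimizer window size.
#' @param alphabet_size 4 for nucleotides, 3 for ternary quantized symbols.
#' @param max_gap Maximum anchor-to-anchor gap considered by chaining, bases.
#' @param band Initial half-width of the banded extension DP; doubled
#'   automatically while insufficient.
#' @param min_chain_score Minimum chain score for a chain to seed an alignment.
#' @param canonical Whether minimizers hash the lexicographically smaller of
#'   k-mer and reverse complement (nucleotide mode); `FALSE` in symbol space.
#' @param gap_scale Linear coefficient of the chaining gap cost
#'   `gap_scale * |dt - dq| + 0.5 * log2(|dt - dq| + 1)`.
#' @param max_occ Seeds occurring more often than this in the target are
#'   skipped (repeat masking).
#' @param max_lookback Chaining DP predecessor window.
#' @return An `align_params` list.
#' @export
align_params <- function(k = 15L, w = 10L, alphabet_size = 4L, max_gap = 5000L,
                         band = 64L, min_chain_score = 40, canonical = alphabet_size == 4L,
                         gap_scale = 0.05, max_occ = 500L, max_lookback = 60L) {
  stopifnot(k >= 1, w >= 1, alphabet_size >= 2)
  if (k * log2(alphabet_size) > 52) {
    abort("k too large for the hash width", class = "quantalign_parameter_error")
  }
  structure(list(k = as.integer(k), w = as.integer(w),
                 alphabet_size = as.integer(alphabet_size),
                 max_gap = as.integer(max_gap), band = as.integer(band),
                 min_chain_score = min_chain_score, canonical = isTRUE(canonical),
                 gap_scale = gap_scale, max_occ = as.integer(max_occ),
                 max_lookback = as.integer(max_lookback)),
            class = "align_params")
}

#' @describeIn align_params Defaults for the ternary quantized stage (k = 18,
#'   forward-only minimizers).
#' @param ... Overrides passed to [align_params()].
#' @export
quantized_params <- function(...) {
  args <- list(...)
  defaults <- list(k = 18L, alphabet_size = 3L, canonical = FALSE)
  do.call(align_params, utils::modifyList(defaults, args))
}

#' Edit distance between two sequences
#'
#' Levenshtein distance with unit costs, computed by the full dynamic
#' program. Accepts nucleotide strings or integer symbol vectors. This exact
#' kernel is the reference the banded routines are checked against.
#'
#' @param a,b Character scalars (ACGT) or integer symbol vectors.
#' @return Integer edit distance.
#' @examples
#' edit_distance("ACGT", "AGT")
#' @export
edit_distance <- function(a, b) {
  av <- if (is.character(a)) encode_dna(a) else as.integer(a)
  bv <- if (is.character(b)) encode_dna(b) else as.integer(b)
  edit_distance_cpp(av, bv)
}

#' Extract minimizers from a sequence
#'
#' Window-minimum minimizers: in every window of `w` consecutive k-mers the
#' k-mer(s) with minimal hash are selected. In canonical mode the smaller of
#' the k-mer and its reverse complement is hashed and the strand recorded; in
#' symbol space hashing is forward-only.
#'
#' @param seq Nucleotide string or integer symbol vector.
#' @param params An [align_params].
#' @return Tibble with `pos` (0-based), `hash`, `strand` (`"+"`/`"-"`);
#'   empty when the sequence is shorter than k.
#' @export
extract_minimizers <- function(seq, params = align_params()) {
  v <- encode_seq_generic(seq, params$alphabet_size)
  if (length(v) < params$k) {
    return(tibble(pos = integer(0), hash = numeric(0), strand = character(0)))
  }
  m <- minimizers_cpp(v, params$k, params$w, params$alphabet_size, params$canonical)
  tibble(pos = m$pos, hash = m$hash, strand = ifelse(m$strand > 0, "+", "-"))
}

#' Chain anchors into co-linear chains
#'
#' Dynamic program over anchors sorted by target position, maximizing the sum
#' of anchor contributions `min(k, dq, dt)` minus the gap cost
#' `gap_scale * |dt - dq| + 0.5 * log2(|dt - dq| + 1)`; anchor pairs farther
#' apart than `max_gap` on either axis are never chained. Chains are returned
#' sorted by score, ties broken by leftmost target start.
#'
#' @param anchors Tibble with 0-based columns `q` and `t` (deduplicated).
#' @param params An [align_params].
#' @param top_n Maximum number of chains to return.
#' @return List of chains, each a list with `anchors` (tibble `q`, `t`) and
#'   `score`.
#' @export
chain_anchors <- function(anchors, params = align_params(), top_n = 50L) {
  if (nrow(anchors) == 0L) return(list())
  anchors <- distinct(anchors, .data$q, .data$t)
  ch <- chain_cpp(as.integer(anchors$q), as.integer(anchors$t), params$k,
                  params$max_gap, params$gap_scale, params$min_chain_score,
                  params$max_lookback, as.integer(top_n))
  map(ch, function(c1) {
    list(anchors = tibble(q = anchors$q[c1$idx], t = anchors$t[c1$idx]),
         score = c1$score)
  })
}

# ---- chain extension -------------------------------------------------------

# stitch a chain into base-level alignment segments: exact M runs over
# anchors, banded unit-cost global DP between anchors, score-maximising
# extension at both ends (so chimeric tails soft-clip). An inter-anchor gap
# whose edit cost far exceeds its length imbalance is a foreign insert (e.g.
# an inverted block that only the opposite-orientation query can align), not
# an indel: the chain is split there and each side becomes its own segment.
stitch_chain <- function(qv, tv, aq, at, params,
                         split_min_gap = 200L, split_excess = 0.3) {
  k <- params$k
  segs <- list()
  lens <- integer(0); ops <- character(0)
  edit <- 0L; nmatch <- 0L; n_anch <- 0L
  q_start <- aq[1]; t_start <- at[1]
  qe <- 0L; te <- 0L
  add <- function(l, o) {
    if (l > 0L) { lens[[length(lens) + 1L]] <<- as.integer(l); ops[[length(ops) + 1L]] <<- o }
  }
  open_segment <- function(q, t, len = k) {
    q_start <<- q; t_start <<- t
    lens <<- as.integer(len); ops <<- "M"
    edit <<- 0L; nmatch <<- len; n_anch <<- 1L
    qe <<- q + len; te <<- t + len
  }
  close_segment <- function() {
    # right extension
    qtail <- length(qv) - qe
    if (qtail > 0L && te < length(tv)) {
      twin <- min(length(tv) - te, qtail + max(100L, qtail %/% 4L))
      band <- max(params$band, ceiling(qtail * 0.2))
      ext <- extend_align_cpp(qv[qe + seq_len(qtail)], tv[te + seq_len(twin)],
                              2L, -6L, -5L, as.integer(band), 100L)
      if (ext$q_used > 0L) {
        p <- cigar_parse(ext$cigar)
        lens <<- c(lens, p$len); ops <<- c(ops, p$op)
        edit <<- edit + ext$edit; nmatch <<- nmatch + ext$nmatch
        qe <<- qe + ext$q_used; te <<- te + ext$t_used
      }
    }
    # left extension (on reversed prefixes)
    if (q_start > 0L && t_start > 0L) {
      twin <- min(t_start, q_start + max(100L, q_start %/% 4L))
      band <- max(params$band, ceiling(q_start * 0.2))
      ext <- extend_align_cpp(qv[q_start:1], tv[t_start:(t_start - twin + 1L)],
                              2L, -6L, -5L, as.integer(band), 100L)
      if (ext$q_used > 0L) {
        rc <- cigar_parse(cigar_reverse(ext$cigar))
        lens <<- c(rc$len, lens); ops <<- c(rc$op, ops)
        edit <<- edit + ext$edit; nmatch <<- nmatch + ext$nmatch
        q_start <<- q_start - ext$q_used; t_start <<- t_start - ext$t_used
      }
    }
    segs[[length(segs) + 1L]] <<- list(
      q_start = q_start, q_end = qe, t_start = t_start, t_end = te,
      cigar = cigar_build(lens, ops), edit = edit, nmatch = nmatch,
      n_anchors = n_anch)
  }
  open_segment(aq[1], at[1])
  if (length(aq) > 1L) {
    for (i in 2:length(aq)) {
      q <- aq[i]; t <- at[i]
      s <- max(0L, qe - q, te - t)
      q <- q + s; t <- t + s; kk <- k - s
      if (kk <= 0L) next
      dq <- q - qe; dt <- t - te
      if (dq > 0L || dt > 0L) {
        gd <- abs(dq - dt)
        mn <- min(dq, dt)
        if (mn >= split_min_gap) {
          # probe with a capped band: excess cost over the unavoidable
          # |dq - dt| marks a foreign insert
          cap <- gd + max(64L, as.integer(ceiling(split_excess * mn)) + 8L)
          res <- banded_global_cpp(qv[seq_len(dq) + qe], tv[seq_len(dt) + te],
                                   max(8L, gd + 8L), cap)
          if (res$edit - gd > split_excess * mn) {
            close_segment()
            open_segment(q, t, kk)  # anchor may be clipped shorter than k
            next
          }
          if (gd >= 50L) {
            res <- affine_global_cpp(qv[seq_len(dq) + qe], tv[seq_len(dt) + te],
                                     max(32L, as.integer(0.2 * mn)), 2L, -4L, 16L, 1L)
          }
        } else if (gd >= 50L) {
          # SV-scale imbalance: affine gaps keep the indel as one run
          res <- affine_global_cpp(qv[seq_len(dq) + qe], tv[seq_len(dt) + te],
                                   max(32L, as.integer(0.2 * mn)), 2L, -4L, 16L, 1L)
        } else {
          res <- banded_global_cpp(qv[seq_len(dq) + qe], tv[seq_len(dt) + te],
                                   max(8L, gd + 8L), dq + dt + 2L)
        }
        p <- cigar_parse(res$cigar)
        for (j in seq_along(p$len)) add(p$len[j], p$op[j])
        edit <- edit + res$edit; nmatch <- nmatch + res$nmatch
      }
      add(kk, "M"); nmatch <- nmatch + kk; n_anch <- n_anch + 1L
      qe <- q + kk; te <- t + kk
    }
  }
  close_segment()
  segs
}

#' Extend a chain to a base-level alignment
#'
#' Fills inter-anchor gaps by banded global alignment (band widened
#' automatically while it cannot certify exactness) and extends both ends with
#' a score-maximising banded extension, emitting a CIGAR whose query- and
#' target-consuming lengths match the reported intervals exactly.
#'
#' @param query,target Nucleotide strings or integer symbol vectors (forward
#'   orientation; callers handle strand).
#' @param chain A chain as returned by [chain_anchors()].
#' @param params An [align_params].
#' @return Alignment tibble, one row per segment (a chain splits at foreign
#'   inserts such as inverted blocks).
#' @export
extend_chain <- function(query, target, chain, params = align_params()) {
  qv <- encode_seq_generic(query, params$alphabet_size)
  tv <- encode_seq_generic(target, params$alphabet_size)
  segs <- stitch_chain(qv, tv, chain$anchors$q, chain$anchors$t, params)
  rows <- imap(segs, function(st, i) {
    tibble(query_id = "query", query_len = length(qv), target_id = "target",
           strand = "+", q_start = st$q_start, q_end = st$q_end,
           t_start = st$t_start, t_end = st$t_end, cigar = st$cigar,
           score = chain$score, edit_dist = st$edit, n_match = st$nmatch,
           mapq = 60L, tag = if (i == 1L) "primary" else "supplementary",
           domain = if (params$alphabet_size == 4L) "nucleotide" else "quantized")
  })
  list_rbind(rows)
}

#' Mapping quality from chain competition
#'
#' `clamp(round(40 * (1 - second/best)) * min(1, anchors/10), 0, 60)`; a
#' placement with no competing chain gets 60, an exact tie 0.
#'
#' @param best_score,second_score Chain scores (`second_score` `NA` when no
#'   secondary chain exists).
#' @param anchor_count Number of anchors in the best chain.
#' @return Integer MAPQ in 0..60.
#' @export
compute_mapq <- function(best_score, second_score, anchor_count) {
  if (is.na(second_score) || second_score <= 0) return(60L)
  as.integer(clamp(round(40 * (1 - second_score / best_score)) *
                     min(1, anchor_count / 10), 0, 60))
}

# ---- index + full alignment ------------------------------------------------

#' Build a minimizer index over target sequences
#'
#' @param targets Named character vector of nucleotide sequences, or named
#'   list of integer symbol vectors in symbol space.
#' @param params An [align_params].
#' @return A `qa_index` reusable across [align()] calls.
#' @export
build_index <- function(targets, params = align_params()) {
  if (is.character(targets)) targets <- as.list(targets)
  ids <- names(targets)
  if (is.null(ids)) abort("targets must be named", class = "quantalign_parameter_error")
  enc <- map(targets, encode_seq_generic, alphabet_size = params$alphabet_size)
  mins <- map(enc, function(v) {
    if (length(v) < params$k) {
      list(pos = integer(0), hash = numeric(0), strand = integer(0))
    } else {
      minimizers_cpp(v, params$k, params$w, params$alphabet_size, params$canonical)
    }
  })
  structure(list(ids = ids, enc = enc, mins = mins,
                 lens = vapply(enc, length, integer(1)), params = params),
            class = "qa_index")
}

empty_alignments <- function() {
  tibble(query_id = character(0), query_len = integer(0), target_id = character(0),
         strand = character(0), q_start = integer(0), q_end = integer(0),
         t_start = integer(0), t_end = integer(0), cigar = character(0),
         score = numeric(0), edit_dist = integer(0), n_match = integer(0),
         mapq = integer(0), tag = character(0), domain = character(0),
         n_anchors = integer(0))
}

# query interval of a chain in original read coordinates
chain_query_span <- function(aq, strand, k, qlen) {
  lo <- min(aq); hi <- max(aq) + k
  if (strand > 0) c(lo, hi) else c(qlen - hi, qlen - lo)
}

#' Align a query against indexed targets
#'
#' Full seed-chain-extend composition: minimizers are matched against the
#' target index, anchors chained per target and strand, chains filtered by a
#' query-coverage rule (a chain is kept as a split segment if better chains
#' cover less than half of its query span; otherwise it is reported as
#' secondary), and each kept chain is extended to a base-level alignment. In
#' canonical (nucleotide) mode both strands are searched inherently; in
#' quantized mode only the supplied orientation is searched and the caller
#' aligns the quantized reverse complement as a second query.
#'
#' @param query Nucleotide string or integer symbol vector.
#' @param targets Named sequences or a prebuilt [build_index()] result.
#' @param params An [align_params]; ignored when `targets` is an index.
#' @param query_id Identifier for the output rows.
#' @param max_secondary Maximum number of secondary alignments reported.
#' @return Alignment tibble (0-based half-open coordinates, query coordinates
#'   on the original read strand, CIGAR covering exactly
#'   `q_end - q_start` query and `t_end - t_start` target bases); zero rows if
#'   the read is unmapped.
#' @export
align <- function(query, targets, params = align_params(), query_id = "query",
                  max_secondary = 5L) {
  idx <- if (inherits(targets, "qa_index")) targets else build_index(targets, params)
  params <- idx$params
  qv <- encode_seq_generic(query, params$alphabet_size)
  qlen <- length(qv)
  if (qlen < params$k) return(empty_alignments())
  qm <- minimizers_cpp(qv, params$k, params$w, params$alphabet_size, params$canonical)
  if (length(qm$pos) == 0L) return(empty_alignments())
  qrc <- if (params$alphabet_size == 4L) rev(3L - qv) else NULL

  cands <- list()
  for (ti in seq_along(idx$ids)) {
    tm <- idx$mins[[ti]]
    if (length(tm$pos) == 0L) next
    an <- collect_anchors_cpp(qm$pos, qm$hash, qm$strand,
                              tm$pos, tm$hash, tm$strand,
                              qlen, params$k, params$max_occ)
    if (length(an$q) == 0L) next
    atb <- distinct(tibble(q = an$q, t = an$t, strand = an$strand))
    for (s in unique(atb$strand)) {
      sub <- atb[atb$strand == s, ]
      ch <- chain_cpp(sub$q, sub$t, params$k, params$max_gap, params$gap_scale,
                      params$min_chain_score, params$max_lookback, 50L)
      for (c1 in ch) {
        cands[[length(cands) + 1L]] <- list(
          target = ti, strand = s, score = c1$score,
          aq = sub$q[c1$idx], at = sub$t[c1$idx])
      }
    }
  }
  if (length(cands) == 0L) return(empty_alignments())
  ord <- order(-vapply(cands, `[[`, numeric(1), "score"))
  cands <- cands[ord]

  # query-coverage selection: accepted chains become primary/supplementary
  accepted <- logical(length(cands))
  spans <- map(cands, function(c1) chain_query_span(c1$aq, c1$strand, params$k, qlen))
  cover <- matrix(numeric(0), nrow = 0, ncol = 2)
  for (i in seq_along(cands)) {
    sp <- spans[[i]]
    ov <- 0
    if (nrow(cover) > 0) {
      ov <- sum(pmax(0, pmin(cover[, 2], sp[2]) - pmax(cover[, 1], sp[1])))
    }
    if (ov < 0.5 * (sp[2] - sp[1])) {
      accepted[i] <- TRUE
      cover <- rbind(cover, sp)
    }
  }
  keep <- which(accepted | cumsum(!accepted) <= max_secondary)

  rows <- map(keep, function(i) {
    c1 <- cands[[i]]
    qv_use <- if (c1$strand > 0) qv else qrc
    segs <- stitch_chain(qv_use, idx$enc[[c1$target]], c1$aq, c1$at, params)
    list_rbind(map(segs, function(st) {
      # query coords back to the original read strand
      if (c1$strand > 0) {
        qs <- st$q_start; qe <- st$q_end
      } else {
        qs <- qlen - st$q_end; qe <- qlen - st$q_start
      }
      tibble(query_id = query_id, query_len = qlen, target_id = idx$ids[[c1$target]],
             strand = if (c1$strand > 0) "+" else "-",
             q_start = qs, q_end = qe, t_start = st$t_start, t_end = st$t_end,
             cigar = st$cigar, score = c1$score, edit_dist = st$edit,
             n_match = st$nmatch, mapq = 0L,
             tag = if (!accepted[i]) "secondary" else "primary",
             domain = if (params$alphabet_size == 4L) "nucleotide" else "quantized",
             n_anchors = st$n_anchors)
    }))
  })
  seg_counts <- vapply(rows, nrow, integer(1))
  out <- list_rbind(rows)
  acc_rows <- which(rep(accepted[keep], seg_counts))
  if (length(acc_rows) > 0L) {
    out$tag[acc_rows] <- c("primary", rep("supplementary", length(acc_rows) - 1L))
    # mapq from chain-score competition among overlapping candidates
    for (r in acc_rows) {
      sp <- c(min(out$q_start[r], out$q_end[r]), max(out$q_start[r], out$q_end[r]))
      second <- NA_real_
      for (j in seq_len(nrow(out))) {
        if (j == r) next
        ov <- max(0, min(out$q_end[j], sp[2]) - max(out$q_start[j], sp[1]))
        if (ov >= 0.5 * (sp[2] - sp[1])) {
          second <- max(second, out$score[j], na.rm = TRUE)
        }
      }
      out$mapq[r] <- compute_mapq(out$score[r], second, out$n_anchors[r])
    }
  }
  out
}
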