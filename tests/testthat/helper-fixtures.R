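# shared fixtures: tiny pore models, genomes and helpers built in code

# hand-set Q = 2 model: current = 10 * index of the first base + index of the
# second base + 50, so every lookup is checkable by hand
toy_model2 <- function() {
  bases <- c("A", "C", "G", "T")
  km <- as.vector(outer(bases, bases, paste0))
  cur <- as.vector(outer(0:3 * 10, 0:3, `+`)) + 50
  p <- tempfile(fileext = ".tsv")
  writeLines(c("kmer\tlevel_mean", sprintf("%s\t%.1f", km, cur)), p)
  load_qmer_model(p)
}

toy_current <- function(kmer) {
  idx <- setNames(0:3, c("A", "C", "G", "T"))
  10 * idx[[substr(kmer, 1, 1)]] + idx[[substr(kmer, 2, 2)]] + 50
}

fixture_model6 <- function() synthetic_qmer_model(6, seed = 11)

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# benchmark-like random SV call/truth instances: truths at separated loci,
# calls as jittered copies with occasional extras/missing
random_match_instance <- function(n_truth, refdist = 500) {
  svtypes <- sample(c("DEL", "INS", "INV"), n_truth, replace = TRUE)
  starts <- sort(sample.int(100000, n_truth)) + seq_len(n_truth) * 3000L
  lens <- sample(60:1500, n_truth, replace = TRUE)
  truths <- tibble::tibble(chrom = "chr1", start = starts,
                           end = ifelse(svtypes == "INS", starts, starts + lens),
                           svtype = svtypes, length = lens)
  keep <- runif(n_truth) < 0.8
  calls <- truths[keep, ]
  if (nrow(calls) > 0) {
    jit <- sample(-300:300, nrow(calls), replace = TRUE)
    calls$start <- calls$start + jit
    calls$length <- pmax(50L, as.integer(round(calls$length * runif(nrow(calls), 0.75, 1.3))))
    calls$end <- ifelse(calls$svtype == "INS", calls$start, calls$start + calls$length)
  }
  if (runif(1) < 0.5) {
    extra_start <- max(truths$end) + 50000L
    calls <- dplyr::bind_rows(calls, tibble::tibble(
      chrom = "chr1", start = extra_start, end = extra_start + 100L,
      svtype = "DEL", length = 100L))
  }
  list(calls = calls, truths = truths)
}

# exhaustive maximum-matching TP count under the match_calls candidate rules
optimal_tp <- function(calls, truths, refdist = 500, pctsize = 0.7) {
  nc <- nrow(calls); nt <- nrow(truths)
  if (nc == 0 || nt == 0) return(0L)
  ok <- function(ci, ti) {
    calls$chrom[ci] == truths$chrom[ti] &&
      calls$svtype[ci] == truths$svtype[ti] &&
      (abs(calls$start[ci] - truths$start[ti]) +
         abs(calls$end[ci] - truths$end[ti])) / 2 <= refdist &&
      min(calls$length[ci], truths$length[ti]) /
        max(calls$length[ci], truths$length[ti]) >= pctsize
  }
  rec <- function(ci, used) {
    if (ci > nc) return(0L)
    best <- rec(ci + 1L, used)
    for (ti in setdiff(seq_len(nt), used)) {
      if (ok(ci, ti)) best <- max(best, 1L + rec(ci + 1L, c(used, ti)))
    }
    best
  }
  rec(1L, integer(0))
}

# an sv_match with given counts, for exercising prf() arithmetic
make_match <- function(tp, fp, fn) {
  row <- tibble::tibble(chrom = "chr1", start = 0L, end = 1L,
                        svtype = "DEL", length = 1L)
  structure(list(
    pairs = tibble::tibble(call_idx = seq_len(tp), truth_idx = seq_len(tp),
                           breakpoint_score = 0, length_similarity = 1),
    fp = row[rep(1, fp), ], fn = row[rep(1, fn), ],
    n_calls = tp + fp, n_truths = tp + fn), class = "sv_match")
}

# independent exhaustive best-chain search over all increasing anchor
# subsequences, replicating the published objective
oracle_best_chain <- function(anchors, k, max_gap, gap_scale) {
  n <- nrow(anchors)
  best <- k
  rec <- function(last, score) {
    best <<- max(best, score)
    for (j in seq_len(n)) {
      dq <- anchors$q[j] - anchors$q[last]
      dt <- anchors$t[j] - anchors$t[last]
      if (dq <= 0 || dt <= 0 || dq > max_gap || dt > max_gap) next
      gd <- abs(dt - dq)
      cost <- if (gd > 0) gap_scale * gd + 0.5 * log2(gd + 1) else 0
      rec(j, score + min(k, dq, dt) - cost)
    }
  }
  for (i in seq_len(n)) rec(i, k)
  best
}

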