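test_that("edit distance matches an independent implementation", {
  expect_equal(edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(edit_distance("ACGT", "AGT"), 1L)
  set.seed(11)
  for (rep in 1:100) {
    a <- random_seq(sample(1:200, 1))
    b <- random_seq(sample(1:200, 1))
    expect_equal(edit_distance(a, b), drop(utils::adist(a, b)))
  }
})

test_that("banded alignment is exact whenever the band suffices", {
  set.seed(12)
  for (rep in 1:120) {
    a <- random_seq(sample(5:300, 1))
    b <- random_seq(sample(5:300, 1))
    res <- quantalign:::banded_global_cpp(quantalign:::encode_dna(a),
                                          quantalign:::encode_dna(b),
                                          16L, nchar(a) + nchar(b))
    expect_true(res$exact)
    expect_equal(res$edit, drop(utils::adist(a, b)))
    # CIGAR consumption invariants
    expect_equal(quantalign:::cigar_query_len(res$cigar), nchar(a))
    expect_equal(quantalign:::cigar_target_len(res$cigar), nchar(b))
  }
})

test_that("minimizer extraction follows the window-minimum definition", {
  p1 <- align_params(k = 5, w = 1)
  s <- random_seq(60)
  m <- extract_minimizers(s, p1)
  expect_equal(m$pos, 0:(60 - 5))  # w = 1: every k-mer reported

  # homopolymer: one distinct hash value
  mh <- extract_minimizers(strrep("A", 50), align_params(k = 5, w = 10))
  expect_equal(length(unique(mh$hash)), 1L)

  # shorter than k -> empty
  expect_equal(nrow(extract_minimizers("ACG", align_params(k = 5))), 0L)

  # canonical hashing: a sequence and its reverse complement share hashes
  p <- align_params(k = 7, w = 5)
  s2 <- random_seq(80)
  h1 <- sort(unique(extract_minimizers(s2, p)$hash))
  h2 <- sort(unique(extract_minimizers(seq_revcomp(s2), p)$hash))
  expect_true(length(intersect(h1, h2)) / length(union(h1, h2)) > 0.5)
})

test_that("chaining DP equals exhaustive best-chain search", {
  params <- align_params(k = 10, max_gap = 2000, min_chain_score = 0)
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    anchors <- dplyr::distinct(
      tibble::tibble(q = sample(0:500, n, replace = TRUE),
                     t = sample(0:500, n, replace = TRUE)))
    ch <- chain_anchors(anchors, params)
    oracle <- oracle_best_chain(anchors, params$k, params$max_gap, params$gap_scale)
    expect_equal(ch[[1]]$score, oracle, tolerance = 1e-9)
  }
  expect_equal(chain_anchors(tibble::tibble(q = integer(0), t = integer(0)), params),
               list())
  # perfectly co-linear anchors chain together
  co <- tibble::tibble(q = seq(0, 90, 10), t = seq(100, 190, 10))
  ch <- chain_anchors(co, params)
  expect_length(ch, 1L)
  expect_equal(nrow(ch[[1]]$anchors), 10L)
})

test_that("chain extension produces consistent CIGARs and exact alignments", {
  params <- align_params(k = 10, w = 5, min_chain_score = 10)
  set.seed(14)
  target <- random_seq(2000)
  # exact substring -> all-M alignment with zero edits
  q <- substr(target, 501, 900)
  anchors <- tibble::tibble(q = c(0, 100, 390), t = c(500, 600, 890))
  al <- extend_chain(q, target, list(anchors = anchors, score = 50), params)
  expect_equal(al$cigar[1], "400M")
  expect_equal(al$edit_dist[1], 0L)
  expect_equal(al$t_start[1], 500L)
  expect_equal(al$t_end[1], 900L)

  # noisy cases: consumption invariants always hold
  for (rep in 1:10) {
    qv <- quantalign:::encode_dna(q)
    set.seed(rep)
    qq <- quantalign:::decode_dna(
      quantalign:::mutate_read_cpp(qv, numeric(0), 1L, 0.08, 0.02, 0.02, 0))
    al <- align(qq, c(t = target), params, query_id = "r")
    for (i in seq_len(nrow(al))) {
      expect_equal(quantalign:::cigar_query_len(al$cigar[i]), al$q_end[i] - al$q_start[i])
      expect_equal(quantalign:::cigar_target_len(al$cigar[i]), al$t_end[i] - al$t_start[i])
    }
  }
})

test_that("mapq follows the chain-competition formula", {
  expect_equal(compute_mapq(100, NA, 20), 60L)
  expect_equal(compute_mapq(100, 100, 20), 0L)
  expect_equal(compute_mapq(100, 50, 20), 20L)
  # damped by low anchor count
  expect_equal(compute_mapq(100, 50, 5), 10L)
  # non-increasing in second/best
  seconds <- seq(0, 100, by = 5)
  mq <- vapply(seconds, function(s) compute_mapq(100, s, 20), integer(1))
  expect_true(all(diff(mq) <= 0))
})

test_that("align recovers planted placements on both strands", {
  set.seed(15)
  target <- random_seq(10000)
  idx <- build_index(c(chr = target), align_params())
  q <- substr(target, 3001, 3500)
  al <- align(q, idx, query_id = "r")
  expect_equal(al$strand[1], "+")
  expect_equal(al$t_start[1], 3000L)
  expect_equal(al$t_end[1], 3500L)
  expect_equal(al$edit_dist[1], 0L)
  expect_equal(al$tag[1], "primary")

  rc <- align(seq_revcomp(q), idx, query_id = "r")
  expect_equal(rc$strand[1], "-")
  expect_equal(rc$t_start[1], 3000L)
  expect_equal(rc$t_end[1], 3500L)

  # unmapped: unrelated random query
  expect_equal(nrow(align(random_seq(300), idx, query_id = "r")), 0L)
})

test_that("duplicated targets yield a low-mapq primary plus a secondary", {
  set.seed(16)
  block <- random_seq(1000)
  target <- paste0(random_seq(500), block, random_seq(800), block, random_seq(500))
  al <- align(substr(block, 100, 600), c(chr = target), align_params(), query_id = "r")
  expect_true(any(al$tag == "secondary"))
  expect_equal(sum(al$tag == "primary"), 1L)
  prim <- al[al$tag == "primary", ]
  expect_lte(prim$mapq, 10L)
  # both placements found
  starts <- sort(al$t_start[al$tag %in% c("primary", "secondary")])
  expect_equal(diff(starts), 1800L)
})

test_that("error-free sampled reads are recovered within seed tolerance", {
  set.seed(17)
  target <- random_seq(20000)
  idx <- build_index(c(chr = target), align_params())
  k <- 15; w <- 10
  for (rep in 1:10) {
    start <- sample(1:(20000 - 800), 1)
    q <- substr(target, start, start + 799)
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") q <- seq_revcomp(q)
    al <- align(q, idx, query_id = "r")
    prim <- al[al$tag == "primary", ]
    expect_equal(prim$strand, strand)
    expect_lte(abs(prim$t_start - (start - 1)), k + w)
    expect_lte(abs(prim$t_end - (start + 799)), k + w)
  }
})
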