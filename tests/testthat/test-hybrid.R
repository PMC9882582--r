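test_that("ROI extension follows b = (1 - f + 0.25) n with clamping", {
  # fully aligned read: b = 0.25 n
  r <- extend_roi(5000, 6000, 1000, 100000)
  expect_equal(r$f, 1)
  expect_equal(r$b, 250)
  expect_equal(c(r$s_q, r$e_q), c(4750, 6250))

  # half aligned: b = 0.75 n, clamped at the left edge
  r <- extend_roi(100, 600, 1000, 100000)
  expect_equal(r$b, 750)
  expect_equal(r$s_q, 0)
  expect_equal(r$e_q, 1350)

  # near the right edge: clamped to target length
  r <- extend_roi(99000, 99900, 1000, 100000)
  expect_equal(r$e_q, 100000)

  # deletion-inflated span (e - s > n): f capped at 1, b keeps its floor
  r <- extend_roi(1000, 3000, 1000, 100000)
  expect_equal(r$f, 1)
  expect_equal(r$b, 250)
})

test_that("find_rois reports one window per step-1 placement", {
  set.seed(21)
  g <- c(chr = random_seq(20000))
  read <- substr(g[[1]], 5001, 7000)
  rois <- find_rois(read, g)
  expect_equal(nrow(rois), 1L)
  expect_equal(rois$f, 1, tolerance = 0.02)
  expect_equal(rois$s_q, as.integer(rois$s - rois$b))

  # duplicated block: two windows
  block <- random_seq(1500)
  g2 <- c(chr = paste0(random_seq(1000), block, random_seq(2000), block, random_seq(1000)))
  rois2 <- find_rois(substr(block, 200, 1300), g2)
  expect_gte(nrow(rois2), 2L)

  # unrelated read: none
  expect_equal(nrow(find_rois(random_seq(500), g)), 0L)
})

test_that("quantized intervals map back to nucleotide coordinates", {
  # forward convention
  expect_equal(map_quantized_interval(0, 10, 100, "+", Q = 6), c(100, 115))
  # round trip contains the original nucleotide interval
  nt <- c(120, 180)
  q <- c(nt[1] - 100, nt[2] - 100 - 6 + 1)  # symbols fully inside [120,180)
  back <- map_quantized_interval(q[1], q[2], 100, "+", Q = 6)
  expect_lte(back[1], nt[1])
  expect_gte(back[2], nt[2])

  # minus strand on a 50-base toy window, hand-computed: window at offset 200,
  # 50 nt -> 45 symbols; RC-symbol interval [10, 20) covers RC nt [10, 25),
  # which mirrors to window nt [25, 40) -> genome [225, 240)
  expect_equal(map_quantized_interval(10, 20, 200, "-", Q = 6, window_qlen = 45),
               c(200 + 45 - 20, 200 + 45 - 10 + 5))
  expect_equal(map_quantized_interval(10, 20, 200, "-", Q = 6, window_qlen = 45),
               c(225, 240))

  expect_error(map_quantized_interval(10, 20, 200, "-", Q = 6),
               class = "quantalign_parameter_error")
  expect_error(map_quantized_interval(40, 50, 200, "-", Q = 6, window_qlen = 45),
               class = "quantalign_bounds_error")
})

test_that("hybrid alignment of an error-free read matches step 1", {
  set.seed(22)
  m <- fixture_model6()
  cfg <- compute_thresholds(m, 3)
  g <- c(chr = random_seq(30000))
  idx <- build_index(g, align_params())
  read <- substr(g[[1]], 8001, 11000)
  s1 <- align(read, idx, query_id = "r")[1, ]
  h <- hybrid_align(read, idx, m, cfg, query_id = "r")
  prim <- h[h$tag == "primary", ]
  expect_equal(prim$stage, "hybrid")
  expect_equal(prim$edit_dist, 0L)
  expect_equal(normalized_alignment_length(prim$t_start, prim$t_end, prim$query_len), 1)
  expect_lte(abs(prim$t_start - s1$t_start), 18 + 6)
  expect_lte(abs(prim$t_end - s1$t_end), 18 + 6)
})

test_that("a planted inversion yields opposite-strand split segments", {
  m <- synthetic_qmer_model(6, seed = 1)
  cfg <- compute_thresholds(m, 3)
  g <- with(list(), {
    set.seed(23); c(chr1 = random_seq(20000))
  })
  flank <- substr(g[[1]], 7001, 8000)
  mid <- seq_revcomp(substr(g[[1]], 8001, 8800))
  tail <- substr(g[[1]], 8801, 9800)
  read <- paste0(flank, mid, tail)
  h <- hybrid_align(read, g, m, cfg, query_id = "r")
  segs <- h[h$tag %in% c("primary", "supplementary"), ]
  expect_gte(nrow(segs), 2L)
  expect_setequal(unique(segs$strand), c("+", "-"))
  minus <- segs[segs$strand == "-", ]
  # the minus segment covers the planted inverted interval
  expect_lte(abs(minus$t_start[1] - 8000), 60)
  expect_lte(abs(minus$t_end[1] - 8800), 60)
  # and the extractor turns it into one INV call
  sv <- extract_sv_candidates(h, min_support = 1)
  expect_equal(sv$svtype, "INV")
  expect_equal(sv$start, minus$t_start[1])
})

test_that("step-2 search space stays inside the extended windows", {
  set.seed(24)
  m <- fixture_model6()
  cfg <- compute_thresholds(m, 3)
  g <- c(chr = random_seq(30000))
  idx <- build_index(g, align_params())
  cfg_sim <- sim_config(genome_length = 30000, seed = 24, n_ins = 0, n_del = 0,
                        n_inv = 0, coverage = 1)
  rd <- simulate_reads(g, cfg_sim, m)
  for (i in seq_along(rd$reads)) {
    read <- rd$reads[[i]]
    rois <- find_rois(read, idx)
    h <- hybrid_align(read, idx, m, cfg, query_id = "r")
    h <- h[h$stage == "hybrid", ]
    for (j in seq_len(nrow(h))) {
      inside <- any(h$t_start[j] >= rois$s_q - 60 & h$t_end[j] <= rois$e_q + 60)
      expect_true(inside)
    }
  }
})

test_that("fallback keeps every read that step 1 mapped", {
  set.seed(25)
  m <- fixture_model6()
  cfg <- compute_thresholds(m, 3)
  g <- c(chr = random_seq(20000))
  read <- substr(g[[1]], 5001, 7000)
  # an unreachable chain score forces the quantized stage to find nothing
  h <- hybrid_align(read, g, m, cfg,
                    qparams = quantized_params(min_chain_score = 1e9),
                    query_id = "r")
  expect_true(all(h$stage == "fallback"))
  expect_gte(nrow(h), 1L)
  expect_equal(h$domain[1], "nucleotide")
})

test_that("align_batch writes deterministic PAF and valid SAM", {
  set.seed(26)
  m <- fixture_model6()
  cfg <- compute_thresholds(m, 3)
  g <- c(chr = random_seq(20000))
  reads <- setNames(
    vapply(1:5, function(i) substr(g[[1]], i * 2000 + 1, i * 2000 + 1500), ""),
    paste0("r", 1:5))
  paf1 <- tempfile(fileext = ".paf"); sam1 <- tempfile(fileext = ".sam")
  a <- align_batch(reads, g, m, cfg, out_sam = sam1, out_paf = paf1)
  expect_equal(sort(unique(a$query_id)), sort(names(reads)))
  expect_true(all(a$tag[a$stage != "fallback"] != "" ))
  sam <- readLines(sam1)
  expect_true(any(grepl("^@SQ\tSN:chr\tLN:20000$", sam)))
  # rerun is byte-identical
  paf2 <- tempfile(fileext = ".paf")
  align_batch(reads, g, m, cfg, out_paf = paf2)
  expect_identical(readLines(paf1), readLines(paf2))
  # empty read set -> valid SAM with header only
  sam0 <- tempfile(fileext = ".sam")
  align_batch(setNames(character(0), character(0)), g, m, cfg, out_sam = sam0)
  expect_true(all(grepl("^@", readLines(sam0))))
})
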