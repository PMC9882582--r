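sv_row <- function(start, end, svtype = "DEL", length = end - start, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = start, end = end, svtype = svtype,
                 length = length)
}

test_that("breakpoint score is the mean absolute offset", {
  expect_equal(breakpoint_score(sv_row(100, 200), sv_row(100, 200)), 0)
  expect_equal(breakpoint_score(sv_row(110, 210), sv_row(100, 200)), 10)
  expect_equal(breakpoint_score(sv_row(100, 230), sv_row(100, 200)), 15)
  expect_error(breakpoint_score(sv_row(1, 2, chrom = "chr2"), sv_row(1, 2)),
               class = "quantalign_parameter_error")
  # invariant under coordinate translation
  set.seed(31)
  for (rep in 1:20) {
    a <- sv_row(sample(1000, 1), sample(1001:2000, 1))
    b <- sv_row(sample(1000, 1), sample(1001:2000, 1))
    sh <- sample(10000, 1)
    expect_equal(breakpoint_score(a, b),
                 breakpoint_score(sv_row(a$start + sh, a$end + sh),
                                  sv_row(b$start + sh, b$end + sh)))
  }
})

test_that("length similarity is min/max and symmetric", {
  expect_equal(length_similarity(sv_row(0, 100), sv_row(0, 100)), 1)
  expect_equal(length_similarity(sv_row(0, 80), sv_row(0, 100)), 0.8)
  set.seed(32)
  for (rep in 1:20) {
    a <- sv_row(0, sample(50:2000, 1))
    b <- sv_row(0, sample(50:2000, 1))
    expect_equal(length_similarity(a, b), length_similarity(b, a))
    expect_gt(length_similarity(a, b), 0)
    expect_lte(length_similarity(a, b), 1)
  }
  expect_error(length_similarity(sv_row(0, 0, length = 0), sv_row(0, 10)),
               class = "quantalign_parameter_error")
})

test_that("well-aligned needs >= 90% genome span and mapq strictly above 20", {
  aln <- tibble::tibble(t_start = 0L, t_end = 950L, mapq = 60L, query_len = 1000L)
  expect_true(is_well_aligned(aln))
  aln$mapq <- 20L
  expect_false(is_well_aligned(aln))
  aln$mapq <- 60L; aln$t_end <- 890L
  expect_false(is_well_aligned(aln))
  aln$t_end <- 900L  # exactly 90%: inclusive
  expect_true(is_well_aligned(aln))
})

test_that("normalized metrics follow their definitions", {
  g <- "TTTTACGTACGTTTTT"
  expect_equal(normalized_edit_distance("ACGTACGT", g, 4, 12), 0)
  # one substitution in an 8-base read
  expect_equal(normalized_edit_distance("ACGTACGT", "ACGAACGTTT", 0, 8), 1 / 8)
  expect_error(normalized_edit_distance("ACGT", g, 5, 5),
               class = "quantalign_interval_error")
  # equals a full-DP oracle on random cases
  set.seed(33)
  for (rep in 1:50) {
    read <- random_seq(sample(20:150, 1))
    target <- random_seq(300)
    s <- sample(0:100, 1); e <- s + sample(50:180, 1)
    expect_equal(normalized_edit_distance(read, target, s, e),
                 drop(utils::adist(read, substr(target, s + 1, e))) / nchar(read))
  }
  expect_equal(normalized_alignment_length(100, 600, 500), 1)
  expect_equal(normalized_alignment_length(100, 350, 500), 0.5)
  expect_gt(normalized_alignment_length(100, 900, 500), 1)  # deletion-spanning
})

test_that("call-truth matching applies type, distance and size rules", {
  truth <- sv_row(1000, 1100)
  expect_equal(nrow(match_calls(truth, truth)$pairs), 1L)

  # length similarity below the 0.7 default: unmatched on both sides
  m <- match_calls(sv_row(1000, 1060, length = 60), truth)
  expect_equal(nrow(m$pairs), 0L)
  expect_equal(nrow(m$fp), 1L)
  expect_equal(nrow(m$fn), 1L)

  # type mismatch never matches
  m <- match_calls(sv_row(1000, 1100, svtype = "INV"), truth)
  expect_equal(nrow(m$pairs), 0L)

  # each record used at most once
  calls <- dplyr::bind_rows(sv_row(1000, 1100), sv_row(1010, 1110))
  m <- match_calls(calls, truth)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$call_idx, 1L)  # closer breakpoint wins
})

test_that("greedy matching achieves the optimal TP count on benchmark-like sets", {
  set.seed(34)
  for (rep in 1:200) {
    inst <- random_match_instance(sample(1:6, 1))
    m <- match_calls(inst$calls, inst$truths)
    expect_equal(nrow(m$pairs), optimal_tp(inst$calls, inst$truths))
    # bookkeeping invariants
    expect_equal(nrow(m$pairs) + nrow(m$fp), nrow(inst$calls))
    expect_equal(nrow(m$pairs) + nrow(m$fn), nrow(inst$truths))
  }
})

test_that("precision, recall and F1 follow their definitions", {
  s <- prf(make_match(94, 6, 6))
  expect_equal(s$precision, 0.94)
  expect_equal(s$recall, 0.94)
  expect_equal(s$f1, 0.94)

  s <- prf(make_match(1, 0, 1))
  expect_equal(s$f1, 2 * 1 * 0.5 / 1.5)

  expect_warning(s0 <- prf(make_match(0, 0, 5)), "empty")
  expect_equal(s0$precision, 0)
  expect_equal(s0$f1, 0)
})

test_that("union model is duplicate-aware and never lowers recall", {
  a <- dplyr::bind_rows(sv_row(1000, 1100), sv_row(5000, 5000, "INS", 200))
  b <- dplyr::bind_rows(sv_row(9000, 9300))
  expect_equal(nrow(union_calls(a, b)), 3L)      # disjoint: concatenation
  expect_equal(nrow(union_calls(a, a)), nrow(a)) # identical: setA
  u <- union_calls(a, dplyr::bind_rows(sv_row(1010, 1110), sv_row(9000, 9300)))
  expect_equal(nrow(u), 3L)                      # duplicate collapses to setA row
  expect_true(1000 %in% u$start)
})

test_that("region exclusion drops any-overlap calls", {
  calls <- dplyr::bind_rows(sv_row(1000, 1100), sv_row(5000, 5200),
                            sv_row(7000, 7000, "INS", 90))
  bed <- tibble::tibble(chrom = "chr1", start = c(1050L, 6950L), end = c(1500L, 7100L))
  out <- exclude_regions(calls, bed)
  expect_equal(out$start, 5000)  # half-overlap and INS-in-region dropped
  expect_equal(exclude_regions(calls, bed[0, ]), calls)
})

test_that("OLS regression matches the closed form", {
  r <- regression_fit(1:10, 1:10)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  r <- regression_fit(1:10, rep(3, 10))
  expect_equal(r$slope, 0)
  set.seed(35)
  x <- rnorm(50); y <- 2 * x + rnorm(50)
  r <- regression_fit(x, y)
  sl <- cov(x, y) / var(x)
  expect_equal(r$slope, sl)
  expect_equal(r$intercept, mean(y) - sl * mean(x))
  expect_error(regression_fit(rep(1, 5), 1:5), class = "quantalign_degenerate_error")
})

test_that("CIGAR runs become SV candidates only at the 50 bp floor", {
  aln <- tibble::tibble(query_id = "r1", query_len = 500L, target_id = "chr1",
                        strand = "+", q_start = 0L, q_end = 500L,
                        t_start = 1000L, t_end = 1560L,
                        cigar = "200M60D300M", score = 100, edit_dist = 60L,
                        n_match = 500L, mapq = 60L, tag = "primary",
                        domain = "nucleotide")
  sv <- extract_sv_candidates(aln, min_support = 1)
  expect_equal(sv$svtype, "DEL")
  expect_equal(sv$start, 1200L)
  expect_equal(sv$length, 60L)

  aln$cigar <- "200M49I251M"; aln$t_end <- 1451L
  expect_equal(nrow(extract_sv_candidates(aln, min_support = 1)), 0L)

  # support threshold
  aln$cigar <- "200M60D300M"; aln$t_end <- 1560L
  expect_equal(nrow(extract_sv_candidates(aln, min_support = 3)), 0L)
})

test_that("sv benchmark object summarises matching and scores", {
  truth <- dplyr::bind_rows(sv_row(1000, 1100), sv_row(5000, 5800))
  calls <- dplyr::bind_rows(sv_row(1010, 1105), sv_row(9000, 9090))
  bm <- evaluate_sv_calls(calls, truth)
  g <- generics::glance(bm)
  expect_equal(g$tp, 1L)
  expect_equal(g$fp, 1L)
  expect_equal(g$fn, 1L)
  expect_equal(g$precision, 0.5)
  expect_equal(g$mean_breakpoint_score, 7.5)
  td <- generics::tidy(bm)
  expect_equal(nrow(td), 1L)
  expect_s3_class(ggplot2::autoplot(bm), "ggplot")
})
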