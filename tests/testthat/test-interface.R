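test_that("FASTA and FASTQ round-trip with identifiers preserved", {
  seqs <- c("read one extra words" = "ACGTACGTAA", "read_2" = "TTTTACGT")
  fa <- tempfile(fileext = ".fa")
  write_fasta(seqs, fa)
  back <- read_fasta(fa)
  expect_identical(names(back), names(seqs))
  expect_identical(unname(back), unname(seqs))

  fq <- tempfile(fileext = ".fastq")
  write_fastq(seqs, fq)
  back <- read_fastq(fq)
  expect_identical(unname(c(back)), unname(seqs))
  expect_identical(unname(attr(back, "qualities")[1]), strrep("I", 10))

  # gzip input reads identically
  fqgz <- tempfile(fileext = ".fastq.gz")
  con <- gzfile(fqgz, "w"); writeLines(readLines(fq), con); close(con)
  expect_identical(unname(c(read_fastq(fqgz))), unname(seqs))
})

test_that("truncated FASTQ errors name the failing record", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+"), fq)
  expect_error(read_fastq(fq), "record 2", class = "quantalign_format_error")
})

test_that("PAF writing preserves the 12 mandatory fields", {
  aln <- tibble::tibble(query_id = "r1", query_len = 500L, target_id = "chr1",
                        strand = "-", q_start = 10L, q_end = 480L,
                        t_start = 1000L, t_end = 1470L, cigar = "470M",
                        score = 100, edit_dist = 12L, n_match = 458L,
                        mapq = 60L, tag = "primary", domain = "nucleotide")
  p <- tempfile(fileext = ".paf")
  write_paf(aln, c(chr1 = 5000L), p)
  back <- read_paf(p)
  expect_equal(back$query_id, "r1")
  expect_equal(back$q_start, 10L)
  expect_equal(back$strand, "-")
  expect_equal(back$target_len, 5000L)
  expect_equal(back$t_end, 1470L)
  expect_equal(back$n_match, 458L)
  expect_equal(back$mapq, 60L)
})

test_that("SAM records use 1-based POS, strand flags and NM tags", {
  aln <- tibble::tibble(query_id = c("r1", "r2"), query_len = c(8L, 8L),
                        target_id = "chr1", strand = c("+", "-"),
                        q_start = c(0L, 2L), q_end = c(8L, 8L),
                        t_start = c(0L, 100L), t_end = c(8L, 106L),
                        cigar = c("8M", "6M"), score = 10, edit_dist = c(0L, 1L),
                        n_match = c(8L, 5L), mapq = 60L, tag = "primary",
                        domain = "nucleotide")
  reads <- c(r1 = "ACGTACGT", r2 = "AACCGGTT")
  p <- tempfile(fileext = ".sam")
  write_sam(aln, c(chr1 = 500L), p, reads = reads, unmapped = "r3")
  sam <- readLines(p)
  recs <- sam[!grepl("^@", sam)]
  f1 <- strsplit(recs[1], "\t")[[1]]
  expect_equal(f1[4], "1")            # POS is 1-based
  expect_equal(f1[2], "0")
  expect_equal(f1[6], "8M")
  expect_equal(f1[10], "ACGTACGT")
  expect_equal(f1[12], "NM:i:0")
  f2 <- strsplit(recs[2], "\t")[[1]]
  expect_equal(f2[2], "16")           # reverse strand
  expect_equal(f2[6], "6M2S")         # soft clip in SAM orientation
  expect_equal(f2[10], seq_revcomp("AACCGGTT"))
  f3 <- strsplit(recs[3], "\t")[[1]]
  expect_equal(f3[2], "4")            # unmapped
  expect_equal(f3[6], "*")

  # a record violating CIGAR consumption is refused with a warning
  bad <- aln[1, ]; bad$cigar <- "5M"
  expect_warning(write_sam(bad, c(chr1 = 500L), tempfile()), "invariants")
})

test_that("SV VCF coordinates convert exactly", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t101\td1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=200",
    "chr1\t301\ti1\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=75",
    "chr1\t400\tx1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL"), p)
  expect_warning(calls <- read_vcf_sv(p), "skipped")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$start[1], 100L)
  expect_equal(calls$end[1], 200L)
  expect_equal(calls$length[1], 100L)
  expect_equal(calls$start[2], 300L)
  expect_equal(calls$end[2], 300L)
  expect_equal(calls$length[2], 75L)
})

test_that("BED regions load as 0-based half-open intervals", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("# comment", "chr1\t100\t200\tname", "chr2\t0\t50"), p)
  bed <- read_bed(p)
  expect_equal(bed$chrom, c("chr1", "chr2"))
  expect_equal(bed$start, c(100L, 0L))
  expect_equal(bed$end, c(200L, 50L))
})

test_that("the command-line surface dispatches and validates", {
  expect_equal(suppressMessages(cli_main("--help")), 0L)
  expect_equal(suppressMessages(cli_main("frobnicate")), 2L)
  expect_equal(suppressMessages(cli_main(c("align", "--reads", "x.fq"))), 2L)
  expect_equal(suppressMessages(cli_main(c("eval-sv", "--help"))), 0L)
})

test_that("the CLI smoke chain simulate -> align -> call-sv -> eval-sv runs", {
  dir <- tempfile(); dir.create(dir)
  yaml::write_yaml(list(genome_length = 30000L, seed = 5, n_ins = 1, n_del = 1,
                        n_inv = 1, sv_length_range = c(100L, 400L),
                        coverage = 8), file.path(dir, "sim.yaml"))
  expect_equal(suppressMessages(
    cli_main(c("simulate", "--config", file.path(dir, "sim.yaml"),
               "--outdir", dir))), 0L)
  model_path <- file.path(dir, "model.tsv")
  write_qmer_model(synthetic_qmer_model(6, seed = 5), model_path)
  expect_equal(suppressMessages(
    cli_main(c("align", "--reads", file.path(dir, "reads.fastq"),
               "--ref", file.path(dir, "genome.fa"),
               "--model", model_path,
               "--out", file.path(dir, "aln.paf")))), 0L)
  expect_true(file.exists(file.path(dir, "aln.paf")))
  expect_equal(suppressMessages(
    cli_main(c("call-sv", "--reads", file.path(dir, "reads.fastq"),
               "--ref", file.path(dir, "genome.fa"),
               "--model", model_path, "--min-support", "2",
               "--out", file.path(dir, "calls.vcf")))), 0L)
  expect_equal(suppressMessages(
    cli_main(c("eval-sv", "--calls", file.path(dir, "calls.vcf"),
               "--truth", file.path(dir, "truth.vcf"),
               "--report", file.path(dir, "report.tsv")))), 0L)
  rep <- readr::read_tsv(file.path(dir, "report.tsv"), show_col_types = FALSE)
  expect_true(all(c("precision", "recall", "f1") %in% names(rep)))
})
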