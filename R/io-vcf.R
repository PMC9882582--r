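#' Read structural variants from VCF
#'
#' Parses a VCF (v4.x) with SVTYPE INFO keys into the package's 0-based
#' half-open call layout: a record at POS with END spans `[POS - 1, END)`;
#' insertions use SVLEN for the inserted length and `start == end`. Records
#' missing both SVLEN and END are skipped with a warning. Genotypes are
#' ignored throughout.
#'
#' @param path VCF path.
#' @param source Label for the `source` column; defaults to the file name.
#' @return SV call tibble (`chrom`, `start`, `end`, `svtype`, `length`,
#'   `support`, `source`).
#' @export
read_vcf_sv <- function(path, source = basename(path)) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- v@fix[, "INFO"]
  get_key <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(^|;)", key, "="), info)
    out[hit] <- sub(paste0(".*", key, "="), "", m)
    out
  }
  svtype <- get_key("SVTYPE")
  svlen <- suppressWarnings(as.numeric(get_key("SVLEN")))
  end <- suppressWarnings(as.numeric(get_key("END")))
  pos <- as.integer(fix$POS)
  rows <- list()
  for (i in seq_along(pos)) {
    if (is.na(svtype[i])) next
    if (is.na(svlen[i]) && is.na(end[i])) {
      warn(sprintf("record %d (%s:%d) missing both SVLEN and END; skipped",
                   i, fix$CHROM[i], pos[i]))
      next
    }
    start0 <- pos[i] - 1L
    if (svtype[i] == "INS") {
      len <- abs(svlen[i])
      if (is.na(len)) { warn(sprintf("INS record %d missing SVLEN; skipped", i)); next }
      e0 <- start0
    } else {
      e0 <- if (!is.na(end[i])) as.integer(end[i]) else start0 + as.integer(abs(svlen[i]))
      len <- e0 - start0
    }
    rows[[length(rows) + 1L]] <- tibble(chrom = fix$CHROM[i], start = start0,
                                        end = as.integer(e0), svtype = svtype[i],
                                        length = as.integer(len),
                                        support = NA_integer_, source = source)
  }
  if (length(rows) == 0L) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  svtype = character(0), length = integer(0),
                  support = integer(0), source = character(0)))
  }
  list_rbind(rows)
}

#' Write structural variants to VCF
#'
#' Minimal VCF v4.2 with symbolic ALT alleles and SVTYPE/SVLEN/END INFO keys
#' (SVLEN negative for deletions, per convention). Round-trips exactly through
#' [read_vcf_sv()].
#'
#' @param calls SV call tibble.
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf_sv <- function(calls, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=quantalign",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of structural variant">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of structural variant">')
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  if (nrow(calls) > 0L) {
    svlen <- ifelse(calls$svtype == "DEL", -calls$length, calls$length)
    recs <- sprintf("%s\t%d\tsv_%d\tN\t<%s>\t.\tPASS\tSVTYPE=%s;SVLEN=%d;END=%d",
                    calls$chrom, calls$start + 1L, seq_len(nrow(calls)),
                    calls$svtype, calls$svtype, as.integer(svlen),
                    as.integer(ifelse(calls$svtype == "INS", calls$start + 1L, calls$end)))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read exclusion regions from BED
#'
#' @param path BED path (first three columns used; 0-based half-open, as BED
#'   defines them).
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                         comment.char = "#", colClasses = "character")
  tibble(chrom = x[[1]], start = as.integer(x[[2]]), end = as.integer(x[[3]]))
}
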