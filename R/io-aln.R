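#' Write alignments as PAF
#'
#' Standard 12 mandatory columns; coordinates stay 0-based half-open as PAF
#' requires, query coordinates on the original read strand.
#'
#' @param alignments Alignment tibble.
#' @param target_lengths Named integer vector of target lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(alignments, target_lengths, path) {
  a <- alignments
  block <- map_int(a$cigar, function(c) {
    p <- cigar_parse(c); as.integer(sum(p$len[p$op %in% c("M", "I", "D", "=", "X")]))
  })
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   a$query_id, a$query_len, a$q_start, a$q_end, a$strand,
                   a$target_id, as.integer(target_lengths[a$target_id]),
                   a$t_start, a$t_end, a$n_match, block, a$mapq)
  writeLines(lines, path)
  invisible(path)
}

#' Read a PAF file
#'
#' @param path PAF path.
#' @return Tibble with the 12 mandatory columns.
#' @export
read_paf <- function(path) {
  cols <- c("query_id", "query_len", "q_start", "q_end", "strand", "target_id",
            "target_len", "t_start", "t_end", "n_match", "block_len", "mapq")
  readr::read_tsv(path, col_names = cols,
                  col_types = "ciiicciiiiii", progress = FALSE)
}

#' Write alignments as SAM
#'
#' Emits an @HD/@SQ header, 1-based POS, CIGAR with soft clips covering the
#' unaligned read ends, FLAG encoding strand/secondary/supplementary, and an
#' NM edit-distance tag. Unmapped reads are emitted as FLAG 4 records with `*`
#' CIGAR. Records violating the CIGAR consumption invariants are refused with
#' a warning rather than written.
#'
#' @param alignments Alignment tibble.
#' @param target_lengths Named integer vector of target lengths.
#' @param path Output path.
#' @param reads Optional named character vector of read sequences for SEQ
#'   (reverse-complemented on `-` records); `*` otherwise.
#' @param unmapped Character vector of read ids to emit as unmapped.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, target_lengths, path, reads = NULL,
                      unmapped = character(0)) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(target_lengths),
                   as.integer(target_lengths)),
           "@PG\tID:quantalign\tPN:quantalign")
  recs <- character(0)
  for (i in seq_len(nrow(alignments))) {
    r <- alignments[i, ]
    if (cigar_query_len(r$cigar) != r$q_end - r$q_start ||
        cigar_target_len(r$cigar) != r$t_end - r$t_start) {
      warn(sprintf("record %s violates CIGAR consumption invariants; not written",
                   r$query_id))
      next
    }
    flag <- 0L
    if (r$strand == "-") flag <- flag + 16L
    if (r$tag == "secondary") flag <- flag + 256L
    if (r$tag == "supplementary") flag <- flag + 2048L
    # soft clips in SAM orientation
    lead <- if (r$strand == "+") r$q_start else r$query_len - r$q_end
    trail <- r$query_len - (r$q_end - r$q_start) - lead
    p <- cigar_parse(r$cigar)
    cig <- cigar_build(c(lead, p$len, trail), c("S", p$op, "S"))
    seq <- "*"
    if (!is.null(reads) && r$query_id %in% names(reads)) {
      seq <- reads[[r$query_id]]
      if (r$strand == "-") seq <- seq_revcomp(seq)
    }
    recs <- c(recs, sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                            r$query_id, flag, r$target_id, r$t_start + 1L,
                            r$mapq, cig, seq, r$edit_dist))
  }
  for (id in unmapped) {
    seq <- if (!is.null(reads) && id %in% names(reads)) reads[[id]] else "*"
    recs <- c(recs, sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", id, seq))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
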