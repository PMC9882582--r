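#' Read sequences from FASTA
#'
#' @param path FASTA path, plain or gzip.
#' @return Named character vector, identifiers preserved verbatim and records
#'   in file order.
#' @export
read_fasta <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                error = function(e) abort(sprintf("malformed FASTA '%s': %s",
                                                  path, conditionMessage(e)),
                                          class = "quantalign_format_error"))
  setNames(as.character(x), names(x))
}

#' Read sequences from FASTQ
#'
#' @param path FASTQ path, plain or gzip.
#' @return Named character vector of sequences with the quality strings in
#'   attribute `qualities`.
#' @export
read_fastq <- function(path) {
  nl <- length(readLines(path))
  if (nl %% 4L != 0L) {
    abort(sprintf("malformed FASTQ '%s': truncated at record %d", path, nl %/% 4L + 1L),
          class = "quantalign_format_error")
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      # diagnose the failing record for a useful message
      ln <- tryCatch(length(readLines(path)), error = function(e2) NA_integer_)
      rec <- if (!is.na(ln) && ln %% 4L != 0L) ln %/% 4L + 1L else NA_integer_
      msg <- if (!is.na(rec)) {
        sprintf("malformed FASTQ '%s': truncated at record %d", path, rec)
      } else sprintf("malformed FASTQ '%s': %s", path, conditionMessage(e))
      abort(msg, class = "quantalign_format_error")
    })
  out <- setNames(as.character(x), names(x))
  q <- S4Vectors::mcols(x)$qualities
  if (!is.null(q)) attr(out, "qualities") <- setNames(as.character(q), names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}

#' Write sequences to FASTQ
#'
#' Quality strings default to a constant placeholder; the pipeline never
#' consumes them.
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param qualities Optional named character vector of quality strings.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, qualities = NULL) {
  qual <- if (is.null(qualities)) {
    vapply(seqs, function(s) strrep("I", nchar(s)), character(1))
  } else qualities[names(seqs)]
  writeLines(as.vector(rbind(paste0("@", names(seqs)), unname(seqs),
                             "+", unname(qual))), path)
  invisible(path)
}
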