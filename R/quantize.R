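#' Translate a nucleotide sequence into current levels
#'
#' Slides a window of length Q along the sequence and looks each Q-mer up in
#' the pore model, yielding the sequence of median current levels the pore
#' would see. The output has `nchar(nt_seq) - Q + 1` elements; element i is
#' the model current for the Q-mer starting at position i.
#'
#' @param nt_seq A single ACGT string of length >= Q.
#' @param model A [qmer_model].
#' @return Numeric vector of currents (picoamperes).
#' @export
current_sequence <- function(nt_seq, model) {
  Q <- qmer_q(model)
  if (nchar(nt_seq) < Q) {
    abort(sprintf("sequence length %d is shorter than Q = %d", nchar(nt_seq), Q),
          class = "quantalign_length_error")
  }
  v <- encode_dna(nt_seq)
  if (any(v < 0L)) {
    abort("sequence contains non-ACGT characters; split with split_on_ambiguous() first",
          class = "quantalign_ambiguity_error")
  }
  qmer_currents_cpp(v, current_vector(model), Q)
}

new_quantized_seq <- function(symbols, source_length, source_id, orientation, levels) {
  structure(as.integer(symbols),
            source_length = as.integer(source_length),
            source_id = source_id,
            orientation = orientation,
            levels = as.integer(levels),
            class = "quantized_seq")
}

#' @export
print.quantized_seq <- function(x, ...) {
  cat(sprintf("<quantized_seq> %s, %d symbols over {0..%d} (%s, source %d nt)\n",
              attr(x, "source_id"), length(x), attr(x, "levels") - 1L,
              attr(x, "orientation"), attr(x, "source_length")))
  invisible(x)
}

#' Quantize a nucleotide sequence to current-level symbols
#'
#' Converts the sequence to currents through the Q-mer map and hard-thresholds
#' each current into one of `cfg$levels` symbols. Symbol i is the number of
#' thresholds strictly below current i, so a current exactly equal to a
#' threshold falls in the lower bin. With three levels this is the ternary
#' "HQ3" code: basecalled sequences whose Q-mers share current levels collapse
#' onto identical symbol strings, which is exactly the confusability the
#' downstream quantized alignment exploits.
#'
#' @param nt_seq A single ACGT string of length >= Q.
#' @param model A [qmer_model].
#' @param cfg A `quantizer_config` from [compute_thresholds()].
#' @param source_id Identifier carried on the result.
#' @return A `quantized_seq`: integer vector of symbols with provenance
#'   attributes (`source_length`, `source_id`, `orientation`, `levels`).
#' @export
quantize_sequence <- function(nt_seq, model, cfg, source_id = "seq") {
  cur <- current_sequence(nt_seq, model)
  sym <- findInterval(cur, cfg$thresholds, left.open = TRUE)
  new_quantized_seq(sym, nchar(nt_seq), source_id, "forward", cfg$levels)
}

#' Quantized reverse complement
#'
#' Quantizes the reverse complement of the nucleotide sequence. In symbol
#' space no complement operation exists - the quantized reverse complement
#' cannot be computed from the forward quantized sequence - so the aligner
#' must be handed both orientations as separate queries; this function
#' produces the second one.
#'
#' @inheritParams quantize_sequence
#' @return A `quantized_seq` with orientation `"reverse-complement"`.
#' @export
quantized_reverse_complement <- function(nt_seq, model, cfg, source_id = "seq") {
  out <- quantize_sequence(seq_revcomp(nt_seq), model, cfg, source_id)
  attr(out, "orientation") <- "reverse-complement"
  out
}

#' Split a sequence on ambiguous bases
#'
#' Q-mer lookup is undefined on non-ACGT characters, so sequences are split
#' into maximal ACGT-only runs before quantization; runs shorter than
#' `min_len` (typically Q) are dropped because they contain no complete
#' window.
#'
#' @param nt_seq A single string.
#' @param min_len Minimum run length to keep.
#' @return A tibble with columns `offset` (0-based start of the run in
#'   `nt_seq`) and `seq`.
#' @export
split_on_ambiguous <- function(nt_seq, min_len = 1L) {
  m <- gregexpr("[ACGTacgt]+", nt_seq)[[1]]
  if (m[1] == -1L) return(tibble(offset = integer(0), seq = character(0)))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  keep <- lens >= min_len
  tibble(offset = starts[keep] - 1L,
         seq = substring(nt_seq, starts[keep], starts[keep] + lens[keep] - 1L))
}

#' Render quantized symbols as characters
#'
#' Maps symbols 0,1,2,... to single characters so quantized sequences can be
#' exported FASTA-style for an external aligner backend.
#'
#' @param qseq A `quantized_seq` or integer vector of symbols.
#' @param chars Character alphabet; defaults to A, C, G so a ternary sequence
#'   is valid DNA text for tools that insist on it.
#' @return A single string.
#' @export
quantized_to_chars <- function(qseq, chars = c("A", "C", "G")) {
  sym <- as.integer(qseq)
  if (max(sym) + 1L > length(chars)) {
    abort("not enough characters for the symbol alphabet",
          class = "quantalign_parameter_error")
  }
  paste(chars[sym + 1L], collapse = "")
}

#' Export quantized sequences as FASTA
#'
#' @param qseqs A named list of `quantized_seq` objects (or integer vectors).
#' @param path Output FASTA path.
#' @param chars Symbol-to-character map, as in [quantized_to_chars()].
#' @return `path`, invisibly.
#' @export
write_quantized_fasta <- function(qseqs, path, chars = c("A", "C", "G")) {
  ids <- names(qseqs) %||% paste0("q", seq_along(qseqs))
  lines <- unlist(map2(ids, qseqs, function(id, q) {
    c(paste0(">", id), quantized_to_chars(q, chars))
  }))
  writeLines(lines, path)
  invisible(path)
}
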