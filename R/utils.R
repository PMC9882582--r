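# internal helpers shared across modules

# run code under a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

BASES <- c("A", "C", "G", "T")

# encode a nucleotide string to 0..3 integers; -1 marks ambiguity
encode_dna <- function(s) encode_dna_cpp(s)

decode_dna <- function(v) {
  paste(BASES[v + 1L], collapse = "")
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of ACGT strings.
#' @return Character vector of reverse complements.
#' @export
seq_revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# accept either a nucleotide string or an integer/quantized symbol vector
encode_seq_generic <- function(x, alphabet_size = 4L) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    v <- encode_dna(x)
    if (any(v < 0L)) {
      abort("sequence contains non-ACGT characters; split with split_on_ambiguous() first",
            class = "quantalign_ambiguity_error")
    }
    v
  } else {
    v <- as.integer(x)
    if (any(v < 0L | v >= alphabet_size)) {
      abort("symbol out of range for alphabet", class = "quantalign_alphabet_error")
    }
    v
  }
}

# ---- CIGAR helpers ---------------------------------------------------------

cigar_parse <- function(cigar) {
  if (is.na(cigar) || cigar == "" || cigar == "*") {
    return(list(len = integer(0), op = character(0)))
  }
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  stopifnot(length(len) == length(op))
  list(len = len, op = op)
}

cigar_build <- function(len, op) {
  keep <- len > 0L
  len <- len[keep]; op <- op[keep]
  if (length(len) == 0L) return("")
  # merge adjacent identical ops
  grp <- cumsum(c(TRUE, op[-1] != op[-length(op)]))
  len <- as.integer(tapply(len, grp, sum))
  op <- op[!duplicated(grp)]
  paste0(len, op, collapse = "")
}

cigar_query_len <- function(cigar) {
  p <- cigar_parse(cigar)
  sum(p$len[p$op %in% c("M", "I", "=", "X")])
}

cigar_target_len <- function(cigar) {
  p <- cigar_parse(cigar)
  sum(p$len[p$op %in% c("M", "D", "=", "X", "N")])
}

# reverse a CIGAR (op order only; used when an extension was computed on
# reversed sequences)
cigar_reverse <- function(cigar) {
  p <- cigar_parse(cigar)
  cigar_build(rev(p$len), rev(p$op))
}
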