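#' Q-mer pore models
#'
#' A Q-mer pore model is the physics table of a nanopore flow cell: for every
#' Q-length nucleotide word it records the median ionic current (picoamperes)
#' observed while that word occupies the pore, optionally with a per-word
#' standard deviation. The model is represented as a tibble with columns
#' `kmer`, `current` and `sd`, carrying the word length in attribute `Q`, and
#' is the sole input to sequence quantization: no raw-signal information is
#' used anywhere.
#'
#' @name qmer_model
NULL

all_kmers <- function(Q) {
  if (Q == 1L) return(BASES)
  rest <- all_kmers(Q - 1L)
  as.vector(vapply(BASES, function(b) paste0(b, rest), character(length(rest))))
}

new_qmer_model <- function(kmer, current, sd = NULL) {
  Q <- unique(nchar(kmer))
  if (length(Q) != 1L) {
    abort("k-mers of inconsistent length in pore model",
          class = "quantalign_format_error")
  }
  Q <- as.integer(Q)
  if (!all(grepl("^[ACGT]+$", kmer))) {
    abort("pore model k-mers must be over {A,C,G,T}",
          class = "quantalign_format_error")
  }
  expected <- all_kmers(Q)
  missing <- setdiff(expected, kmer)
  if (length(missing) > 0L) {
    abort(sprintf("pore model incomplete: %d of %d %d-mers absent (first: %s)",
                  length(missing), length(expected), Q, missing[1]),
          class = "quantalign_completeness_error")
  }
  if (anyDuplicated(kmer)) {
    abort("duplicated k-mer in pore model", class = "quantalign_format_error")
  }
  if (!all(is.finite(current)) || any(current <= 0)) {
    abort("current values must be finite and strictly positive",
          class = "quantalign_value_error")
  }
  out <- tibble(kmer = kmer, current = as.numeric(current),
                sd = if (is.null(sd)) NA_real_ else as.numeric(sd))
  # store lexicographic (A<C<G<T) order so the base-4 code indexes directly
  out <- out[order(out$kmer), ]
  structure(out, Q = Q, class = c("qmer_model", class(tibble())))
}

#' @describeIn qmer_model The k-mer length Q of a pore model.
#' @param model A `qmer_model`.
#' @export
qmer_q <- function(model) attr(model, "Q")

# dense current vector indexed by the base-4 encoding of the k-mer
current_vector <- function(model) model$current

#' Load a Q-mer pore model from an ONT-style table
#'
#' Reads a tab-separated pore model in the ONT dialect: a `kmer` column and a
#' `level_mean` current column (plus optional `level_stdv`), with or without a
#' header line. The table must be complete - one row per possible Q-mer.
#'
#' @param path Path to the tab-separated model file.
#' @return A [qmer_model] tibble with attribute `Q` inferred from the k-mer
#'   strings.
#' @examples
#' p <- tempfile()
#' write_qmer_model(synthetic_qmer_model(2, seed = 1), p)
#' m <- load_qmer_model(p)
#' qmer_q(m)
#' @export
load_qmer_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("empty pore model file", class = "quantalign_format_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- fields[[1]]
  has_header <- !grepl("^[ACGTacgt]+$", first[[1]])
  kcol <- 1L; ccol <- 2L; scol <- NA_integer_
  if (has_header) {
    hdr <- tolower(first)
    kcol <- match("kmer", hdr, nomatch = 1L)
    ccol <- match("level_mean", hdr, nomatch = 2L)
    scol <- match("level_stdv", hdr)
    fields <- fields[-1]
  }
  kmer <- toupper(vapply(fields, `[[`, character(1), kcol))
  cur_chr <- vapply(fields, `[[`, character(1), ccol)
  current <- suppressWarnings(as.numeric(cur_chr))
  if (anyNA(current)) {
    abort(sprintf("non-numeric current value '%s' in pore model",
                  cur_chr[which(is.na(current))[1]]),
          class = "quantalign_parse_error")
  }
  sd <- NULL
  if (!is.na(scol) && all(lengths(fields) >= scol)) {
    sd <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), scol)))
  }
  new_qmer_model(kmer, current, sd)
}

#' Write a Q-mer pore model in the ONT table dialect
#'
#' @param model A [qmer_model].
#' @param path Output path; a tab-separated file with a header line is
#'   written, round-trippable through [load_qmer_model()].
#' @return `path`, invisibly.
#' @export
write_qmer_model <- function(model, path) {
  has_sd <- any(is.finite(model$sd))
  hdr <- if (has_sd) "kmer\tlevel_mean\tlevel_stdv" else "kmer\tlevel_mean"
  body <- if (has_sd) {
    sprintf("%s\t%.6f\t%.6f", model$kmer, model$current, model$sd)
  } else {
    sprintf("%s\t%.6f", model$kmer, model$current)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate a synthetic Q-mer pore model
#'
#' Builds a physically structured stand-in for a flow-cell model: the median
#' current of a Q-mer is modelled as a position-weighted sum of per-base
#' contributions (weights peaked at the central positions, as in nanopore
#' pores where two or three bases dominate the signal) plus a small
#' idiosyncratic term per Q-mer. This additivity is what real pore tables
#' exhibit and what creates genuine current-level confusability: substituting
#' a base for one with a close contribution shifts every overlapping window's
#' current by the same small amount, so whole regions can change in nucleotide
#' space while staying identical in quantized space. Deterministic for a fixed
#' seed; the default mean/sd roughly matches the 50-130 pA dynamic range of
#' R9.4 pores.
#'
#' @param Q K-mer length (>= 1).
#' @param seed Integer seed; the same arguments always yield the identical
#'   model.
#' @param mean,sd Centre and spread of the current distribution, picoamperes.
#' @param weights Optional positive weights of length Q for the per-position
#'   contributions; default is centre-peaked.
#' @param idio Standard deviation of the per-Q-mer idiosyncratic term as a
#'   fraction of `sd`.
#' @param pair_scatter Within-class scatter of the per-base contributions as a
#'   fraction of the between-class spread. The four bases form two current
#'   classes (A/T and C/G); a small value makes within-class substitutions
#'   nearly invisible to the pore, reproducing the strong k-mer confusability
#'   real flow-cell tables show.
#' @return A [qmer_model] with 4^Q entries.
#' @export
synthetic_qmer_model <- function(Q, seed = 1L, mean = 90, sd = 12,
                                 weights = NULL, idio = 0.05,
                                 pair_scatter = 0.15) {
  if (!is.numeric(Q) || Q < 1) {
    abort("Q must be a positive integer", class = "quantalign_parameter_error")
  }
  if (sd <= 0) abort("sd must be > 0", class = "quantalign_parameter_error")
  Q <- as.integer(Q)
  if (is.null(weights)) {
    # centre-peaked profile: each step away from the pore centre contributes
    # 3x less, roughly the shape of published per-position importances
    weights <- 3^(-abs(seq_len(Q) - (Q + 1) / 2))
  }
  weights <- weights / sum(weights)
  km <- all_kmers(Q)
  cur <- with_seed(seed, {
    # two current classes (A/T, C/G) with small within-class scatter
    centers <- matrix(rnorm(2L * Q), nrow = 2L)
    contrib <- centers[c(1L, 2L, 2L, 1L), , drop = FALSE] +
      matrix(rnorm(4L * Q, 0, pair_scatter), nrow = 4L)
    eps <- rnorm(length(km), 0, idio)
    codes <- t(vapply(strsplit(km, "", fixed = TRUE),
                      function(b) match(b, BASES), integer(Q)))
    z <- vapply(seq_len(Q), function(j) contrib[codes[, j], j] * weights[j],
                numeric(length(km)))
    raw <- rowSums(z) / sqrt(sum(weights^2)) + eps
    mean + sd * raw / sqrt(1 + idio^2)
  })
  cur <- abs(cur)
  cur[cur == 0] <- mean
  new_qmer_model(km, cur)
}

#' Quantizer configuration: current-level thresholds
#'
#' Computes the hard-thresholding configuration that maps continuous current
#' levels to `levels` discrete symbols. Thresholds are the equal-mass
#' quantiles of the multiset of 4^Q median currents (for three levels, the 1/3
#' and 2/3 quantiles), using the lower empirical quantile convention: the
#' value at index `floor(m * i / levels)` of the sorted multiset. Equal-mass
#' thresholds give the maximum-entropy short-alphabet code for the model at
#' hand; the rule is a documented package choice and the thresholds are plain
#' numbers, so any other rule can be supplied by constructing the config
#' directly.
#'
#' @param model A [qmer_model].
#' @param levels Number of quantization levels (>= 1); 3 is the ternary "HQ3"
#'   setting used throughout.
#' @return A `quantizer_config`: list with `levels` and a strictly increasing
#'   numeric vector `thresholds` of length `levels - 1`.
#' @examples
#' m <- synthetic_qmer_model(2, seed = 1)
#' compute_thresholds(m, 3)
#' @export
compute_thresholds <- function(model, levels = 3L) {
  if (!is.numeric(levels) || levels < 1) {
    abort("levels must be >= 1", class = "quantalign_parameter_error")
  }
  levels <- as.integer(levels)
  cur <- sort(model$current)
  m <- length(cur)
  if (levels > length(unique(cur))) {
    abort("more levels than distinct current values: thresholds degenerate",
          class = "quantalign_degenerate_error")
  }
  if (levels == 1L) return(quantizer_config(1L, numeric(0)))
  idx <- floor(m * seq_len(levels - 1L) / levels)
  idx <- pmax(idx, 1L)
  thr <- cur[idx]
  if (any(diff(thr) <= 0)) {
    abort("tied current values make thresholds non-increasing; reduce levels",
          class = "quantalign_degenerate_error")
  }
  quantizer_config(levels, thr)
}

#' @describeIn compute_thresholds Construct a quantizer configuration from
#'   explicit thresholds.
#' @param thresholds Strictly increasing numeric vector of length
#'   `levels - 1` (picoamperes).
#' @export
quantizer_config <- function(levels, thresholds) {
  levels <- as.integer(levels)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != levels - 1L) {
    abort("levels must equal length(thresholds) + 1",
          class = "quantalign_parameter_error")
  }
  if (length(thresholds) > 1L && any(diff(thresholds) <= 0)) {
    abort("thresholds must be strictly increasing",
          class = "quantalign_parameter_error")
  }
  structure(list(levels = levels, thresholds = thresholds),
            class = "quantizer_config")
}

#' @export
print.quantizer_config <- function(x, ...) {
  cat(sprintf("<quantizer_config> %d levels; thresholds: %s\n", x$levels,
              paste(signif(x$thresholds, 5), collapse = ", ")))
  invisible(x)
}
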