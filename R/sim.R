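#' Simulation configuration
#'
#' Parameters of the synthetic study: a random genome, planted structural
#' variants, and nanopore-like long reads whose substitution errors prefer
#' current-level-confusable Q-mers. Defaults are a desk-scale version of the
#' usual long-read SV benchmark design (a 200-kb genome with 10 deletions, 10
#' insertions and 5 inversions of length uniform on 50-2000 bases, 20x
#' coverage at ~10% total error); the full-scale design uses SV lengths up to
#' 10 kb and thousands of indels, which the same knobs express.
#'
#' @param genome_length Genome length, bases.
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed; every simulation step is deterministic given it.
#' @param n_ins,n_del,n_inv Planted SV counts per type.
#' @param sv_length_range Two integers, inclusive SV length bounds.
#' @param min_sv_separation Minimum distance between planted SVs, bases.
#' @param coverage Mean read coverage.
#' @param read_meanlog,read_sdlog Log-normal read-length parameters; the
#'   defaults give a median read of 3 kb.
#' @param min_read_length Shortest read emitted.
#' @param sub_rate,ins_rate,del_rate Per-base error rates (defaults sum to
#'   0.10, the technology's average error).
#' @param confusion_weight Probability in `[0, 1]` that a substitution picks
#'   the base whose Q-mer current is nearest the original (1 = fully
#'   signal-biased, 0 = uniform).
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 200000L, gc = 0.5, seed = 1L,
                       n_ins = 10L, n_del = 10L, n_inv = 5L,
                       sv_length_range = c(50L, 2000L),
                       min_sv_separation = 1000L,
                       coverage = 20, read_meanlog = log(3000), read_sdlog = 0.45,
                       min_read_length = 1000L,
                       sub_rate = 0.06, ins_rate = 0.02, del_rate = 0.02,
                       confusion_weight = 0.8) {
  stopifnot(genome_length >= 1000, gc > 0, gc < 1,
            n_ins >= 0, n_del >= 0, n_inv >= 0,
            length(sv_length_range) == 2, sv_length_range[1] <= sv_length_range[2],
            coverage >= 0, sub_rate >= 0, sub_rate <= 1, ins_rate >= 0,
            del_rate >= 0, confusion_weight >= 0, confusion_weight <= 1)
  structure(list(genome_length = as.integer(genome_length), gc = gc,
                 seed = as.integer(seed), n_ins = as.integer(n_ins),
                 n_del = as.integer(n_del), n_inv = as.integer(n_inv),
                 sv_length_range = as.integer(sv_length_range),
                 min_sv_separation = as.integer(min_sv_separation),
                 coverage = coverage, read_meanlog = read_meanlog,
                 read_sdlog = read_sdlog, min_read_length = as.integer(min_read_length),
                 sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
                 confusion_weight = confusion_weight),
            class = "sim_config")
}

random_dna <- function(n, gc) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a random genome
#'
#' I.i.d. bases at the configured GC content, deterministic per seed.
#'
#' @param cfg A [sim_config].
#' @return Named character vector of one chromosome, `chr1`.
#' @export
simulate_genome <- function(cfg) {
  with_seed(cfg$seed, c(chr1 = random_dna(cfg$genome_length, cfg$gc)))
}

#' Plant structural variants into a genome
#'
#' Places the configured numbers of insertions, deletions and inversions at
#' rejection-sampled positions separated by at least `min_sv_separation`
#' bases, with lengths uniform on `sv_length_range`. Deletions remove
#' sequence, insertions add random sequence, inversions reverse-complement in
#' place. Truth coordinates are reported on the ORIGINAL reference (0-based
#' half-open), so alignment-based calls against that reference are directly
#' comparable; sequence outside the SV intervals is conserved exactly.
#'
#' @param genome Named character vector (single chromosome used per name).
#' @param cfg A [sim_config].
#' @return List with `genome` (mutated, same names) and `truth` (SV call
#'   tibble with a `source = "truth"` column).
#' @export
plant_svs <- function(genome, cfg) {
  chrom <- names(genome)[1]
  seq0 <- genome[[1]]
  L <- nchar(seq0)
  types <- c(rep("INS", cfg$n_ins), rep("DEL", cfg$n_del), rep("INV", cfg$n_inv))
  nsv <- length(types)
  if (nsv == 0L) {
    return(list(genome = genome,
                truth = tibble(chrom = character(0), start = integer(0),
                               end = integer(0), svtype = character(0),
                               length = integer(0), support = integer(0),
                               source = character(0))))
  }
  res <- with_seed(cfg$seed + 1L, {
    lens <- cfg$sv_length_range[1] - 1L +
      sample.int(cfg$sv_length_range[2] - cfg$sv_length_range[1] + 1L, nsv,
                 replace = TRUE)
    sep <- cfg$min_sv_separation
    if (sum(lens + sep) + 2L * sep > 0.8 * L) {
      abort("genome too small for the requested SVs",
            class = "quantalign_capacity_error")
    }
    placed <- tibble(start = integer(0), end = integer(0))
    pos <- integer(nsv)
    for (i in seq_len(nsv)) {
      span <- if (types[i] == "INS") 0L else lens[i]
      ok <- FALSE
      for (try in 1:2000) {
        p <- sample.int(L - span - 2L * sep, 1L) + sep
        if (nrow(placed) == 0L ||
            all(p - sep >= placed$end | p + span + sep <= placed$start)) {
          ok <- TRUE; break
        }
      }
      if (!ok) abort("could not place SVs with the required separation",
                     class = "quantalign_capacity_error")
      pos[i] <- p
      placed <- bind_rows(placed, tibble(start = p, end = p + span))
    }
    ins_seq <- map_chr(seq_len(nsv), function(i) {
      if (types[i] == "INS") random_dna(lens[i], cfg$gc) else ""
    })
    list(lens = lens, pos = pos, ins_seq = ins_seq)
  })
  truth <- tibble(chrom = chrom, start = res$pos,
                  end = ifelse(types == "INS", res$pos, res$pos + res$lens),
                  svtype = types, length = res$lens,
                  support = NA_integer_, source = "truth") |>
    arrange(.data$start)
  ins_by_start <- setNames(res$ins_seq, as.character(res$pos))
  # apply right-to-left so earlier coordinates stay valid
  ord <- order(truth$start, decreasing = TRUE)
  mut <- seq0
  for (i in ord) {
    s <- truth$start[i]; e <- truth$end[i]
    pre <- substr(mut, 1L, s)
    post <- substr(mut, e + 1L, nchar(mut))
    mid <- switch(truth$svtype[i],
                  DEL = "",
                  INS = ins_by_start[[as.character(s)]],
                  INV = seq_revcomp(substr(mut, s + 1L, e)))
    mut <- paste0(pre, mid, post)
  }
  truth$support <- NA_integer_
  list(genome = setNames(mut, chrom), truth = truth)
}

#' Simulate nanopore-like long reads
#'
#' Reads are sampled uniformly from the genome with random strand, lengths
#' log-normal (truncated to `[min_read_length, genome length]`), and mutated
#' base by base: substitutions at `sub_rate` pick, with probability
#' `confusion_weight`, the alternative base whose Q-mer (original context) has
#' the current level nearest the original Q-mer's - the signal-induced error
#' bias - and a uniform alternative otherwise; insertions and deletions occur
#' at their own rates. Quality strings are constant placeholders; the pipeline
#' never reads them.
#'
#' @param genome Named character vector (typically the mutated genome from
#'   [plant_svs()]).
#' @param cfg A [sim_config].
#' @param model A [qmer_model]; required when `confusion_weight > 0`.
#' @return List with `reads` (named character vector) and `truth` (tibble of
#'   origins: `read_id`, `chrom`, `start`, `end`, `strand`, `length` on the
#'   sampled genome).
#' @export
simulate_reads <- function(genome, cfg, model = NULL) {
  if (cfg$confusion_weight > 0 && cfg$sub_rate > 0 && is.null(model)) {
    abort("a qmer_model is required when confusion_weight > 0",
          class = "quantalign_parameter_error")
  }
  currents <- if (is.null(model)) numeric(0) else current_vector(model)
  Q <- if (is.null(model)) 1L else qmer_q(model)
  chroms <- names(genome)
  clens <- nchar(genome)
  with_seed(cfg$seed + 2L, {
    total <- cfg$coverage * sum(clens)
    reads <- character(0); ids <- character(0)
    truth <- list()
    acc <- 0; i <- 0L
    while (acc < total) {
      i <- i + 1L
      len <- round(rlnorm(1, cfg$read_meanlog, cfg$read_sdlog))
      ci <- if (length(chroms) == 1L) 1L else sample(seq_along(chroms), 1L, prob = clens)
      len <- min(max(len, cfg$min_read_length), clens[ci])
      start <- sample.int(clens[ci] - len + 1L, 1L) - 1L
      strand <- if (runif(1) < 0.5) "+" else "-"
      sub <- substr(genome[[ci]], start + 1L, start + len)
      if (strand == "-") sub <- seq_revcomp(sub)
      v <- encode_dna(sub)
      if (cfg$sub_rate + cfg$ins_rate + cfg$del_rate > 0) {
        v <- mutate_read_cpp(v, currents, Q, cfg$sub_rate, cfg$ins_rate,
                             cfg$del_rate, cfg$confusion_weight)
      }
      id <- sprintf("read_%05d", i)
      ids <- c(ids, id)
      reads <- c(reads, decode_dna(v))
      truth[[i]] <- tibble(read_id = id, chrom = chroms[ci], start = start,
                           end = start + len, strand = strand, length = len)
      acc <- acc + len
    }
    list(reads = setNames(reads, ids), truth = list_rbind(truth))
  })
}

#' Find a current-level-confusable sequence pair
#'
#' Randomized search for two distinct nucleotide sequences with identical
#' quantized sequences under the given model and quantizer - the
#' quantization-collapses-errors phenomenon that motivates aligning in symbol
#' space. Candidates are single-base substitutions of random sequences; the
#' verifier is the quantizer itself.
#'
#' @param model A [qmer_model].
#' @param cfg A `quantizer_config`.
#' @param length Sequence length (>= Q).
#' @param max_tries Search budget.
#' @param seed Seed for the search.
#' @return Character vector `c(seqA, seqB)` with
#'   `quantize_sequence(seqA) == quantize_sequence(seqB)` and `seqA != seqB`.
#' @export
confusable_pair <- function(model, cfg, length = 10L, max_tries = 20000L, seed = 1L) {
  Q <- qmer_q(model)
  if (length < Q) abort("length must be >= Q", class = "quantalign_parameter_error")
  with_seed(seed, {
    for (t in seq_len(max_tries)) {
      a <- random_dna(length, 0.5)
      qa <- as.integer(quantize_sequence(a, model, cfg))
      pos <- sample.int(length, 1L)
      orig <- substr(a, pos, pos)
      alt <- sample(setdiff(BASES, orig), 1L)
      b <- paste0(substr(a, 1L, pos - 1L), alt, substr(a, pos + 1L, length))
      qb <- as.integer(quantize_sequence(b, model, cfg))
      if (identical(qa, qb)) return(c(a, b))
    }
    abort("no confusable pair found within the trial budget",
          class = "quantalign_notfound_error")
  })
}
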