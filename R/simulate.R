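# Synthetic-data generators: random references, mutated references,
# simulated reads, and the edit-distance calibration experiment that
# motivates the learning-rate schedule.

#' Random DNA sequence with controlled GC content
#'
#' I.i.d. draws with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`.
#'
#' @param length Sequence length.
#' @param gc GC content in `[0, 1]` (default 0.5).
#' @param seed Optional RNG seed.
#' @return A character scalar.
#' @export
random_sequence <- function(length, gc = 0.5, seed = NULL) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_ALPHABET, length, replace = TRUE, prob = p), collapse = "")
}

#' Mutate a sequence with substitutions and single-base indels
#'
#' Each position is independently substituted to a uniformly chosen
#' *different* base with probability `sub_rate`.  Independently, an indel
#' event hits each position with probability `indel_rate`; an event is an
#' insertion or a deletion with equal probability (`ins_fraction`), a
#' deletion removing the position and an insertion adding one uniform
#' base after it.
#'
#' @param seq Input DNA string.
#' @param sub_rate,indel_rate Per-position rates in `[0, 1]`.
#' @param ins_fraction Fraction of indel events that are insertions
#'   (default 0.5).
#' @param seed Optional RNG seed.
#' @return The mutated string.
#' @export
mutate_sequence <- function(seq, sub_rate, indel_rate = 0,
                            ins_fraction = 0.5, seed = NULL) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  chars <- seq_to_chars(seq)
  n <- length(chars)
  sub <- runif(n) < sub_rate
  if (any(sub)) {
    cur <- match(chars[sub], DNA_ALPHABET)
    shift <- sample.int(3, sum(sub), replace = TRUE)
    chars[sub] <- DNA_ALPHABET[((cur - 1 + shift) %% 4) + 1]
  }
  ev <- runif(n) < indel_rate
  if (any(ev)) {
    is_ins <- runif(n) < ins_fraction
    out <- chars
    out[ev & !is_ins] <- ""                    # deletions
    ins_at <- ev & is_ins
    if (any(ins_at)) {
      out[ins_at] <- paste0(out[ins_at],
                            sample(DNA_ALPHABET, sum(ins_at), replace = TRUE))
    }
    chars <- out
  }
  paste(chars, collapse = "")
}

error_rate_to_phred <- function(error_rate, cap = 42L) {
  if (error_rate <= 0) return(as.integer(cap))
  min(as.integer(cap), as.integer(round(-10 * log10(error_rate))))
}

#' Simulate short reads with uniform errors
#'
#' Reads of fixed length start at uniformly random positions of the input
#' sequence; each base is flipped to a uniformly chosen different base
#' with probability `error_rate`.  Emitted qualities are constant at
#' `Q = round(-10 * log10(error_rate))` (capped at 42; 42 when the error
#' rate is zero), consistent with the simulated error process.
#'
#' @param seq Source DNA string.
#' @param n_reads Number of reads; alternatively give `coverage` and
#'   `n_reads = ceiling(coverage * nchar(seq) / read_length)` is used.
#' @param coverage Target mean coverage (used when `n_reads` is `NULL`).
#' @param read_length Read length (default 150); must not exceed the
#'   sequence length.
#' @param error_rate Per-base error probability (default 0.01).
#' @param seed Optional RNG seed.
#' @return A tibble with columns `id`, `sequence`, `quality` (Phred+33
#'   string) and `start` (true 0-based start position), directly
#'   consumable by [assemble()] and writable with [write_fastq()].
#' @export
simulate_reads <- function(seq, n_reads = NULL, coverage = NULL,
                           read_length = 150L, error_rate = 0.01,
                           seed = NULL) {
  len <- nchar(seq)
  if (read_length > len) {
    stop("read_length exceeds sequence length", call. = FALSE)
  }
  if (is.null(n_reads)) {
    if (is.null(coverage)) stop("give n_reads or coverage", call. = FALSE)
    n_reads <- ceiling(coverage * len / read_length)
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- sample.int(len - read_length + 1L, n_reads, replace = TRUE) - 1L
  build_reads(seq, starts, read_length, error_rate)
}

#' Deterministically tiled error-controlled reads
#'
#' Reads start every `read_length / coverage` bases (rounded, at least 1)
#' so that every position of the sequence — ends included — is covered
#' and interior positions see approximately `coverage` reads.  Useful for
#' parameter-recovery experiments where end coverage must not be left to
#' chance; the stream order is still randomised by [assemble()].
#'
#' @inheritParams simulate_reads
#' @param coverage Target interior coverage (default 30).
#' @return A tibble as in [simulate_reads()].
#' @export
tile_reads <- function(seq, read_length = 150L, coverage = 30,
                       error_rate = 0, seed = NULL) {
  len <- nchar(seq)
  if (read_length > len) {
    stop("read_length exceeds sequence length", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  step <- max(1L, as.integer(round(read_length / coverage)))
  starts <- unique(c(seq(0L, len - read_length, by = step),
                     len - read_length))
  build_reads(seq, starts, read_length, error_rate)
}

build_reads <- function(seq, starts, read_length, error_rate) {
  n_reads <- length(starts)
  reads <- substring(seq, starts + 1L, starts + read_length)
  if (error_rate > 0) {
    chars <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                    nrow = n_reads, byrow = TRUE)
    flip <- matrix(runif(length(chars)) < error_rate, nrow = n_reads)
    if (any(flip)) {
      cur <- match(chars[flip], DNA_ALPHABET)
      shift <- sample.int(3, sum(flip), replace = TRUE)
      chars[flip] <- DNA_ALPHABET[((cur - 1 + shift) %% 4) + 1]
    }
    reads <- apply(chars, 1, paste, collapse = "")
  }
  q <- error_rate_to_phred(error_rate)
  qual <- strrep(intToUtf8(q + 33L), read_length)
  tibble::tibble(id = sprintf("read%05d", seq_len(n_reads)),
                 sequence = reads,
                 quality = qual,
                 start = as.integer(starts))
}

#' Edit-distance calibration experiment
#'
#' For each replicate: draw a random truth sequence of length
#' `U(length_range)` at the given GC content, simulate one read from it,
#' build mutated references at each substitution rate (each also carrying
#' single-base indels at `indel_rate`) plus one fresh random sequence of
#' the same length, and align the read to the truth (`own`), to every
#' mutated reference, and to the random sequence.  The distribution of
#' the resulting normalised edit distances is what motivates the
#' learning-rate schedule thresholds: the `own` condition concentrates
#' below 0.05 (sequencing error only) while distant references push the
#' edit rate past 0.35.
#'
#' @param n_reps Number of replicates (the reference experiment uses
#'   1000; tests use a scaled-down 200).
#' @param length_range Truth length range, uniform (default
#'   `c(500, 5000)`).
#' @param gc GC content (default 0.5).
#' @param read_length Read length (default 150).
#' @param error_rate Sequencing error rate (default 0.01).
#' @param sub_rates Reference mutation rates (default
#'   `c(0.01, 0.05, 0.10, 0.30, 0.50)`).
#' @param indel_rate Per-position single-base indel rate applied to every
#'   mutated reference (default 0.10).
#' @param gap_cost Alignment gap cost (default 1).
#' @param seed Optional RNG seed.
#' @return A tibble with columns `replicate`, `condition` (ordered
#'   factor: `own`, `1%`, ..., `50%`, `random`) and `edit_rate`.
#' @export
edit_distance_calibration <- function(n_reps = 200,
                                      length_range = c(500, 5000),
                                      gc = 0.5, read_length = 150L,
                                      error_rate = 0.01,
                                      sub_rates = c(0.01, 0.05, 0.10, 0.30, 0.50),
                                      indel_rate = 0.10, gap_cost = 1,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cond_names <- c("own", sprintf("%g%%", 100 * sub_rates), "random")
  rows <- vector("list", n_reps)
  for (rep_i in seq_len(n_reps)) {
    len <- floor(runif(1, length_range[1], length_range[2] + 1))
    truth <- random_sequence(len, gc = gc)
    rd <- simulate_reads(truth, n_reads = 1, read_length = read_length,
                         error_rate = error_rate)
    prof <- encode_read(rd$sequence[1], rd$quality[1], id = rd$id[1])
    refs <- c(list(truth),
              lapply(sub_rates, function(r) {
                mutate_sequence(truth, sub_rate = r, indel_rate = indel_rate)
              }),
              list(random_sequence(len, gc = gc)))
    er <- vapply(refs, function(s) {
      align_read(encode_reference(s), prof, gap_cost = gap_cost)$edit_rate
    }, numeric(1))
    rows[[rep_i]] <- tibble::tibble(
      replicate = rep_i,
      condition = cond_names,
      edit_rate = er)
  }
  out <- do.call(rbind, rows)
  out$condition <- factor(out$condition, levels = cond_names, ordered = TRUE)
  out
}

#' Parameter-recovery experiment
#'
#' Builds a random truth sequence, corrupts a copy of it with a given
#' number of substitutions, single-base insertions and deletions (at
#' distinct random positions away from the extreme ends), streams
#' error-free tiled reads over it with [assemble()], and evaluates the
#' consensus against the truth with [evaluate_assembly()].
#'
#' @param truth_length Truth length (default 500).
#' @param n_sub,n_ins,n_del Number of corrupting substitutions,
#'   insertions, deletions (defaults 5, 1, 1).
#' @param read_length Read length (default 150).
#' @param coverage Tiling coverage (default 30).
#' @param epochs Learning epochs (default 1).
#' @param seed RNG seed driving the whole experiment.
#' @return List with `truth`, `reference` (corrupted string), `assembly`
#'   (the `nl_assembly`) and `evaluation` (the `nl_eval`).
#' @export
reference_recovery <- function(truth_length = 500, n_sub = 5, n_ins = 1,
                               n_del = 1, read_length = 150L, coverage = 30,
                               epochs = 1L, seed = 1L) {
  set.seed(seed)
  truth <- random_sequence(truth_length)
  chars <- seq_to_chars(truth)
  margin <- 2L  # keep structural edits off the exact termini
  pos <- sample((margin + 1):(truth_length - margin), n_sub + n_ins + n_del)
  sub_pos <- pos[seq_len(n_sub)]
  ins_pos <- pos[n_sub + seq_len(n_ins)]
  del_pos <- pos[n_sub + n_ins + seq_len(n_del)]
  cur <- match(chars[sub_pos], DNA_ALPHABET)
  shift <- sample.int(3, n_sub, replace = TRUE)
  chars[sub_pos] <- DNA_ALPHABET[((cur - 1 + shift) %% 4) + 1]
  chars[ins_pos] <- paste0(chars[ins_pos],
                           sample(DNA_ALPHABET, n_ins, replace = TRUE))
  chars[del_pos] <- ""
  reference <- paste(chars, collapse = "")
  reads <- tile_reads(truth, read_length = read_length, coverage = coverage,
                      error_rate = 0)
  fit <- assemble(reference, reads,
                  learn_config(seed = seed, epochs = epochs,
                               strand = "forward"))
  list(truth = truth, reference = reference, assembly = fit,
       evaluation = evaluate_assembly(fit$consensus, truth))
}

#' Plot a calibration table
#'
#' Boxplots of the normalised edit distance per condition, with the
#' schedule thresholds 0.05 and 0.35 marked.
#'
#' @param calibration A tibble from [edit_distance_calibration()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(calibration) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(calibration,
                  ggplot2::aes(x = condition, y = edit_rate)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = c(0.05, 0.35), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "reference condition",
                  y = "normalised edit distance") +
    ggplot2::theme_minimal()
}
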