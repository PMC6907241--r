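# The learning assembly pipeline: stream reads in random order over one
# or more epochs, align + update, track coverage, trim uncovered ends,
# emit the consensus.

#' Configuration for the learning assembler
#'
#' @param gap_cost Linear indel cost `c` of the read-to-reference
#'   alignment (default 1).
#' @param slope,intercept,w_min,w_max Learning-rate schedule parameters,
#'   see [learn_rate_schedule()].
#' @param indel_threshold_offset `"w"` (default) or a fixed numeric
#'   offset for the persistence thresholds `1 +/- offset`.
#' @param epochs Number of passes over the read set (default 1).
#' @param window_size Bases flanking a mapping hint when hints are
#'   supplied; `NULL` aligns against the whole reference.
#' @param seed Integer RNG seed for the per-epoch read permutation;
#'   `NULL` leaves the session RNG untouched.
#' @param strand `"both"` (align read and reverse complement, keep the
#'   better; the default for real FASTQ input) or `"forward"`.
#' @param quality_offset FASTQ quality offset (33 or 64).
#' @param max_edit_rate Optional skip threshold: reads whose edit rate
#'   exceeds it are logged but not applied. Default `NULL` (every read is
#'   applied, distant ones at the minimum learning rate).
#' @param resample_per_epoch Optional fraction in `(0, 1]`: each epoch
#'   re-samples (without replacement) that fraction of the reads.
#' @param reset_coverage_each_epoch Reset the coverage counters at the
#'   start of each epoch instead of accumulating (default `FALSE`).
#' @return A `learn_config` list.
#' @export
learn_config <- function(gap_cost = 1, slope = 3, intercept = -0.1,
                         w_min = 0.05, w_max = 0.95,
                         indel_threshold_offset = "w",
                         epochs = 1L, window_size = NULL, seed = NULL,
                         strand = c("both", "forward"),
                         quality_offset = 33L,
                         max_edit_rate = NULL,
                         resample_per_epoch = NULL,
                         reset_coverage_each_epoch = FALSE) {
  strand <- match.arg(strand)
  stopifnot(epochs >= 1, gap_cost > 0)
  structure(list(gap_cost = gap_cost, slope = slope, intercept = intercept,
                 w_min = w_min, w_max = w_max,
                 indel_threshold_offset = indel_threshold_offset,
                 epochs = as.integer(epochs), window_size = window_size,
                 seed = seed, strand = strand,
                 quality_offset = as.integer(quality_offset),
                 max_edit_rate = max_edit_rate,
                 resample_per_epoch = resample_per_epoch,
                 reset_coverage_each_epoch = reset_coverage_each_epoch),
            class = "learn_config")
}

reads_to_profiles <- function(reads, quality_offset = 33L) {
  if (is.data.frame(reads)) {
    ids <- if ("id" %in% names(reads)) as.character(reads$id)
           else paste0("read", seq_len(nrow(reads)))
    lapply(seq_len(nrow(reads)), function(i) {
      encode_read(reads$sequence[i], reads$quality[i],
                  offset = quality_offset, id = ids[i])
    })
  } else if (is.list(reads) && all(vapply(reads, inherits, TRUE, "read_profile"))) {
    reads
  } else {
    stop("reads must be a data frame (id, sequence, quality) or a list of read_profile objects",
         call. = FALSE)
  }
}

#' Assemble reads by dynamic reference learning
#'
#' Runs the learning pipeline: for each epoch the reads are permuted at
#' random and aligned one at a time to the current reference with
#' [align_read_stranded()]; each alignment's edit rate sets the learning
#' rate through [learn_rate_schedule()] and the reference is updated with
#' [apply_update()].  After the final epoch, runs of zero coverage at the
#' reference ends are trimmed and the per-position argmax consensus is
#' emitted.  Deterministic given `(reads, reference, config$seed)`.
#'
#' @param reference A `reference_profile`, or a character scalar that is
#'   encoded with [encode_reference()].
#' @param reads A tibble/data frame with columns `id`, `sequence`,
#'   `quality` (as from [read_fastq()] or [simulate_reads()]), or a list
#'   of `read_profile` objects.
#' @param config A [learn_config()].
#' @param hints Optional named integer vector mapping read id to a
#'   0-based reference position (as from [read_sam_hints()]); alignment
#'   is then restricted to `hint +/- window_size` (clipped).  Reads
#'   without a hint, or all reads when `config$window_size` is `NULL`,
#'   are aligned against the whole reference.
#' @return An `nl_assembly`: list with `consensus` (trimmed assembly
#'   string), `reference` (final untrimmed profile), `trimmed_reference`,
#'   `coverage` (untrimmed final counters), `bases_covered`, `read_log`
#'   (tibble: epoch, read id, orientation, edit distance and rate, `w`,
#'   substitution/insertion/deletion counts, footprint), and `config`.
#' @examples
#' truth <- random_sequence(300, seed = 1)
#' reads <- tile_reads(truth, read_length = 50, coverage = 5)
#' fit <- assemble(truth, reads, learn_config(seed = 1, strand = "forward"))
#' fit
#' @export
assemble <- function(reference, reads, config = learn_config(), hints = NULL) {
  if (is.character(reference)) reference <- encode_reference(reference)
  stopifnot(inherits(reference, "reference_profile"),
            inherits(config, "learn_config"))
  profiles <- reads_to_profiles(reads, config$quality_offset)
  n_reads <- length(profiles)
  if (n_reads == 0) stop("no reads supplied", call. = FALSE)
  if (all(vapply(profiles, function(p) nrow(p$mat) == 0, TRUE))) {
    stop("all reads are empty", call. = FALSE)
  }
  if (!is.null(hints)) {
    ids <- vapply(profiles, `[[`, "", "id")
    unknown <- setdiff(names(hints), ids)
    if (length(unknown) > 0) {
      warning(sprintf("%d hint(s) name unknown reads and are ignored",
                      length(unknown)))
    }
  }
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  log_rows <- vector("list", 0)
  for (epoch in seq_len(config$epochs)) {
    if (config$reset_coverage_each_epoch) {
      reference$coverage <- rep(0L, nrow(reference$mat))
    }
    ord <- sample.int(n_reads)
    if (!is.null(config$resample_per_epoch)) {
      k <- max(1L, round(config$resample_per_epoch * n_reads))
      ord <- ord[seq_len(k)]
    }
    for (i in ord) {
      prof <- profiles[[i]]
      window <- NULL
      if (!is.null(hints) && !is.null(config$window_size) &&
          prof$id %in% names(hints)) {
        l <- nrow(reference$mat)
        pos <- hints[[prof$id]]
        lo <- max(0L, pos - config$window_size)
        hi <- min(l, pos + nrow(prof$mat) + config$window_size)
        if (lo < hi) window <- c(lo, hi)
      }
      fit <- align_read_stranded(reference, prof,
                                 gap_cost = config$gap_cost,
                                 window = window, strand = config$strand)
      aln <- fit$alignment
      sched <- learn_rate_schedule(aln$edit_rate, slope = config$slope,
                                   intercept = config$intercept,
                                   w_min = config$w_min, w_max = config$w_max)
      skipped <- !is.null(config$max_edit_rate) &&
        aln$edit_rate > config$max_edit_rate
      if (skipped) {
        out <- list(n_substituted = 0L, n_inserted = 0L, n_deleted = 0L,
                    new_length = nrow(reference$mat))
      } else {
        upd <- apply_update(reference, fit$read, aln, sched$w,
                            indel_threshold_offset = config$indel_threshold_offset)
        reference <- upd$reference
        out <- upd$outcome
      }
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        epoch = epoch, read_id = prof$id, orientation = aln$orientation,
        edit_distance = aln$edit_distance, edit_rate = aln$edit_rate,
        w = sched$w, learning_rate = sched$learning_rate,
        ref_start = aln$ref_start, ref_end = aln$ref_end,
        n_substituted = out$n_substituted, n_inserted = out$n_inserted,
        n_deleted = out$n_deleted, new_length = out$new_length,
        skipped = skipped)
    }
  }

  trimmed <- trim_uncovered_ends(reference)
  structure(list(
    consensus = consensus(trimmed),
    reference = reference,
    trimmed_reference = trimmed,
    coverage = reference$coverage,
    bases_covered = sum(reference$coverage),
    read_log = do.call(rbind, log_rows),
    config = config
  ), class = "nl_assembly")
}

#' Call the consensus sequence of a reference profile
#'
#' Per position, the base with the highest probability; exact ties go to
#' the first base in alphabet order (A < C < G < T).
#'
#' @param reference A `reference_profile`.
#' @return A character scalar.
#' @export
consensus <- function(reference) {
  stopifnot(inherits(reference, "reference_profile"))
  if (nrow(reference$mat) == 0) return("")
  paste(DNA_ALPHABET[max.col(reference$mat, ties.method = "first")],
        collapse = "")
}

#' Trim uncovered reference ends
#'
#' Removes leading and trailing runs of zero-coverage positions; interior
#' zero-coverage gaps are retained.  If nothing is covered an empty
#' profile is returned with a warning.
#'
#' @param reference A `reference_profile` with coverage counters.
#' @return The trimmed `reference_profile`.
#' @export
trim_uncovered_ends <- function(reference) {
  stopifnot(inherits(reference, "reference_profile"))
  covered <- which(reference$coverage > 0)
  if (length(covered) == 0) {
    warning("no reference position is covered; assembly is empty")
    reference$mat <- reference$mat[0, , drop = FALSE]
    reference$persistence <- numeric(0)
    reference$coverage <- integer(0)
    return(reference)
  }
  idx <- covered[1]:covered[length(covered)]
  reference$mat <- reference$mat[idx, , drop = FALSE]
  reference$persistence <- reference$persistence[idx]
  reference$coverage <- reference$coverage[idx]
  reference
}

#' Total read coverage of an assembly
#'
#' The position-wise sum of the coverage counters — equivalently, the sum
#' of aligned reference footprint lengths over reads (when no structural
#' deletion removed counted positions).
#'
#' @param x An `nl_assembly` or a `reference_profile`.
#' @return A count.
#' @export
bases_covered <- function(x) {
  if (inherits(x, "nl_assembly")) return(sum(x$coverage))
  stopifnot(inherits(x, "reference_profile"))
  sum(x$coverage)
}

#' @export
print.nl_assembly <- function(x, ...) {
  cat(sprintf("<nl_assembly: %d bp consensus, %d reads aligned, %d bases covered>\n",
              nchar(x$consensus), nrow(x$read_log), x$bases_covered))
  invisible(x)
}

#' Per-read log of an assembly
#'
#' @param x An `nl_assembly`.
#' @return The read-log tibble (one row per aligned read per epoch).
#' @export
read_log <- function(x) {
  stopifnot(inherits(x, "nl_assembly"))
  x$read_log
}
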