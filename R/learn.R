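# Learning-rate schedule and the online reference update.
#
# Terminology, fixed once: w is the *retention* weight of the old
# reference given by the linear schedule; the *learning rate* is 1 - w,
# the weight given to the read.  A well-aligned read (edit rate <= 0.05)
# therefore learns at 0.95; a poorly aligned one (edit rate >= 0.35) at
# 0.05.

#' The learning-rate schedule
#'
#' Maps an alignment's normalised edit rate to the retention weight
#' `w = clamp(slope * edit_rate + intercept, w_min, w_max)` and the
#' learning rate `1 - w`.  With the defaults (`slope = 3`,
#' `intercept = -0.1`, clamps at 0.05 and 0.95) the learning rate is 0.95
#' for edit rates below 0.05 — the range attributable to sequencing error
#' alone — and 0.05 above 0.35, roughly the edit rate of a read against a
#' reference of under 70% identity.
#'
#' @param edit_rate Normalised edit distance of the read alignment
#'   (edit distance / read length); non-negative.
#' @param slope,intercept Linear schedule coefficients.
#' @param w_min,w_max Clamp bounds for `w`, `0 < w_min < w_max < 1`.
#' @return List with `w` and `learning_rate = 1 - w`.
#' @examples
#' learn_rate_schedule(0.03)$learning_rate  # 0.95
#' learn_rate_schedule(0.40)$learning_rate  # 0.05
#' @export
learn_rate_schedule <- function(edit_rate, slope = 3, intercept = -0.1,
                                w_min = 0.05, w_max = 0.95) {
  if (any(edit_rate < 0)) stop("edit_rate must be non-negative", call. = FALSE)
  stopifnot(w_min > 0, w_min < w_max, w_max < 1)
  w <- pmin(pmax(slope * edit_rate + intercept, w_min), w_max)
  list(w = w, learning_rate = 1 - w)
}

#' Update the reference profile from one aligned read
#'
#' Walks the alignment path in read order and applies the online update:
#' a match/substitution step at reference position `x` and read position
#' `y` replaces `f_x` by the convex combination `w * f_x + (1 - w) * r_y`;
#' an insertion-from-read step adds `1 - w` to the persistence value at
#' the insertion locus; a deletion-from-read step subtracts `1 - w` from
#' the persistence value of the skipped reference position.  After the
#' walk, each touched locus whose persistence exceeds `1 + offset`
#' receives a structural insertion (new position initialised to the
#' aligned read vector, persistence 1, coverage 0) and each touched
#' position whose persistence falls below `1 - offset` is deleted; at
#' most one structural edit per locus per read, and persistence at an
#' edited locus is reset to 1.  Coverage is incremented on every
#' reference position in the aligned footprint `[ref_start, ref_end)`
#' before structural edits are applied.
#'
#' @param reference A `reference_profile`; must be the exact state the
#'   alignment was computed against.
#' @param read The (oriented) `read_profile` that was aligned.
#' @param alignment The `nl_alignment` for this read and reference.
#' @param w Retention weight from [learn_rate_schedule()], in `(0, 1)`.
#' @param indel_threshold_offset Either the string `"w"` (threshold
#'   `1 +/- w`, the default) or a fixed numeric offset.
#' @return List with `reference` (the updated profile) and `outcome`, a
#'   list of `n_substituted`, `n_inserted`, `n_deleted`, `new_length`.
#' @export
apply_update <- function(reference, read, alignment, w,
                         indel_threshold_offset = "w") {
  stopifnot(inherits(reference, "reference_profile"),
            inherits(read, "read_profile"),
            inherits(alignment, "nl_alignment"))
  if (w <= 0 || w >= 1) stop("w must be in (0, 1)", call. = FALSE)
  l <- nrow(reference$mat)
  path <- alignment$path
  if (alignment$ref_end > l || max(path$ref) >= l + 1L ||
      alignment$read_length != nrow(read$mat)) {
    stop("stale alignment: coordinates do not fit the current reference",
         call. = FALSE)
  }
  offset <- if (identical(indel_threshold_offset, "w")) w
            else as.numeric(indel_threshold_offset)

  mat <- reference$mat
  pers <- reference$persistence
  cov <- reference$coverage
  lr <- 1 - w

  n_sub <- 0L
  ins_locus <- integer(0)       # loci (0-based, insert-before position)
  ins_vecs <- list()
  del_touched <- integer(0)     # 0-based positions nudged down

  for (i in seq_len(nrow(path))) {
    op <- path$op[i]
    x <- path$ref[i]
    if (op == "matchsub") {
      r <- read$mat[path$read[i] + 1L, ]
      mat[x + 1L, ] <- w * mat[x + 1L, ] + lr * r
      n_sub <- n_sub + 1L
    } else if (op == "del_from_read") {
      pers[x + 1L] <- pers[x + 1L] - lr
      del_touched <- c(del_touched, x)
    } else {
      pidx <- min(x, l - 1L) + 1L   # persistence slot tracking locus x
      pers[pidx] <- pers[pidx] + lr
      key <- as.character(x)
      ins_vecs[[key]] <- read$mat[path$read[i] + 1L, ]
      ins_locus <- c(ins_locus, x)
    }
  }

  if (alignment$ref_end > alignment$ref_start) {
    idx <- (alignment$ref_start + 1L):alignment$ref_end
    cov[idx] <- cov[idx] + 1L
  }

  # structural edits: evaluated once per read, after the full walk
  ins_locus <- unique(ins_locus)
  fire_ins <- ins_locus[pers[pmin(ins_locus, l - 1L) + 1L] > 1 + offset]
  del_touched <- unique(del_touched)
  fire_del <- del_touched[pers[del_touched + 1L] < 1 - offset]

  n_ins <- length(fire_ins)
  n_del <- length(fire_del)
  if (n_ins > 0) pers[pmin(fire_ins, l - 1L) + 1L] <- 1
  if (n_del > 0) pers[fire_del + 1L] <- 1  # about to be removed; kept tidy

  if (n_ins > 0 || n_del > 0) {
    keep <- !(seq_len(l) - 1L) %in% fire_del
    ins_before <- (seq_len(l + 1L) - 1L) %in% fire_ins
    npos <- l - n_del + n_ins
    new_mat <- matrix(0, nrow = npos, ncol = 4,
                      dimnames = list(NULL, DNA_ALPHABET))
    new_pers <- numeric(npos)
    new_cov <- integer(npos)
    j <- 0L
    for (i in 0:l) {
      if (ins_before[i + 1L]) {
        j <- j + 1L
        new_mat[j, ] <- ins_vecs[[as.character(i)]]
        new_pers[j] <- 1
        new_cov[j] <- 0L
      }
      if (i < l && keep[i + 1L]) {
        j <- j + 1L
        new_mat[j, ] <- mat[i + 1L, ]
        new_pers[j] <- pers[i + 1L]
        new_cov[j] <- cov[i + 1L]
      }
    }
    mat <- new_mat
    pers <- new_pers
    cov <- new_cov
  }

  reference$mat <- mat
  reference$persistence <- pers
  reference$coverage <- cov
  list(reference = reference,
       outcome = list(n_substituted = n_sub,
                      n_inserted = n_ins,
                      n_deleted = n_del,
                      new_length = nrow(mat)))
}
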