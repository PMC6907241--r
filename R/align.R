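# Free-ends dynamic-programming alignment of a read profile to a
# reference profile.  The reference's flanks are free (a path may enter
# and leave the reference anywhere) but the read is consumed in full.

#' Align a read profile to a reference profile
#'
#' Fills the `(L+1) x (n+1)` edit-distance matrix `M` with `M(x,0) = 0`
#' (free start anywhere in the reference), `M(0,y) = c*y`, and
#' `M(x,y) = min(M(x-1,y-1) + d(f_x, r_y), M(x-1,y) + c, M(x,y-1) + c)`,
#' where `d` is [vector_distance()] and `c` the linear gap cost.  The
#' edit distance is the minimum of the last column, its row the end of the
#' aligned reference segment; the edit rate is the edit distance divided
#' by read length.  Ties are resolved deterministically: in the recurrence
#' and traceback, match/substitution is preferred over deletion-from-read
#' (reference advances) over insertion-from-read (read advances), and the
#' end row takes the smallest reference position.
#'
#' @param reference A `reference_profile` from [encode_reference()].
#' @param read A `read_profile` from [encode_read()].
#' @param gap_cost Linear insertion/deletion cost `c` (default 1, the
#'   maximum possible distance between two base vectors).
#' @param window Optional `c(lo, hi)` 0-based half-open reference interval
#'   restricting the alignment; coordinates in the result are global.
#' @param keep_matrix Keep the filled matrix `M` in the result (for
#'   inspection; off by default).
#' @return An `nl_alignment`: list with `edit_distance`, `edit_rate`,
#'   `ref_start`, `ref_end` (0-based half-open aligned reference segment),
#'   `path` (tibble of steps with `op` in `matchsub`, `del_from_read`,
#'   `ins_from_read`, plus 0-based `ref` and `read` coordinates),
#'   `orientation`, and optionally `matrix`.
#' @examples
#' ref <- encode_reference("TTACGTTT")
#' rd <- encode_read("ACGT", phred = rep(60, 4))
#' align_read(ref, rd)
#' @export
align_read <- function(reference, read, gap_cost = 1, window = NULL,
                       keep_matrix = FALSE) {
  stopifnot(inherits(reference, "reference_profile"),
            inherits(read, "read_profile"))
  if (gap_cost <= 0) stop("gap_cost must be positive", call. = FALSE)
  l <- nrow(reference$mat)
  n <- nrow(read$mat)
  lo <- 0L
  fmat <- reference$mat
  if (!is.null(window)) {
    lo <- as.integer(window[[1]])
    hi <- as.integer(window[[2]])
    if (lo < 0 || hi > l || lo >= hi) {
      stop(sprintf("window [%d, %d) outside reference of length %d",
                   lo, hi, l), call. = FALSE)
    }
    fmat <- fmat[(lo + 1):hi, , drop = FALSE]
  }
  res <- dtw_align_cpp(fmat, read$mat, gap_cost, keep_matrix)
  path <- res$path
  ops <- c("matchsub", "del_from_read", "ins_from_read")[path[, "op"]]
  out <- structure(list(
    edit_distance = res$edit_distance,
    edit_rate = res$edit_distance / n,
    ref_start = res$ref_start + lo,
    ref_end = res$ref_end + lo,
    path = tibble::tibble(op = ops,
                          ref = path[, "ref"] + lo,
                          read = path[, "read"]),
    read_id = read$id,
    orientation = "forward",
    gap_cost = gap_cost,
    read_length = n
  ), class = "nl_alignment")
  if (keep_matrix) out$matrix <- res$matrix
  out
}

#' Align a read in the better of the two orientations
#'
#' Aligns the read as given and, when `strand = "both"`, also its reverse
#' complement, keeping the orientation with the smaller edit rate (ties
#' prefer forward).  Returns both the alignment and the read profile in
#' the orientation actually used, so downstream reference updates see the
#' oriented vectors.
#'
#' @inheritParams align_read
#' @param strand `"both"` or `"forward"`.
#' @return List with `alignment` (an `nl_alignment`) and `read` (the
#'   oriented `read_profile`).
#' @export
align_read_stranded <- function(reference, read, gap_cost = 1,
                                window = NULL, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  fwd <- align_read(reference, read, gap_cost = gap_cost, window = window)
  if (strand == "forward") {
    return(list(alignment = fwd, read = read))
  }
  rc_read <- revcomp_profile(read)
  rc <- align_read(reference, rc_read, gap_cost = gap_cost, window = window)
  if (rc$edit_rate < fwd$edit_rate) {
    rc$orientation <- "reverse"
    list(alignment = rc, read = rc_read)
  } else {
    list(alignment = fwd, read = read)
  }
}

#' @export
print.nl_alignment <- function(x, ...) {
  cat(sprintf(
    "<alignment '%s' (%s): edit distance %.4g, edit rate %.4g, ref [%d, %d)>\n",
    x$read_id, x$orientation, x$edit_distance, x$edit_rate,
    x$ref_start, x$ref_end))
  invisible(x)
}
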