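# Probabilistic Voss encoding: every sequence position is a probability
# vector over (A, C, G, T), in that fixed order.  Reads derive their
# vectors from base calls + Phred qualities; references start as one-hot
# vectors.  'N' maps to the uniform vector in both; other IUPAC codes are
# rejected.

seq_to_chars <- function(x) {
  strsplit(toupper(x), "", fixed = TRUE)[[1]]
}

check_bases <- function(chars, what = "sequence") {
  bad <- which(!chars %in% c(DNA_ALPHABET, "N"))
  if (length(bad) > 0) {
    stop(sprintf("invalid character '%s' in %s at position %d",
                 chars[bad[1]], what, bad[1]), call. = FALSE)
  }
  invisible(chars)
}

base_matrix <- function(chars) {
  m <- matrix(0, nrow = length(chars), ncol = 4,
              dimnames = list(NULL, DNA_ALPHABET))
  idx <- match(chars, DNA_ALPHABET)
  is_n <- is.na(idx)
  m[cbind(which(!is_n), idx[!is_n])] <- 1
  m[is_n, ] <- 0.25
  m
}

#' Encode a read as a profile of base-probability vectors
#'
#' Converts base calls and Phred quality scores into per-position
#' probability vectors over (A, C, G, T).  A base called `b` with calling
#' error probability `q = 10^(-Q/10)` receives probability `1 - q`, and
#' each alternative base `q / 3`, so every vector sums to one.  An `N`
#' call becomes the uniform vector `(0.25, 0.25, 0.25, 0.25)`.
#'
#' @param bases Character scalar over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @param phred Integer vector of Phred scores, one per base, or a
#'   character scalar of quality characters to decode using `offset`.
#' @param offset Quality encoding offset when `phred` is a character
#'   string: 33 (Sanger/modern Illumina, the default) or 64.
#' @param id Read identifier stored with the profile.
#' @return A `read_profile`: list with `id` and `mat`, an `n x 4`
#'   probability matrix with columns `A`, `C`, `G`, `T`.
#' @examples
#' p <- encode_read("ACGT", phred = c(40, 40, 15, 2))
#' rowSums(p$mat)
#' @export
encode_read <- function(bases, phred, offset = 33L, id = "read") {
  chars <- seq_to_chars(bases)
  if (length(chars) == 0) stop("empty read", call. = FALSE)
  check_bases(chars, what = sprintf("read '%s'", id))
  if (is.character(phred)) phred <- decode_quality(phred, offset = offset)
  phred <- as.numeric(phred)
  if (length(phred) != length(chars)) {
    stop(sprintf("read '%s': %d bases but %d quality values",
                 id, length(chars), length(phred)), call. = FALSE)
  }
  if (any(phred < 0)) stop("negative Phred score", call. = FALSE)
  q <- 10^(-phred / 10)
  m <- matrix(rep(q / 3, 4), ncol = 4, dimnames = list(NULL, DNA_ALPHABET))
  idx <- match(chars, DNA_ALPHABET)
  called <- !is.na(idx)
  m[cbind(which(called), idx[called])] <- 1 - q[called]
  m[!called, ] <- 0.25
  structure(list(id = id, mat = m), class = "read_profile")
}

#' Encode a reference sequence as an evolving profile
#'
#' The reference profile carries, per position, a base-probability vector
#' (initially one-hot from the sequence, uniform for `N`), a persistence
#' value (initially 1) that accumulates insertion/deletion evidence, and a
#' read-coverage counter (initially 0).
#'
#' @param sequence Character scalar over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @return A `reference_profile`: list with `mat` (`l x 4` probability
#'   matrix), `persistence` (numeric, length `l`) and `coverage`
#'   (integer, length `l`).
#' @examples
#' ref <- encode_reference("ACGTN")
#' ref$mat
#' @export
encode_reference <- function(sequence) {
  chars <- seq_to_chars(sequence)
  if (length(chars) == 0) stop("empty reference sequence", call. = FALSE)
  check_bases(chars, what = "reference")
  structure(list(mat = base_matrix(chars),
                 persistence = rep(1, length(chars)),
                 coverage = rep(0L, length(chars))),
            class = "reference_profile")
}

#' Distance between a reference vector and a read vector
#'
#' Only the read's most probable base matters: with
#' `i = argmax(r)` (ties broken in alphabet order A < C < G < T), the
#' distance is `|f[i] - r[i]|`.  Note the asymmetry — the argmax is taken
#' over the second (read) argument.
#'
#' @param f Reference base-probability vector (length 4).
#' @param r Read base-probability vector (length 4).
#' @return A number in `[0, 1]`.
#' @examples
#' vector_distance(c(1, 0, 0, 0), c(0, 1, 0, 0))
#' @export
vector_distance <- function(f, r) {
  stopifnot(length(f) == 4, length(r) == 4)
  i <- which.max(r)
  abs(f[[i]] - r[[i]])
}

#' @export
print.read_profile <- function(x, ...) {
  cat(sprintf("<read_profile '%s': %d positions>\n", x$id, nrow(x$mat)))
  invisible(x)
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("<reference_profile: %d positions, %d covered>\n",
              nrow(x$mat), sum(x$coverage > 0)))
  invisible(x)
}

#' @export
length.reference_profile <- function(x) nrow(x$mat)

#' @export
length.read_profile <- function(x) nrow(x$mat)

# reverse complement of a read profile: reverse positions, swap A<->T, C<->G
revcomp_profile <- function(read) {
  m <- read$mat[rev(seq_len(nrow(read$mat))), rev(seq_len(4)), drop = FALSE]
  colnames(m) <- DNA_ALPHABET
  structure(list(id = read$id, mat = m), class = "read_profile")
}

validate_profile_matrix <- function(m, tol = 1e-9) {
  all(m >= 0) && all(abs(rowSums(m) - 1) < tol)
}
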