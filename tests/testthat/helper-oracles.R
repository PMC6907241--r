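# Independent oracles used to check the dynamic-programming engines.

# Top-down memoized evaluation of the free-ends recurrence
#   M(x,0) = 0; M(0,y) = c*y;
#   M(x,y) = min(M(x-1,y-1) + d(f_x, r_y), M(x-1,y) + c, M(x,y-1) + c)
# returning min over 1 <= x <= L of M(x, n).  Structured as recursion over
# the printed equations, independent of the package's bottom-up C++ fill.
oracle_edit_distance <- function(fmat, rmat, gap_cost = 1) {
  L <- nrow(fmat)
  n <- nrow(rmat)
  iy <- apply(rmat, 1, which.max)
  memo <- matrix(NA_real_, L + 1, n + 1)
  M <- function(x, y) {
    if (!is.na(memo[x + 1, y + 1])) return(memo[x + 1, y + 1])
    v <- if (y == 0) {
      0
    } else if (x == 0) {
      gap_cost * y
    } else {
      i <- iy[y]
      min(M(x - 1, y - 1) + abs(fmat[x, i] - rmat[y, i]),
          M(x - 1, y) + gap_cost,
          M(x, y - 1) + gap_cost)
    }
    memo[x + 1, y + 1] <<- v
    v
  }
  min(vapply(1:L, function(x) M(x, n), numeric(1)))
}

# random probability profile (rows sum to 1, generic values)
random_prob_profile <- function(n) {
  m <- matrix(runif(4 * n), ncol = 4, dimnames = list(NULL, c("A","C","G","T")))
  m / rowSums(m)
}

make_reference_profile <- function(mat) {
  structure(list(mat = mat,
                 persistence = rep(1, nrow(mat)),
                 coverage = rep(0L, nrow(mat))),
            class = "reference_profile")
}

make_read_profile <- function(mat, id = "r") {
  structure(list(id = id, mat = mat), class = "read_profile")
}

certain_read <- function(bases, id = "r") {
  encode_read(bases, phred = rep(1000, nchar(bases)), id = id)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- brute-force affine alignment oracle -------------------------------
# Enumerates every monotone alignment path of a and b and scores it under
# the affine scheme (gap of length k costs open + k*extend); with
# free_ends, columns outside the first..last substitution column cost 0.
# Returns the maximum score (and the number of gap columns inside the
# retained region of one optimal alignment).
oracle_affine_score <- function(a, b, open = 10, extend = 0.5,
                                smat = nuc44(), free_ends = TRUE) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na_ <- length(ca)
  nb_ <- length(cb)
  best <- -Inf
  best_gapcols <- NA_integer_

  # With free ends, only the leading run of gap columns in one single
  # sequence and the trailing run in one single sequence cost nothing
  # (the path travels the first/last row or column of the matrix);
  # everything between is charged.
  score_cols <- function(pa, pb) {
    n <- length(pa)
    lo <- 1
    hi <- n
    if (free_ends) {
      gap_in <- ifelse(pa == "-", 1L, ifelse(pb == "-", 2L, 0L))
      if (gap_in[1] != 0L) {
        k <- 1
        while (k < n && gap_in[k + 1] == gap_in[1]) k <- k + 1
        lo <- k + 1
      }
      if (lo <= n && gap_in[n] != 0L) {
        k <- n
        while (k > lo && gap_in[k - 1] == gap_in[n]) k <- k - 1
        hi <- k - 1
      }
      if (lo > hi) return(c(0, 0))
    }
    rng <- lo:hi
    s <- 0
    gap_a <- FALSE
    gap_b <- FALSE
    ngap <- 0L
    for (k in rng) {
      if (pa[k] == "-") {
        s <- s - extend - if (gap_a) 0 else open
        gap_a <- TRUE; gap_b <- FALSE; ngap <- ngap + 1L
      } else if (pb[k] == "-") {
        s <- s - extend - if (gap_b) 0 else open
        gap_b <- TRUE; gap_a <- FALSE; ngap <- ngap + 1L
      } else {
        s <- s + smat[pa[k], pb[k]]
        gap_a <- gap_b <- FALSE
      }
    }
    c(s, ngap)
  }

  pa <- character(na_ + nb_)
  pb <- character(na_ + nb_)
  rec <- function(i, j, k) {
    if (i == na_ && j == nb_) {
      r <- score_cols(pa[seq_len(k)], pb[seq_len(k)])
      if (r[1] > best) {
        best <<- r[1]
        best_gapcols <<- as.integer(r[2])
      }
      return(invisible(NULL))
    }
    if (i < na_ && j < nb_) {
      pa[k + 1] <<- ca[i + 1]; pb[k + 1] <<- cb[j + 1]
      rec(i + 1, j + 1, k + 1)
    }
    if (i < na_) {
      pa[k + 1] <<- ca[i + 1]; pb[k + 1] <<- "-"
      rec(i + 1, j, k + 1)
    }
    if (j < nb_) {
      pa[k + 1] <<- "-"; pb[k + 1] <<- cb[j + 1]
      rec(i, j + 1, k + 1)
    }
  }
  rec(0, 0, 0)
  list(score = best, gap_columns = best_gapcols)
}
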