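test_that("an exact substring aligns perfectly with free ends", {
  ref <- encode_reference("TTACGTTT")
  rd <- certain_read("ACGT")
  a <- align_read(ref, rd)
  expect_equal(a$edit_distance, 0)
  expect_equal(a$edit_rate, 0)
  expect_equal(a$ref_start, 2)
  expect_equal(a$ref_end, 6)
  expect_true(all(a$path$op == "matchsub"))
})

test_that("the boundary condition charges c per unmatched leading read base", {
  ref <- encode_reference("ACGT")
  rd <- certain_read("T")
  a <- align_read(ref, rd, keep_matrix = TRUE)
  # M(0, y) = c * y, checked along the first row
  expect_equal(a$matrix[1, ], c(0, 1))
  a2 <- align_read(ref, certain_read("TT"), gap_cost = 2, keep_matrix = TRUE)
  expect_equal(a2$matrix[1, ], c(0, 2, 4))
  # free start: first column is all zeros
  expect_equal(a$matrix[, 1], rep(0, 5))
})

test_that("edit distance matches the recursive oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    L <- sample(1:12, 1)
    n <- sample(1:8, 1)
    fmat <- random_prob_profile(L)
    rmat <- random_prob_profile(n)
    a <- align_read(make_reference_profile(fmat), make_read_profile(rmat))
    expect_equal(a$edit_distance, oracle_edit_distance(fmat, rmat),
                 tolerance = 1e-12)
    expect_lte(a$edit_distance, n)  # upper bound c*n
  }
})

test_that("reference 'ACGT' vs read 'AGT' agrees with the oracle", {
  fmat <- encode_reference("ACGT")$mat
  rmat <- certain_read("AGT")$mat
  a <- align_read(make_reference_profile(fmat), make_read_profile(rmat))
  expect_equal(a$edit_distance, oracle_edit_distance(fmat, rmat))
})

test_that("replaying the path reproduces the edit distance", {
  set.seed(55)
  for (i in 1:30) {
    L <- sample(4:40, 1)
    n <- sample(2:20, 1)
    ref <- make_reference_profile(random_prob_profile(L))
    rd <- make_read_profile(random_prob_profile(n))
    a <- align_read(ref, rd)
    # the path consumes exactly n read positions
    expect_equal(sum(a$path$op != "del_from_read"), n)
    cost <- 0
    for (k in seq_len(nrow(a$path))) {
      if (a$path$op[k] == "matchsub") {
        cost <- cost + vector_distance(ref$mat[a$path$ref[k] + 1, ],
                                       rd$mat[a$path$read[k] + 1, ])
      } else {
        cost <- cost + 1
      }
    }
    expect_equal(cost, a$edit_distance, tolerance = 1e-9)
    expect_lte(a$ref_start, a$ref_end)
    expect_lte(a$ref_end, L)
  }
})

test_that("a certain mismatch in the matched segment never lowers the distance", {
  set.seed(77)
  for (i in 1:10) {
    truth <- random_dna(60)
    rd <- certain_read(substr(truth, 21, 50))
    base_a <- align_read(encode_reference(truth), rd)
    pos <- sample(25:45, 1)
    cur <- substr(truth, pos, pos)
    other <- setdiff(c("A", "C", "G", "T"), cur)[1]
    mutated <- paste0(substr(truth, 1, pos - 1), other,
                      substr(truth, pos + 1, 60))
    worse <- align_read(encode_reference(mutated), rd)
    expect_gte(worse$edit_distance, base_a$edit_distance)
  }
})

test_that("tie-breaking prefers substitution and the smallest end row", {
  # perfect repeat: several rows tie at distance 0; smallest x wins
  ref <- encode_reference("ACACAC")
  a <- align_read(ref, certain_read("AC"))
  expect_equal(a$ref_start, 0)
  expect_equal(a$ref_end, 2)
  # substitution (d = 1) ties with an insertion route in the same cell;
  # matchsub is chosen
  a2 <- align_read(encode_reference("A"), certain_read("C"))
  expect_equal(a2$edit_distance, 1)
  expect_equal(a2$path$op, "matchsub")
  # a leading mismatch ties with an insertion route; the substitution wins
  a3 <- align_read(encode_reference("AC"), certain_read("CC"))
  expect_equal(a3$edit_distance, 1)
  expect_true(all(a3$path$op == "matchsub"))
  expect_equal(a3$ref_end, 2)
  # equal-cost endings resolve to the smallest end row: a mid-read
  # mismatch can tie with an insertion path ending one row earlier
  a4 <- align_read(encode_reference("AAA"), certain_read("ATA"))
  expect_equal(a4$edit_distance, 1)
  expect_equal(a4$ref_end, 2)
})

test_that("a read longer than the reference needs exactly one insertion", {
  ref <- encode_reference("ACGT")
  a <- align_read(ref, certain_read("ACGAT"))
  expect_equal(a$edit_distance, 1)
  expect_equal(sum(a$path$op == "ins_from_read"), 1)
  expect_equal(sum(a$path$op == "matchsub"), 4)
})

test_that("windowed alignment is consistent with the global optimum", {
  set.seed(9)
  truth <- random_dna(400)
  rd <- certain_read(substr(truth, 101, 180))
  ref <- encode_reference(truth)
  full <- align_read(ref, rd)
  win <- align_read(ref, rd, window = c(50, 250))
  expect_equal(win$edit_distance, full$edit_distance)
  expect_equal(win$ref_start, full$ref_start)
  expect_equal(win$ref_end, full$ref_end)
  expect_equal(win$path$ref, full$path$ref)
  expect_error(align_read(ref, rd, window = c(-1, 100)), "window")
  expect_error(align_read(ref, rd, window = c(100, 500)), "window")
})

test_that("stranded alignment picks the better orientation, ties forward", {
  truth <- "ACGGTTACGATCGATCGGAT"
  ref <- encode_reference(truth)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(truth, "")[[1]]), collapse = ""))
  rd <- certain_read(substr(rc, 3, 12))
  fwd_only <- align_read_stranded(ref, rd, strand = "forward")
  both <- align_read_stranded(ref, rd, strand = "both")
  expect_equal(both$alignment$orientation, "reverse")
  expect_lt(both$alignment$edit_rate, fwd_only$alignment$edit_rate)
  expect_equal(both$alignment$edit_distance, 0)
  # palindromic read aligns equally both ways: forward kept
  pal <- align_read_stranded(encode_reference("AATT"), certain_read("AATT"))
  expect_equal(pal$alignment$orientation, "forward")
})
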