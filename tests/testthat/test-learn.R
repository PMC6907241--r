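test_that("the schedule maps edit rates to the documented learning rates", {
  # below the sequencing-error threshold: maximal learning
  for (er in c(0, 0.01, 0.03, 0.049)) {
    s <- learn_rate_schedule(er)
    expect_equal(s$learning_rate, 0.95)
    expect_equal(s$w, 0.05)
  }
  # above the distant-reference threshold: minimal learning
  for (er in c(0.351, 0.40, 1, 5)) {
    s <- learn_rate_schedule(er)
    expect_equal(s$learning_rate, 0.05)
    expect_equal(s$w, 0.95)
  }
  # linear in between: midpoint
  s <- learn_rate_schedule(0.20)
  expect_equal(s$w, 0.5)
  expect_equal(s$learning_rate, 0.5)
  expect_error(learn_rate_schedule(-0.1), "non-negative")
})

test_that("a perfect read leaves the reference at its fixed point", {
  ref <- encode_reference("ACGTACGT")
  rd <- certain_read("ACGTACGT")
  a <- align_read(ref, rd)
  u <- apply_update(ref, rd, a, w = 0.3)
  expect_equal(u$reference$mat, ref$mat)
  expect_equal(u$reference$persistence, ref$persistence)
  expect_equal(u$outcome,
               list(n_substituted = 8L, n_inserted = 0L, n_deleted = 0L,
                    new_length = 8L))
  expect_equal(u$reference$coverage, rep(1L, 8))
})

test_that("a substitution is a convex combination of old and read vectors", {
  ref <- encode_reference("A")
  rd <- certain_read("C")
  a <- align_read(ref, rd)
  u <- apply_update(ref, rd, a, w = 0.05)
  expect_equal(unname(u$reference$mat[1, ]), c(0.05, 0.95, 0, 0))
})

test_that("one well-aligned read triggers a pending insertion", {
  # reference lacks one base present in the read
  ref <- encode_reference("ACGGTAC")
  rd <- certain_read("ACGAGTAC")  # extra A after position 2
  a <- align_read(ref, rd)
  expect_equal(sum(a$path$op == "ins_from_read"), 1)
  u <- apply_update(ref, rd, a, w = 0.05)
  expect_equal(u$outcome$n_inserted, 1L)
  expect_equal(u$outcome$new_length, 8L)
  expect_equal(consensus(u$reference), "ACGAGTAC")
  expect_true(all(u$reference$persistence > 0 & u$reference$persistence < 2))
  # a subsequent perfect read now has edit distance 0
  a2 <- align_read(u$reference, rd)
  expect_lt(a2$edit_distance, 1e-3)
})

test_that("one well-aligned read triggers a pending deletion", {
  ref <- encode_reference("ACGAGTAC")  # has an extra A the reads lack
  rd <- certain_read("ACGGTAC")
  a <- align_read(ref, rd)
  expect_equal(sum(a$path$op == "del_from_read"), 1)
  u <- apply_update(ref, rd, a, w = 0.05)
  expect_equal(u$outcome$n_deleted, 1L)
  expect_equal(u$outcome$new_length, 7L)
  expect_equal(consensus(u$reference), "ACGGTAC")
})

test_that("a poorly aligned read can never trigger an indel", {
  ref <- encode_reference("ACGGTAC")
  rd <- certain_read("ACGAGTAC")
  a <- align_read(ref, rd)
  u <- apply_update(ref, rd, a, w = 0.95)
  expect_equal(u$outcome$n_inserted, 0L)
  expect_equal(u$outcome$n_deleted, 0L)
  expect_equal(u$outcome$new_length, 7L)
  ref2 <- encode_reference("ACGAGTAC")
  rd2 <- certain_read("ACGGTAC")
  u2 <- apply_update(ref2, rd2, align_read(ref2, rd2), w = 0.95)
  expect_equal(u2$outcome$n_deleted, 0L)
})

test_that("updates conserve probability and length bookkeeping", {
  set.seed(13)
  ref <- encode_reference(random_dna(120))
  for (i in 1:40) {
    rd <- encode_read(random_dna(30), phred = sample(5:40, 30, TRUE),
                      id = paste0("r", i))
    a <- align_read(ref, rd)
    w <- learn_rate_schedule(a$edit_rate)$w
    old_len <- nrow(ref$mat)
    u <- apply_update(ref, rd, a, w)
    expect_equal(u$outcome$new_length,
                 old_len + u$outcome$n_inserted - u$outcome$n_deleted)
    ref <- u$reference
    expect_true(all(abs(rowSums(ref$mat) - 1) < 1e-9))
    expect_true(all(ref$mat >= 0))
    expect_true(all(ref$persistence > 0 & ref$persistence < 2))
    expect_equal(length(ref$persistence), nrow(ref$mat))
    expect_equal(length(ref$coverage), nrow(ref$mat))
  }
})

test_that("a stale alignment is rejected", {
  ref <- encode_reference("ACGTACGTAC")
  rd <- certain_read("ACGT")
  a <- align_read(ref, rd)
  short <- encode_reference("ACG")
  expect_error(apply_update(short, rd, a, w = 0.5), "stale")
})

test_that("a corrupted reference converges to the truth in one epoch", {
  # truth 500 bp; reference differs by 5 substitutions, 1 insertion and
  # 1 deletion; error-free tiled reads at 30x in random order
  for (seed in 1:10) {
    rec <- reference_recovery(truth_length = 500, n_sub = 5, n_ins = 1,
                              n_del = 1, coverage = 30, seed = seed)
    expect_equal(consensus(rec$assembly$reference), rec$truth)
  }
})

test_that("the truth is a fixed point of further error-free updates", {
  set.seed(3)
  truth <- random_dna(300)
  reads <- tile_reads(truth, read_length = 60, coverage = 10)
  fit1 <- assemble(truth, reads, learn_config(seed = 1, strand = "forward"))
  expect_equal(fit1$consensus, truth)
  fit2 <- assemble(fit1$reference, reads,
                   learn_config(seed = 2, strand = "forward"))
  expect_equal(fit2$consensus, truth)
})
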