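toy_profile <- function() {
  sc <- matrix(-2, nrow = 2, ncol = 20, dimnames = list(NULL, aa_alphabet()))
  sc[1, "A"] <- 2
  sc[2, "G"] <- 3
  profile_def("PRF", sc, gap_open = -4, gap_extend = -1, cutoff = 4)
}

test_that("profile_score recovers the known best alignments", {
  pr <- toy_profile()
  expect_equal(profile_score(pr, "AG"), list(score = 5, start = 1L, end = 2L))
  # contiguous AG beats gapped alternatives; span is local in the sequence
  expect_equal(profile_score(pr, "AAG"), list(score = 5, start = 2L, end = 3L))
  sc1 <- matrix(-1, nrow = 1, ncol = 20, dimnames = list(NULL, aa_alphabet()))
  sc1[1, "M"] <- 1
  pr1 <- profile_def("P1", sc1, gap_open = -4, gap_extend = -1, cutoff = 0.5)
  expect_equal(profile_score(pr1, "M"), list(score = 1, start = 1L, end = 1L))
  # no zero floor: with every match score negative the best score is negative
  expect_equal(profile_score(pr1, "G")$score, -1)
})

test_that("profile_def enforces its invariants", {
  sc <- matrix(0, nrow = 2, ncol = 20, dimnames = list(NULL, aa_alphabet()))
  expect_error(profile_def("X", sc[, 1:19], -4, -1, 1), "20 columns")
  expect_error(profile_def("X", sc, 1, -1, 1), "<= 0")
  expect_error(profile_def("X", sc, -1, -4, 1), "gap_extend")
  expect_error(profile_def("X", sc, -4, -1, 0), "cutoff")
})

test_that("profile_score agrees with exhaustive alignment enumeration", {
  withr::local_seed(202)
  for (i in 1:150) {
    pr <- random_profile()
    s <- random_sequence(sample(1:8, 1))
    got <- profile_score(pr, s)
    want <- oracle_profile_score(pr$scores, s, pr$gap_open, pr$gap_extend)
    expect_equal(got$score, want$score, label = paste("score, instance", i))
    expect_equal(got$start, want$start, label = paste("start, instance", i))
    expect_equal(got$end, want$end, label = paste("end, instance", i))
  }
})

test_that("extending a sequence never lowers the best local score", {
  withr::local_seed(303)
  for (i in 1:60) {
    pr <- random_profile()
    s <- random_sequence(sample(3:12, 1))
    base <- profile_score(pr, s)$score
    longer <- paste0(s, random_sequence(sample(1:5, 1)))
    expect_gte(profile_score(pr, longer)$score, base)
    prefixed <- paste0(random_sequence(sample(1:5, 1)), s)
    expect_gte(profile_score(pr, prefixed)$score, base)
  }
})
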