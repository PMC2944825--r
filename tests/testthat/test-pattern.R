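test_that("the pattern dialect parses into the documented structure", {
  p <- parse_pattern("[AC]-x-V-x(4)-{ED}.")
  expect_equal(p$elements$kind,
               c("any_of", "wildcard", "exact", "wildcard", "none_of"))
  expect_equal(p$elements$residues[[1]], c("A", "C"))
  expect_equal(p$elements$residues[[3]], "V")
  expect_equal(p$elements$residues[[5]], c("D", "E"))
  expect_equal(p$elements$min_repeat, c(1L, 1L, 1L, 4L, 1L))
  expect_equal(p$elements$max_repeat, c(1L, 1L, 1L, 4L, 1L))
  expect_false(p$n_anchor)
  expect_false(p$c_anchor)

  q <- parse_pattern("<M-x(2,3)-D")
  expect_true(q$n_anchor)
  expect_equal(q$elements$kind, c("exact", "wildcard", "exact"))
  expect_equal(q$elements$min_repeat[2], 2L)
  expect_equal(q$elements$max_repeat[2], 3L)

  r <- parse_pattern("A-[KR]>")
  expect_true(r$c_anchor)
})

test_that("malformed patterns are rejected with a column offset", {
  expect_error(parse_pattern("[]-A"), "empty class")
  expect_error(parse_pattern("[AC"), "unbalanced")
  expect_error(parse_pattern("A-x(3,2)"), "n > m")
  expect_error(parse_pattern("A-x(0)"), ">= 1")
  expect_error(parse_pattern("A-B-Z"), "unexpected character")
  expect_error(parse_pattern("[AB1]"), "illegal letter")
  expect_error(parse_pattern("A-"), "trailing")
  expect_error(parse_pattern(""), "empty pattern")
  err <- tryCatch(parse_pattern("A-x-[]"), error = function(e) conditionMessage(e))
  expect_match(err, "column 5")
})

test_that("scan_pattern reports greedy longest-per-start spans", {
  p <- parse_pattern("[AC]-x-V-x(4)-{ED}")
  expect_equal(scan_pattern(p, "CPVAAAAH"),
               tibble::tibble(start = 1L, end = 8L), ignore_attr = TRUE)
  expect_equal(nrow(scan_pattern(parse_pattern("<M-x(2)-D"), "AMKAD")), 0L)
  expect_equal(nrow(scan_pattern(parse_pattern("F"), "AAA")), 0L)
  # greedy repetition: longest span per start, overlapping starts allowed
  hits <- scan_pattern(parse_pattern("A(1,3)"), "AAAG")
  expect_equal(hits$start, 1:3)
  expect_equal(hits$end, c(3L, 3L, 3L))
  # anchors restrict where matches may start/end
  expect_equal(scan_pattern(parse_pattern("<M-x(2)-D"), "MKAD"),
               tibble::tibble(start = 1L, end = 4L), ignore_attr = TRUE)
  expect_equal(scan_pattern(parse_pattern("G-x>"), "AGAGC"),
               tibble::tibble(start = 4L, end = 5L), ignore_attr = TRUE)
})

test_that("parse/deparse round-trips the pattern structure", {
  withr::local_seed(11)
  for (i in 1:50) {
    p <- random_pattern()
    q <- parse_pattern(deparse_pattern(p))
    expect_equal(q$elements, p$elements)
    expect_equal(q$n_anchor, p$n_anchor)
    expect_equal(q$c_anchor, p$c_anchor)
  }
})

test_that("scan_pattern agrees with the expansion-enumeration oracle", {
  withr::local_seed(101)
  for (i in 1:300) {
    p <- random_pattern()
    s <- random_sequence(sample(5:25, 1))
    got <- scan_pattern(p, s)
    want <- oracle_scan_pattern(p, s)
    expect_equal(got$start, want$start,
                 label = paste0("starts for ", deparse_pattern(p), " on ", s))
    expect_equal(got$end, want$end,
                 label = paste0("ends for ", deparse_pattern(p), " on ", s))
  }
})
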