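test_that("apply_snp substitutes exactly one residue", {
  expect_equal(apply_snp("MKTV", 2, "R"), "MRTV")
  expect_equal(apply_snp("M", 1, "L"), "L")
  expect_error(apply_snp("MKTV", 5, "A"), "outside sequence")
  expect_error(apply_snp("MKTV", 0, "A"), "outside sequence")
  expect_error(apply_snp("MKTV", 2, "X"), "illegal residue")
})

test_that("domain distortion is the clamped relative score drop", {
  expect_identical(domain_distortion(100, 85), 0.15)
  expect_identical(domain_distortion(42, 42), 0)
  expect_identical(domain_distortion(50, 60), 0)  # improving SNPs do not distort
  expect_error(domain_distortion(0, 5), "undefined")
  expect_error(domain_distortion(-3, 5), "undefined")
})

test_that("the toy fixture classifies as constructed: 2 DA, 2 D, 1 outside", {
  doms <- toy_domains()
  prot <- toy_proteome()
  cl <- classify_all(toy_snps(), prot, doms, dd_cutoff = 0.10)
  expect_equal(cl$summary$n_snps, 5L)
  expect_equal(cl$summary$n_d_snp, 4L)
  expect_equal(cl$summary$n_da_snp, 2L)
  status <- setNames(cl$snp_status$status, cl$snp_status$snp_id)
  expect_equal(status, toy_expected_status())
  calls <- cl$calls
  expect_equal(calls$mechanism[calls$snp_id == "s1"], "pattern_loss")
  expect_equal(calls$mechanism[calls$snp_id == "s3"], "profile_distortion")
  expect_equal(calls$dd[calls$snp_id == "s3"], 1 / 3)
  expect_equal(calls$ms_ref[calls$snp_id == "s3"], 9)
  expect_equal(calls$ms_alt[calls$snp_id == "s3"], 6)
  expect_false(calls$erased[calls$snp_id == "s3"])  # MS_alt 6 still >= cutoff 6
  expect_equal(calls$dd[calls$snp_id == "s4"], 0)
  expect_true(is.na(calls$domain_id[calls$snp_id == "s5"]))
})

test_that("profile-domain erasure forces a DA call even below the DD cutoff", {
  sc <- matrix(-2, nrow = 4, ncol = 20, dimnames = list(NULL, aa_alphabet()))
  sc[1, "M"] <- 5; sc[2, "K"] <- 5; sc[3, "T"] <- 5; sc[4, "V"] <- 5
  # cutoff just under the full score: losing 7 (5 -> -2) drops below it
  pr <- profile_def("ERASE", sc, gap_open = -10, gap_extend = -10, cutoff = 19)
  doms <- structure(list(ERASE = pr), class = "domain_set")
  prot <- tibble::tibble(protein_id = "P1", gene_symbol = "",
                         sequence = "GGMKTVGG")
  snp <- tibble::tibble(snp_id = "e1", protein_id = "P1", position = 4L,
                        ref_aa = "K", alt_aa = "R")
  # DD = 7/20 = 0.35: pick a cutoff above it so only the erasure rule fires
  cl <- classify_all(snp, prot, doms, dd_cutoff = 0.9)
  expect_equal(cl$calls$status, "da_snp")
  expect_true(cl$calls$erased)
  expect_lt(cl$calls$dd, 0.9)
})

test_that("classification is deterministic and handles empty input", {
  u <- small_universe()
  a <- classify_all(u$snps, u$proteome, u$domains)
  b <- classify_all(u$snps, u$proteome, u$domains)
  expect_identical(a$calls, b$calls)
  empty <- classify_all(u$snps[0, ], u$proteome, u$domains,
                        ref_matches = u$ref_matches)
  expect_equal(empty$summary$n_snps, 0L)
  expect_equal(empty$summary$n_da_snp, 0L)
})

test_that("raising the DD cutoff never increases the DA count", {
  u <- small_universe()
  cl <- classify_all(u$snps, u$proteome, u$domains, ref_matches = u$ref_matches)
  cutoffs <- c(0.05, 0.10, 0.15, 0.20, 0.5, 1)
  counts <- vapply(cutoffs, function(co) {
    sum(snp_status(cl$calls, co)$status == "da_snp")
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pattern-loss calls are confirmed by the expansion oracle", {
  u <- small_universe()
  cl <- classify_all(u$snps, u$proteome, u$domains, ref_matches = u$ref_matches)
  losses <- cl$calls[cl$calls$mechanism == "pattern_loss", ]
  expect_gt(nrow(losses), 0L)
  seq_of <- setNames(u$proteome$sequence, u$proteome$protein_id)
  for (i in seq_len(nrow(losses))) {
    snp <- u$snps[u$snps$snp_id == losses$snp_id[i], ]
    mutated <- apply_snp(seq_of[[snp$protein_id]], snp$position, snp$alt_aa)
    hits <- oracle_scan_pattern(u$domains[[losses$domain_id[i]]], mutated)
    overlapping <- nrow(hits) > 0 &&
      any(hits$start <= snp$position & hits$end >= snp$position)
    expect_false(overlapping,
                 label = paste("surviving overlap for", losses$snp_id[i]))
  }
})

test_that("tidy and glance expose calls and summary", {
  doms <- toy_domains()
  cl <- classify_all(toy_snps(), toy_proteome(), doms)
  expect_identical(tidy(cl), cl$calls)
  expect_identical(glance(cl), cl$summary)
})
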