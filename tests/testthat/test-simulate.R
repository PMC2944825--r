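test_that("universe_config validates its fields", {
  expect_s3_class(universe_config(seed = 1), "universe_config")
  expect_error(universe_config(seed = 1, frac_snp_in_domain = 1.5), "\\[0, 1\\]")
  expect_error(universe_config(seed = 1, disease_odds_ratio_da = 0.5), ">= 1")
  expect_error(universe_config(seed = 1, rule_fidelity = 0.4), "rule_fidelity")
  expect_error(universe_config(seed = 1, protein_length = c(400, 80)),
               "increasing")
  expect_error(universe_config(seed = 1, protein_length = c(10, 30)),
               "minimum protein length")
})

test_that("generation is byte-reproducible for a fixed seed", {
  cfg <- universe_config(seed = 5, n_proteins = 40)
  a <- generate_universe(cfg)
  b <- generate_universe(cfg)
  expect_identical(a$proteome, b$proteome)
  expect_identical(a$snps, b$snps)
  expect_identical(a$edges, b$edges)
  expect_identical(a$disease, b$disease)
  expect_identical(a$truth$rules, b$truth$rules)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_universe(a, d1)
  write_universe(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("generated files pass every reader's validation", {
  u <- small_universe()
  dir <- withr::local_tempdir()
  write_universe(u, dir)
  prot <- read_proteome(file.path(dir, "proteome.fasta"))
  expect_equal(nrow(prot), nrow(u$proteome))
  snps <- read_snps(file.path(dir, "snps.tsv"), prot)  # no warning: all valid
  expect_equal(nrow(snps), nrow(u$snps))
  expect_equal(nrow(load_report(snps)), 0L)
  expect_equal(read_ppi_edges(file.path(dir, "edges.tsv")), u$edges)
  doms <- read_domains(file.path(dir, "domains.txt"))
  expect_equal(names(doms), names(u$domains))
  expect_silent(read_motifs(file.path(dir, "motifs.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
})

test_that("intended SNP classes are realized by the classifier", {
  u <- small_universe()
  cl <- classify_all(u$snps, u$proteome, u$domains,
                     dd_cutoff = u$config$dd_cutoff,
                     ref_matches = u$ref_matches)
  truth <- u$truth$snps
  status <- setNames(cl$snp_status$status, cl$snp_status$snp_id)
  # constructive guarantee: every intended DA-SNP is classified DA
  da_ids <- truth$snp_id[truth$intended_class == "da_snp"]
  expect_gt(length(da_ids), 0L)
  expect_true(all(status[da_ids] == "da_snp"))
  # >= 95% of intended benign in-domain SNPs classify as plain D-SNPs
  benign <- truth$snp_id[truth$intended_class == "d_snp"]
  expect_gte(mean(status[benign] == "d_snp"), 0.95)
  # and intended outside SNPs stay outside
  outside <- truth$snp_id[truth$intended_class == "outside"]
  expect_gte(mean(status[outside] == "outside"), 0.95)
})

test_that("a zero DA fraction yields zero DA calls", {
  u0 <- generate_universe(universe_config(seed = 9, n_proteins = 60,
                                          frac_da_given_domain = 0))
  cl <- classify_all(u0$snps, u0$proteome, u0$domains,
                     ref_matches = u0$ref_matches)
  expect_equal(cl$summary$n_da_snp, 0L)
  expect_gt(cl$summary$n_d_snp, 0L)
})

test_that("expected_counts reflects the manifest", {
  u <- small_universe()
  ec <- expected_counts(u)
  val <- setNames(ec$value, ec$quantity)
  expect_equal(val[["n_snps"]], nrow(u$snps))
  expect_equal(val[["n_da_snp_intended"]],
               sum(u$truth$snps$intended_class == "da_snp"))
  expect_equal(val[["n_edges"]], nrow(u$edges))
  expect_equal(val[["n_rules"]], nrow(u$truth$rules))
  dis <- ec[ec$quantity == "n_diseased_snps", ]
  expect_false(dis$exact)
  expect_true(dis$value >= dis$lower && dis$value <= dis$upper)
})

test_that("rule-generated edges dominate at the configured fidelity", {
  u <- small_universe()
  et <- u$truth$edges
  expect_gt(mean(et$rule_id != "noise"), 0.5)
  # zero-noise wiring attributes every edge to a rule
  u1 <- generate_universe(universe_config(seed = 3, n_proteins = 60,
                                          rule_fidelity = 1))
  expect_true(all(u1$truth$edges$rule_id != "noise"))
})
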