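test_that("hypergeom_upper matches hand-derived values", {
  expect_equal(hypergeom_upper(10, 5, 5, 5), 1 / 252)
  expect_identical(hypergeom_upper(100, 30, 10, 0), 1.0)
  # proteome-scale contingency: enrichment so extreme the p-value is
  # numerically indistinguishable from zero at reporting precision
  expect_lt(hypergeom_upper(63899, 1782, 12965, 801), 1e-10)
  expect_error(hypergeom_upper(10, 11, 5, 2), "invalid contingency")
  expect_error(hypergeom_upper(10, 5, 5, 6), "invalid contingency")
})

test_that("hypergeom_upper equals the combinatorial sum", {
  # exhaustive for small populations
  for (N in c(1:12, 25)) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeom_upper(N, K, n, k),
                       oracle_hyper_upper(N, K, n, k),
                       tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
  # random spot checks at larger scale
  withr::local_seed(7)
  for (i in 1:200) {
    N <- sample(50:400, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_upper(N, K, n, k), oracle_hyper_upper(N, K, n, k),
                 tolerance = 1e-9)
  }
})

test_that("the upper tail is non-increasing in k", {
  ps <- vapply(0:10, function(k) hypergeom_upper(40, 15, 10, k), numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("enrich_class builds the documented contingency", {
  pop <- paste0("s", 1:20)
  ann <- paste0("s", 1:6)
  res <- enrich_class(paste0("s", 1:5), ann, pop)
  expect_equal(res$population_n, 20L)
  expect_equal(res$population_k, 6L)
  expect_equal(res$sample_n, 5L)
  expect_equal(res$sample_k, 5L)
  expect_equal(res$p_value, oracle_hyper_upper(20, 6, 5, 5))
  # degenerate cases
  expect_equal(enrich_class(pop, ann, pop)$p_value, 1.0)
  expect_equal(enrich_class(paste0("s", 10:15), paste0("x", 1:4), pop)$p_value, 1.0)
  expect_error(enrich_class("zzz", ann, pop), "subset")
})

test_that("dd_sweep rows are consistent with the classifier", {
  u <- small_universe()
  cl <- classify_all(u$snps, u$proteome, u$domains, ref_matches = u$ref_matches)
  sw <- dd_sweep(cl, u$disease, cutoffs = c(0.05, 0.10, 0.15, 0.20),
                 snps = u$snps)
  expect_equal(sw$dd_cutoff, c(0.05, 0.10, 0.15, 0.20))
  expect_true(all(diff(sw$n_da_snp) <= 0))
  # the 0.10 row must reproduce classify_all's working-cutoff count exactly
  expect_equal(sw$n_da_snp[sw$dd_cutoff == 0.10], cl$summary$n_da_snp)
  expect_equal(attr(sw, "population_n"), cl$summary$n_d_snp)
  expect_error(dd_sweep(cl, u$disease, cutoffs = numeric(0)), "non-empty")
  # at cutoff 1 only pattern losses, erasures and DD = 1 SNPs remain
  sw1 <- dd_sweep(cl, u$disease, cutoffs = 1, snps = u$snps)
  hard <- cl$calls |>
    dplyr::group_by(snp_id) |>
    dplyr::summarise(hard = any(mechanism == "pattern_loss" |
                                  (!is.na(erased) & erased) |
                                  (!is.na(dd) & dd >= 1)))
  expect_equal(sw1$n_da_snp, sum(hard$hard))
})

test_that("protein-level disease matching is supported", {
  u <- small_universe()
  cl <- classify_all(u$snps, u$proteome, u$domains, ref_matches = u$ref_matches)
  swp <- dd_sweep(cl, u$disease, cutoffs = 0.10, snps = u$snps,
                  level = "protein")
  expect_true(swp$n_da_snp_diseased >= 0)
  # protein-level annotation covers every SNP in an annotated protein, so
  # the annotated count can only grow relative to snp-level matching
  sws <- dd_sweep(cl, u$disease, cutoffs = 0.10, snps = u$snps, level = "snp")
  expect_gte(attr(swp, "population_k"), attr(sws, "population_k"))
})

test_that("term_enrichment ranks a perfectly matching term first", {
  universe <- paste0("g", 1:50)
  gs <- paste0("g", 1:8)
  terms <- list(
    perfect = gs,
    half = paste0("g", c(1:4, 20:23)),
    unrelated = paste0("g", 30:40)
  )
  res <- term_enrichment(gs, terms, universe, p_cutoff = 1)
  expect_equal(res$term[1], "perfect")
  expect_equal(res$p_value[res$term == "unrelated"], 1.0)
  expect_true(all(res$q_value >= res$p_value))
  # default reporting cutoff drops non-significant terms
  res2 <- term_enrichment(gs, terms, universe)
  expect_false("unrelated" %in% res2$term)
  expect_error(term_enrichment(gs, terms, character(0)), "non-empty")
  expect_error(term_enrichment("nope", terms, universe), "subset")
})
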