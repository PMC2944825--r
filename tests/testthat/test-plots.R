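test_that("result types have plot methods and tidiers", {
  u <- small_universe()
  cl <- classify_all(u$snps, u$proteome, u$domains, ref_matches = u$ref_matches)
  sw <- dd_sweep(cl, u$disease, snps = u$snps)
  expect_s3_class(autoplot(sw), "ggplot")
  expect_s3_class(autoplot(cl), "ggplot")
  expect_s3_class(tidy(sw), "tbl_df")
  expect_equal(glance(sw)$n_cutoffs, 4L)

  an <- annotate_signatures(u$ref_matches, u$motifs, u$proteome)
  rd <- unique(u$truth$rules$domain_id)
  counts <- build_score_matrix(rd, an, u$edges)
  sc <- score_pairs(counts, an, u$edges, rd, reference_pairs = u$reference_pairs)
  expect_s3_class(autoplot(sc), "ggplot")
  expect_equal(glance(sc)$n_pairs, nrow(sc))

  br <- call_broken_edges(cl, sc, an, u$edges)
  rep <- connectivity_report(br, u$edges, proteome = u$proteome)
  expect_s3_class(plot_connectivity(rep), "ggplot")
})
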