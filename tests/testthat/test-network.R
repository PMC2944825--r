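toy_annotations <- function() {
  ann <- tibble::tibble(
    protein_id = c("K", "L", "L", "M", "N"),
    signature_id = c("D1", "S1", "S2", "S1", "D2"),
    kind = c("domain", "motif", "motif", "motif", "domain")
  )
  attr(ann, "proteins") <- c("K", "L", "M", "N", "O")
  ann
}

test_that("build_score_matrix counts domain/partner-signature co-occurrences", {
  ann <- toy_annotations()
  edges <- tibble::tibble(protein_a = "K", protein_b = "L")
  m <- build_score_matrix("D1", ann, edges)
  expect_equal(m$observed[m$signature_id == "S1"], 1L)
  expect_equal(m$observed[m$signature_id == "S2"], 1L)
  # an edge whose endpoints carry no alterable domain contributes nothing
  m2 <- build_score_matrix("D1", ann,
                           tibble::tibble(protein_a = "L", protein_b = "M"))
  expect_equal(nrow(m2), 0L)
  # endpoints outside the annotated universe skip the edge, with a count
  m3 <- build_score_matrix("D1", ann,
                           tibble::tibble(protein_a = "K", protein_b = "ZZ"))
  expect_equal(nrow(m3), 0L)
  expect_equal(attr(m3, "n_skipped"), 1L)
})

test_that("score-matrix counts equal a brute-force recount on a toy network", {
  ann <- toy_annotations()
  edges <- tibble::tibble(protein_a = c("K", "K", "L"),
                          protein_b = c("L", "M", "N"))
  da <- c("D1", "D2")
  m <- build_score_matrix(da, ann, edges)
  # brute force over every edge, orientation, domain and signature
  brute <- list()
  sets <- split(ann$signature_id, ann$protein_id)
  doms <- split(ann$signature_id[ann$kind == "domain"],
                ann$protein_id[ann$kind == "domain"])
  for (i in seq_len(nrow(edges))) {
    for (o in 1:2) {
      host <- if (o == 1) edges$protein_a[i] else edges$protein_b[i]
      partner <- if (o == 1) edges$protein_b[i] else edges$protein_a[i]
      for (d in intersect(doms[[host]], da)) {
        for (s in sets[[partner]]) {
          key <- paste(d, s)
          brute[[key]] <- (brute[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  got <- setNames(m$observed, paste(m$domain_id, m$signature_id))
  expect_mapequal(as.list(got), brute)
})

test_that("score_pairs assigns evidence tiers from the reference lists", {
  u <- small_universe()
  an <- annotate_signatures(u$ref_matches, u$motifs, u$proteome)
  rd <- unique(u$truth$rules$domain_id)
  counts <- build_score_matrix(rd, an, u$edges)
  sc <- score_pairs(counts, an, u$edges, rd, reference_pairs = u$reference_pairs)
  # every planted rule present in the reference list gets its tier
  ref_dd <- u$reference_pairs[u$reference_pairs$kind == "domain_domain", ]
  for (i in seq_len(nrow(sc))) {
    d <- sc$domain_id[i]; s <- sc$signature_id[i]
    in_dd <- sc$signature_kind[i] == "domain" &&
      any(ref_dd$sig_a == pmin(d, s) & ref_dd$sig_b == pmax(d, s))
    if (in_dd) expect_equal(sc$tier[i], "ddi_reference")
  }
  expect_true(all(sc$tier %in% c("ddi_reference", "domain_motif_reference",
                                 "enrichment_only")))
  # alpha bounds: nothing enriched at alpha ~ 0, everything at alpha = 1
  sc0 <- score_pairs(counts, an, u$edges, rd, alpha = 1e-300)
  expect_false(any(sc0$enriched))
  sc1 <- score_pairs(counts, an, u$edges, rd, alpha = 1)
  expect_true(all(sc1$enriched))
})

test_that("empirical background agrees with the analytic null in rank order", {
  u <- small_universe()
  an <- annotate_signatures(u$ref_matches, u$motifs, u$proteome)
  rd <- unique(u$truth$rules$domain_id)
  counts <- build_score_matrix(rd, an, u$edges)
  analytic <- score_pairs(counts, an, u$edges, rd)
  empirical <- score_pairs(counts, an, u$edges, rd, mode = "empirical",
                           n_background = 400, seed = 99)
  expect_equal(nrow(analytic), nrow(empirical))
  rho <- cor(analytic$p_value, empirical$p_value, method = "spearman")
  expect_gte(rho, 0.9)
  # the empirical estimator is bounded below by 1/(1+B)
  expect_true(all(empirical$p_value >= 1 / (1 + 400)))
  # and is reproducible for a fixed seed
  again <- score_pairs(counts, an, u$edges, rd, mode = "empirical",
                       n_background = 400, seed = 99)
  expect_identical(empirical$p_value, again$p_value)
  expect_error(score_pairs(counts, an, u$edges, rd, mode = "empirical",
                           n_background = 400), "seed")
})

test_that("broken-edge calls respect enrichment and the tier filter", {
  ann <- toy_annotations()
  edges <- tibble::tibble(protein_a = c("K", "K"), protein_b = c("L", "O"))
  calls <- tibble::tibble(
    snp_id = "rs1", protein_id = "K", domain_id = "D1", status = "da_snp",
    mechanism = "pattern_loss", dd = NA_real_, ms_ref = NA_real_,
    ms_alt = NA_real_, erased = NA
  )
  scores <- tibble::tibble(
    domain_id = "D1", signature_id = "S1", signature_kind = "motif",
    observed = 1L, population_n = 5L, population_k = 2L, sample_n = 2L,
    sample_k = 2L, p_value = 0.01, enriched = TRUE, tier = "ddi_reference"
  )
  br <- call_broken_edges(calls, scores, ann, edges)
  expect_equal(nrow(br), 2L)
  kl <- br[br$protein_b == "L", ]
  expect_equal(kl$status, "broken")
  expect_equal(kl$best_tier, "ddi_reference")
  expect_equal(kl$matched_signatures, "S1")
  # partner O carries nothing: intact
  expect_equal(br$status[br$protein_b == "O"], "intact")
  # an enrichment_only pair is excluded under a stricter min_tier
  scores$tier <- "enrichment_only"
  br2 <- call_broken_edges(calls, scores, ann, edges,
                           min_tier = "ddi_reference")
  expect_true(all(br2$status == "intact"))
  br3 <- call_broken_edges(calls, scores, ann, edges,
                           min_tier = "enrichment_only")
  expect_equal(br3$status[br3$protein_b == "L"], "broken")
  # non-enriched pairs never break an edge
  scores$enriched <- FALSE
  br4 <- call_broken_edges(calls, scores, ann, edges)
  expect_true(all(br4$status == "intact"))
})

test_that("connectivity totals equal the evaluated degree and recount", {
  u <- small_universe()
  an <- annotate_signatures(u$ref_matches, u$motifs, u$proteome)
  cl <- classify_all(u$snps, u$proteome, u$domains, ref_matches = u$ref_matches)
  da_domains <- unique(cl$calls$domain_id[cl$calls$status == "da_snp"])
  counts <- build_score_matrix(da_domains, an, u$edges)
  sc <- score_pairs(counts, an, u$edges, da_domains,
                    reference_pairs = u$reference_pairs)
  br <- call_broken_edges(cl, sc, an, u$edges)
  rep <- connectivity_report(br, u$edges, proteome = u$proteome)
  expect_gt(nrow(rep$connectivity), 0L)
  # n_broken + n_intact = evaluated degree, and matches a brute-force recount
  for (i in seq_len(nrow(rep$connectivity))) {
    p <- rep$connectivity$protein_id[i]
    mine <- br[br$da_protein == p, ]
    edge_key <- paste(mine$protein_a, mine$protein_b)
    degree <- length(unique(edge_key))
    broken <- length(unique(edge_key[mine$status == "broken"]))
    expect_equal(rep$connectivity$n_broken[i] + rep$connectivity$n_intact[i],
                 degree)
    expect_equal(rep$connectivity$n_broken[i], broken)
  }
  # histogram mirrors the connectivity table
  expect_equal(sort(rep$histogram$protein_id),
               sort(rep$connectivity$protein_id))
  expect_equal(rep$histogram$degree,
               rep$histogram$n_broken +
                 rep$connectivity$n_intact[match(rep$histogram$protein_id,
                                                 rep$connectivity$protein_id)])
  # tightening the tier filter never breaks more edges
  br_strict <- call_broken_edges(cl, sc, an, u$edges, min_tier = "ddi_reference")
  rep_strict <- connectivity_report(br_strict, u$edges)
  merged <- dplyr::left_join(rep$connectivity,
                             rep_strict$connectivity,
                             by = "protein_id", suffix = c("", "_strict"))
  expect_true(all(merged$n_broken_strict <= merged$n_broken))
})

test_that("planted binding rules are recovered on the small universe", {
  u <- small_universe()
  an <- annotate_signatures(u$ref_matches, u$motifs, u$proteome)
  rd <- unique(u$truth$rules$domain_id)
  counts <- build_score_matrix(rd, an, u$edges)
  sc <- score_pairs(counts, an, u$edges, rd, reference_pairs = u$reference_pairs)
  rec <- rule_recovery(u, sc)
  expect_gte(rec$recall, 0.8)
})
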