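TIER_LEVELS <- c("enrichment_only", "domain_motif_reference", "ddi_reference")

tier_rank <- function(tier) match(tier, TIER_LEVELS)

#' Annotate proteins with domain and motif signatures
#'
#' The signature set of a protein is the union of its matched domains (from
#' [scan_proteome()] on the reference sequences) and the linear motifs whose
#' pattern matches anywhere in its sequence.
#'
#' @param matches Domain matches from [scan_proteome()].
#' @param motifs Motif tibble from [read_motifs()] (may be zero rows).
#' @param proteome Proteome tibble.
#' @return A tibble with columns `protein_id`, `signature_id`, `kind`
#'   (`domain`/`motif`); the full protein universe is kept in attribute
#'   `proteins` (proteins may legitimately carry no signature).
#' @export
annotate_signatures <- function(matches, motifs, proteome) {
  dom <- matches |>
    dplyr::distinct(.data$protein_id, signature_id = .data$domain_id) |>
    dplyr::mutate(kind = "domain")
  mot <- if (!is.null(motifs) && nrow(motifs) > 0L) {
    hits <- purrr::map(seq_len(nrow(motifs)), function(i) {
      p <- motifs$parsed[[i]]
      hit <- vapply(proteome$sequence, function(s) pattern_present(p, s),
                    logical(1), USE.NAMES = FALSE)
      tibble::tibble(protein_id = proteome$protein_id[hit],
                     signature_id = motifs$motif_id[i], kind = "motif")
    })
    dplyr::bind_rows(hits)
  } else {
    tibble::tibble(protein_id = character(), signature_id = character(),
                   kind = character())
  }
  out <- dplyr::bind_rows(dom, mot) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$protein_id, .data$signature_id)
  attr(out, "proteins") <- proteome$protein_id
  out
}

sig_sets <- function(annotations) {
  split(annotations$signature_id, annotations$protein_id)
}

#' Build the signature-pair score matrix
#'
#' For every PPI edge (K, L) and every alterable domain `d` carried by K,
#' increments the count of (d, s) for each signature `s` on the partner L.
#' Both edge orientations are evaluated. Edges with an endpoint outside the
#' annotated protein universe are skipped and counted (attribute
#' `n_skipped`).
#'
#' @param da_domains Character vector of domain ids that can be altered by a
#'   SNP (the score-matrix rows).
#' @param annotations Signature annotation from [annotate_signatures()].
#' @param edges Undirected edge tibble from [read_ppi_edges()].
#' @return A tibble with columns `domain_id`, `signature_id`, `observed`
#'   (counts over edges), in deterministic order.
#' @export
build_score_matrix <- function(da_domains, annotations, edges) {
  proteins <- attr(annotations, "proteins")
  if (is.null(proteins)) proteins <- unique(annotations$protein_id)
  sets <- sig_sets(annotations)
  dom_sets <- sig_sets(annotations[annotations$kind == "domain", , drop = FALSE])
  counts <- list()
  n_skipped <- 0L
  bump <- function(counts, host, partner) {
    hd <- intersect(dom_sets[[host]], da_domains)
    ps <- sets[[partner]]
    if (length(hd) == 0L || length(ps) == 0L) return(counts)
    for (d in hd) {
      for (s in ps) {
        key <- paste0(d, "\r", s)
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
    counts
  }
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[i]
    b <- edges$protein_b[i]
    if (!(a %in% proteins) || !(b %in% proteins)) {
      n_skipped <- n_skipped + 1L
      next
    }
    counts <- bump(counts, a, b)
    counts <- bump(counts, b, a)
  }
  if (length(counts) == 0L) {
    out <- tibble::tibble(domain_id = character(), signature_id = character(),
                          observed = integer())
  } else {
    keys <- strsplit(names(counts), "\r", fixed = TRUE)
    out <- tibble::tibble(
      domain_id = vapply(keys, `[[`, character(1), 1L),
      signature_id = vapply(keys, `[[`, character(1), 2L),
      observed = unlist(counts, use.names = FALSE)
    ) |>
      dplyr::arrange(.data$domain_id, .data$signature_id)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score signature pairs for enrichment among binding partners
#'
#' For each pair (altered domain `d`, partner signature `s`) observed in the
#' score matrix, tests whether the distinct binding partners of d-carrying
#' proteins are enriched for carriers of `s`, against a random-partner
#' background. The default analytic background is the closed-form
#' hypergeometric over the proteome (population = all proteins, annotated =
#' carriers of `s`, sample = distinct partners of d-carriers); the empirical
#' mode resamples partner sets uniformly from the proteome (`n_background`
#' seeded draws) and reports `p = (1 + #\{null >= observed\}) / (1 +
#' n_background)`. Pairs are tagged with an evidence tier by lookup in the
#' reference pair lists: `ddi_reference` for known domain-domain pairs
#' (order-normalized), `domain_motif_reference` for known (domain, motif)
#' pairs, otherwise `enrichment_only`.
#'
#' @param counts Score matrix from [build_score_matrix()].
#' @param annotations Signature annotation from [annotate_signatures()].
#' @param edges Undirected edge tibble.
#' @param da_domains Character vector of alterable domain ids.
#' @param alpha Significance level for the `enriched` flag (default 0.05).
#' @param mode `"analytic"` (default) or `"empirical"`.
#' @param n_background Number of background resamples in empirical mode
#'   (default 1000).
#' @param seed Seed for the empirical background (required for
#'   reproducibility in empirical mode).
#' @param reference_pairs Reference pair tibble from
#'   [read_reference_pairs()]; NULL leaves every pair `enrichment_only`.
#' @param adjust_p Apply Benjamini-Hochberg across pairs and flag enrichment
#'   on the adjusted p-value (off by default).
#' @return A tibble of class `signature_pairs`: `domain_id`, `signature_id`,
#'   `signature_kind`, `observed`, `population_n`, `population_k`,
#'   `sample_n`, `sample_k`, `p_value`, (`p_adj`,) `enriched`, `tier`.
#' @export
score_pairs <- function(counts, annotations, edges, da_domains, alpha = 0.05,
                        mode = c("analytic", "empirical"), n_background = 1000L,
                        seed = NULL, reference_pairs = NULL, adjust_p = FALSE) {
  mode <- match.arg(mode)
  if (mode == "empirical" && n_background < 1L) {
    abort("`n_background` must be >= 1 in empirical mode")
  }
  proteins <- attr(annotations, "proteins")
  if (is.null(proteins)) proteins <- unique(annotations$protein_id)
  N <- length(proteins)
  sets <- sig_sets(annotations)
  dom_sets <- sig_sets(annotations[annotations$kind == "domain", , drop = FALSE])
  sig_kind <- annotations |>
    dplyr::distinct(.data$signature_id, .data$kind)
  kind_of <- stats::setNames(sig_kind$kind, sig_kind$signature_id)
  carriers_of <- split(annotations$protein_id, annotations$signature_id)

  # distinct partners of proteins carrying each alterable domain
  partner_sets <- lapply(stats::setNames(nm = unique(counts$domain_id)), function(d) {
    hosts <- names(dom_sets)[vapply(dom_sets, function(x) d %in% x, logical(1))]
    partners <- c(edges$protein_b[edges$protein_a %in% hosts],
                  edges$protein_a[edges$protein_b %in% hosts])
    intersect(unique(partners), proteins)
  })

  if (nrow(counts) == 0L) {
    out <- tibble::tibble(
      domain_id = character(), signature_id = character(),
      signature_kind = character(), observed = integer(),
      population_n = integer(), population_k = integer(),
      sample_n = integer(), sample_k = integer(), p_value = double(),
      enriched = logical(), tier = character()
    )
    class(out) <- c("signature_pairs", class(out))
    return(out)
  }

  empirical_p <- function(K_carriers, n, k) {
    null_ge <- 0L
    for (b in seq_len(n_background)) {
      draw <- sample(proteins, n, replace = FALSE)
      if (sum(draw %in% K_carriers) >= k) null_ge <- null_ge + 1L
    }
    (1 + null_ge) / (1 + n_background)
  }

  compute <- function() {
    rows <- purrr::map(seq_len(nrow(counts)), function(i) {
      d <- counts$domain_id[i]
      s <- counts$signature_id[i]
      carriers <- carriers_of[[s]]
      if (is.null(carriers) || length(carriers) == 0L) return(NULL)  # signature absent
      partners <- partner_sets[[d]]
      n <- length(partners)
      k <- sum(partners %in% carriers)
      K <- length(carriers)
      p <- if (mode == "analytic") {
        hypergeom_upper(N, K, n, k)
      } else {
        empirical_p(carriers, n, k)
      }
      tibble::tibble(
        domain_id = d, signature_id = s,
        signature_kind = unname(kind_of[s]), observed = counts$observed[i],
        population_n = N, population_k = K, sample_n = n, sample_k = k,
        p_value = p
      )
    })
    dplyr::bind_rows(rows)
  }
  out <- if (mode == "empirical") {
    if (is.null(seed)) abort("empirical mode requires `seed`")
    withr::with_seed(seed, compute())
  } else {
    compute()
  }
  if (adjust_p) {
    out$p_adj <- p.adjust(out$p_value, method = "BH")
    out$enriched <- out$p_adj <= alpha
  } else {
    out$enriched <- out$p_value <= alpha
  }
  out$tier <- pair_tier(out$domain_id, out$signature_id, out$signature_kind,
                        reference_pairs)
  out <- dplyr::arrange(out, .data$domain_id, .data$signature_id)
  class(out) <- c("signature_pairs", class(out))
  out
}

pair_tier <- function(domain_id, signature_id, signature_kind, reference_pairs) {
  tier <- rep("enrichment_only", length(domain_id))
  if (is.null(reference_pairs) || nrow(reference_pairs) == 0L) return(tier)
  dd <- reference_pairs[reference_pairs$kind == "domain_domain", , drop = FALSE]
  dm <- reference_pairs[reference_pairs$kind == "domain_motif", , drop = FALSE]
  dd_keys <- paste(dd$sig_a, dd$sig_b, sep = "\r")
  dm_keys <- paste(dm$sig_a, dm$sig_b, sep = "\r")
  is_dom <- signature_kind == "domain"
  norm_keys <- paste(pmin(domain_id, signature_id), pmax(domain_id, signature_id), sep = "\r")
  tier[is_dom & norm_keys %in% dd_keys] <- "ddi_reference"
  is_mot <- signature_kind == "motif"
  ord_keys <- paste(domain_id, signature_id, sep = "\r")
  tier[is_mot & ord_keys %in% dm_keys] <- "domain_motif_reference"
  tier
}

#' Predict broken PPI edges
#'
#' For every protein P carrying a domain-altering SNP in domain `d`, and
#' every PPI edge incident to P, the edge is called broken when the partner
#' carries at least one signature `s` such that (d, s) is enriched and its
#' evidence tier is admitted by `min_tier`; otherwise intact. One call is
#' produced per (edge, DA-protein, altered domain) triple.
#'
#' @param classification A `snp_classification` (or its call tibble); the
#'   DA (protein, domain) pairs are taken from its `da_snp` calls.
#' @param scores Scored pairs from [score_pairs()].
#' @param annotations Signature annotation from [annotate_signatures()].
#' @param edges Undirected edge tibble.
#' @param min_tier Minimum admitted evidence tier: `"enrichment_only"`
#'   (default, admits every enriched pair), `"domain_motif_reference"`, or
#'   `"ddi_reference"` (strictest, reference-supported domain-domain pairs
#'   only).
#' @return A tibble with columns `protein_a`, `protein_b`, `da_protein`,
#'   `domain_id`, `status` (`broken`/`intact`), `best_tier` (NA when
#'   intact), `matched_signatures` (comma-separated).
#' @export
call_broken_edges <- function(classification, scores, annotations, edges,
                              min_tier = "enrichment_only") {
  if (!min_tier %in% TIER_LEVELS) {
    abort(paste0("`min_tier` must be one of: ", paste(TIER_LEVELS, collapse = ", ")))
  }
  calls <- if (inherits(classification, "snp_classification")) {
    classification$calls
  } else {
    classification
  }
  da <- calls |>
    dplyr::filter(.data$status == "da_snp") |>
    dplyr::distinct(.data$protein_id, .data$domain_id)
  admitted <- scores |>
    dplyr::filter(.data$enriched, tier_rank(.data$tier) >= tier_rank(min_tier))
  sets <- sig_sets(annotations)
  out <- purrr::map(seq_len(nrow(da)), function(i) {
    p <- da$protein_id[i]
    d <- da$domain_id[i]
    inc <- edges[edges$protein_a == p | edges$protein_b == p, , drop = FALSE]
    if (nrow(inc) == 0L) return(NULL)
    ok_sigs <- admitted$signature_id[admitted$domain_id == d]
    ok_tiers <- admitted$tier[admitted$domain_id == d]
    purrr::map(seq_len(nrow(inc)), function(j) {
      partner <- if (inc$protein_a[j] == p) inc$protein_b[j] else inc$protein_a[j]
      matched <- intersect(sets[[partner]] %||% character(), ok_sigs)
      broken <- length(matched) > 0L
      best <- if (broken) {
        TIER_LEVELS[max(tier_rank(ok_tiers[ok_sigs %in% matched]))]
      } else {
        NA_character_
      }
      tibble::tibble(
        protein_a = inc$protein_a[j], protein_b = inc$protein_b[j],
        da_protein = p, domain_id = d,
        status = if (broken) "broken" else "intact",
        best_tier = best,
        matched_signatures = paste(sort(matched), collapse = ",")
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(out))
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      protein_a = character(), protein_b = character(), da_protein = character(),
      domain_id = character(), status = character(), best_tier = character(),
      matched_signatures = character()
    ))
  }
  dplyr::arrange(out, .data$da_protein, .data$protein_a, .data$protein_b,
                 .data$domain_id)
}

#' Per-protein connectivity report
#'
#' Summarises broken-edge calls per DA-protein: an edge counts as broken
#' once, even when several altered domains of the protein break it.
#' `n_broken + n_intact` equals the protein's evaluated degree. Also returns
#' the per-protein (degree, n_broken) histogram table.
#'
#' @param broken_calls Calls from [call_broken_edges()].
#' @param edges Undirected edge tibble (used for degrees).
#' @param proteome Optional proteome tibble to attach gene symbols.
#' @param top Optional: keep only the `top` proteins by `n_broken`.
#' @return A list with `connectivity` (tibble `protein_id`, `gene_symbol`,
#'   `n_broken`, `n_intact`, sorted by `n_broken` descending) and
#'   `histogram` (tibble `protein_id`, `degree`, `n_broken`).
#' @export
connectivity_report <- function(broken_calls, edges, proteome = NULL, top = NULL) {
  per_edge <- broken_calls |>
    dplyr::group_by(.data$da_protein, .data$protein_a, .data$protein_b) |>
    dplyr::summarise(broken = any(.data$status == "broken"), .groups = "drop")
  conn <- per_edge |>
    dplyr::group_by(protein_id = .data$da_protein) |>
    dplyr::summarise(
      n_broken = sum(.data$broken),
      n_intact = sum(!.data$broken),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_broken), .data$protein_id)
  gene <- if (!is.null(proteome)) {
    stats::setNames(proteome$gene_symbol, proteome$protein_id)
  } else {
    NULL
  }
  conn$gene_symbol <- if (is.null(gene)) "" else unname(gene[conn$protein_id])
  conn <- conn[, c("protein_id", "gene_symbol", "n_broken", "n_intact")]
  hist <- conn |>
    dplyr::transmute(.data$protein_id, degree = .data$n_broken + .data$n_intact,
                     .data$n_broken) |>
    dplyr::arrange(.data$protein_id)
  if (!is.null(top)) conn <- head(conn, top)
  list(connectivity = conn, histogram = hist)
}
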