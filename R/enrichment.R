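#' Hypergeometric upper-tail probability
#'
#' Exact P(X >= k) where X is the number of annotated items in a sample of
#' size `n` drawn without replacement from a population of `N` items of
#' which `K` are annotated. Evaluated in log space (via the log-scale
#' cumulative hypergeometric) so that extreme enrichments do not underflow
#' prematurely.
#'
#' @param N Population size.
#' @param K Annotated items in the population.
#' @param n Sample size.
#' @param k Annotated items in the sample.
#' @return The upper-tail p-value in (0, 1].
#' @export
#' @examples
#' hypergeom_upper(10, 5, 5, 5) # 1/252
hypergeom_upper <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > n || k > K) {
    abort(paste0("invalid contingency: N=", N, " K=", K, " n=", n, " k=", k))
  }
  if (k == 0) return(1.0)
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Enrichment of an annotated set within a sample
#'
#' Builds the contingency for a sample drawn from a population and tests
#' over-representation of annotated ids by [hypergeom_upper()].
#'
#' @param sample_ids Character vector, a subset of `population_ids`.
#' @param annotated_ids Character vector of annotated ids.
#' @param population_ids Character vector, the population.
#' @return A one-row tibble: `population_n` (N), `population_k` (K),
#'   `sample_n` (n), `sample_k` (k), `p_value`.
#' @export
enrich_class <- function(sample_ids, annotated_ids, population_ids) {
  sample_ids <- unique(sample_ids)
  annotated_ids <- unique(annotated_ids)
  population_ids <- unique(population_ids)
  if (!all(sample_ids %in% population_ids)) {
    abort("`sample_ids` must be a subset of `population_ids`")
  }
  N <- length(population_ids)
  K <- length(intersect(population_ids, annotated_ids))
  n <- length(sample_ids)
  k <- length(intersect(sample_ids, annotated_ids))
  tibble::tibble(
    population_n = N, population_k = K, sample_n = n, sample_k = k,
    p_value = hypergeom_upper(N, K, n, k)
  )
}

disease_snp_ids <- function(disease, snps, level = c("snp", "protein")) {
  level <- match.arg(level)
  if (level == "snp") {
    snps$snp_id[snps$snp_id %in% disease$id[disease$id_type == "snp"]]
  } else {
    snps$snp_id[snps$protein_id %in% disease$id[disease$id_type == "protein"]]
  }
}

#' DD-cutoff enrichment sweep
#'
#' For each DD cutoff, takes the domain-altering SNPs at that cutoff as the
#' sample, all domain SNPs (D-SNPs) as the population, and tests enrichment
#' of disease-annotated SNPs by the hypergeometric upper tail. Pattern-loss
#' and domain-erasure SNPs are domain-altering at every cutoff; profile
#' SNPs enter when their maximal DD reaches the cutoff.
#'
#' @param classification A `snp_classification` from [classify_all()] (or
#'   its call tibble).
#' @param disease Disease-annotation tibble from [read_disease_annotations()].
#' @param cutoffs Numeric vector of DD cutoffs; default
#'   `c(0.05, 0.10, 0.15, 0.20)`.
#' @param snps The validated SNP tibble (needed to resolve protein-level
#'   annotation; may be omitted for `level = "snp"` if `classification` is a
#'   `snp_classification`).
#' @param level Match disease annotations at the `snp` (default) or
#'   `protein` level.
#' @param adjust_p Also report Benjamini-Hochberg adjusted p-values across
#'   the sweep rows (off by default; the sweep is reported unadjusted).
#' @return A tibble of class `dd_sweep` with columns `dd_cutoff`,
#'   `n_da_snp`, `n_da_snp_diseased`, `p_value` (plus `p_adj` when
#'   requested), ordered by cutoff, with the population contingency in
#'   attributes `population_n` and `population_k`.
#' @export
dd_sweep <- function(classification, disease, cutoffs = c(0.05, 0.10, 0.15, 0.20),
                     snps = NULL, level = c("snp", "protein"), adjust_p = FALSE) {
  level <- match.arg(level)
  if (length(cutoffs) == 0L) abort("`cutoffs` must be non-empty")
  calls <- if (inherits(classification, "snp_classification")) {
    classification$calls
  } else {
    classification
  }
  base <- snp_status(calls, dd_cutoff = 1)  # cutoff value irrelevant for D-SNP set
  d_set <- base[base$status != "outside", , drop = FALSE]
  if (is.null(snps)) snps <- tibble::tibble(snp_id = base$snp_id, protein_id = base$protein_id)
  ann <- disease_snp_ids(disease, snps, level)
  N <- nrow(d_set)
  K <- length(intersect(d_set$snp_id, ann))
  rows <- purrr::map(sort(cutoffs), function(co) {
    st <- snp_status(calls, dd_cutoff = co)
    da <- st$snp_id[st$status == "da_snp"]
    k <- length(intersect(da, ann))
    tibble::tibble(
      dd_cutoff = co, n_da_snp = length(da), n_da_snp_diseased = k,
      p_value = hypergeom_upper(N, K, length(da), k)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (adjust_p) out$p_adj <- p.adjust(out$p_value, method = "BH")
  attr(out, "population_n") <- N
  attr(out, "population_k") <- K
  class(out) <- c("dd_sweep", class(out))
  out
}

#' Write a DD sweep table
#' @param sweep A `dd_sweep` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  readr::write_tsv(tibble::as_tibble(sweep), path)
  invisible(path)
}

#' Generic term enrichment with BH correction
#'
#' Hypergeometric over-representation of a gene set in annotation terms
#' (Gene Ontology-style categories, pathway memberships, or any user-supplied
#' term-to-gene mapping), with Benjamini-Hochberg q-values computed by the
#' step-up procedure across all tested terms.
#'
#' @param gene_set Character vector of genes of interest (subset of
#'   `universe`).
#' @param term_genes Either a named list of character vectors (term ->
#'   genes) or a two-column tibble/data frame `term`, `gene`.
#' @param universe Character vector: the gene population.
#' @param p_cutoff Report only terms with raw p-value <= this cutoff
#'   (default 0.01; use 1 to keep every term). q-values are computed across
#'   all tested terms before filtering.
#' @return A tibble with columns `term`, `population_n`, `population_k`,
#'   `sample_n`, `sample_k`, `p_value`, `q_value`, sorted by `p_value`.
#' @export
term_enrichment <- function(gene_set, term_genes, universe, p_cutoff = 0.01) {
  universe <- unique(universe)
  if (length(universe) == 0L) abort("`universe` must be non-empty")
  if (is.data.frame(term_genes)) {
    term_genes <- split(term_genes$gene, term_genes$term)
  }
  if (length(term_genes) == 0L) abort("`term_genes` must be non-empty")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe)) {
    abort("`gene_set` must be a subset of `universe`")
  }
  rows <- purrr::imap(term_genes, function(genes, term) {
    tg <- intersect(unique(genes), universe)
    if (length(tg) == 0L) return(NULL)
    N <- length(universe)
    K <- length(tg)
    n <- length(gene_set)
    k <- length(intersect(gene_set, tg))
    tibble::tibble(term = term, population_n = N, population_k = K,
                   sample_n = n, sample_k = k,
                   p_value = hypergeom_upper(N, K, n, k))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(term = character(), population_n = integer(),
                          population_k = integer(), sample_n = integer(),
                          sample_k = integer(), p_value = double(),
                          q_value = double()))
  }
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out |>
    dplyr::filter(.data$p_value <= p_cutoff) |>
    dplyr::arrange(.data$p_value, .data$term)
}
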