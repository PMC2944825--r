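#' Pipeline configuration
#'
#' Collects input paths and analysis parameters for [run_pipeline()].
#'
#' @param proteome,snps,edges,disease,pairs,motifs,domains Paths to the
#'   input files ([write_universe()] produces a directory with all of them;
#'   see the reader functions for each format). `motifs` and `pairs` may be
#'   NULL.
#' @param dd_cutoffs DD cutoffs for the enrichment sweep (default
#'   `c(0.05, 0.10, 0.15, 0.20)`).
#' @param dd_cutoff Working DD cutoff for classification and the network
#'   stage (default 0.10).
#' @param alpha Significance level for signature-pair enrichment (0.05).
#' @param min_tier Minimum evidence tier for breaking an edge (default
#'   `"enrichment_only"`).
#' @param background `"analytic"` or `"empirical"` signature-pair background.
#' @param n_background Resamples for the empirical background (1000).
#' @param seed Seed used by the empirical background.
#' @param disease_level Match disease ids at `"snp"` (default) or
#'   `"protein"` level.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(proteome, snps, edges, disease, domains,
                            pairs = NULL, motifs = NULL,
                            dd_cutoffs = c(0.05, 0.10, 0.15, 0.20),
                            dd_cutoff = 0.10, alpha = 0.05,
                            min_tier = "enrichment_only",
                            background = c("analytic", "empirical"),
                            n_background = 1000L, seed = 1L,
                            disease_level = c("snp", "protein")) {
  structure(list(
    proteome = proteome, snps = snps, edges = edges, disease = disease,
    domains = domains, pairs = pairs, motifs = motifs,
    dd_cutoffs = dd_cutoffs, dd_cutoff = dd_cutoff, alpha = alpha,
    min_tier = min_tier, background = match.arg(background),
    n_background = as.integer(n_background), seed = as.integer(seed),
    disease_level = match.arg(disease_level)
  ), class = "pipeline_config")
}

#' Pipeline configuration for a [write_universe()] directory
#'
#' @param dir Directory written by [write_universe()].
#' @param ... Further arguments passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
pipeline_config_for_dir <- function(dir, ...) {
  pipeline_config(
    proteome = file.path(dir, "proteome.fasta"),
    snps = file.path(dir, "snps.tsv"),
    edges = file.path(dir, "edges.tsv"),
    disease = file.path(dir, "disease.tsv"),
    domains = file.path(dir, "domains.txt"),
    pairs = file.path(dir, "pairs.tsv"),
    motifs = file.path(dir, "motifs.tsv"),
    ...
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys are the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Executes scan, classify, sweep, signature annotation, pair scoring,
#' broken-edge prediction and connectivity reporting in order, writing every
#' stage table plus a run log into `out_dir`. A rerun with the same config
#' and seed produces byte-identical outputs. A stage failure halts with a
#' stage-named error and leaves a `FAILED` marker next to the partial
#' outputs.
#'
#' @param config A `pipeline_config` (or path to a YAML config, see
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results
#'   (`classification`, `sweep`, `annotations`, `pair_scores`,
#'   `broken`, `connectivity`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("domainsnp version: ", as.character(utils::packageVersion("domainsnp"))),
    paste0("seed: ", config$seed)
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  required <- c("proteome", "snps", "edges", "disease", "domains")
  for (f in required) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      abort(paste0("missing input file for '", f, "': ",
                   config[[f]] %||% "<unset>"))
    }
  }

  inputs <- stage("load", {
    proteome <- read_proteome(config$proteome)
    snps <- suppressWarnings(read_snps(config$snps, proteome))
    edges <- read_ppi_edges(config$edges)
    disease <- suppressWarnings(read_disease_annotations(config$disease, snps, proteome))
    domains <- read_domains(config$domains)
    motifs <- if (!is.null(config$motifs) && file.exists(config$motifs)) {
      read_motifs(config$motifs)
    } else {
      NULL
    }
    pairs <- if (!is.null(config$pairs) && file.exists(config$pairs)) {
      read_reference_pairs(config$pairs)
    } else {
      NULL
    }
    list(proteome = proteome, snps = snps, edges = edges, disease = disease,
         domains = domains, motifs = motifs, pairs = pairs)
  })
  log_lines <- c(log_lines,
                 paste0("proteins: ", nrow(inputs$proteome)),
                 paste0("snps: ", nrow(inputs$snps)),
                 paste0("edges: ", nrow(inputs$edges)))

  classification <- stage("classify", {
    cl <- classify_all(inputs$snps, inputs$proteome, inputs$domains,
                       dd_cutoff = config$dd_cutoff)
    write_matches(cl$ref_matches, file.path(out_dir, "matches.tsv"))
    write_calls(cl, file.path(out_dir, "calls.tsv"))
    readr::write_tsv(cl$summary, file.path(out_dir, "summary.tsv"))
    cl
  })
  log_lines <- c(log_lines,
                 paste0("domain matches: ", nrow(classification$ref_matches)),
                 paste0("d_snps: ", classification$summary$n_d_snp),
                 paste0("da_snps: ", classification$summary$n_da_snp))

  sweep <- stage("sweep", {
    sw <- dd_sweep(classification, inputs$disease, cutoffs = config$dd_cutoffs,
                   snps = inputs$snps, level = config$disease_level)
    write_sweep(sw, file.path(out_dir, "sweep.tsv"))
    sw
  })

  annotations <- stage("annotate_signatures", {
    an <- annotate_signatures(classification$ref_matches, inputs$motifs,
                              inputs$proteome)
    readr::write_tsv(an, file.path(out_dir, "signatures.tsv"))
    an
  })

  pair_scores <- stage("score_pairs", {
    da_domains <- unique(classification$calls$domain_id[
      classification$calls$status == "da_snp"])
    counts <- build_score_matrix(da_domains, annotations, inputs$edges)
    sc <- score_pairs(counts, annotations, inputs$edges, da_domains,
                      alpha = config$alpha, mode = config$background,
                      n_background = config$n_background, seed = config$seed,
                      reference_pairs = inputs$pairs)
    readr::write_tsv(tibble::as_tibble(sc), file.path(out_dir, "pairs_scored.tsv"))
    sc
  })
  log_lines <- c(log_lines,
                 paste0("signature pairs tested: ", nrow(pair_scores)),
                 paste0("signature pairs enriched: ", sum(pair_scores$enriched)))

  broken <- stage("broken_edges", {
    br <- call_broken_edges(classification, pair_scores, annotations,
                            inputs$edges, min_tier = config$min_tier)
    readr::write_tsv(br, file.path(out_dir, "broken.tsv"))
    br
  })

  connectivity <- stage("connectivity", {
    cr <- connectivity_report(broken, inputs$edges, proteome = inputs$proteome)
    readr::write_tsv(cr$connectivity, file.path(out_dir, "connectivity.tsv"))
    readr::write_tsv(cr$histogram, file.path(out_dir, "histogram.tsv"))
    cr
  })
  log_lines <- c(log_lines,
                 paste0("edges broken: ", sum(broken$status == "broken")),
                 paste0("da proteins reported: ", nrow(connectivity$connectivity)))

  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(classification = classification, sweep = sweep,
                 annotations = annotations, pair_scores = pair_scores,
                 broken = broken, connectivity = connectivity))
}
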