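#' Plot a DD-cutoff enrichment sweep
#'
#' Shows the number of domain-altering SNPs and the hypergeometric
#' enrichment p-value at each DD cutoff.
#'
#' @param object A `dd_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dd_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("n_da_snp", "p_value"), names_to = "panel",
                        values_to = "value") |>
    dplyr::mutate(panel = dplyr::recode(.data$panel,
                                        n_da_snp = "domain-altering SNPs",
                                        p_value = "enrichment p-value"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dd_cutoff, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::geom_hline(
      data = tibble::tibble(panel = "enrichment p-value", y = 0.05),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed"
    ) +
    ggplot2::labs(x = "DD cutoff", y = NULL,
                  title = "Disease enrichment across DD cutoffs")
}

#' Plot scored signature pairs
#'
#' Observed partner-carrier counts against enrichment significance, coloured
#' by evidence tier.
#'
#' @param object A `signature_pairs` tibble from [score_pairs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signature_pairs <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_k,
                                   y = -log10(.data$p_value),
                                   colour = .data$tier,
                                   shape = .data$enriched)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = "partners carrying the signature",
                  y = expression(-log[10](p)),
                  title = "Signature-pair enrichment across PPI edges")
}

#' Plot per-protein broken/intact connectivity
#'
#' Stacked per-protein counts of predicted broken and surviving PPI edges
#' for proteins carrying a domain-altering SNP.
#'
#' @param report The result of [connectivity_report()] (or its
#'   `connectivity` tibble).
#' @param top Show only the `top` proteins by broken-edge count (default 10,
#'   mirroring a top-ten most-connected table).
#' @return A ggplot object.
#' @export
plot_connectivity <- function(report, top = 10L) {
  conn <- if (is.list(report) && !is.data.frame(report)) report$connectivity else report
  conn <- head(conn, top)
  label <- ifelse(nzchar(conn$gene_symbol), conn$gene_symbol, conn$protein_id)
  df <- tibble::tibble(
    protein = factor(rep(label, 2), levels = rev(label)),
    status = rep(c("broken", "intact"), each = nrow(conn)),
    n = c(conn$n_broken, conn$n_intact)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$protein, y = .data$n,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "PPI edges",
                  title = "Edges broken by domain-altering SNPs")
}

#' @rdname classify_all
#' @param object A `snp_classification`.
#' @export
autoplot.snp_classification <- function(object, ...) {
  df <- object$snp_status |>
    dplyr::count(.data$status)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "SNPs",
                  title = paste0("SNP impact classes (DD cutoff ",
                                 object$dd_cutoff, ")"))
}

#' @rdname dd_sweep
#' @param x A `dd_sweep`.
#' @param ... Unused.
#' @export
tidy.dd_sweep <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "dd_sweep")
  out
}

#' @rdname dd_sweep
#' @export
glance.dd_sweep <- function(x, ...) {
  tibble::tibble(
    population_n = attr(x, "population_n"),
    population_k = attr(x, "population_k"),
    n_cutoffs = nrow(x),
    min_p = min(x$p_value)
  )
}

#' @rdname score_pairs
#' @param x A `signature_pairs`.
#' @param ... Unused.
#' @export
tidy.signature_pairs <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "signature_pairs")
  out
}

#' @rdname score_pairs
#' @export
glance.signature_pairs <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_enriched = sum(x$enriched),
    n_reference_supported = sum(x$tier != "enrichment_only")
  )
}
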