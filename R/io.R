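#' @title Readers and writers for the pipeline's on-disk formats
#'
#' @description
#' All tabular files are tab-separated with a header row, UTF-8, and may
#' contain `#` comment lines. Protein coordinates are 1-based with spans
#' inclusive on both ends. Each reader validates its input and returns a
#' tibble; rejected records are collected in a load report attached to the
#' result (see [load_report()]).
#'
#' @name io_formats
NULL

read_tsv_checked <- function(path, required, col_types) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  x <- readr::read_tsv(path, comment = "#", col_types = col_types,
                       progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    abort(paste0("file ", path, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x
}

set_load_report <- function(x, report) {
  attr(x, "load_report") <- report
  x
}

#' Retrieve the load report of a reader result
#'
#' @param x A tibble returned by [read_snps()] or [read_disease_annotations()].
#' @return A tibble describing dropped/rejected records (`reason`, `n`),
#'   or a zero-row tibble when everything loaded cleanly.
#' @export
load_report <- function(x) {
  rep <- attr(x, "load_report")
  if (is.null(rep)) tibble::tibble(reason = character(), n = integer()) else rep
}

#' Read a proteome from a FASTA file
#'
#' The record identifier is the first whitespace-delimited token of the
#' header; a gene symbol is parsed from a `GN=` tag when present. Sequences
#' are validated against the 20 standard amino-acid letters; lower-case
#' input, gaps or ambiguity codes are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id`, `gene_symbol`, `sequence`.
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  seqs <- as.character(ss)
  if (length(seqs) == 0L) abort(paste0("no FASTA records in ", path))
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  gene <- stringr::str_match(headers, "GN=(\\S+)")[, 2]
  gene[is.na(gene)] <- ""
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) {
      abort(paste0("empty sequence for record '", ids[i], "' in ", path))
    }
    bad <- regmatches(seqs[i], regexpr(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs[i]))
    if (length(bad) > 0L) {
      abort(paste0("illegal residue '", bad, "' in record '", ids[i],
                   "' (entry ", i, ") of ", path))
    }
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated protein_id in ", path, ": ",
                 ids[duplicated(ids)][1]))
  }
  tibble::tibble(protein_id = ids, gene_symbol = gene, sequence = unname(seqs))
}

#' Write a proteome to FASTA
#'
#' @param proteome A tibble as returned by [read_proteome()].
#' @param path Output path.
#' @param width Line-folding width.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path, width = 60L) {
  lines <- purrr::pmap(proteome, function(protein_id, gene_symbol, sequence, ...) {
    header <- paste0(">", protein_id,
                     if (nzchar(gene_symbol)) paste0(" GN=", gene_symbol) else "")
    starts <- seq(1L, nchar(sequence), by = width)
    c(header, substring(sequence, starts, pmin(starts + width - 1L, nchar(sequence))))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read missense SNPs in protein coordinates
#'
#' Loads a TSV with columns `snp_id`, `protein_id`, `position`, `ref_aa`,
#' `alt_aa` and validates every record against the proteome: records
#' referencing unknown proteins are dropped and counted; records whose
#' `ref_aa` disagrees with the sequence, whose position is out of range, or
#' whose alleles are not two distinct standard residues are rejected with a
#' reason. The load report is attached to the result (see [load_report()]).
#'
#' @param path Path to the SNP TSV.
#' @param proteome Proteome tibble from [read_proteome()].
#' @return A tibble of validated SNP records.
#' @export
read_snps <- function(path, proteome) {
  x <- read_tsv_checked(
    path,
    required = c("snp_id", "protein_id", "position", "ref_aa", "alt_aa"),
    col_types = readr::cols(
      snp_id = readr::col_character(),
      protein_id = readr::col_character(),
      position = readr::col_integer(),
      ref_aa = readr::col_character(),
      alt_aa = readr::col_character()
    )
  )
  validate_snps(x, proteome)
}

validate_snps <- function(x, proteome) {
  seq_of <- stats::setNames(proteome$sequence, proteome$protein_id)
  reason <- rep(NA_character_, nrow(x))
  known <- x$protein_id %in% names(seq_of)
  reason[!known] <- "unknown protein"
  ok <- known
  bad_allele <- ok & (!x$ref_aa %in% AA_ALPHABET | !x$alt_aa %in% AA_ALPHABET)
  reason[bad_allele] <- "illegal residue letter"
  ok <- ok & !bad_allele
  same <- ok & x$ref_aa == x$alt_aa
  reason[same] <- "ref_aa equals alt_aa"
  ok <- ok & !same
  len <- ifelse(known, nchar(seq_of[x$protein_id]), NA_integer_)
  out_of_range <- ok & (x$position < 1L | x$position > len)
  reason[out_of_range] <- "position out of range"
  ok <- ok & !out_of_range
  mism <- ok & substr(seq_of[x$protein_id], x$position, x$position) != x$ref_aa
  reason[mism] <- "reference mismatch"
  ok <- ok & !mism

  if (any(!ok)) {
    warn(paste0(sum(!ok), " SNP record(s) dropped (",
                paste(unique(reason[!ok]), collapse = "; "), ")"))
  }
  report <- tibble::tibble(reason = reason[!ok]) |>
    dplyr::count(.data$reason, name = "n") |>
    dplyr::arrange(.data$reason)
  set_load_report(x[ok, , drop = FALSE], report)
}

#' Write SNP records
#' @param snps SNP tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snps <- function(snps, path) {
  readr::write_tsv(snps[, c("snp_id", "protein_id", "position", "ref_aa", "alt_aa")], path)
  invisible(path)
}

#' Read an undirected PPI edge list
#'
#' Edges are undirected: endpoint order is normalized (lexicographically) and
#' duplicates are merged silently. Self-loops are dropped with a warning.
#'
#' @param path Path to a TSV with columns `protein_a`, `protein_b`.
#' @return A tibble of unique undirected edges with `protein_a < protein_b`.
#' @export
read_ppi_edges <- function(path) {
  x <- read_tsv_checked(path, required = c("protein_a", "protein_b"),
                        col_types = readr::cols(.default = readr::col_character()))
  normalize_edges(x)
}

normalize_edges <- function(x) {
  self <- x$protein_a == x$protein_b
  if (any(self)) warn(paste0(sum(self), " self-loop edge(s) dropped"))
  x <- x[!self, , drop = FALSE]
  tibble::tibble(
    protein_a = pmin(x$protein_a, x$protein_b),
    protein_b = pmax(x$protein_a, x$protein_b)
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Write a PPI edge list
#' @param edges Edge tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi_edges <- function(edges, path) {
  readr::write_tsv(edges[, c("protein_a", "protein_b")], path)
  invisible(path)
}

#' Read disease annotations
#'
#' Loads a TSV with columns `id_type` (`snp` or `protein`), `id`, `disorder`.
#' When a SNP table and/or proteome is supplied, annotations whose id is not
#' in the loaded universe are flagged as orphans and counted in the load
#' report (with a warning) but retained, so partial universes stay usable.
#'
#' @param path Path to the annotation TSV.
#' @param snps Optional SNP tibble defining the SNP-id universe.
#' @param proteome Optional proteome tibble defining the protein-id universe.
#' @return A tibble with columns `id_type`, `id`, `disorder`, `orphan`.
#' @export
read_disease_annotations <- function(path, snps = NULL, proteome = NULL) {
  x <- read_tsv_checked(path, required = c("id_type", "id", "disorder"),
                        col_types = readr::cols(.default = readr::col_character()))
  bad <- !x$id_type %in% c("snp", "protein")
  if (any(bad)) abort(paste0("invalid id_type '", x$id_type[bad][1], "' in ", path))
  x <- dplyr::distinct(x)
  orphan <- rep(FALSE, nrow(x))
  if (!is.null(snps)) {
    orphan <- orphan | (x$id_type == "snp" & !x$id %in% snps$snp_id)
  }
  if (!is.null(proteome)) {
    orphan <- orphan | (x$id_type == "protein" & !x$id %in% proteome$protein_id)
  }
  x$orphan <- orphan
  if (any(orphan)) {
    warn(paste0(sum(orphan), " orphan annotation(s): ids absent from the loaded universe"))
  }
  report <- if (any(orphan)) {
    tibble::tibble(reason = "orphan annotation", n = sum(orphan))
  } else {
    tibble::tibble(reason = character(), n = integer())
  }
  set_load_report(x, report)
}

#' Write disease annotations
#' @param ann Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disease_annotations <- function(ann, path) {
  readr::write_tsv(ann[, c("id_type", "id", "disorder")], path)
  invisible(path)
}

#' Read a reference signature-pair list
#'
#' Loads known domain-domain and domain-motif interaction pairs. Pairs of
#' kind `domain_domain` are unordered and get order-normalized; pairs of kind
#' `domain_motif` are ordered `(domain, motif)`. Duplicates merge silently.
#'
#' @param path Path to a TSV with columns `kind`, `sig_a`, `sig_b`.
#' @return A tibble with columns `kind`, `sig_a`, `sig_b`.
#' @export
read_reference_pairs <- function(path) {
  x <- read_tsv_checked(path, required = c("kind", "sig_a", "sig_b"),
                        col_types = readr::cols(.default = readr::col_character()))
  bad <- !x$kind %in% c("domain_domain", "domain_motif")
  if (any(bad)) abort(paste0("invalid pair kind '", x$kind[bad][1], "' in ", path))
  normalize_pairs(x)
}

normalize_pairs <- function(x) {
  dd <- x$kind == "domain_domain"
  tibble::tibble(
    kind = x$kind,
    sig_a = ifelse(dd, pmin(x$sig_a, x$sig_b), x$sig_a),
    sig_b = ifelse(dd, pmax(x$sig_a, x$sig_b), x$sig_b)
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$kind, .data$sig_a, .data$sig_b)
}

#' Write a reference signature-pair list
#' @param pairs Pair tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_pairs <- function(pairs, path) {
  readr::write_tsv(pairs[, c("kind", "sig_a", "sig_b")], path)
  invisible(path)
}

#' Read linear-motif definitions
#'
#' Loads named sequence motifs (short signatures in the same pattern dialect
#' as domain patterns, see [parse_pattern()]); every pattern is parsed at
#' load time so syntax errors surface immediately.
#'
#' @param path Path to a TSV with columns `motif_id`, `pattern`.
#' @return A tibble with columns `motif_id`, `pattern`, and a list column
#'   `parsed` of `pattern_def` objects.
#' @export
read_motifs <- function(path) {
  x <- read_tsv_checked(path, required = c("motif_id", "pattern"),
                        col_types = readr::cols(.default = readr::col_character()))
  if (anyDuplicated(x$motif_id)) abort(paste0("duplicated motif_id in ", path))
  x$parsed <- purrr::map2(x$pattern, x$motif_id, ~ parse_pattern(.x, domain_id = .y))
  x
}

#' Write motif definitions
#' @param motifs Motif tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path) {
  readr::write_tsv(motifs[, c("motif_id", "pattern")], path)
  invisible(path)
}
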