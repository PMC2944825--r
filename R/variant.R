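#' Apply a missense SNP to a protein sequence
#'
#' @param s A protein sequence string.
#' @param position 1-based residue position.
#' @param alt_aa Replacement residue (single standard letter).
#' @return The mutated sequence (same length).
#' @export
#' @examples
#' apply_snp("MKTV", 2, "R")
apply_snp <- function(s, position, alt_aa) {
  if (position < 1L || position > nchar(s)) {
    abort(paste0("SNP position ", position, " outside sequence of length ", nchar(s)))
  }
  if (!alt_aa %in% AA_ALPHABET) abort(paste0("illegal residue '", alt_aa, "'"))
  paste0(substr(s, 1L, position - 1L), alt_aa, substr(s, position + 1L, nchar(s)))
}

#' Domain distortion
#'
#' DD = (MS_ref - MS_alt) / MS_ref: the relative drop in a profile's
#' matching score caused by a SNP, clamped below at 0 (a score-improving
#' substitution does not distort the domain).
#'
#' @param ms_ref Matching score of the reference (SNP-free) sequence; must
#'   be > 0 for DD to be defined.
#' @param ms_alt Matching score of the mutated sequence.
#' @return DD in \[0, 1\] (can exceed 1 only if MS_alt < -MS_ref; values are
#'   not clamped above).
#' @export
#' @examples
#' domain_distortion(100, 85) # 0.15
domain_distortion <- function(ms_ref, ms_alt) {
  if (!is.finite(ms_ref) || ms_ref <= 0) {
    abort("DD is undefined for ms_ref <= 0", class = "domainsnp_dd_undefined")
  }
  max(0, (ms_ref - ms_alt) / ms_ref)
}

empty_calls <- function() {
  tibble::tibble(
    snp_id = character(), protein_id = character(), domain_id = character(),
    status = character(), mechanism = character(), dd = double(),
    ms_ref = double(), ms_alt = double(), erased = logical()
  )
}

#' Classify one SNP against the reference domain matches of its protein
#'
#' Every reference match whose span contains the SNP position yields one
#' call (baseline: D-SNP). For pattern domains the mutated sequence is
#' rescanned: if no surviving match of that pattern overlaps the SNP
#' position the domain is lost (`da_snp` / `pattern_loss`). For profile
#' domains the mutated sequence is rescored; the call is `da_snp` /
#' `profile_distortion` when DD reaches the cutoff (inclusive) or when the
#' mutated score falls below the profile's presence cutoff (the domain is
#' erased outright, which forces `da_snp` regardless of DD). A SNP inside no
#' match yields one `outside` call.
#'
#' @param snp A one-row tibble (or list) with `snp_id`, `protein_id`,
#'   `position`, `ref_aa`, `alt_aa`.
#' @param sequence Reference sequence of the SNP's protein.
#' @param ref_matches [scan_proteome()] rows for this protein.
#' @param domains The `domain_set` used for scanning.
#' @param dd_cutoff DD threshold in (0, 1] for calling a profile-domain SNP
#'   domain-altering; default 0.10.
#' @return A tibble of calls with columns `snp_id`, `protein_id`,
#'   `domain_id`, `status`, `mechanism`, `dd`, `ms_ref`, `ms_alt`, `erased`.
#' @export
classify_snp <- function(snp, sequence, ref_matches, domains, dd_cutoff = 0.10) {
  stopifnot(dd_cutoff > 0, dd_cutoff <= 1)
  pos <- snp$position
  if (substr(sequence, pos, pos) != snp$ref_aa) {
    abort(paste0("SNP ", snp$snp_id, ": ref_aa does not match the sequence"))
  }
  keep <- ref_matches$start <= pos & ref_matches$end >= pos
  containing <- ref_matches[keep, , drop = FALSE]
  nc <- nrow(containing)
  if (nc == 0L) {
    return(fast_tibble(
      snp_id = snp$snp_id, protein_id = snp$protein_id, domain_id = NA_character_,
      status = "outside", mechanism = "none", dd = NA_real_,
      ms_ref = NA_real_, ms_alt = NA_real_, erased = NA
    ))
  }
  # the same profile domain can only appear once per protein, but a pattern
  # may contain the position in several spans: one call per domain suffices
  containing <- containing[!duplicated(containing$domain_id), , drop = FALSE]
  nc <- nrow(containing)
  mutated <- apply_snp(sequence, pos, snp$alt_aa)
  status <- mechanism <- character(nc)
  dd <- ms_ref_v <- ms_alt_v <- rep(NA_real_, nc)
  erased <- rep(NA, nc)
  for (i in seq_len(nc)) {
    dom <- domains[[containing$domain_id[i]]]
    if (inherits(dom, "pattern_def")) {
      alt_hits <- scan_pattern(dom, mutated)
      survives <- nrow(alt_hits) > 0L && any(alt_hits$start <= pos & alt_hits$end >= pos)
      status[i] <- if (survives) "d_snp" else "da_snp"
      mechanism[i] <- if (survives) "none" else "pattern_loss"
    } else {
      ms_ref <- containing$matching_score[i]
      ms_alt <- profile_score(dom, mutated)$score
      dd[i] <- domain_distortion(ms_ref, ms_alt)
      erased[i] <- ms_alt < dom$cutoff
      da <- dd[i] >= dd_cutoff || erased[i]
      status[i] <- if (da) "da_snp" else "d_snp"
      mechanism[i] <- if (da) "profile_distortion" else "none"
      ms_ref_v[i] <- ms_ref
      ms_alt_v[i] <- ms_alt
    }
  }
  fast_tibble(
    snp_id = rep(snp$snp_id, nc), protein_id = rep(snp$protein_id, nc),
    domain_id = containing$domain_id, status = status, mechanism = mechanism,
    dd = dd, ms_ref = ms_ref_v, ms_alt = ms_alt_v, erased = erased
  )
}

#' Classify every SNP in a universe
#'
#' Scans the proteome once, then classifies each SNP against the reference
#' matches of its protein (see [classify_snp()]). The result is a pure
#' function of its inputs: repeated runs are identical.
#'
#' @param snps Validated SNP tibble from [read_snps()].
#' @param proteome Proteome tibble.
#' @param domains A `domain_set`.
#' @param dd_cutoff Working DD cutoff, default 0.10.
#' @param ref_matches Optional precomputed [scan_proteome()] result (skips
#'   the reference scan).
#' @return An object of class `snp_classification`: a list with `calls`
#'   (per-SNP, per-domain call tibble ordered by `snp_id`), `snp_status`
#'   (per-SNP rollup at the working cutoff), `summary` (one-row count
#'   tibble: `dd_cutoff`, `n_snps`, `n_d_snp`, `n_da_snp`), `dd_cutoff`,
#'   and `ref_matches`.
#' @export
classify_all <- function(snps, proteome, domains, dd_cutoff = 0.10,
                         ref_matches = NULL) {
  if (is.null(ref_matches)) ref_matches <- scan_proteome(domains, proteome)
  seq_of <- stats::setNames(proteome$sequence, proteome$protein_id)
  matches_by_protein <- split(ref_matches, ref_matches$protein_id)
  no_match <- ref_matches[0, , drop = FALSE]

  calls <- if (nrow(snps) == 0L) {
    empty_calls()
  } else {
    dplyr::bind_rows(purrr::map(seq_len(nrow(snps)), function(i) {
      snp <- snps[i, ]
      rm <- matches_by_protein[[snp$protein_id]]
      if (is.null(rm)) rm <- no_match
      classify_snp(snp, seq_of[[snp$protein_id]], rm, domains, dd_cutoff)
    }))
  }
  calls <- dplyr::arrange(calls, .data$snp_id, .data$domain_id)
  status <- snp_status(calls, dd_cutoff)
  summary <- tibble::tibble(
    dd_cutoff = dd_cutoff,
    n_snps = nrow(snps),
    n_d_snp = sum(status$status != "outside"),
    n_da_snp = sum(status$status == "da_snp")
  )
  structure(
    list(calls = calls, snp_status = status, summary = summary,
         dd_cutoff = dd_cutoff, ref_matches = ref_matches),
    class = "snp_classification"
  )
}

#' Per-SNP status rollup at a given DD cutoff
#'
#' Collapses per-domain calls to one status per SNP: `da_snp` if any call is
#' domain-altering at `dd_cutoff` (pattern loss and outright domain erasure
#' count at every cutoff; profile distortion counts when DD >= cutoff),
#' otherwise `d_snp` if the SNP lies inside any matched domain, otherwise
#' `outside`. Because calls carry their DD values, the rollup can be
#' re-evaluated at any cutoff without rescanning.
#'
#' @param calls A call tibble from [classify_all()]/[classify_snp()].
#' @param dd_cutoff DD threshold in (0, 1].
#' @return A tibble with columns `snp_id`, `protein_id`, `status`, `max_dd`.
#' @export
snp_status <- function(calls, dd_cutoff) {
  stopifnot(dd_cutoff > 0, dd_cutoff <= 1)
  if (nrow(calls) == 0L) {
    return(tibble::tibble(snp_id = character(), protein_id = character(),
                          status = character(), max_dd = double()))
  }
  calls |>
    dplyr::group_by(.data$snp_id, .data$protein_id) |>
    dplyr::summarise(
      in_domain = any(.data$status != "outside"),
      da = any(.data$mechanism == "pattern_loss" |
                 (!is.na(.data$erased) & .data$erased) |
                 (!is.na(.data$dd) & .data$dd >= dd_cutoff)),
      max_dd = if (all(is.na(.data$dd))) NA_real_ else max(.data$dd, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$da ~ "da_snp",
      .data$in_domain ~ "d_snp",
      TRUE ~ "outside"
    )) |>
    dplyr::select("snp_id", "protein_id", "status", "max_dd") |>
    dplyr::arrange(.data$snp_id)
}

#' @export
print.snp_classification <- function(x, ...) {
  cat("<snp_classification> dd_cutoff=", x$dd_cutoff, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname classify_all
#' @param x A `snp_classification`.
#' @param ... Unused.
#' @export
tidy.snp_classification <- function(x, ...) x$calls

#' @rdname classify_all
#' @export
glance.snp_classification <- function(x, ...) x$summary

#' Write per-SNP domain calls
#' @param classification A `snp_classification` (or its call tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(classification, path) {
  calls <- if (inherits(classification, "snp_classification")) {
    classification$calls
  } else {
    classification
  }
  readr::write_tsv(calls, path)
  invisible(path)
}
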