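#' Read domain definitions
#'
#' Parses a line-oriented domain-definition file holding PROSITE-style
#' pattern and generalized-profile signatures. Each record is
#' ```
#' ID    <domain_id>
#' TYPE  PATTERN | PROFILE
#' ```
#' followed, for patterns, by a `PA <pattern>` line (dialect of
#' [parse_pattern()]); and for profiles by `GAP_OPEN`, `GAP_EXT` and
#' `CUTOFF` key lines plus `MA <L>` introducing L rows of 20 tab-separated
#' scores in [aa_alphabet()] column order. Records end with `//`; blank and
#' `#` comment lines are ignored.
#'
#' @param path Path to a domains file.
#' @return A named list of [parse_pattern()] / [profile_def()] objects,
#'   of class `domain_set`.
#' @export
read_domains <- function(path) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  out <- list()
  i <- 1L
  fields <- list()
  ma_rows <- NULL
  ma_expect <- 0L
  flush <- function(fields, ma_rows, line_no) {
    if (is.null(fields$ID)) abort(paste0(path, ": record ending at line ", line_no, " has no ID"))
    if (is.null(fields$TYPE)) abort(paste0(path, ": record '", fields$ID, "' has no TYPE"))
    if (fields$TYPE == "PATTERN") {
      if (is.null(fields$PA)) abort(paste0(path, ": pattern record '", fields$ID, "' has no PA line"))
      parse_pattern(fields$PA, domain_id = fields$ID)
    } else if (fields$TYPE == "PROFILE") {
      for (k in c("GAP_OPEN", "GAP_EXT", "CUTOFF")) {
        if (is.null(fields[[k]])) {
          abort(paste0(path, ": profile record '", fields$ID, "' is missing ", k))
        }
      }
      if (is.null(ma_rows) || length(ma_rows) == 0L) {
        abort(paste0(path, ": profile record '", fields$ID, "' has no MA rows"))
      }
      sc <- do.call(rbind, lapply(ma_rows, function(r) {
        v <- suppressWarnings(as.numeric(strsplit(r, "\t", fixed = TRUE)[[1]]))
        if (length(v) != 20L || anyNA(v)) {
          abort(paste0(path, ": profile record '", fields$ID,
                       "' has a malformed MA row (need 20 numeric scores)"))
        }
        v
      }))
      profile_def(fields$ID, sc,
                  gap_open = as.numeric(fields$GAP_OPEN),
                  gap_extend = as.numeric(fields$GAP_EXT),
                  cutoff = as.numeric(fields$CUTOFF))
    } else {
      abort(paste0(path, ": unknown TYPE '", fields$TYPE, "' in record '", fields$ID, "'"))
    }
  }
  for (ln in idx) {
    line <- lines[ln]
    if (ma_expect > 0L) {
      ma_rows <- c(ma_rows, line)
      ma_expect <- ma_expect - 1L
      next
    }
    if (grepl("^//", line)) {
      def <- flush(fields, ma_rows, ln)
      if (def$domain_id %in% names(out)) {
        abort(paste0(path, ": duplicated domain ID '", def$domain_id, "'"))
      }
      out[[def$domain_id]] <- def
      fields <- list()
      ma_rows <- NULL
      next
    }
    m <- stringr::str_match(line, "^(\\S+)\\s+(.*\\S)\\s*$")
    if (is.na(m[1, 1])) abort(paste0(path, ": malformed line ", ln, ": '", line, "'"))
    key <- m[1, 2]
    val <- m[1, 3]
    if (key == "MA") {
      ma_expect <- suppressWarnings(as.integer(val))
      if (is.na(ma_expect) || ma_expect < 1L) {
        abort(paste0(path, ": MA must declare a positive row count (line ", ln, ")"))
      }
      ma_rows <- character()
    } else {
      fields[[key]] <- val
    }
  }
  if (length(fields) > 0L || ma_expect > 0L) {
    abort(paste0(path, ": last record is not terminated by '//'"))
  }
  structure(out, class = "domain_set")
}

#' Write domain definitions
#'
#' Serializes a set of pattern/profile definitions in the dialect read by
#' [read_domains()].
#'
#' @param domains A `domain_set` or plain list of definitions.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domains <- function(domains, path) {
  fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  blocks <- lapply(domains, function(d) {
    if (inherits(d, "pattern_def")) {
      c(paste("ID", d$domain_id),
        "TYPE PATTERN",
        paste("PA", paste0(deparse_pattern(d), ".")),
        "//")
    } else if (inherits(d, "profile_def")) {
      c(paste("ID", d$domain_id),
        "TYPE PROFILE",
        paste("GAP_OPEN", fmt_num(d$gap_open)),
        paste("GAP_EXT", fmt_num(d$gap_extend)),
        paste("CUTOFF", fmt_num(d$cutoff)),
        paste("MA", nrow(d$scores)),
        apply(d$scores, 1, function(r) paste(fmt_num(r), collapse = "\t")),
        "//")
    } else {
      abort("`domains` must contain pattern_def/profile_def objects")
    }
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' @export
print.domain_set <- function(x, ...) {
  kinds <- vapply(x, function(d) if (inherits(d, "pattern_def")) "pattern" else "profile",
                  character(1))
  cat("<domain_set> ", length(x), " definitions (",
      sum(kinds == "pattern"), " patterns, ", sum(kinds == "profile"),
      " profiles)\n", sep = "")
  invisible(x)
}

domain_kind <- function(d) if (inherits(d, "pattern_def")) "pattern" else "profile"

#' Scan a proteome for domain occurrences
#'
#' Annotates every protein with every matching domain signature. Patterns
#' report every (greedy, longest-per-start) match span; profiles report the
#' single best-scoring span per protein, emitted only when the matching
#' score reaches the profile's presence cutoff (inclusive).
#'
#' @param domains A `domain_set` (or list of definitions).
#' @param proteome A proteome tibble from [read_proteome()].
#' @return A tibble with columns `protein_id`, `domain_id`, `kind`
#'   (`pattern`/`profile`), `start`, `end`, `matching_score` (NA for
#'   patterns), ordered by `protein_id`, `domain_id`, `start`.
#' @export
#' @examples
#' prot <- tibble::tibble(protein_id = "P1", gene_symbol = "", sequence = "CPVAAAAH")
#' doms <- list(D1 = parse_pattern("[AC]-x-V", domain_id = "D1"))
#' scan_proteome(doms, prot)
scan_proteome <- function(domains, proteome) {
  if (length(domains) == 0L || nrow(proteome) == 0L) {
    return(tibble::tibble(
      protein_id = character(), domain_id = character(), kind = character(),
      start = integer(), end = integer(), matching_score = double()
    ))
  }
  acc_pid <- acc_dom <- acc_kind <- list()
  acc_start <- acc_end <- acc_score <- list()
  k <- 0L
  for (i in seq_len(nrow(proteome))) {
    pid <- proteome$protein_id[i]
    s <- proteome$sequence[i]
    idx <- seq_to_idx(s)
    for (d in domains) {
      if (inherits(d, "pattern_def")) {
        hits <- scan_pattern(d, s)
        nh <- nrow(hits)
        if (nh == 0L) next
        k <- k + 1L
        acc_pid[[k]] <- rep(pid, nh)
        acc_dom[[k]] <- rep(d$domain_id, nh)
        acc_kind[[k]] <- rep("pattern", nh)
        acc_start[[k]] <- hits$start
        acc_end[[k]] <- hits$end
        acc_score[[k]] <- rep(NA_real_, nh)
      } else {
        res <- profile_dp(d$scores, idx, d$gap_open, d$gap_extend)
        if (!is.finite(res$score) || res$score < d$cutoff) next
        k <- k + 1L
        acc_pid[[k]] <- pid
        acc_dom[[k]] <- d$domain_id
        acc_kind[[k]] <- "profile"
        acc_start[[k]] <- res$start
        acc_end[[k]] <- res$end
        acc_score[[k]] <- res$score
      }
    }
  }
  out <- fast_tibble(
    protein_id = unlist(acc_pid) %||% character(),
    domain_id = unlist(acc_dom) %||% character(),
    kind = unlist(acc_kind) %||% character(),
    start = as.integer(unlist(acc_start)),
    end = as.integer(unlist(acc_end)),
    matching_score = as.double(unlist(acc_score) %||% double())
  )
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      protein_id = character(), domain_id = character(), kind = character(),
      start = integer(), end = integer(), matching_score = double()
    ))
  }
  dplyr::arrange(out, .data$protein_id, .data$domain_id, .data$start)
}

#' Write domain matches
#' @param matches Match tibble from [scan_proteome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  readr::write_tsv(matches, path)
  invisible(path)
}
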