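#' Parse a PROSITE-style pattern
#'
#' Parses a domain signature written in a restricted regular-expression
#' dialect modelled on PROSITE patterns. Elements are joined by `-`:
#' a single letter matches that residue exactly, `[ACD]` matches any listed
#' residue, `{P}` matches any residue *except* those listed, and `x` matches
#' any residue. Any element may carry a repetition suffix `(n)` or `(n,m)`;
#' the default is a single occurrence. A leading `<` anchors the pattern to
#' the N-terminus (the match must start at position 1) and a trailing `>`
#' anchors it to the C-terminus. A terminal `.` is permitted and ignored.
#'
#' @param text A single pattern string, e.g. `"[AC]-x-V-x(4)-{ED}."`.
#' @param domain_id Optional identifier attached to the parsed definition.
#'
#' @return An object of class `pattern_def`: a list with `domain_id`,
#'   `elements` (a tibble with columns `kind`, `residues`, `min_repeat`,
#'   `max_repeat`), `n_anchor`, `c_anchor` and the compiled `regex` used by
#'   [scan_pattern()].
#' @export
#' @examples
#' p <- parse_pattern("[AC]-x-V-x(4)-{ED}.")
#' p$elements
#' scan_pattern(p, "CPVAAAAH")
parse_pattern <- function(text, domain_id = NA_character_) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("`text` must be a single pattern string.")
  }
  s <- trimws(text)
  if (!nzchar(s)) pattern_error("empty pattern", 1L)

  n_anchor <- FALSE
  c_anchor <- FALSE
  offset <- 0L  # columns consumed before the element region, for error messages
  if (startsWith(s, "<")) {
    n_anchor <- TRUE
    s <- substr(s, 2L, nchar(s))
    offset <- 1L
  }
  if (endsWith(s, ".")) s <- substr(s, 1L, nchar(s) - 1L)
  if (endsWith(s, ">")) {
    c_anchor <- TRUE
    s <- substr(s, 1L, nchar(s) - 1L)
  }
  if (!nzchar(s)) pattern_error("pattern has no elements", offset + 1L)

  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  kind <- character()
  residues <- list()
  min_rep <- integer()
  max_rep <- integer()

  col <- function(j) offset + j

  while (i <= n) {
    ch <- chars[i]
    el_col <- col(i)
    if (ch == "x") {
      el_kind <- "wildcard"
      el_res <- character()
      i <- i + 1L
    } else if (ch == "[" || ch == "{") {
      close <- if (ch == "[") "]" else "}"
      j <- i + 1L
      letters <- character()
      while (j <= n && chars[j] != close) {
        if (!chars[j] %in% AA_ALPHABET) {
          pattern_error(paste0("illegal letter '", chars[j], "' in class"), col(j))
        }
        letters <- c(letters, chars[j])
        j <- j + 1L
      }
      if (j > n) pattern_error("unbalanced bracket", el_col)
      if (length(letters) == 0L) pattern_error("empty class", el_col)
      letters <- sort(unique(letters))
      if (ch == "{" && length(letters) >= length(AA_ALPHABET)) {
        pattern_error("exclusion class covers the whole alphabet", el_col)
      }
      el_kind <- if (ch == "[") "any_of" else "none_of"
      el_res <- letters
      i <- j + 1L
    } else if (ch %in% AA_ALPHABET) {
      el_kind <- "exact"
      el_res <- ch
      i <- i + 1L
    } else {
      pattern_error(paste0("unexpected character '", ch, "'"), el_col)
    }

    el_min <- 1L
    el_max <- 1L
    if (i <= n && chars[i] == "(") {
      j <- i + 1L
      digits1 <- ""
      while (j <= n && grepl("[0-9]", chars[j])) {
        digits1 <- paste0(digits1, chars[j])
        j <- j + 1L
      }
      if (!nzchar(digits1)) pattern_error("malformed repetition", col(i))
      if (j <= n && chars[j] == ",") {
        j <- j + 1L
        digits2 <- ""
        while (j <= n && grepl("[0-9]", chars[j])) {
          digits2 <- paste0(digits2, chars[j])
          j <- j + 1L
        }
        if (!nzchar(digits2)) pattern_error("malformed repetition", col(i))
      } else {
        digits2 <- digits1
      }
      if (j > n || chars[j] != ")") pattern_error("unbalanced repetition parenthesis", col(i))
      el_min <- as.integer(digits1)
      el_max <- as.integer(digits2)
      if (el_min > el_max) {
        pattern_error(paste0("repetition (", el_min, ",", el_max, ") has n > m"), col(i))
      }
      if (el_max == 0L) pattern_error("repetition maximum must be >= 1", col(i))
      i <- j + 1L
    }

    kind <- c(kind, el_kind)
    residues <- c(residues, list(el_res))
    min_rep <- c(min_rep, el_min)
    max_rep <- c(max_rep, el_max)

    if (i <= n) {
      if (chars[i] != "-") pattern_error(paste0("expected '-' before '", chars[i], "'"), col(i))
      i <- i + 1L
      if (i > n) pattern_error("trailing '-'", col(i - 1L))
    }
  }

  elements <- tibble::tibble(
    kind = kind,
    residues = residues,
    min_repeat = min_rep,
    max_repeat = max_rep
  )
  out <- structure(
    list(
      domain_id = domain_id,
      elements = elements,
      n_anchor = n_anchor,
      c_anchor = c_anchor
    ),
    class = "pattern_def"
  )
  out$regex <- pattern_regex(out)
  out
}

pattern_error <- function(msg, column) {
  abort(paste0("pattern parse error at column ", column, ": ", msg),
        class = "domainsnp_parse_error")
}

#' @export
print.pattern_def <- function(x, ...) {
  cat("<pattern_def> ", if (!is.na(x$domain_id)) x$domain_id else "", "\n", sep = "")
  cat("  ", deparse_pattern(x), "\n", sep = "")
  invisible(x)
}

#' Render a parsed pattern back to its text form
#'
#' @param p A [parse_pattern()] result.
#' @return A single pattern string (without the optional terminal `.`).
#' @export
deparse_pattern <- function(p) {
  stopifnot(inherits(p, "pattern_def"))
  el <- purrr::pmap_chr(p$elements, function(kind, residues, min_repeat, max_repeat) {
    body <- switch(kind,
      exact = residues,
      wildcard = "x",
      any_of = paste0("[", paste(residues, collapse = ""), "]"),
      none_of = paste0("{", paste(residues, collapse = ""), "}")
    )
    rep <- if (min_repeat == 1L && max_repeat == 1L) {
      ""
    } else if (min_repeat == max_repeat) {
      paste0("(", min_repeat, ")")
    } else {
      paste0("(", min_repeat, ",", max_repeat, ")")
    }
    paste0(body, rep)
  })
  paste0(
    if (p$n_anchor) "<" else "",
    paste(el, collapse = "-"),
    if (p$c_anchor) ">" else ""
  )
}

# Compile a pattern_def into a PCRE body (no anchors except the C-terminal $).
pattern_regex <- function(p) {
  el <- purrr::pmap_chr(p$elements, function(kind, residues, min_repeat, max_repeat) {
    body <- switch(kind,
      exact = residues,
      wildcard = ".",
      any_of = paste0("[", paste(residues, collapse = ""), "]"),
      none_of = paste0("[^", paste(residues, collapse = ""), "]")
    )
    rep <- if (min_repeat == 1L && max_repeat == 1L) {
      ""
    } else if (min_repeat == max_repeat) {
      paste0("{", min_repeat, "}")
    } else {
      paste0("{", min_repeat, ",", max_repeat, "}")
    }
    paste0(body, rep)
  })
  paste0(paste(el, collapse = ""), if (p$c_anchor) "$" else "")
}

#' Scan a sequence with a parsed pattern
#'
#' Reports every match span of the pattern on the sequence. Variable
#' repetitions are resolved greedily (longest first, element by element), and
#' only that first, greedy span is reported per start position; matches
#' starting at different positions may overlap. Anchored patterns are tested
#' only at the forced position(s). Zero-length expansions (possible when all
#' repetitions allow zero occurrences) are never reported as matches.
#'
#' @param p A `pattern_def` from [parse_pattern()].
#' @param s A single protein sequence string.
#' @return A tibble with columns `start`, `end` (1-based, inclusive), ordered
#'   by `start`; zero rows when the pattern does not match.
#' @export
#' @examples
#' scan_pattern(parse_pattern("[AC]-x-V-x(4)-{ED}"), "CPVAAAAH")
scan_pattern <- function(p, s) {
  stopifnot(inherits(p, "pattern_def"))
  if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
    abort("`s` must be a single non-empty sequence string.")
  }
  body <- p$regex
  if (p$n_anchor) {
    m <- regexpr(paste0("^(?:", body, ")"), s, perl = TRUE)
    if (m[1] == -1L || attr(m, "match.length") == 0L) {
      return(fast_tibble(start = integer(), end = integer()))
    }
    return(fast_tibble(start = 1L, end = attr(m, "match.length")))
  }
  m <- gregexpr(paste0("(?=(", body, "))"), s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(fast_tibble(start = integer(), end = integer()))
  starts <- as.integer(attr(m, "capture.start")[, 1L])
  lens <- as.integer(attr(m, "capture.length")[, 1L])
  keep <- lens > 0L
  fast_tibble(start = starts[keep], end = starts[keep] + lens[keep] - 1L)
}

# Presence-only pattern test; cheaper than scan_pattern for annotation.
pattern_present <- function(p, s) {
  body <- p$regex
  if (p$n_anchor) {
    m <- regexpr(paste0("^(?:", body, ")"), s, perl = TRUE)
    return(m[1] != -1L && attr(m, "match.length") > 0L)
  }
  m <- regexpr(body, s, perl = TRUE)
  if (m[1] == -1L) return(FALSE)
  if (attr(m, "match.length") > 0L) return(TRUE)
  nrow(scan_pattern(p, s)) > 0L  # leftmost match degenerate: fall back
}
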