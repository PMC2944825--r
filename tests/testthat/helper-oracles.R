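# Independent brute-force oracles. These deliberately share no code with the
# package implementation: patterns are matched by enumerating every concrete
# repetition expansion, profile alignments by enumerating every match-set,
# and hypergeometric tails by the direct combinatorial sum.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

element_allowed <- function(kind, residues) {
  switch(kind,
    exact = residues,
    any_of = residues,
    none_of = setdiff(AA, residues),
    wildcard = AA
  )
}

# All repetition-count vectors in greedy preference order: leftmost element
# most significant, counts descending (the order a greedy longest-first
# matcher explores expansions in).
rep_grid <- function(elements) {
  ranges <- lapply(seq_len(nrow(elements)), function(i) {
    seq(elements$max_repeat[i], elements$min_repeat[i])
  })
  g <- do.call(expand.grid, rev(ranges))        # last column varies slowest
  g <- g[, rev(seq_along(ranges)), drop = FALSE] # column i = element i
  unname(as.matrix(g))
}

oracle_scan_pattern <- function(p, s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  allowed <- lapply(seq_len(nrow(p$elements)), function(i) {
    element_allowed(p$elements$kind[i], p$elements$residues[[i]])
  })
  grid <- rep_grid(p$elements)
  starts <- if (p$n_anchor) 1L else seq_len(n)
  out_start <- integer()
  out_end <- integer()
  for (st in starts) {
    for (r in seq_len(nrow(grid))) {
      reps <- grid[r, ]
      total <- sum(reps)
      if (total == 0L) next
      en <- st + total - 1L
      if (en > n) next
      if (p$c_anchor && en != n) next
      sets <- rep(allowed, times = reps)
      ok <- TRUE
      for (j in seq_len(total)) {
        if (!chars[st + j - 1L] %in% sets[[j]]) { ok <- FALSE; break }
      }
      if (ok) {
        out_start <- c(out_start, st)
        out_end <- c(out_end, en)
        break  # greedy: first expansion in preference order wins this start
      }
    }
  }
  data.frame(start = out_start, end = out_end)
}

# Number of concrete expansions a pattern has (to cap oracle work).
pattern_expansion_count <- function(p) {
  prod(p$elements$max_repeat - p$elements$min_repeat + 1)
}

# Best local-local profile alignment by exhaustive enumeration: choose a
# non-empty set of profile positions and an equally sized increasing set of
# sequence positions; internal gap runs cost affine penalties, end gaps are
# free on both sides.
oracle_profile_score <- function(scores, s, gap_open, gap_extend) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(chars, AA)
  L <- nrow(scores)
  n <- length(idx)
  gap_cost <- function(pos) {
    g <- diff(pos) - 1L
    sum(ifelse(g > 0L, gap_open + (g - 1L) * gap_extend, 0))
  }
  best <- -Inf
  best_start <- best_end <- 0L
  for (k in seq_len(min(L, n))) {
    psets <- utils::combn(L, k)
    ssets <- utils::combn(n, k)
    for (a in seq_len(ncol(psets))) {
      pp <- psets[, a]
      pcost <- gap_cost(pp)
      for (b in seq_len(ncol(ssets))) {
        ss <- ssets[, b]
        sc <- sum(scores[cbind(pp, idx[ss])]) + pcost + gap_cost(ss)
        st <- ss[1]
        en <- ss[k]
        if (sc > best ||
            (sc == best && (st < best_start ||
                            (st == best_start && en < best_end)))) {
          best <- sc
          best_start <- st
          best_end <- en
        }
      }
    }
  }
  list(score = best, start = best_start, end = best_end)
}

oracle_hyper_upper <- function(N, K, n, k) {
  if (k == 0) return(1)
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Random pattern for property tests: arbitrary element mix, variable
# repetitions and anchors, capped expansion count.
random_pattern <- function() {
  repeat {
    n_el <- sample(1:5, 1)
    parts <- character(n_el)
    for (i in seq_len(n_el)) {
      kind <- sample(c("exact", "any_of", "none_of", "wildcard"), 1,
                     prob = c(0.35, 0.25, 0.15, 0.25))
      body <- switch(kind,
        exact = sample(AA, 1),
        any_of = paste0("[", paste(sort(sample(AA, sample(2:4, 1))), collapse = ""), "]"),
        none_of = paste0("{", paste(sort(sample(AA, sample(1:18, 1))), collapse = ""), "}"),
        wildcard = "x"
      )
      rep_suffix <- if (runif(1) < 0.35) {
        lo <- sample(0:3, 1)
        hi <- lo + sample(0:3, 1)
        if (hi == 0L) hi <- 1L
        if (lo == hi) paste0("(", lo, ")") else paste0("(", lo, ",", hi, ")")
      } else {
        ""
      }
      parts[i] <- paste0(body, rep_suffix)
    }
    text <- paste0(
      if (runif(1) < 0.2) "<" else "",
      paste(parts, collapse = "-"),
      if (runif(1) < 0.2) ">" else ""
    )
    p <- tryCatch(parse_pattern(text), error = function(e) NULL)
    if (!is.null(p) && pattern_expansion_count(p) <= 1e4) return(p)
  }
}

random_sequence <- function(len) paste(sample(AA, len, replace = TRUE), collapse = "")

# Scores on a 0.25 grid are exact in binary, so alignment-score sums are
# exact and score ties are genuine ties rather than rounding artefacts.
random_profile <- function(L = sample(1:5, 1)) {
  sc <- matrix(sample(seq(-4, 4, by = 0.25), L * 20, replace = TRUE), nrow = L,
               dimnames = list(NULL, AA))
  go <- -sample(seq(1, 6, by = 0.25), 1)
  ge <- go + sample(seq(0, -go, by = 0.25), 1)
  profile_def("RND", sc, gap_open = go, gap_extend = ge,
              cutoff = sample(seq(0.5, 5, by = 0.25), 1))
}
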