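#' Construct a generalized-profile domain definition
#'
#' A generalized profile is a position-specific score matrix with affine gap
#' penalties and a presence cutoff: a protein carries the domain when the
#' best local alignment score of the profile against its sequence (the
#' matching score, MS) reaches the cutoff.
#'
#' @param domain_id Identifier of the domain.
#' @param scores Numeric matrix, one row per profile position and 20 columns
#'   in the order of [aa_alphabet()] (column names, when present, are checked).
#' @param gap_open Penalty (<= 0) for opening a gap: the first inserted
#'   residue or the first deleted profile position of a run.
#' @param gap_extend Penalty (<= 0, >= `gap_open`) per additional inserted
#'   residue or deleted profile position.
#' @param cutoff Presence threshold (> 0) on the matching score; the domain
#'   is called present iff MS >= cutoff.
#'
#' @return An object of class `profile_def`.
#' @export
profile_def <- function(domain_id, scores, gap_open, gap_extend, cutoff) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 1L || ncol(scores) != 20L) {
    abort("`scores` must have >= 1 row and exactly 20 columns.")
  }
  if (!is.null(colnames(scores)) && !identical(colnames(scores), AA_ALPHABET)) {
    abort("`scores` columns must follow aa_alphabet() order.")
  }
  colnames(scores) <- AA_ALPHABET
  if (anyNA(scores)) abort("`scores` must not contain NA.")
  if (gap_open > 0 || gap_extend > 0) abort("gap penalties must be <= 0.")
  if (gap_extend < gap_open) abort("`gap_extend` must be >= `gap_open`.")
  if (!is.finite(cutoff) || cutoff <= 0) abort("`cutoff` must be > 0.")
  structure(
    list(
      domain_id = domain_id,
      scores = scores,
      gap_open = as.numeric(gap_open),
      gap_extend = as.numeric(gap_extend),
      cutoff = as.numeric(cutoff)
    ),
    class = "profile_def"
  )
}

#' @export
print.profile_def <- function(x, ...) {
  cat("<profile_def> ", x$domain_id, ": L=", nrow(x$scores),
      ", gap_open=", x$gap_open, ", gap_extend=", x$gap_extend,
      ", cutoff=", x$cutoff, "\n", sep = "")
  invisible(x)
}

seq_to_idx <- function(s) {
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    abort(paste0("illegal residue '", substr(s, bad, bad), "' at position ", bad))
  }
  idx
}

#' Score a sequence against a profile
#'
#' Computes the matching score (MS): the best local alignment score of the
#' profile against the sequence. The alignment is local on both sides —
#' unaligned flanking residues and flanking profile positions are free —
#' while internal insertions of sequence residues and internal deletions of
#' profile positions are penalised affinely (`gap_open` for the first,
#' `gap_extend` per further one). At least one profile position must be
#' matched to a residue, and no zero floor is applied, so the score can be
#' negative. Ties are broken towards the smallest start, then smallest end.
#'
#' @param pr A [profile_def()].
#' @param s A single protein sequence string.
#' @return A list with `score` (the MS), and `start`, `end`: the 1-based
#'   inclusive sequence span of the best alignment.
#' @export
#' @examples
#' sc <- matrix(-2, nrow = 2, ncol = 20, dimnames = list(NULL, aa_alphabet()))
#' sc[1, "A"] <- 2; sc[2, "G"] <- 3
#' pr <- profile_def("PRF", sc, gap_open = -4, gap_extend = -1, cutoff = 4)
#' profile_score(pr, "AAG")
profile_score <- function(pr, s) {
  stopifnot(inherits(pr, "profile_def"))
  if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
    abort("`s` must be a single non-empty sequence string.")
  }
  res <- profile_dp(pr$scores, seq_to_idx(s), pr$gap_open, pr$gap_extend)
  list(score = res$score, start = res$start, end = res$end)
}
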