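#' Alignment scoring scheme
#'
#' Integer match reward and penalties for an affine-gap Smith-Waterman
#' alignment. A gap of length L costs `gap_open + L * gap_extend`. The
#' default is BLASTN-like.
#'
#' @param match Positive match reward.
#' @param mismatch Mismatch penalty (<= 0).
#' @param gap_open Gap-open penalty (<= 0).
#' @param gap_extend Gap-extension penalty (<= 0).
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L,
                           gap_open = -5L, gap_extend = -2L) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> match=%d mismatch=%d gap_open=%d gap_extend=%d\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend))
  invisible(x)
}

new_alignment_result <- function(raw, strand, qlen) {
  identity <- if (raw$n_columns > 0) 100 * raw$matches / raw$n_columns else 0
  structure(list(score = raw$score,
                 identity_pct = identity,
                 matches = raw$matches,
                 n_columns = raw$n_columns,
                 query_span = c(raw$q_start, raw$q_end),
                 target_span = c(raw$t_start, raw$t_end),
                 strand = strand),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> score=%d identity=%.2f%% strand=%s q[%d,%d) t[%d,%d) cols=%d\n",
    x$score, x$identity_pct, x$strand,
    x$query_span[1], x$query_span[2], x$target_span[1], x$target_span[2],
    x$n_columns))
  invisible(x)
}

#' Local (Smith-Waterman) alignment
#'
#' Optimal affine-gap local alignment. `N` matches nothing (scored as a
#' mismatch, even against `N`). Identity is `100 * matches / n_columns`
#' where `n_columns` counts every alignment column including gaps. When
#' `both_strands` is set, the query is also aligned as its reverse
#' complement and the better strand is returned (ties prefer `+`); minus-
#' strand query spans are reported in original query coordinates. All spans
#' are 0-based half-open.
#'
#' @param query,target [dna_seq] or character.
#' @param scheme A [scoring_scheme].
#' @param both_strands Also try the reverse-complemented query.
#' @return An `alignment_result`.
#' @export
local_align <- function(query, target, scheme = scoring_scheme(),
                        both_strands = FALSE) {
  q <- seq_chr(as_dna_seq(query)); t <- seq_chr(as_dna_seq(target))
  if (!nzchar(q) || !nzchar(t)) stop("empty sequence", call. = FALSE)
  # Exact-occurrence fast path: an alignment scoring match * L must consist
  # of L matched columns covering the whole query, i.e. a verbatim
  # occurrence, and the DP tie-break selects the earliest one -- so the
  # first exact hit is the DP answer. N never matches, hence the guard.
  if (!grepl("N", q, fixed = TRUE)) {
    L <- nchar(q)
    hit <- regexpr(q, t, fixed = TRUE)[1]
    if (hit < 0 && both_strands) {
      rc <- revcomp_chr(q)
      hit2 <- regexpr(rc, t, fixed = TRUE)[1]
      if (hit2 > 0)
        return(new_alignment_result(
          list(score = scheme$match * L, matches = L, n_columns = L,
               q_start = 0L, q_end = L,
               t_start = hit2 - 1L, t_end = hit2 - 1L + L), "-", L))
    }
    if (hit > 0)
      return(new_alignment_result(
        list(score = scheme$match * L, matches = L, n_columns = L,
             q_start = 0L, q_end = L,
             t_start = hit - 1L, t_end = hit - 1L + L), "+", L))
  }
  fwd <- cpp_local_align(q, t, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend)
  res <- new_alignment_result(fwd, "+", nchar(q))
  if (both_strands) {
    rc <- revcomp_chr(q)
    rev <- cpp_local_align(rc, t, scheme$match, scheme$mismatch,
                           scheme$gap_open, scheme$gap_extend)
    if (rev$score > fwd$score) {
      res <- new_alignment_result(rev, "-", nchar(q))
      # map span on the reverse-complemented query back to original coords
      L <- nchar(q)
      res$query_span <- c(L - rev$q_end, L - rev$q_start)
    }
  }
  res
}

#' Fitting (glocal) alignment
#'
#' Aligns the entire query against the best-matching substring of the
#' target (leading/trailing target is free; every query base is part of the
#' alignment). Used for back-verifying inserts against the source genome so
#' that mutated insert ends count against identity instead of being
#' trimmed. Identity is 100 exactly when the query occurs verbatim in the
#' target.
#'
#' @inheritParams local_align
#' @return An `alignment_result` (score may be negative).
#' @export
fit_align <- function(query, target, scheme = scoring_scheme(),
                      both_strands = FALSE) {
  q <- seq_chr(as_dna_seq(query)); t <- seq_chr(as_dna_seq(target))
  if (!nzchar(q) || !nzchar(t)) stop("empty sequence", call. = FALSE)
  fwd <- cpp_fit_align(q, t, scheme$match, scheme$mismatch,
                       scheme$gap_open, scheme$gap_extend)
  res <- new_alignment_result(fwd, "+", nchar(q))
  if (both_strands) {
    rc <- revcomp_chr(q)
    rev <- cpp_fit_align(rc, t, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend)
    if (rev$score > fwd$score) {
      res <- new_alignment_result(rev, "-", nchar(q))
      L <- nchar(q)
      res$query_span <- c(L - rev$q_end, L - rev$q_start)
    }
  }
  res
}
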