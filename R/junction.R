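#' Classify an observed junction sequence against the expected HDR allele
#'
#' Globally aligns a Sanger read covering a knock-in junction to the
#' expected homology-directed-repair allele and classifies the outcome:
#'
#' * `precise`: observed equals expected over the compared span;
#' * `partial_duplication`: an inserted segment is (mostly) an exact copy
#'   of part of a homology arm, optionally with extra non-arm bases
#'   (`ins_seq`), as in imperfect repair that re-copies arm sequence;
#' * `small_insertion`: extra bases not matching either arm;
#' * `deletion`: missing bases relative to the expected allele;
#' * `complex`: any other combination of differences.
#'
#' The observed read may be shorter than the expected allele; it is
#' aligned to the best-matching region (classification is invariant under
#' extra flanking context beyond the compared span).
#'
#' @param observed Observed junction sequence (must cover the junction
#'   plus `min_flank` bp on each side).
#' @param expected Expected HDR allele (see [build_expected_allele()]).
#' @param wild_type Optional wild-type window (currently informational).
#' @param feature_anchor 1-based position, in `expected`, of the first
#'   base of the reference start or stop codon used to report the edit
#'   offset.
#' @param feature_type `"start"` or `"stop"`: whether `feature_anchor` is
#'   a start codon (coding downstream) or stop codon (coding upstream).
#' @param arms Character vector of homology-arm sequences used for the
#'   duplication test (exact substring identity required).
#' @param min_flank Required junction coverage on each side, in bp.
#' @param junction_at Optional 1-based position in `expected` of the last
#'   base before the (5' or 3') donor junction; used with `min_flank` to
#'   check coverage. Skipped when `NULL`.
#' @param min_dup Minimum arm-matching length to call a duplication.
#' @return A list of class `junction_call` with `status`, `dup_len`,
#'   `dup_seq`, `ins_seq`, `del_len`, `offset_from_feature`,
#'   `coding_affected`, and `n_mismatch`.
#' @export
classify_junction <- function(observed, expected, wild_type = NULL,
                              feature_anchor = NA_integer_,
                              feature_type = c("start", "stop"),
                              arms = character(0), min_flank = 40L,
                              junction_at = NULL, min_dup = 6L) {
  observed <- assert_dna(observed, "observed")
  expected <- assert_dna(expected, "expected")
  feature_type <- match.arg(feature_type)

  ## align observed (global) to the best region of expected (local)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(observed, expected,
                                      type = "global-local",
                                      substitutionMatrix = mat,
                                      gapOpening = 2, gapExtension = 1)
  win_start <- Biostrings::start(Biostrings::subject(pa))
  win_end <- Biostrings::end(Biostrings::subject(pa))
  if (!is.null(junction_at)) {
    if (win_start > junction_at - min_flank + 1L ||
        win_end < junction_at + min_flank)
      stop("observed sequence does not cover the junction by ", min_flank,
           " bp on each side", call. = FALSE)
  }
  exp_win <- substr(expected, win_start, win_end)

  call <- list(status = "complex", dup_len = 0L, dup_seq = "",
               ins_seq = "", del_len = 0L,
               offset_from_feature = NA_integer_,
               coding_affected = NA, n_mismatch = 0L)
  class(call) <- "junction_call"

  offset_of <- function(edit_gap_expected) {
    ## edit_gap: index (in expected) of the last base before the edit
    if (is.na(feature_anchor)) return(NA_integer_)
    codon_start <- feature_anchor
    codon_end <- feature_anchor + 2L
    if (edit_gap_expected < codon_start)
      as.integer(edit_gap_expected - (codon_start - 1L))
    else if (edit_gap_expected >= codon_end)
      as.integer(edit_gap_expected - codon_end)
    else 0L
  }
  coding_of <- function(offset) {
    if (is.na(offset)) return(NA)
    if (feature_type == "start") offset >= 0L else offset <= 0L
  }

  if (observed == exp_win) {
    call$status <- "precise"
    call$offset_from_feature <- 0L
    call$coding_affected <- FALSE
    return(call)
  }

  n_obs <- nchar(observed); n_exp <- nchar(exp_win)
  L <- lcp_len(observed, exp_win)
  R <- lcs_len(observed, exp_win)

  if (n_obs > n_exp && L + R >= n_exp) {
    ## pure insertion of (n_obs - n_exp) bases; the split point is
    ## ambiguous within the duplicated region, so scan all consistent
    ## placements and keep the one with the longest exact arm match
    ins_len <- n_obs - n_exp
    c_range <- seq.int(max(0L, n_exp - R), min(L, n_exp))
    best <- NULL
    for (cc in c_range) {
      seg <- substr(observed, cc + 1L, cc + ins_len)
      d <- arm_dup_of(seg, arms, min_dup)
      cand <- list(c = cc, seg = seg, dup_len = d$dup_len,
                   dup_seq = d$dup_seq, ins_seq = d$ins_seq)
      if (is.null(best) || cand$dup_len > best$dup_len) best <- cand
    }
    edit_gap <- win_start - 1L + best$c
    call$offset_from_feature <- offset_of(edit_gap)
    call$coding_affected <- coding_of(call$offset_from_feature)
    if (best$dup_len >= min_dup) {
      call$status <- "partial_duplication"
      call$dup_len <- best$dup_len
      call$dup_seq <- best$dup_seq
      call$ins_seq <- best$ins_seq
    } else {
      call$status <- "small_insertion"
      call$ins_seq <- best$seg
    }
    return(call)
  }

  if (n_obs < n_exp && L + R >= n_obs) {
    call$status <- "deletion"
    call$del_len <- n_exp - n_obs
    edit_gap <- win_start - 1L + L
    call$offset_from_feature <- offset_of(edit_gap)
    ## a deletion removes expected bases starting right after the gap
    del_span <- c(edit_gap + 1L, edit_gap + call$del_len)
    if (!is.na(feature_anchor)) {
      covers_codon <- del_span[1] <= feature_anchor + 2L &
        del_span[2] >= feature_anchor
      o <- call$offset_from_feature
      call$coding_affected <- covers_codon ||
        isTRUE(coding_of(o))
    }
    return(call)
  }

  ## substitutions and/or mixed events: report via alignment summary
  call$status <- "complex"
  call$n_mismatch <- Biostrings::nmismatch(pa)
  if (call$n_mismatch > 0L && Biostrings::nindel(pa)@insertion[1] == 0L &&
      Biostrings::nindel(pa)@deletion[1] == 0L && n_obs == n_exp) {
    ## pure substitutions: nearest mismatch defines the offset
    ov <- strsplit(observed, "")[[1]]
    ev <- strsplit(exp_win, "")[[1]]
    mm <- which(ov != ev)
    edit_gap <- win_start - 1L + mm[1] - 1L
    call$offset_from_feature <- offset_of(edit_gap)
    call$coding_affected <- coding_of(call$offset_from_feature)
  }
  call
}

## Decompose an inserted segment into (arm-duplicated prefix/suffix,
## residual insertion). Exact substring identity to an arm is required.
arm_dup_of <- function(seg, arms, min_dup) {
  n <- nchar(seg)
  best <- list(dup_len = 0L, dup_seq = "", ins_seq = seg)
  if (!length(arms) || n == 0L) return(best)
  in_arm <- function(x) any(vapply(
    arms, function(a) grepl(x, a, fixed = TRUE), logical(1)))
  ## longest prefix of seg that is an arm substring
  for (j in seq.int(n, 1L)) {
    p <- substr(seg, 1L, j)
    if (in_arm(p)) {
      if (j > best$dup_len)
        best <- list(dup_len = j, dup_seq = p, ins_seq = substring(seg, j + 1L))
      break
    }
  }
  ## longest suffix of seg that is an arm substring
  for (j in seq.int(n, 1L)) {
    s <- substring(seg, n - j + 1L)
    if (in_arm(s)) {
      if (j > best$dup_len)
        best <- list(dup_len = j, dup_seq = s,
                     ins_seq = substr(seg, 1L, n - j))
      break
    }
  }
  best
}

#' @export
print.junction_call <- function(x, ...) {
  cat("<junction_call> ", x$status, sep = "")
  if (x$dup_len > 0L)
    cat(": ", x$dup_len, "-bp arm duplication (", x$dup_seq, ")", sep = "")
  if (nchar(x$ins_seq))
    cat(" + ", nchar(x$ins_seq), "-bp insertion (", x$ins_seq, ")", sep = "")
  if (x$del_len > 0L) cat(": ", x$del_len, "-bp deletion", sep = "")
  if (!is.na(x$offset_from_feature))
    cat("; offset ", x$offset_from_feature, " bp from feature", sep = "")
  if (!is.na(x$coding_affected))
    cat("; coding ", if (x$coding_affected) "affected" else "unaffected",
        sep = "")
  cat("\n")
  invisible(x)
}
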