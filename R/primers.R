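## Pick an annealing length within `range` whose segment GC lands in
## [0.4, 0.6] if achievable, else closest to 0.5; ties -> shorter.
pick_anneal_len <- function(segment_fn, range = c(18L, 25L)) {
  ks <- seq.int(range[1], range[2])
  gcs <- vapply(ks, function(k) gc_content(segment_fn(k)), numeric(1))
  inside <- gcs >= 0.4 & gcs <= 0.6
  pool <- if (any(inside)) ks[inside] else ks
  dev <- abs(gcs[match(pool, ks)] - 0.5)
  pool[order(dev, pool)][1]
}

#' Design biotinylated donor-amplification primers
#'
#' The donor is synthesized by PCR on the tag-cassette template with
#' primers that carry the homology arms as 5' tails and are biotinylated
#' at their 5' ends (the biotin protects donor ends and enables
#' monomeric integration with Cas9-mSA). The forward primer is
#' `left_arm + first k nt of the cassette block`; the reverse primer is the
#' reverse complement of `last k' nt of the block + right_arm`. Annealing
#' lengths are chosen from `anneal_range` targeting 40-60% GC.
#'
#' @param donor A [assemble_donor()] result.
#' @param anneal_range Integer range of candidate annealing lengths.
#' @return A `primer_pair` list with `fwd_seq`, `rev_seq`,
#'   `fwd_biotin = rev_biotin = TRUE` and the chosen annealing lengths.
#' @export
design_donor_primers <- function(donor, anneal_range = c(18L, 25L)) {
  stopifnot(inherits(donor, "donor_design"))
  block <- cassette_block(donor$cassette)
  if (nchar(block) < max(anneal_range))
    stop("cassette block shorter than the requested annealing length",
         call. = FALSE)
  k_f <- pick_anneal_len(function(k) substr(block, 1L, k), anneal_range)
  k_r <- pick_anneal_len(function(k) substring(block, nchar(block) - k + 1L),
                         anneal_range)
  structure(
    list(fwd_seq = paste0(donor$left_arm, substr(block, 1L, k_f)),
         rev_seq = revcomp(paste0(substring(block, nchar(block) - k_r + 1L),
                                  donor$right_arm)),
         fwd_biotin = TRUE, rev_biotin = TRUE,
         purpose = "donor_amplification",
         fwd_anneal_len = k_f, rev_anneal_len = k_r),
    class = "primer_pair")
}

#' In-silico PCR
#'
#' Locates the longest 3'-terminal segment of the forward primer (and of
#' the reverse primer on the minus strand) that matches the template
#' exactly, and returns the predicted product including 5' primer tails.
#'
#' @param template Template DNA string.
#' @param fwd,rev Primer sequences, 5' to 3'.
#' @param min_anneal Minimum exact 3' annealing length.
#' @return The product sequence, or `NA_character_` if either primer finds
#'   no site or the sites are not convergent.
#' @export
simulate_pcr <- function(template, fwd, rev, min_anneal = 12L) {
  template <- assert_dna(template, "template")
  fwd <- assert_dna(fwd, "fwd"); rev <- assert_dna(rev, "rev")
  ## forward: longest suffix of fwd present in template
  f_hit <- NULL
  for (m in seq.int(nchar(fwd), min_anneal)) {
    site <- regexpr(substring(fwd, nchar(fwd) - m + 1L), template,
                    fixed = TRUE)
    if (site > 0) { f_hit <- list(m = m, at = as.integer(site)); break }
  }
  if (is.null(f_hit)) return(NA_character_)
  ## reverse: longest prefix of revcomp(rev) present downstream
  rcr <- revcomp(rev)
  r_hit <- NULL
  for (m in seq.int(nchar(rcr), min_anneal)) {
    hits <- gregexpr(substr(rcr, 1L, m), template, fixed = TRUE)[[1]]
    hits <- hits[hits >= f_hit$at]
    if (length(hits) && hits[1] > 0) {
      r_hit <- list(m = m, at = as.integer(hits[length(hits)]))
      break
    }
  }
  if (is.null(r_hit)) return(NA_character_)
  paste0(substr(fwd, 1L, nchar(fwd) - f_hit$m),
         substr(template, f_hit$at, r_hit$at + r_hit$m - 1L),
         substring(rcr, r_hit$m + 1L))
}

#' Design external genotyping primers
#'
#' Genotyping primers sit strictly outside the donor footprint (outside
#' both homology arms), so only a genuine genomic integration - not
#' residual donor molecules - can yield the knock-in amplicon. The
#' knock-in amplicon exceeds the wild-type amplicon by exactly the
#' cassette block length.
#'
#' @param locus A [target_locus()].
#' @param arms Result of [extract_homology_arms()] (defines the footprint).
#' @param cassette Tag cassette (for the predicted knock-in amplicon), or
#'   `NULL`.
#' @param flank_min Minimum genomic flank beyond each arm that must be
#'   available in the window.
#' @param primer_len Primer length.
#' @param search_span How far beyond the footprint to search for a
#'   GC-balanced primer.
#' @return A `primer_pair` list with `purpose = "genotyping"`, predicted
#'   wild-type and knock-in amplicon lengths, and primer window positions.
#' @export
design_genotyping_primers <- function(locus, arms, cassette = NULL,
                                      flank_min = 60L, primer_len = 20L,
                                      search_span = 80L) {
  stopifnot(inherits(locus, "target_locus"))
  w <- locus$window_seq
  n <- nchar(w)
  foot_lo <- arms$left_start
  foot_hi <- arms$right_end
  if (foot_lo - 1L < flank_min)
    stop("window provides only ", foot_lo - 1L, " bp of 5' flank; ",
         flank_min, " bp required", call. = FALSE)
  if (n - foot_hi < flank_min)
    stop("window provides only ", n - foot_hi, " bp of 3' flank; ",
         flank_min, " bp required", call. = FALSE)
  ## forward candidates end at least 1 bp before the footprint
  f_ends <- seq.int(max(primer_len, foot_lo - 1L - search_span + 1L),
                    foot_lo - 1L)
  f_seqs <- substring(w, f_ends - primer_len + 1L, f_ends)
  f_pick <- order(abs(gc_content(f_seqs) - 0.5), -f_ends)[1]
  ## reverse candidates start after the footprint
  r_starts <- seq.int(foot_hi + 1L,
                      min(n - primer_len + 1L, foot_hi + search_span))
  r_seqs <- substring(w, r_starts, r_starts + primer_len - 1L)
  r_pick <- order(abs(gc_content(r_seqs) - 0.5), r_starts)[1]
  wt_amplicon <- (r_starts[r_pick] + primer_len - 1L) -
    (f_ends[f_pick] - primer_len + 1L) + 1L
  block_len <- nchar(cassette_block(
    if (inherits(cassette, "donor_design")) cassette$cassette else cassette))
  structure(
    list(fwd_seq = f_seqs[f_pick], rev_seq = revcomp(r_seqs[r_pick]),
         fwd_biotin = FALSE, rev_biotin = FALSE, purpose = "genotyping",
         fwd_start = f_ends[f_pick] - primer_len + 1L,
         rev_end = r_starts[r_pick] + primer_len - 1L,
         predicted_wt_amplicon_bp = wt_amplicon,
         predicted_ki_amplicon_bp = wt_amplicon + block_len),
    class = "primer_pair")
}
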