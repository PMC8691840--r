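#' Describe a knock-in target locus
#'
#' A target locus is a genomic sequence window together with the insertion
#' junction (a codon boundary of the tagged gene) and the reading-frame
#' anchor. The insertion point is given as the index of the last base
#' before the junction, so `insertion_point = 40` means the tag cassette is
#' spliced between window positions 40 and 41.
#'
#' @param window_seq DNA string: the genomic window around the insertion site.
#' @param insertion_point Integer, 0..nchar(window_seq): index of the last
#'   base before the junction.
#' @param frame_anchor 1-based window position of the first base of a codon
#'   of the tagged open reading frame (typically the A of the start codon).
#'   The junction must fall on a codon boundary relative to this anchor.
#' @param terminus `"N"` or `"C"`: which protein terminus is tagged.
#' @param contig_id,window_start Provenance of the window on its source
#'   contig (`window_start` is the 1-based contig coordinate of window
#'   position 1), used when reporting genomic coordinates.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `target_locus`.
#' @export
target_locus <- function(window_seq, insertion_point, frame_anchor,
                         terminus = c("N", "C"), contig_id = "locus",
                         window_start = 1L, strand = c("+", "-")) {
  window_seq <- assert_dna(window_seq, "window_seq")
  terminus <- match.arg(terminus)
  strand <- match.arg(strand)
  insertion_point <- as.integer(insertion_point)
  frame_anchor <- as.integer(frame_anchor)
  n <- nchar(window_seq)
  if (insertion_point < 0L || insertion_point > n)
    stop("insertion_point must lie within the window (0..", n, ")",
         call. = FALSE)
  if (frame_anchor < 1L || frame_anchor > n)
    stop("frame_anchor must be a 1-based window position", call. = FALSE)
  ## junction gap minus gap before the frame anchor must be a whole number
  ## of codons
  if ((insertion_point - (frame_anchor - 1L)) %% 3L != 0L)
    stop("insertion_point is not on a codon boundary relative to ",
         "frame_anchor", call. = FALSE)
  structure(
    list(contig_id = contig_id, window_seq = window_seq,
         window_start = as.integer(window_start),
         insertion_point = insertion_point, frame_anchor = frame_anchor,
         terminus = terminus, strand = strand),
    class = "target_locus")
}

#' @export
print.target_locus <- function(x, ...) {
  cat("<target_locus> ", x$contig_id, ":", x$window_start, "-",
      x$window_start + nchar(x$window_seq) - 1L, " (", x$strand, ")\n",
      "  window: ", nchar(x$window_seq), " bp; insertion after window pos ",
      x$insertion_point, " (", x$terminus, "-terminal tag)\n", sep = "")
  invisible(x)
}

## 1-based contig coordinate of the last base before the junction.
locus_genomic_coordinate <- function(locus) {
  locus$window_start + locus$insertion_point - 1L
}
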