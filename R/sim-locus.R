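#' Simulate a target locus with an in-frame gene model
#'
#' Generates a random genomic window containing an open reading frame
#' (`ATG ... stop`) and returns it as a [target_locus()] with the
#' insertion junction immediately after the start codon (N-terminal
#' tagging geometry by default).
#'
#' @param length Window length in bp.
#' @param gc GC fraction of the background sequence.
#' @param seed RNG seed (deterministic output for a given seed).
#' @param orf_len ORF length in bp (multiple of 3, >= 9; includes ATG and
#'   stop).
#' @param orf_start 1-based ORF start position (default: centered).
#' @param terminus Tag geometry: `"N"` puts the junction right after the
#'   start codon, `"C"` right before the stop codon.
#' @param contig_id Contig name used in reports.
#' @return A [target_locus()] with attributes `orf_start`, `orf_end`, and
#'   `sim_truth` (seed and parameters).
#' @export
simulate_locus <- function(length = 2000L, gc = 0.5, seed = 1L,
                           orf_len = 300L, orf_start = NULL,
                           terminus = c("N", "C"), contig_id = "sim_chr1") {
  terminus <- match.arg(terminus)
  stopifnot(orf_len %% 3L == 0L, orf_len >= 9L, length >= orf_len + 6L)
  with_seed(seed, {
    if (is.null(orf_start))
      orf_start <- as.integer((length - orf_len) %/% 2L) + 1L
    seq <- random_dna(length, gc)
    n_codons <- orf_len %/% 3L - 2L
    sense <- setdiff(
      apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        c("A", "C", "G", "T")), 1L, paste, collapse = ""),
      STOP_CODONS)
    body <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
    orf <- paste0("ATG", body, "TAA")
    seq <- paste0(substr(seq, 1L, orf_start - 1L), orf,
                  substring(seq, orf_start + orf_len))
    ip <- if (terminus == "N") orf_start + 2L else
      orf_start + orf_len - 4L  # junction just before the stop codon
    locus <- target_locus(seq, insertion_point = ip,
                          frame_anchor = orf_start, terminus = terminus,
                          contig_id = contig_id)
    attr(locus, "orf_start") <- as.integer(orf_start)
    attr(locus, "orf_end") <- as.integer(orf_start + orf_len - 1L)
    attr(locus, "sim_truth") <- list(kind = "locus", seed = seed,
                                     parameters = list(length = length,
                                                       gc = gc,
                                                       orf_len = orf_len))
    locus
  })
}

#' Plant a cassette insertion into a host sequence
#'
#' Splices `tandem_copies` copies of the cassette block at the junction
#' after `position`, producing the allele pair of an edited individual
#' (heterozygous keeps one wild-type allele) together with the ground
#' truth needed to score callers.
#'
#' @param host Host contig DNA string.
#' @param cassette Cassette block DNA string (or a `tag_cassette`).
#' @param position 1-based index of the last host base before the insert.
#' @param zygosity `"het"` or `"hom"`.
#' @param tandem_copies Number of tandem cassette copies (>= 1);
#'   concatemers model the classic failure mode of injected linear
#'   donors.
#' @return A list of class `planted_insertion` with `alleles` (named
#'   character vector) and `truth` (`position`, `copies`, `zygosity`,
#'   `cassette_len`).
#' @export
plant_insertion <- function(host, cassette, position,
                            zygosity = c("het", "hom"),
                            tandem_copies = 1L) {
  host <- assert_dna(host, "host")
  if (inherits(cassette, "tag_cassette")) cassette <- cassette$block
  cassette <- assert_dna(cassette, "cassette")
  zygosity <- match.arg(zygosity)
  stopifnot(tandem_copies >= 1L, position >= 0L, position <= nchar(host))
  block <- strrep(cassette, tandem_copies)
  edited <- paste0(substr(host, 1L, position), block,
                   substring(host, position + 1L))
  alleles <- if (zygosity == "het")
    c(hap1 = edited, hap2 = host) else c(hap1 = edited, hap2 = edited)
  structure(list(alleles = alleles,
                 truth = list(position = as.integer(position),
                              copies = as.integer(tandem_copies),
                              zygosity = zygosity,
                              cassette_len = nchar(cassette))),
            class = "planted_insertion")
}
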