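# Shared fixtures for the test suite.

## A deterministic tag ORF (ATG ... TAA) of n_codons codons with no
## internal in-frame stop; 240 codons -> 720-nt ORF -> 714-nt cassette.
fix_tag_orf <- function(n_codons = 240L) {
  sense <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1L, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))
  body <- with_seed(299L + n_codons,
                    sample(sense, n_codons - 2L, replace = TRUE))
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

## N-terminal-tag locus reproducing the 5' imprecise-repair geometry:
## the 21-bp duplicated segment sits in the 5' homology arm, ending 22 bp
## upstream of the ATG.  Returns locus, cassette, arms, expected allele,
## and a precise + an imprecise observed read.
fix_junction_5prime <- function() {
  dup21 <- "CGCAACCCTCCACAGAATAAC"
  extra <- "GGTCGAC"
  up <- with_seed(301, random_dna(400, 0.45))
  ## 22-bp spacer between the duplicated segment and the ATG; its first
  ## base differs from both dup21[1] and extra[1] so the inserted segment
  ## parses uniquely
  spacer22 <- "TACCTGAAGGACATCCTTGGAT"
  orf <- fix_tag_orf(34L)                     # 102-nt host ORF
  down <- with_seed(302, random_dna(400, 0.45))
  window <- paste0(up, dup21, spacer22, orf, down)
  fa <- nchar(up) + nchar(dup21) + nchar(spacer22) + 1L   # ATG position
  locus <- target_locus(window, insertion_point = fa + 2L,
                        frame_anchor = fa, terminus = "N",
                        contig_id = "fix5")
  cassette <- build_tag_cassette(fix_tag_orf(240L), "tag")
  arms <- suppressWarnings(extract_homology_arms(locus, 46L, 33L))
  expected <- build_expected_allele(locus, cassette)
  ip <- locus$insertion_point
  edit_gap <- fa - 23L      # last base before the event, 22 bp upstream
  observed_precise <- substr(expected, ip - 80L, ip + 90L)
  observed_dup <- paste0(substr(expected, edit_gap - 80L, edit_gap),
                         dup21, extra,
                         substr(expected, edit_gap + 1L, ip + 80L))
  list(locus = locus, cassette = cassette, arms = arms,
       expected = expected, ip = ip, fa = fa, edit_gap = edit_gap,
       dup21 = dup21, extra = extra,
       observed_precise = observed_precise, observed_dup = observed_dup)
}

## C-terminal-tag locus reproducing the 3' event: a 26-bp segment of the
## 3' homology arm duplicated 4 bp after the stop codon.
fix_junction_3prime <- function() {
  dup26 <- "TTTCCTCGGTGTGGACCTTCCTACTT"
  up <- with_seed(303, random_dna(400, 0.45))
  orf_body <- fix_tag_orf(34L)                # ATG ... TAA, 102 nt
  f4 <- "CAGA"                                # the 4 bp after the stop
  down <- paste0("G", with_seed(304, random_dna(399, 0.45)))
  window <- paste0(up, orf_body, f4, dup26, down)
  s <- nchar(up) + 1L                         # ORF start
  t <- s + nchar(orf_body) - 3L               # stop codon start
  locus <- target_locus(window, insertion_point = t - 1L,
                        frame_anchor = s, terminus = "C",
                        contig_id = "fix3")
  cassette <- build_tag_cassette(fix_tag_orf(240L), "tag")
  arms <- extract_homology_arms(locus, 35L, 33L)
  expected <- build_expected_allele(locus, cassette)
  block_len <- nchar(cassette$block)
  ip <- locus$insertion_point
  fa_exp <- t + block_len                     # stop-codon start in expected
  junction3 <- ip + block_len                 # last block base
  edit_gap <- fa_exp + 2L + 4L                # 4 bp after the stop codon
  observed_dup <- paste0(substr(expected, junction3 - 80L, edit_gap),
                         dup26,
                         substr(expected, edit_gap + 1L, edit_gap + 80L))
  list(locus = locus, cassette = cassette, arms = arms,
       expected = expected, ip = ip, fa_exp = fa_exp,
       junction3 = junction3, edit_gap = edit_gap, dup26 = dup26,
       observed_dup = observed_dup)
}

## Small planted-insertion WGS scene for unit tests (fast).
fix_wgs_scene <- function(host_len = 20000L, position = 9000L,
                          zygosity = "het", copies = 1L, depth = 30,
                          seed = 7L) {
  host <- with_seed(401, random_dna(host_len, 0.45))
  cassette <- with_seed(402, random_dna(714, 0.5))
  planted <- plant_insertion(host, cassette, position, zygosity,
                             tandem_copies = copies)
  reads <- simulate_read_pairs(planted, depth = depth, seed = seed)
  ref <- augment_reference(c(chrH = host), c(cassette = cassette))
  list(host = host, cassette = cassette, planted = planted,
       reads = reads, ref = ref)
}
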