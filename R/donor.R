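#' Extract homology arms around the insertion junction
#'
#' The donor's homology arms are the genomic sequence immediately flanking
#' the insertion junction. Arms of 30-40 bp are the intended regime; other
#' lengths are allowed with a warning so designs can be explored.
#'
#' @param locus A [target_locus()].
#' @param arm_len Arm length in bp (same for both arms unless
#'   `right_len` is given).
#' @param right_len Optional distinct right-arm length.
#' @return List with `left`, `right` arm sequences and their window span.
#' @export
extract_homology_arms <- function(locus, arm_len = 35L, right_len = arm_len) {
  stopifnot(inherits(locus, "target_locus"))
  arm_len <- as.integer(arm_len); right_len <- as.integer(right_len)
  if (arm_len < 1L || right_len < 1L) stop("arm lengths must be positive")
  for (len in unique(c(arm_len, right_len)))
    if (len < 30L || len > 40L)
      warning("arm length ", len, " bp is outside the recommended 30-40 bp",
              call. = FALSE)
  ip <- locus$insertion_point
  n <- nchar(locus$window_seq)
  if (ip - arm_len < 0L)
    stop("left arm extends ", arm_len - ip, " bp beyond the window start",
         call. = FALSE)
  if (ip + right_len > n)
    stop("right arm extends ", ip + right_len - n,
         " bp beyond the window end", call. = FALSE)
  list(left = substring(locus$window_seq, ip - arm_len + 1L, ip),
       right = substring(locus$window_seq, ip + 1L, ip + right_len),
       left_start = ip - arm_len + 1L, right_end = ip + right_len)
}

#' Build an in-frame tag cassette from a fluorophore ORF
#'
#' Strips the leading ATG and the trailing stop codon from the tag open
#' reading frame (for both N- and C-terminal designs: the donor cassettes
#' carry neither) and attaches optional linkers. The resulting block must
#' be a whole number of codons with no internal in-frame stop.
#'
#' @param raw_orf DNA string: the tag ORF (`ATG ... stop`) or an
#'   already-trimmed coding sequence.
#' @param name Cassette name (e.g. `"eGFP"`).
#' @param linker_5,linker_3 Optional linker sequences placed 5' and 3' of
#'   the tag within the cassette block.
#' @return An object of class `tag_cassette` with fields `name`, `seq`
#'   (trimmed tag), `linker_5`, `linker_3` and `block` (the full
#'   linker + tag + linker insert).
#' @export
build_tag_cassette <- function(raw_orf, name = "tag",
                               linker_5 = "", linker_3 = "") {
  raw_orf <- assert_dna(raw_orf, "raw_orf")
  if (nchar(raw_orf) < 6L) stop("tag ORF is shorter than 6 nt")
  if (nchar(linker_5)) linker_5 <- assert_dna(linker_5, "linker_5")
  if (nchar(linker_3)) linker_3 <- assert_dna(linker_3, "linker_3")
  seq <- raw_orf
  if (substr(seq, 1L, 3L) == "ATG") seq <- substring(seq, 4L)
  if (nchar(seq) %% 3L == 0L &&
      substring(seq, nchar(seq) - 2L) %in% STOP_CODONS)
    seq <- substr(seq, 1L, nchar(seq) - 3L)
  block <- paste0(linker_5, seq, linker_3)
  if (nchar(block) %% 3L != 0L)
    stop("cassette block length (", nchar(block),
         ") is not divisible by 3; adjust linkers", call. = FALSE)
  if (has_inframe_stop(block))
    stop("cassette block contains an in-frame stop codon", call. = FALSE)
  structure(list(name = name, seq = seq, linker_5 = linker_5,
                 linker_3 = linker_3, block = block),
            class = "tag_cassette")
}

## The full insert block of a cassette (or "" for NULL).
cassette_block <- function(cassette) {
  if (is.null(cassette)) "" else cassette$block
}

#' Expected HDR allele of a locus and cassette
#'
#' The locus window with the cassette block spliced at the insertion
#' junction: what a precise homology-directed repair event produces.
#'
#' @param locus A [target_locus()].
#' @param cassette A [build_tag_cassette()] result, a `donor_design`, or
#'   `NULL` (identity edit).
#' @return DNA string of the edited window.
#' @export
build_expected_allele <- function(locus, cassette = NULL) {
  stopifnot(inherits(locus, "target_locus"))
  if (inherits(cassette, "donor_design")) cassette <- cassette$cassette
  block <- cassette_block(cassette)
  ip <- locus$insertion_point
  paste0(substr(locus$window_seq, 1L, ip), block,
         substring(locus$window_seq, ip + 1L))
}

#' Assemble a knock-in donor from arms and cassette
#'
#' `donor_seq = left_arm + cassette block + right_arm`. The simulated HDR
#' allele is checked to stay in frame across both junctions (the block is a
#' whole number of codons and introduces no in-frame stop).
#'
#' @param locus A [target_locus()].
#' @param arms Result of [extract_homology_arms()] on the same locus.
#' @param cassette A [build_tag_cassette()] result (or `NULL` for the
#'   identity edit).
#' @return An object of class `donor_design`.
#' @export
assemble_donor <- function(locus, arms, cassette = NULL) {
  stopifnot(inherits(locus, "target_locus"), is.list(arms))
  ip <- locus$insertion_point
  if (substr(locus$window_seq, ip - nchar(arms$left) + 1L, ip) != arms$left ||
      substring(locus$window_seq, ip + 1L,
                ip + nchar(arms$right)) != arms$right)
    stop("arms do not match the locus at its insertion point", call. = FALSE)
  block <- cassette_block(cassette)
  if (nchar(block) %% 3L != 0L)
    stop("cassette block is not a whole number of codons", call. = FALSE)
  ## frame check across the junction: the block occupies whole codons of
  ## the edited reading frame and must not introduce a stop
  if (nchar(block) && has_inframe_stop(block))
    stop("cassette block introduces an in-frame stop codon", call. = FALSE)
  donor_seq <- paste0(arms$left, block, arms$right)
  structure(
    list(left_arm = arms$left, right_arm = arms$right, cassette = cassette,
         donor_seq = donor_seq, length = nchar(donor_seq),
         locus_coordinate = locus_genomic_coordinate(locus),
         contig_id = locus$contig_id),
    class = "donor_design")
}

#' @export
print.donor_design <- function(x, ...) {
  cat("<donor_design> ", x$length, " bp: ", nchar(x$left_arm), " bp arm + ",
      nchar(cassette_block(x$cassette)), " bp cassette + ",
      nchar(x$right_arm), " bp arm\n", sep = "")
  invisible(x)
}

#' Molar concentration of a linear dsDNA donor
#'
#' Converts a mass concentration to molarity using a mean double-stranded
#' base-pair mass of 650 g/mol/bp. A small mass of a short PCR donor
#' yields many molecules: 10 ng/ul of a 780-bp donor is about 20 nM.
#'
#' @param mass_conc Mass concentration in ng/ul.
#' @param length_bp Donor length in bp.
#' @param bp_mass Mean bp mass in g/mol (default 650).
#' @return Molarity in nM.
#' @export
donor_molarity <- function(mass_conc, length_bp, bp_mass = 650) {
  if (any(mass_conc <= 0) || any(length_bp <= 0) || bp_mass <= 0)
    stop("mass_conc, length_bp and bp_mass must be positive", call. = FALSE)
  mass_conc * 1e6 / (length_bp * bp_mass)
}

#' Injection mix recipe (metadata)
#'
#' Records the standard one-cell-stage injection mix; warns when a
#' component leaves its recommended range (sgRNA 15-20, Cas9 mRNA 150,
#' donor 8-10 ng/ul).
#'
#' @param sgRNA_ng_per_ul,cas9_mRNA_ng_per_ul,donor_ng_per_ul Component
#'   concentrations in ng/ul.
#' @return A named list of class `mix_recipe`.
#' @export
mix_recipe <- function(sgRNA_ng_per_ul = 17.5, cas9_mRNA_ng_per_ul = 150,
                       donor_ng_per_ul = 9) {
  check <- function(x, lo, hi, what) {
    if (x < lo || x > hi)
      warning(what, " = ", x, " ng/ul is outside the recommended ",
              lo, "-", hi, " ng/ul", call. = FALSE)
  }
  check(sgRNA_ng_per_ul, 15, 20, "sgRNA")
  check(cas9_mRNA_ng_per_ul, 150, 150, "Cas9 mRNA")
  check(donor_ng_per_ul, 8, 10, "donor")
  structure(list(sgRNA_ng_per_ul = sgRNA_ng_per_ul,
                 cas9_mRNA_ng_per_ul = cas9_mRNA_ng_per_ul,
                 donor_ng_per_ul = donor_ng_per_ul),
            class = "mix_recipe")
}
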