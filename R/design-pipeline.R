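#' One-stop knock-in donor design
#'
#' Runs the full design arithmetic for a locus and tag: homology arms,
#' in-frame cassette, donor assembly, biotinylated donor primers, external
#' genotyping primers, guide-candidate scan, and donor molarity at the
#' standard injection concentration.
#'
#' @param locus A [target_locus()].
#' @param tag_orf Tag ORF sequence (see [build_tag_cassette()]).
#' @param tag_name Cassette name.
#' @param arm_len Homology arm length (30-40 bp recommended).
#' @param linker_5,linker_3 Optional linkers.
#' @param guide_radius Cut-site search radius around the junction.
#' @param donor_ng_per_ul Donor concentration used for the molarity report.
#' @return A list of class `ki_design` with components `locus`, `arms`,
#'   `cassette`, `donor`, `donor_primers`, `genotyping_primers`, `guides`,
#'   `molarity_nM`, `mix`, and `hdr_allele`.
#' @export
design_knockin <- function(locus, tag_orf, tag_name = "tag", arm_len = 35L,
                           linker_5 = "", linker_3 = "",
                           guide_radius = 50L, donor_ng_per_ul = 9) {
  cassette <- build_tag_cassette(tag_orf, tag_name, linker_5, linker_3)
  arms <- extract_homology_arms(locus, arm_len)
  donor <- assemble_donor(locus, arms, cassette)
  structure(
    list(locus = locus, arms = arms, cassette = cassette, donor = donor,
         donor_primers = design_donor_primers(donor),
         genotyping_primers = tryCatch(
           design_genotyping_primers(locus, arms, cassette),
           error = function(e) NULL),
         guides = find_protospacers(locus, guide_radius),
         molarity_nM = donor_molarity(donor_ng_per_ul, donor$length),
         mix = mix_recipe(donor_ng_per_ul = donor_ng_per_ul),
         hdr_allele = build_expected_allele(locus, cassette)),
    class = "ki_design")
}

#' Primer table of a design
#'
#' @param design A [design_knockin()] result.
#' @return Data frame with one row per primer: name, sequence, 5'
#'   modification, purpose, predicted amplicons.
#' @export
primer_table <- function(design) {
  rows <- list()
  add <- function(pp, prefix) {
    if (is.null(pp)) return()
    wt <- pp$predicted_wt_amplicon_bp %||% NA_integer_
    ki <- pp$predicted_ki_amplicon_bp %||% NA_integer_
    rows[[length(rows) + 1L]] <<- data.frame(
      name = paste0(prefix, c("_fwd", "_rev")),
      sequence = c(pp$fwd_seq, pp$rev_seq),
      mod_5prime = ifelse(c(pp$fwd_biotin, pp$rev_biotin), "Biotin", "none"),
      purpose = pp$purpose,
      predicted_wt_amplicon_bp = wt,
      predicted_ki_amplicon_bp = ki,
      stringsAsFactors = FALSE)
  }
  add(design$donor_primers, "donor")
  add(design$genotyping_primers, "genotyping")
  do.call(rbind, rows)
}

#' Write design outputs
#'
#' Writes the donor FASTA, the primer TSV, and a JSON design report
#' (including the injection-mix defaults) into `dir`.
#'
#' @param design A [design_knockin()] result.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_design_report <- function(design, dir, prefix = "ki_design") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, "_donor.fa"))
  write_fasta(setNames(design$donor$donor_seq,
                       paste0(prefix, "_donor_", design$donor$length, "bp")),
              fa)
  tsv <- file.path(dir, paste0(prefix, "_primers.tsv"))
  write.table(primer_table(design), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  js <- file.path(dir, paste0(prefix, "_report.json"))
  report <- list(
    contig = design$locus$contig_id,
    insertion_coordinate = locus_genomic_coordinate(design$locus),
    terminus = design$locus$terminus,
    cassette = list(name = design$cassette$name,
                    block_bp = nchar(design$cassette$block)),
    arms_bp = c(left = nchar(design$donor$left_arm),
                right = nchar(design$donor$right_arm)),
    donor_bp = design$donor$length,
    molarity_nM = design$molarity_nM,
    mix_ng_per_ul = unclass(design$mix),
    n_guides = nrow(design$guides),
    best_guide = if (nrow(design$guides))
      as.list(design$guides[1, c("spacer", "pam", "strand", "distance")])
      else NULL)
  jsonlite::write_json(report, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(donor_fasta = fa, primer_tsv = tsv, report_json = js))
}
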