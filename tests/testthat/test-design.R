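test_that("cut_site_of follows the blunt-cut rule on both strands", {
  expect_identical(cut_site_of(1L, "+"), 17L)
  expect_identical(cut_site_of(101L, "+"), 117L)
  ## reverse-complement symmetry: a minus-strand protospacer at footprint
  ## start s in a window of length n corresponds, after revcomp, to a
  ## plus-strand protospacer at n - (s + 19) + 1; cut offsets must mirror
  n <- 100L
  s <- 31L
  cut_minus <- cut_site_of(s, "-")
  s_rc <- n - (s + 19L) + 1L
  cut_plus_rc <- cut_site_of(s_rc, "+")
  expect_identical(cut_minus, n - cut_plus_rc)
})

test_that("find_protospacers matches a brute-force scan", {
  win <- with_seed(501, random_dna(400, 0.5))
  locus <- target_locus(win, insertion_point = 201L, frame_anchor = 199L,
                        terminus = "N")
  got <- find_protospacers(locus, search_radius = 60L)
  ## brute force: every 23-mer on both strands
  chars <- strsplit(win, "")[[1]]
  brute <- list()
  for (s in seq_len(nchar(win) - 22L)) {
    if (chars[s + 21L] == "G" && chars[s + 22L] == "G") {
      cut <- s + 16L
      if (abs(cut - 201L) <= 60L)
        brute[[length(brute) + 1L]] <- c(substr(win, s, s + 19L), "+", cut)
    }
    if (chars[s] == "C" && chars[s + 1L] == "C") {
      cut <- (s + 3L) + 2L
      if (abs(cut - 201L) <= 60L)
        brute[[length(brute) + 1L]] <-
          c(revcomp(substr(win, s + 3L, s + 22L)), "-", cut)
    }
  }
  brute <- do.call(rbind, brute)
  expect_equal(nrow(got), nrow(brute))
  key <- function(sp, st, cut) paste(sp, st, cut)
  expect_setequal(key(got$spacer, got$strand, got$cut_site),
                  key(brute[, 1], brute[, 2], brute[, 3]))
  expect_true(!is.unsorted(abs(got$distance)))
})

test_that("protospacer scan returns empty on AT-only windows", {
  win <- strrep("AT", 150)
  locus <- target_locus(win, insertion_point = 150L, frame_anchor = 148L,
                        terminus = "N")
  expect_identical(nrow(find_protospacers(locus)), 0L)
})

test_that("homology arms reconstruct the genomic span and warn off-range", {
  win <- with_seed(502, random_dna(80, 0.5))
  locus <- target_locus(win, insertion_point = 40L, frame_anchor = 38L,
                        terminus = "N")
  arms <- extract_homology_arms(locus, 35L)
  expect_identical(nchar(arms$left), 35L)
  expect_identical(nchar(arms$right), 35L)
  expect_identical(paste0(arms$left, arms$right), substr(win, 6L, 75L))
  expect_warning(extract_homology_arms(locus, 29L), "30-40")
  expect_warning(a41 <- extract_homology_arms(locus, 40L, 40L), NA)
  expect_error(suppressWarnings(extract_homology_arms(locus, 41L)),
               "beyond the window")
})

test_that("build_tag_cassette strips ATG and stop and enforces frame", {
  orf <- fix_tag_orf(240L)
  expect_identical(nchar(orf), 720L)
  cas <- build_tag_cassette(orf, "tag")
  expect_identical(nchar(cas$block), 714L)
  expect_identical(cas$block, substr(orf, 4L, 717L))
  ## trimmed block has no in-frame stop by construction
  codons <- substring(cas$block, seq(1, 712, 3), seq(3, 714, 3))
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  ## internal in-frame stop -> error
  bad <- paste0("ATG", "GCTTGAGCT", "TAA")
  expect_error(build_tag_cassette(bad), "stop codon")
  ## 714-nt cassette + 6-nt linker -> 720, still a whole number of codons
  cas2 <- build_tag_cassette(orf, "tag", linker_5 = "GGTGGA")
  expect_identical(nchar(cas2$block), 720L)
  ## off-frame linker -> error
  expect_error(build_tag_cassette(orf, "tag", linker_5 = "GG"),
               "divisible by 3")
})

test_that("assemble_donor produces arm+cassette+arm and the identity edit", {
  win <- with_seed(503, random_dna(300, 0.5))
  locus <- target_locus(win, insertion_point = 150L, frame_anchor = 142L,
                        terminus = "N")
  cas <- build_tag_cassette(fix_tag_orf(240L))
  arms <- extract_homology_arms(locus, 33L)
  donor <- assemble_donor(locus, arms, cas)
  expect_identical(donor$length, 33L + 714L + 33L)
  expect_identical(donor$donor_seq, paste0(arms$left, cas$block, arms$right))
  ## HDR allele length and arm flanking
  hdr <- build_expected_allele(locus, cas)
  expect_identical(nchar(hdr), nchar(win) + 714L)
  expect_true(grepl(donor$donor_seq, hdr, fixed = TRUE))
  ## empty cassette is the identity edit
  expect_identical(build_expected_allele(locus, NULL), win)
  d0 <- assemble_donor(locus, arms, NULL)
  expect_identical(d0$donor_seq, paste0(arms$left, arms$right))
  ## arms from a different locus -> error
  locus2 <- target_locus(win, insertion_point = 153L, frame_anchor = 142L,
                         terminus = "N")
  expect_error(assemble_donor(locus2, arms, cas), "do not match")
})

test_that("donor primers carry arm tails, biotin, and amplify the donor", {
  win <- with_seed(504, random_dna(300, 0.5))
  locus <- target_locus(win, insertion_point = 150L, frame_anchor = 142L,
                        terminus = "N")
  cas <- build_tag_cassette(fix_tag_orf(240L))
  arms <- extract_homology_arms(locus, 33L)
  donor <- assemble_donor(locus, arms, cas)
  pp <- design_donor_primers(donor)
  expect_true(pp$fwd_biotin && pp$rev_biotin)
  expect_true(startsWith(pp$fwd_seq, arms$left))
  expect_true(endsWith(revcomp(pp$rev_seq), arms$right))
  expect_true(pp$fwd_anneal_len >= 18L && pp$fwd_anneal_len <= 25L)
  ## in-silico PCR on the cassette template reproduces donor_seq exactly
  expect_identical(simulate_pcr(cas$block, pp$fwd_seq, pp$rev_seq),
                   donor$donor_seq)
})

test_that("genotyping primers sit outside the footprint with the right delta", {
  win <- with_seed(505, random_dna(500, 0.5))
  locus <- target_locus(win, insertion_point = 250L, frame_anchor = 248L,
                        terminus = "N")
  cas <- build_tag_cassette(fix_tag_orf(240L))
  arms <- extract_homology_arms(locus, 33L)
  donor <- assemble_donor(locus, arms, cas)
  gp <- design_genotyping_primers(locus, arms, cas)
  expect_identical(gp$predicted_ki_amplicon_bp - gp$predicted_wt_amplicon_bp,
                   714L)
  ## strictly outside the donor footprint
  expect_lt(gp$fwd_start + 19L, arms$left_start)
  expect_gt(gp$rev_end - 19L, arms$right_end)
  ## primers are not substrings of the donor
  expect_false(grepl(gp$fwd_seq, donor$donor_seq, fixed = TRUE))
  expect_false(grepl(revcomp(gp$rev_seq), donor$donor_seq, fixed = TRUE))
  ## in-silico PCR on WT and HDR alleles gives the predicted lengths
  wt <- simulate_pcr(win, gp$fwd_seq, gp$rev_seq)
  ki <- simulate_pcr(build_expected_allele(locus, cas), gp$fwd_seq,
                     gp$rev_seq)
  expect_identical(nchar(wt), gp$predicted_wt_amplicon_bp)
  expect_identical(nchar(ki), gp$predicted_ki_amplicon_bp)
  ## insufficient flank -> boundary error
  narrow <- target_locus(substr(win, 200, 300), insertion_point = 51L,
                         frame_anchor = 49L, terminus = "N")
  arms_n <- extract_homology_arms(narrow, 33L)
  expect_error(design_genotyping_primers(narrow, arms_n, cas), "flank")
})

test_that("donor molarity matches the closed form and is monotone", {
  expect_equal(donor_molarity(0.650, 1000), 1.0, tolerance = 1e-9)
  expect_equal(donor_molarity(10, 780), 10 * 1e6 / (780 * 650),
               tolerance = 1e-9)
  expect_equal(donor_molarity(10, 1560), donor_molarity(10, 780) / 2,
               tolerance = 1e-9)
  lens <- seq(100, 5000, by = 100)
  expect_true(all(diff(donor_molarity(10, lens)) < 0))
  expect_error(donor_molarity(-1, 780), "positive")
  expect_error(donor_molarity(10, 0), "positive")
})

test_that("mix recipe warns outside the recommended ranges", {
  expect_warning(mix_recipe(), NA)
  expect_warning(mix_recipe(sgRNA_ng_per_ul = 25), "sgRNA")
  expect_warning(mix_recipe(donor_ng_per_ul = 12), "donor")
})
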