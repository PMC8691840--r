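test_that("simulate_locus is deterministic with a well-formed ORF", {
  l1 <- simulate_locus(length = 3000L, seed = 42L)
  l2 <- simulate_locus(length = 3000L, seed = 42L)
  expect_identical(l1$window_seq, l2$window_seq)
  expect_identical(nchar(l1$window_seq), 3000L)
  os <- attr(l1, "orf_start"); oe <- attr(l1, "orf_end")
  orf <- substr(l1$window_seq, os, oe)
  expect_identical(substr(orf, 1L, 3L), "ATG")
  expect_true(substr(orf, nchar(orf) - 2L, nchar(orf)) %in%
                c("TAA", "TAG", "TGA"))
  codons <- substring(orf, seq(4L, nchar(orf) - 5L, 3L),
                      seq(6L, nchar(orf) - 3L, 3L))
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  ## N geometry: junction right after the start codon
  expect_identical(l1$insertion_point, os + 2L)
  expect_identical(l1$frame_anchor, os)
  ## gc = 0 background is AT-only outside the ORF
  l0 <- simulate_locus(length = 600L, gc = 0, orf_len = 30L, seed = 2L)
  flank <- paste0(substr(l0$window_seq, 1L, attr(l0, "orf_start") - 1L),
                  substring(l0$window_seq, attr(l0, "orf_end") + 1L))
  expect_false(grepl("[GC]", flank))
})

test_that("plant_insertion splices exactly where a string search finds it", {
  host <- with_seed(411, random_dna(5000, 0.45))
  cas <- with_seed(412, random_dna(714, 0.5))
  pl <- plant_insertion(host, cas, 2500L, "het", tandem_copies = 2L)
  ed <- pl$alleles[["hap1"]]
  expect_identical(nchar(ed), 5000L + 2L * 714L)
  expect_identical(pl$alleles[["hap2"]], host)
  ## string-search oracle for the splice point
  hit <- regexpr(strrep(cas, 2L), ed, fixed = TRUE)
  expect_identical(as.integer(hit), 2501L)
  expect_identical(substr(ed, 1L, 2500L), substr(host, 1L, 2500L))
  expect_identical(substring(ed, 2501L + 2L * 714L), substring(host, 2501L))
  expect_identical(pl$truth$position, 2500L)
  expect_identical(pl$truth$copies, 2L)
  ## hom plants on both alleles
  hom <- plant_insertion(host, cas, 2500L, "hom")
  expect_identical(hom$alleles[["hap1"]], hom$alleles[["hap2"]])
})

test_that("read-pair counts follow the depth formula and splits evenly", {
  host <- with_seed(413, random_dna(30000, 0.5))
  rp <- simulate_read_pairs(c(a = host, b = host), depth = 20,
                            error_rate = 0, seed = 3L)
  expected_per_allele <- round((20 / 2) * 30000 / (2 * 150))
  tab <- table(rp$pairs$allele)
  expect_identical(as.integer(tab[["a"]]), as.integer(expected_per_allele))
  expect_identical(as.integer(tab[["b"]]), as.integer(expected_per_allele))
})

test_that("error-free reads are exact substrings at their truth positions", {
  host <- with_seed(414, random_dna(12000, 0.5))
  rp <- simulate_read_pairs(c(h = host), depth = 6, error_rate = 0,
                            seed = 4L)
  p <- rp$pairs
  expect_identical(p$read1,
                   substring(host, p$frag_start, p$frag_start + 149L))
  expect_identical(p$read2,
                   vapply(seq_len(nrow(p)), function(i)
                     revcomp(substring(host,
                                       p$frag_start[i] + p$frag_len[i] - 150L,
                                       p$frag_start[i] + p$frag_len[i] - 1L)),
                     character(1)))
  expect_true(all(nchar(p$read1) == 150L))
})

test_that("the substitution error rate is realized near its target", {
  host <- with_seed(415, random_dna(50000, 0.5))
  clean <- simulate_read_pairs(c(h = host), depth = 10, error_rate = 0,
                               seed = 5L)
  noisy <- simulate_read_pairs(c(h = host), depth = 10, error_rate = 0.001,
                               seed = 5L)
  mism <- function(a, b) sum(vapply(seq_along(a), function(i)
    sum(strsplit(a[i], "")[[1]] != strsplit(b[i], "")[[1]]), numeric(1)))
  n_err <- mism(clean$pairs$read1, noisy$pairs$read1) +
    mism(clean$pairs$read2, noisy$pairs$read2)
  total <- sum(nchar(noisy$pairs$read1)) + sum(nchar(noisy$pairs$read2))
  ## binomial(total, 0.001): mean 500-ish, check within 4 SDs
  expect_gt(n_err, 0.001 * total - 4 * sqrt(0.001 * total))
  expect_lt(n_err, 0.001 * total + 4 * sqrt(0.001 * total))
})

test_that("FASTQ round-trip preserves ids and sequences", {
  host <- with_seed(416, random_dna(6000, 0.5))
  rp <- simulate_read_pairs(c(h = host), depth = 4, seed = 6L)
  prefix <- tempfile("rt")
  paths <- write_fastq(rp, prefix)
  back <- read_fastq_pairs(paths[1], paths[2])
  expect_identical(back$pairs$id, rp$pairs$id)
  expect_identical(back$pairs$read1, rp$pairs$read1)
  expect_identical(back$pairs$read2, rp$pairs$read2)
  unlink(paths)
})

test_that("movie ROI means track the programmed intensity model", {
  m <- simulate_nucleus_movie(make_phase_schedule(30L, 20L, 26L, 6L),
                              seed = 9L)
  tr <- extract_trace(m$movie, m$roi)
  ## frames without speckles or dispersion: ROI mean within a CLT bound
  plain <- which(m$truth$labels == "S" & m$truth$disp == 0)
  bound <- 3 * 25 / sqrt(m$truth$n_px) + 0.5  # noise CLT + rounding
  expect_true(all(abs(tr$I[plain] - m$truth$mu[plain]) < bound))
  ## the programmed dispersion profile peaks exactly at the S/G2 frame
  expect_identical(which.max(m$truth$disp), m$truth$t_sg2)
  ## M frames drop the mean sharply
  expect_lt(tr$I[m$truth$t_m + 1L], 0.5 * tr$I[m$truth$t_m - 1L])
})

test_that("a noise-free G1 track decays strictly monotonically", {
  m <- simulate_nucleus_movie(rep("G1", 15L), noise_sd = 0, seed = 10L)
  tr <- extract_trace(m$movie, m$roi)
  expect_true(all(diff(tr$I) < 0))
  expect_equal(tr$I[1], 3000, tolerance = 1)
})

test_that("movie TIFF and ROI TSV round-trips are lossless", {
  m <- simulate_nucleus_movie(make_phase_schedule(12L, 8L, 11L, 3L),
                              img_size = 32L, roi_radius = 6, seed = 11L)
  tf <- tempfile(fileext = ".tif")
  write_movie_tiff(m$movie, tf)
  back <- read_movie_tiff(tf, frame_interval = 20)
  expect_identical(length(back$frames), length(m$movie$frames))
  for (f in seq_along(back$frames))
    expect_equal(back$frames[[f]], m$movie$frames[[f]], tolerance = 1e-9)
  rf <- tempfile(fileext = ".tsv")
  write_roi_tsv(m$roi, rf)
  roi2 <- read_roi_tsv(rf)
  expect_equal(roi2$cx, m$roi$cx)
  expect_equal(roi2$r, m$roi$r)
  unlink(c(tf, rf))
})

test_that("schedule construction validates its landmarks", {
  s <- make_phase_schedule(68L, 48L, 61L, 14L)
  expect_identical(length(s), 68L)
  expect_identical(max(which(s %in% c("S", "lateS"))), 48L)
  expect_identical(which(s == "M")[1], 61L)
  expect_identical(sum(s == "lateS"), 14L)
  expect_error(make_phase_schedule(68L, 48L, 40L), "t_m > t_sg2")
  expect_error(simulate_nucleus_movie(c("S", "X", "G2")), "schedule")
})
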