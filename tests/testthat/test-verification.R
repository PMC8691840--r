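test_that("augment_reference rejects name collisions and tracks contigs", {
  ref <- augment_reference(c(chrA = "ACGTACGTAC"), c(cas = "GGGCCC"))
  expect_identical(ref$host_names, "chrA")
  expect_identical(ref$insert_names, "cas")
  expect_true(is_insert_contig(ref, "cas"))
  expect_false(is_insert_contig(ref, "chrA"))
  expect_error(augment_reference(c(x = "ACGT"), c(x = "GGCC")), "duplicate")
  expect_error(augment_reference("ACGT", c(cas = "GGCC")), "named")
})

test_that("anchor pairs match an exhaustive per-pair scan", {
  sc <- fix_wgs_scene(host_len = 12000L, position = 6000L, depth = 16,
                      seed = 21L)
  aln <- map_reads_naive(sc$reads, sc$ref)
  got <- collect_anchor_pairs(aln, sc$ref, min_mapq = 20L)
  ## oracle: for every read pair with both mates mapped at MAPQ >= 20,
  ## keep it iff exactly one mate is on the insert contig
  ok <- !aln$unmapped & aln$mapq >= 20L
  expected <- character(0)
  for (qn in unique(aln$qname)) {
    rows <- aln[aln$qname == qn & ok, , drop = FALSE]
    if (nrow(rows) != 2L) next
    if (sum(is_insert_contig(sc$ref, rows$contig)) == 1L)
      expected <- c(expected, qn)
  }
  expect_setequal(got$qname, expected)
  expect_gt(nrow(got), 0L)
  ## side comes from the host-mate orientation
  expect_identical(got$side, ifelse(got$host_strand == "+", "left", "right"))
  ## left anchors sit before the junction, right anchors after it
  expect_true(all(got$host_end[got$side == "left"] <= 6000L + 60L))
  expect_true(all(got$host_pos[got$side == "right"] >= 6000L - 60L))
})

test_that("cluster_anchors agrees with all-pairs single linkage", {
  ## synthetic anchors: three groups on one contig/side plus a second side
  mk <- function(pos, side) {
    data.frame(qname = sprintf("%s_%d", side, seq_along(pos)),
               insert_name = "cas", insert_pos = 1L,
               host_contig = "chrH", host_pos = as.integer(pos),
               host_end = as.integer(pos + 149L), host_strand =
                 if (side == "left") "+" else "-",
               side = side, stringsAsFactors = FALSE)
  }
  pos_l <- with_seed(31, sort(c(sample(1000:1800, 40, replace = TRUE),
                                sample(5000:5600, 30, replace = TRUE),
                                sample(9000:9100, 5, replace = TRUE))))
  pos_r <- with_seed(32, sort(sample(2000:2900, 25, replace = TRUE)))
  anchors <- rbind(mk(pos_l, "left"), mk(pos_r, "right"))
  w <- 300L
  got <- cluster_anchors(anchors, cluster_window = w, min_support = 1L)
  ## oracle: union-find over all pairs on the same contig/side within w
  n <- nrow(anchors)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (anchors$side[i] == anchors$side[j] &&
        anchors$host_contig[i] == anchors$host_contig[j] &&
        abs(anchors$host_pos[i] - anchors$host_pos[j]) <= w) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  oracle <- split(anchors$qname, roots)
  oracle_keys <- sort(vapply(oracle, function(m)
    paste(sort(m), collapse = ","), character(1)))
  got_keys <- sort(vapply(got$members, function(m)
    paste(sort(m), collapse = ","), character(1)))
  expect_identical(got_keys, unname(oracle_keys))
  ## cluster bounds and support are consistent with their members
  for (k in seq_len(nrow(got))) {
    m <- anchors[anchors$qname %in% got$members[[k]], ]
    expect_identical(got$lo[k], min(m$host_pos))
    expect_identical(got$hi[k], max(m$host_pos))
    expect_identical(got$support[k], nrow(m))
  }
})

test_that("weak clusters are tallied as subthreshold, not called", {
  anchors <- data.frame(
    qname = c("a", "b", "c", "d", "e"),
    insert_name = "cas", insert_pos = 1L, host_contig = "chrH",
    host_pos = c(1000L, 1050L, 1100L, 7000L, 7040L),
    host_end = c(1000L, 1050L, 1100L, 7000L, 7040L) + 149L,
    host_strand = "+", side = "left", stringsAsFactors = FALSE)
  cl <- cluster_anchors(anchors, cluster_window = 500L, min_support = 3L)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$support, 3L)
  sub <- attr(cl, "subthreshold")
  expect_identical(nrow(sub), 1L)
  expect_identical(sub$support, 2L)
  expect_identical(sub$lo, 7000L)
  ## no anchors at all -> empty frame with empty diagnostics
  cl0 <- cluster_anchors(anchors[0, ], cluster_window = 500L)
  expect_identical(nrow(cl0), 0L)
  expect_identical(nrow(attr(cl0, "subthreshold")), 0L)
})

test_that("joint resolution disambiguates micro-homologous junctions", {
  ## craft host/insert so the left-junction evidence alone is ambiguous:
  ## ins[1] equals the host base at the planted coordinate p, so a
  ## right-clip at p is consistent with both p and p-1
  p <- 100L
  host <- with_seed(41, random_dna(300, 0.5))
  ins <- with_seed(42, random_dna(20, 0.5))
  substr(host, p, p) <- substr(ins, 1L, 1L)
  ## suppress accidental homology elsewhere around the junction
  bad <- c(substr(ins, 1L, 1L), substr(ins, 20L, 20L))
  pick <- setdiff(c("A", "C", "G", "T"), bad)[1]
  substr(host, p + 1L, p + 1L) <- pick  # no right extension, no PL growth
  substr(host, p - 1L, p - 1L) <-
    setdiff(c("A", "C", "G", "T"), c(substr(ins, 1L, 1L),
                                     substr(ins, 19L, 19L)))[1]
  qR <- p   # no mapper extension rightward
  qL <- p   # no mapper extension leftward
  got <- crisprki:::resolve_junction(qR, qL, host, ins)
  expect_identical(got, p)
  ## one-sided right-clip evidence alone would have left-aligned to p-1
  expect_identical(crisprki:::resolve_junction(qR, NA_integer_, host, ins),
                   p - 1L)
})

test_that("end-to-end verification recovers the planted junction exactly", {
  sc <- fix_wgs_scene(host_len = 20000L, position = 9000L, depth = 30,
                      seed = 7L)
  res <- verify_wgs(sc$ref, reads = sc$reads)
  expect_s3_class(res$calls, "integration_calls")
  expect_identical(nrow(res$calls), 1L)
  expect_identical(res$calls$coordinate, 9000L)
  expect_identical(res$calls$host_contig, "chrH")
  expect_identical(res$calls$insert_name, "cassette")
  expect_false(res$calls$one_sided)
  expect_gt(res$calls$split_support, 0L)
  expect_gte(res$calls$left_support, 3L)
  expect_gte(res$calls$right_support, 3L)
})

test_that("no calls arise from an insertion-free genome", {
  host <- with_seed(403, random_dna(20000, 0.45))
  cassette <- with_seed(404, random_dna(714, 0.5))
  reads <- simulate_read_pairs(c(hap1 = host, hap2 = host), depth = 20,
                               seed = 8L)
  ref <- augment_reference(c(chrH = host), c(cassette = cassette))
  res <- verify_wgs(ref, reads = reads)
  expect_identical(nrow(res$calls), 0L)
})

test_that("depth ratio separates het single copy from concatemers", {
  run <- function(copies, zygosity, seed) {
    sc <- fix_wgs_scene(host_len = 20000L, position = 9000L,
                        zygosity = zygosity, copies = copies,
                        depth = 30, seed = seed)
    verify_wgs(sc$ref, reads = sc$reads)$calls
  }
  het <- run(1L, "het", 9L)
  expect_identical(het$copy_class, "single_copy_het")
  expect_gt(het$depth_ratio, 0.25)
  expect_lt(het$depth_ratio, 0.75)
  hom <- run(1L, "hom", 10L)
  expect_gt(hom$depth_ratio, 0.75)
  expect_identical(hom$copy_class, "multi_copy_or_concatemer")
  concat <- run(3L, "het", 11L)
  expect_gt(concat$depth_ratio, 0.75)
  expect_identical(concat$copy_class, "multi_copy_or_concatemer")
  ## concatemer host-level junction coordinate is still exact
  expect_identical(concat$coordinate, 9000L)
})

test_that("copy-number assessment needs host coverage", {
  ref <- augment_reference(c(chrH = with_seed(405, random_dna(2000, 0.5))),
                           c(cas = with_seed(406, random_dna(714, 0.5))))
  aln <- data.frame(qname = "r1", mate = 1L, contig = "cas", pos = 1L,
                    strand = "+", mapq = 60L, qstart = 1L, qend = 150L,
                    aln_len = 150L, read_len = 150L, nm = 0L,
                    cigar = "150M", unmapped = FALSE,
                    stringsAsFactors = FALSE)
  calls <- data.frame(insert_name = "cas", host_contig = "chrH",
                      coordinate = 1000L, left_support = 3L,
                      right_support = 3L, split_support = 2L,
                      one_sided = FALSE, stringsAsFactors = FALSE)
  expect_error(assess_copy_number(aln, calls, ref), "host depth")
})

test_that("verify_wgs demands evidence input", {
  ref <- augment_reference(c(chrH = "ACGTACGTACGT"), c(cas = "GGTT"))
  expect_error(verify_wgs(ref), "alignments or reads")
})
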