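#' Map read pairs to an augmented reference (naive seed-and-extend)
#'
#' A deliberately simple mapper for synthetic, low-error libraries: exact
#' k-mer seeds vote on a diagonal, the best diagonal is extended ungapped
#' (match +1, mismatch -3), and the maximum-scoring run is kept, so a read
#' spanning a junction absent from the reference is soft-clipped at the
#' junction. Real data should be aligned externally and ingested via
#' [read_sam()].
#'
#' @param reads A `read_pairs` object from [simulate_read_pairs()], or a
#'   data frame with columns `id`, `read1`, `read2`.
#' @param ref An [augment_reference()] result.
#' @param k Seed length.
#' @param stride Seed sampling stride along the read.
#' @return An alignment table (class `ki_alignments`): one row per mate
#'   with `qname`, `mate`, `contig`, `pos` (1-based leftmost aligned
#'   base), `strand`, `mapq`, `cigar`, `qstart`, `qend`, `aln_len`,
#'   `read_len`, `nm`, `unmapped`, and `seq` (the read sequence in
#'   reference orientation, as in SAM).
#' @export
map_reads_naive <- function(reads, ref, k = 21L, stride = 4L) {
  stopifnot(inherits(ref, "augmented_reference"))
  if (inherits(reads, "read_pairs")) reads <- reads$pairs
  stopifnot(all(c("id", "read1", "read2") %in% names(reads)))
  n <- nrow(reads)
  seqs <- c(reads$read1, reads$read2)
  hit <- map_reads_cpp(unname(ref$seqs), seqs, k = k, stride = stride)
  read_len <- nchar(seqs)
  unmapped <- is.na(hit$contig)
  aln_len <- ifelse(unmapped, 0L, hit$qend - hit$qstart + 1L)
  cigar <- ifelse(unmapped, "*", paste0(
    ifelse(!unmapped & hit$qstart > 1L, paste0(hit$qstart - 1L, "S"), ""),
    aln_len, "M",
    ifelse(!unmapped & hit$qend < read_len,
           paste0(read_len - hit$qend, "S"), "")))
  oriented <- seqs
  minus <- !unmapped & hit$strand < 0
  if (any(minus)) oriented[minus] <- revcomp(seqs[minus])
  aln <- data.frame(
    qname = rep(as.character(reads$id), 2L),
    mate = rep(c(1L, 2L), each = n),
    contig = ifelse(unmapped, NA_character_,
                    names(ref$seqs)[hit$contig]),
    pos = hit$pos,
    strand = ifelse(unmapped, NA_character_,
                    ifelse(hit$strand > 0, "+", "-")),
    mapq = ifelse(unmapped, 0L, hit$mapq),
    cigar = cigar,
    qstart = hit$qstart, qend = hit$qend,
    aln_len = aln_len, read_len = read_len,
    nm = hit$nm, unmapped = unmapped,
    seq = oriented,
    stringsAsFactors = FALSE)
  class(aln) <- c("ki_alignments", "data.frame")
  aln
}

parse_cigar <- function(cigar, read_len) {
  ## returns qstart/qend/aln_len for simple [0-9]+[SMIDH] cigars; only
  ## leading/trailing soft clips and M/I/D are understood
  qstart <- integer(length(cigar)); qend <- integer(length(cigar))
  aln <- integer(length(cigar))
  ops <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))
  for (i in seq_along(ops)) {
    o <- ops[[i]]
    if (!length(o)) { qstart[i] <- NA; next }
    lens <- as.integer(sub("[A-Z=]", "", o))
    code <- sub("[0-9]+", "", o)
    lead <- if (code[1] %in% c("S", "H")) lens[1] else 0L
    trail <- if (length(code) > 1L && code[length(code)] %in% c("S", "H"))
      lens[length(code)] else 0L
    qstart[i] <- lead + 1L
    qend[i] <- read_len[i] - trail
    aln[i] <- sum(lens[code %in% c("M", "=", "X", "D")])
  }
  list(qstart = qstart, qend = qend, aln_len = aln)
}

#' Read a minimal SAM file into an alignment table
#'
#' Parses the plain-text SAM fields needed for integration calling
#' (QNAME, FLAG, RNAME, POS, MAPQ, CIGAR); secondary and supplementary
#' records are dropped.
#'
#' @param path Path to a SAM file.
#' @return A `ki_alignments` data frame (see [map_reads_naive()]).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t")
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  keep <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  f <- f[keep]; flag <- flag[keep]
  qname <- vapply(f, `[`, "", 1L)
  rname <- vapply(f, `[`, "", 3L)
  pos <- as.integer(vapply(f, `[`, "", 4L))
  mapq <- as.integer(vapply(f, `[`, "", 5L))
  cigar <- vapply(f, `[`, "", 6L)
  seq <- vapply(f, `[`, "", 10L)
  unmapped <- bitwAnd(flag, 4L) != 0L | rname == "*"
  read_len <- ifelse(seq == "*", NA_integer_, nchar(seq))
  cg <- parse_cigar(ifelse(unmapped, "", cigar), read_len)
  ## infer read length from the cigar when SEQ is omitted
  no_seq <- is.na(read_len) & !unmapped
  if (any(no_seq)) {
    consume <- vapply(regmatches(cigar[no_seq],
                                 gregexpr("[0-9]+[MIS=X]", cigar[no_seq])),
                      function(o) sum(as.integer(sub("[A-Z=]", "", o))),
                      numeric(1))
    read_len[no_seq] <- as.integer(consume)
    cg2 <- parse_cigar(cigar[no_seq], read_len[no_seq])
    cg$qstart[no_seq] <- cg2$qstart
    cg$qend[no_seq] <- cg2$qend
    cg$aln_len[no_seq] <- cg2$aln_len
  }
  aln <- data.frame(
    qname = qname,
    mate = ifelse(bitwAnd(flag, 128L) != 0L, 2L, 1L),
    contig = ifelse(unmapped, NA_character_, rname),
    pos = ifelse(unmapped, NA_integer_, pos),
    strand = ifelse(unmapped, NA_character_,
                    ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")),
    mapq = mapq, cigar = cigar,
    qstart = cg$qstart, qend = cg$qend, aln_len = cg$aln_len,
    read_len = read_len, nm = NA_integer_, unmapped = unmapped,
    seq = ifelse(seq == "*", NA_character_, seq),
    stringsAsFactors = FALSE)
  class(aln) <- c("ki_alignments", "data.frame")
  aln
}

#' Write an alignment table as minimal SAM
#'
#' @param aln A `ki_alignments` table.
#' @param ref The [augment_reference()] used for mapping (for `@SQ`
#'   headers).
#' @param path Output path.
#' @param seqs Optional character vector of read sequences (oriented as
#'   aligned) matching rows of `aln`; defaults to `aln$seq` when present
#'   and is written as `*` when absent.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref, path, seqs = NULL) {
  if (is.null(seqs) && !is.null(aln$seq)) seqs <- aln$seq
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(ref$seqs), "\tLN:", nchar(ref$seqs)))
  flag <- ifelse(aln$mate == 2L, 128L + 64L * 0L, 64L)
  flag <- flag + 1L  # paired
  flag <- flag + ifelse(aln$unmapped, 4L, 0L)
  flag <- flag + ifelse(!aln$unmapped & aln$strand == "-", 16L, 0L)
  body <- paste(aln$qname, flag,
                ifelse(aln$unmapped, "*", aln$contig),
                ifelse(aln$unmapped, 0L, aln$pos),
                aln$mapq,
                ifelse(aln$unmapped, "*", aln$cigar),
                "*", 0L, 0L,
                if (is.null(seqs)) "*" else ifelse(is.na(seqs), "*", seqs),
                "*", sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
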