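#' Simulate a paired-end sequencing library
#'
#' Draws fragments uniformly from each allele (fragment lengths normal,
#' truncated at the read length), reads both fragment ends, and applies
#' independent substitution errors. Defaults mirror a 150-bp paired-end
#' short-insert genome library. The total depth is split evenly across
#' the supplied alleles (two alleles of a diploid each get half).
#'
#' @param alleles Named character vector of allele sequences, or a
#'   [plant_insertion()] result.
#' @param depth Total haploid-genome-equivalent depth across all alleles.
#' @param read_len Read length in bp.
#' @param insert_mean,insert_sd Fragment-length distribution (bp);
#'   `insert_mean` must be >= `read_len`.
#' @param error_rate Per-base substitution error rate.
#' @param seed RNG seed.
#' @return A list of class `read_pairs` with `pairs` (data frame: `id`,
#'   `read1`, `read2`, `allele`, `frag_start`, `frag_len`) and `truth`
#'   (generator parameters; plus the planted-insertion truth when
#'   `alleles` is a `planted_insertion`).
#' @export
simulate_read_pairs <- function(alleles, depth = 20, read_len = 150L,
                                insert_mean = 400, insert_sd = 60,
                                error_rate = 0.001, seed = 1L) {
  planted_truth <- NULL
  if (inherits(alleles, "planted_insertion")) {
    planted_truth <- alleles$truth
    alleles <- alleles$alleles
  }
  if (is.null(names(alleles)))
    names(alleles) <- paste0("allele", seq_along(alleles))
  if (insert_mean < read_len)
    stop("insert_mean must be at least the read length", call. = FALSE)
  stopifnot(depth > 0, read_len >= 20L, error_rate >= 0, error_rate < 1)
  per_allele_depth <- depth / length(alleles)
  with_seed(seed, {
    out <- vector("list", length(alleles))
    for (ai in seq_along(alleles)) {
      a <- alleles[[ai]]
      n_pairs <- as.integer(round(per_allele_depth * nchar(a) /
                                    (2 * read_len)))
      if (n_pairs == 0L) next
      frag <- as.integer(round(rnorm(n_pairs, insert_mean, insert_sd)))
      frag <- pmin(pmax(frag, read_len), nchar(a))
      start <- as.integer(floor(runif(n_pairs, 1, nchar(a) - frag + 2)))
      r1 <- substring(a, start, start + read_len - 1L)
      r2 <- revcomp(substring(a, start + frag - read_len, start + frag - 1L))
      out[[ai]] <- data.frame(
        id = sprintf("%s_p%06d", names(alleles)[ai], seq_len(n_pairs)),
        read1 = r1, read2 = r2, allele = names(alleles)[ai],
        frag_start = start, frag_len = frag, stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, out)
    rownames(pairs) <- NULL
    if (error_rate > 0 && nrow(pairs)) {
      for (col in c("read1", "read2")) {
        reads <- pairs[[col]]
        total <- sum(nchar(reads))
        n_err <- rbinom(1L, total, error_rate)
        if (n_err > 0L) {
          pos <- sort(sample.int(total, n_err))
          offsets <- c(0L, cumsum(nchar(reads)))
          ri <- findInterval(pos, offsets + 1L)
          within <- pos - offsets[ri]
          for (j in seq_along(pos)) {
            cur <- substr(reads[ri[j]], within[j], within[j])
            substr(reads[ri[j]], within[j], within[j]) <-
              sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
          }
        }
        pairs[[col]] <- reads
      }
    }
    structure(
      list(pairs = pairs,
           truth = c(list(kind = "reads", seed = seed, depth = depth,
                          read_len = read_len, insert_mean = insert_mean,
                          insert_sd = insert_sd, error_rate = error_rate,
                          alleles = setNames(nchar(alleles),
                                             names(alleles))),
                     if (!is.null(planted_truth))
                       list(planted = planted_truth))),
      class = "read_pairs")
  })
}

#' Write simulated pairs as FASTQ
#'
#' Qualities are constant Q37 (`"F"`): the error model is
#' substitution-only.
#'
#' @param reads A `read_pairs` object.
#' @param prefix Output prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @return The two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  if (inherits(reads, "read_pairs")) reads <- reads$pairs
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (m in 1:2) {
    seqs <- reads[[paste0("read", m)]]
    writeLines(as.vector(rbind(paste0("@", reads$id, "/", m), seqs, "+",
                               strrep("F", nchar(seqs)))), paths[m])
  }
  invisible(paths)
}

#' Read paired FASTQ files into a `read_pairs`-style table
#'
#' @param r1,r2 FASTQ paths for mates 1 and 2.
#' @return A list of class `read_pairs` (without generator truth).
#' @export
read_fastq_pairs <- function(r1, r2) {
  get <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    setNames(as.character(x), sub("/[12]$", "", sub(" .*", "", names(x))))
  }
  s1 <- get(r1); s2 <- get(r2)
  if (!identical(names(s1), names(s2)))
    stop("mate files disagree on read ids", call. = FALSE)
  structure(list(pairs = data.frame(id = names(s1), read1 = unname(s1),
                                    read2 = unname(s2),
                                    stringsAsFactors = FALSE),
                 truth = NULL),
            class = "read_pairs")
}
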