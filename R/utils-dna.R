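#' @useDynLib crisprki, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom rnorm runif sd setNames
#' @importFrom utils read.delim write.table head tail
NULL

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")
STOP_CODONS <- c("TAA", "TAG", "TGA")

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  chars <- unique(strsplit(toupper(x), "")[[1]])
  bad <- setdiff(chars, IUPAC_DNA)
  if (length(bad))
    stop(what, " contains non-IUPAC letters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  toupper(x)
}

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Numeric vector of G+C fractions in `[0, 1]`.
#' @export
gc_content <- function(x) {
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(x),
                                   letters = c("G", "C"))
  unname(rowSums(f) / nchar(x))
}

#' Random DNA sequence
#'
#' Draws bases independently with the requested GC fraction (G and C
#' equiprobable, likewise A and T). Uses the current RNG stream.
#'
#' @param n Sequence length.
#' @param gc Target GC fraction.
#' @return A single DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## Split into codons starting at `from` (1-based); incomplete tail dropped.
codons_of <- function(seq, from = 1L) {
  n <- nchar(seq)
  if (from > n) return(character(0))
  starts <- seq.int(from, n - 2L, by = 3L)
  if (!length(starts)) return(character(0))
  substring(seq, starts, starts + 2L)
}

has_inframe_stop <- function(seq, from = 1L) {
  any(codons_of(seq, from) %in% STOP_CODONS)
}

#' Run code with a locally-set RNG seed
#'
#' Evaluates `code` after `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so library code never perturbs the session RNG.
#'
#' @param seed Integer seed, or `NULL` to run unchanged.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## Longest common prefix / suffix length of two strings.
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  d <- which(av != bv)
  if (!length(d)) n else d[1] - 1L
}

lcs_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- rev(strsplit(a, "")[[1]])
  bv <- rev(strsplit(b, "")[[1]])
  d <- which(av[seq_len(n)] != bv[seq_len(n)])
  if (!length(d)) n else d[1] - 1L
}

## First mode of an integer vector; ties broken by smallest value.
int_mode <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

#' Read a FASTA file as a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
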