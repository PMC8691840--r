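#' Augment a host genome with known insert sequences
#'
#' Integration discovery works against a reference in which every tag
#' cassette is an extra contig, so an integration shows up as an
#' inter-chromosomal breakpoint with one end on an insert contig.
#'
#' @param host Named character vector of host contig sequences, or a FASTA
#'   path.
#' @param inserts Named character vector of insert (cassette) sequences,
#'   or a FASTA path.
#' @return An object of class `augmented_reference` with `seqs` (all
#'   contigs), `host_names` and `insert_names`.
#' @export
augment_reference <- function(host, inserts) {
  if (is.character(host) && length(host) == 1L && is.null(names(host)) &&
      file.exists(host)) host <- read_fasta(host)
  if (is.character(inserts) && length(inserts) == 1L &&
      is.null(names(inserts)) && file.exists(inserts))
    inserts <- read_fasta(inserts)
  if (is.null(names(host)) || is.null(names(inserts)) ||
      anyNA(names(host)) || anyNA(names(inserts)))
    stop("host and insert sequences must be named", call. = FALSE)
  all_names <- c(names(host), names(inserts))
  if (anyDuplicated(all_names))
    stop("duplicate contig name(s): ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "),
         call. = FALSE)
  structure(list(seqs = toupper(c(host, inserts)),
                 host_names = names(host),
                 insert_names = names(inserts)),
            class = "augmented_reference")
}

is_insert_contig <- function(ref, contig) contig %in% ref$insert_names

#' @export
print.augmented_reference <- function(x, ...) {
  cat("<augmented_reference> ", length(x$host_names), " host contig(s) (",
      sum(nchar(x$seqs[x$host_names])), " bp) + ", length(x$insert_names),
      " insert contig(s) (", sum(nchar(x$seqs[x$insert_names])), " bp)\n",
      sep = "")
  invisible(x)
}
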