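#' Blunt SpCas9 cut site of a protospacer
#'
#' SpCas9 cuts bluntly 3 bp 5' of the PAM, i.e. between protospacer
#' positions 17 and 18. Cut sites are reported as junction offsets: the
#' index of the last window base before the cut.
#'
#' @param protospacer_start 1-based window coordinate of the leftmost base
#'   of the 20-nt protospacer footprint (for either strand).
#' @param strand `"+"` (PAM to the right) or `"-"` (PAM to the left).
#' @return Integer junction offset of the blunt cut.
#' @export
cut_site_of <- function(protospacer_start, strand = c("+", "-")) {
  strand <- match.arg(strand)
  s <- as.integer(protospacer_start)
  if (strand == "+") s + 16L else s + 2L
}

#' Exhaustively scan a locus window for SpCas9 protospacers
#'
#' Finds every 20-mer followed by an NGG PAM on either strand whose blunt
#' cut site lies within `search_radius` of the insertion junction. Ranking
#' is by absolute cut-to-junction distance only; off-target scoring is
#' deliberately out of scope (the study delegated it to external web
#' tools).
#'
#' @param locus A [target_locus()].
#' @param search_radius Maximum |cut_site - insertion_point| in bp.
#' @return A data frame with one row per candidate: `spacer` (5'->3' on its
#'   own strand), `pam`, `strand`, `start` (1-based leftmost window
#'   coordinate of the protospacer footprint), `cut_site` (junction
#'   offset), and `distance` (cut_site - insertion_point), sorted by
#'   |distance|, then `start`, then `+` before `-`.
#' @export
find_protospacers <- function(locus, search_radius = 50L) {
  stopifnot(inherits(locus, "target_locus"), search_radius >= 0)
  w <- locus$window_seq
  n <- nchar(w)
  ip <- locus$insertion_point
  out <- list()
  if (n >= 23L) {
    chars <- strsplit(w, "")[[1]]
    ## + strand: protospacer at s..s+19, PAM at s+20..s+22 = NGG
    s <- seq_len(n - 22L)
    plus <- s[chars[s + 21L] == "G" & chars[s + 22L] == "G"]
    if (length(plus)) {
      cut <- cut_site_of(plus, "+")
      keep <- abs(cut - ip) <= search_radius
      plus <- plus[keep]; cut <- cut[keep]
      if (length(plus))
        out$plus <- data.frame(
          spacer = substring(w, plus, plus + 19L),
          pam = substring(w, plus + 20L, plus + 22L),
          strand = "+", start = plus, cut_site = cut,
          distance = cut - ip, stringsAsFactors = FALSE)
    }
    ## - strand: CCN at p..p+2 on +, protospacer footprint p+3..p+22
    p <- seq_len(n - 22L)
    minus <- p[chars[p] == "C" & chars[p + 1L] == "C"]
    if (length(minus)) {
      ps <- minus + 3L
      cut <- cut_site_of(ps, "-")
      keep <- abs(cut - ip) <= search_radius
      ps <- ps[keep]; cut <- cut[keep]; minus <- minus[keep]
      if (length(ps))
        out$minus <- data.frame(
          spacer = revcomp(substring(w, ps, ps + 19L)),
          pam = revcomp(substring(w, minus, minus + 2L)),
          strand = "-", start = ps, cut_site = cut,
          distance = cut - ip, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(spacer = character(0), pam = character(0),
               strand = character(0), start = integer(0),
               cut_site = integer(0), distance = integer(0))
  ord <- order(abs(res$distance), res$start, res$strand != "+")
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}
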