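#' Collect insert/host anchor pairs
#'
#' An anchor pair is a read pair with exactly one mate on an insert contig
#' and one on a host contig - the paired-end signature of an integration
#' junction. Both-host and both-insert pairs are excluded, as are mates
#' below the mapping-quality cutoff. The `side` of the host mate is taken
#' from its orientation: a forward host mate points toward the junction on
#' its right (`left` side of the junction); a reverse mate the opposite.
#'
#' @param aln A `ki_alignments` table.
#' @param ref An [augment_reference()] result.
#' @param min_mapq Minimum MAPQ for both mates.
#' @return Data frame with one row per anchor pair: `qname`,
#'   `insert_name`, `insert_pos`, `host_contig`, `host_pos`, `host_end`,
#'   `host_strand`, `side`.
#' @export
collect_anchor_pairs <- function(aln, ref, min_mapq = 20L) {
  stopifnot(inherits(ref, "augmented_reference"))
  ok <- !aln$unmapped & aln$mapq >= min_mapq
  a <- aln[ok, , drop = FALSE]
  m1 <- a[a$mate == 1L, , drop = FALSE]
  m2 <- a[a$mate == 2L, , drop = FALSE]
  i <- match(m1$qname, m2$qname)
  keep <- !is.na(i)
  m1 <- m1[keep, , drop = FALSE]
  m2 <- m2[i[keep], , drop = FALSE]
  ins1 <- is_insert_contig(ref, m1$contig)
  ins2 <- is_insert_contig(ref, m2$contig)
  anchor <- xor(ins1, ins2)
  if (!any(anchor))
    return(data.frame(qname = character(0), insert_name = character(0),
                      insert_pos = integer(0), host_contig = character(0),
                      host_pos = integer(0), host_end = integer(0),
                      host_strand = character(0), side = character(0)))
  m1 <- m1[anchor, , drop = FALSE]
  m2 <- m2[anchor, , drop = FALSE]
  ins_is_1 <- ins1[anchor]
  ins <- ifelse(ins_is_1, m1$contig, m2$contig)
  ins_pos <- ifelse(ins_is_1, m1$pos, m2$pos)
  h_ctg <- ifelse(ins_is_1, m2$contig, m1$contig)
  h_pos <- ifelse(ins_is_1, m2$pos, m1$pos)
  h_len <- ifelse(ins_is_1, m2$aln_len, m1$aln_len)
  h_str <- ifelse(ins_is_1, m2$strand, m1$strand)
  data.frame(qname = m1$qname, insert_name = ins,
             insert_pos = as.integer(ins_pos),
             host_contig = h_ctg, host_pos = as.integer(h_pos),
             host_end = as.integer(h_pos + h_len - 1L),
             host_strand = h_str,
             side = ifelse(h_str == "+", "left", "right"),
             stringsAsFactors = FALSE)
}

#' Cluster anchor pairs into breakpoint clusters
#'
#' Single-linkage clustering of anchor host positions per (contig, side)
#' with maximum gap `cluster_window`. Clusters below `min_support` are not
#' returned as clusters but are tallied in the `subthreshold` diagnostics
#' attribute, mirroring weakly supported partial-insertion signals that
#' deserve a look but not a call.
#'
#' @param anchors Output of [collect_anchor_pairs()].
#' @param cluster_window Maximum gap (bp) joining anchors into a cluster.
#' @param min_support Minimum anchors per reported cluster.
#' @return Data frame of clusters (`host_contig`, `side`, `lo`, `hi`,
#'   `inner`, `support`, `insert_name`, `members`), sorted by contig, `lo`,
#'   then side (`left` < `right`); the dropped clusters are in
#'   `attr(, "subthreshold")`.
#' @export
cluster_anchors <- function(anchors, cluster_window = 500L,
                            min_support = 3L) {
  stopifnot(cluster_window > 0)
  empty <- data.frame(host_contig = character(0), side = character(0),
                      lo = integer(0), hi = integer(0), inner = integer(0),
                      support = integer(0), insert_name = character(0),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  if (!nrow(anchors)) {
    attr(empty, "subthreshold") <- empty
    return(empty)
  }
  out <- list()
  for (key in unique(paste(anchors$host_contig, anchors$side))) {
    g <- anchors[paste(anchors$host_contig, anchors$side) == key, ,
                 drop = FALSE]
    g <- g[order(g$host_pos, g$qname), , drop = FALSE]
    brk <- cumsum(c(0L, diff(g$host_pos) > cluster_window))
    for (b in unique(brk)) {
      m <- g[brk == b, , drop = FALSE]
      inner <- if (m$side[1] == "left") max(m$host_end) else min(m$host_pos)
      row <- data.frame(host_contig = m$host_contig[1], side = m$side[1],
                        lo = min(m$host_pos), hi = max(m$host_pos),
                        inner = as.integer(inner), support = nrow(m),
                        insert_name = names(which.max(table(m$insert_name))),
                        stringsAsFactors = FALSE)
      row$members <- list(m$qname)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$host_contig, res$lo, res$side != "left"), ,
             drop = FALSE]
  rownames(res) <- NULL
  sub <- res[res$support < min_support, , drop = FALSE]
  res <- res[res$support >= min_support, , drop = FALSE]
  attr(res, "subthreshold") <- sub
  res
}

#' Extract split-read junction evidence
#'
#' Soft-clipped host-contig alignments whose clip is long enough to be
#' informative. A forward-facing clip (clip at the read's right, on the
#' reference) puts the junction immediately after the last aligned base;
#' a left clip puts it immediately before the first.
#'
#' @param aln A `ki_alignments` table.
#' @param ref An [augment_reference()] result.
#' @param min_clip Minimum soft-clip length (bp).
#' @param min_mapq Minimum MAPQ.
#' @return Data frame with `host_contig`, `junction` (1-based coordinate
#'   of the last host base before the junction, un-normalized),
#'   `clip_side` (`"R"` right clip, `"L"` left clip), and `clip_seq`
#'   (the soft-clipped bases in reference orientation, `NA` when the
#'   alignment carries no sequence).
#' @export
find_split_reads <- function(aln, ref, min_clip = 10L, min_mapq = 20L) {
  host <- !aln$unmapped & aln$mapq >= min_mapq &
    !is_insert_contig(ref, aln$contig)
  a <- aln[host, , drop = FALSE]
  left_clip <- a$qstart - 1L
  right_clip <- a$read_len - a$qend
  seq <- if (is.null(a$seq)) rep(NA_character_, nrow(a)) else a$seq
  out <- list()
  r <- right_clip >= min_clip
  if (any(r))
    out$R <- data.frame(host_contig = a$contig[r],
                        junction = a$pos[r] + a$aln_len[r] - 1L,
                        clip_side = "R",
                        clip_seq = substr(seq[r], a$qend[r] + 1L,
                                          a$read_len[r]),
                        stringsAsFactors = FALSE)
  l <- left_clip >= min_clip
  if (any(l))
    out$L <- data.frame(host_contig = a$contig[l],
                        junction = a$pos[l] - 1L,
                        clip_side = "L",
                        clip_seq = substr(seq[l], 1L, a$qstart[l] - 1L),
                        stringsAsFactors = FALSE)
  if (!length(out))
    return(data.frame(host_contig = character(0), junction = integer(0),
                      clip_side = character(0),
                      clip_seq = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Jointly resolve the insertion coordinate from the modal raw clip
## coordinates of both junction sides by modelling the mapper's own
## extension rule (ungapped, match +1 / mismatch -3, maximum-scoring run
## kept). A right-clip at qR is consistent with a coordinate p <= qR when
## extending the insert head against the host after p under that scoring
## first attains its maximum exactly at qR - p bases -- this covers both
## exact micro-homology and near-match overshoot (e.g. one mismatch
## followed by several matches still scores positive, so the raw clip
## lands past the junction). A left-clip at qL is consistent with p >= qL
## when the absorbed insert-tail bases, compared to the host after qL,
## keep every running prefix score non-negative (no Kadane reset, so the
## run start can reach back to qL + 1). The true planted coordinate lies
## in both candidate sets, and their intersection is almost surely
## unique; one-sided evidence falls back to the maximally shifted
## (canonical) candidate. Rarely the clip coordinates alone cannot
## separate two neighbouring candidates (when the insert termini and
## the flanking host share bases, both hypotheses predict the same raw
## clips); the soft-clipped read content then breaks the tie, since the
## clipped bases must continue the insert head (right clips) or end at
## the insert tail (left clips) at the offset each candidate implies.
resolve_junction <- function(qR, qL, host_seq, insert_seq,
                             max_shift = 60L,
                             clip_r = character(0), clip_l = character(0)) {
  n <- nchar(insert_seq)
  hlen <- nchar(host_seq)
  score <- function(a, b) ifelse(strsplit(a, "")[[1]] == strsplit(b, "")[[1]],
                                 1L, -3L)
  PR <- NULL; PL <- NULL
  if (!is.na(qR)) {
    js <- 0:min(max_shift, qR - 1L, n)
    ok <- vapply(js, function(j) {
      p <- qR - j
      emax <- min(max_shift, n, hlen - p)
      if (j > emax) return(FALSE)
      if (emax == 0L) return(j == 0L)
      s <- c(0L, cumsum(score(substr(insert_seq, 1L, emax),
                              substr(host_seq, p + 1L, p + emax))))
      which.max(s) - 1L == j
    }, logical(1))
    PR <- qR - js[ok]
  }
  if (!is.na(qL)) {
    ks <- 0:min(max_shift, n, hlen - qL)
    ok <- vapply(ks, function(k) {
      if (k == 0L) return(TRUE)
      s <- cumsum(score(substring(insert_seq, n - k + 1L),
                        substr(host_seq, qL + 1L, qL + k)))
      all(s >= 0L)
    }, logical(1))
    PL <- qL + ks[ok]
  }
  clip_r <- if (is.na(qR)) character(0) else
    clip_r[!is.na(clip_r) & nzchar(clip_r)]
  clip_l <- if (is.na(qL)) character(0) else
    clip_l[!is.na(clip_l) & nzchar(clip_l)]
  content_score <- function(p) {
    tot <- 0L
    for (cs in clip_r) {
      off <- qR - p
      len <- min(nchar(cs), n - off)
      if (len < 1L) next
      a <- strsplit(substr(cs, 1L, len), "")[[1]]
      b <- strsplit(substr(insert_seq, off + 1L, off + len), "")[[1]]
      tot <- tot + sum(a == b) - sum(a != b)
    }
    for (cs in clip_l) {
      k <- p - qL
      len <- min(nchar(cs), n - k)
      if (len < 1L) next
      a <- strsplit(substring(cs, nchar(cs) - len + 1L), "")[[1]]
      b <- strsplit(substr(insert_seq, n - k - len + 1L, n - k), "")[[1]]
      tot <- tot + sum(a == b) - sum(a != b)
    }
    tot
  }
  choose <- function(cand, canonical = min) {
    cand <- sort(unique(as.integer(cand)))
    if (length(cand) > 1L && (length(clip_r) || length(clip_l))) {
      sc <- vapply(cand, content_score, integer(1))
      cand <- cand[sc == max(sc)]
    }
    canonical(cand)
  }
  if (!is.null(PR) && !is.null(PL)) {
    cand <- intersect(PR, PL)
    if (length(cand)) return(choose(cand))
    return(choose(PR))
  }
  if (!is.null(PR)) return(choose(PR))
  if (!is.null(PL)) return(choose(PL, canonical = max))
  NA_integer_
}

#' Call integration sites from breakpoint clusters and split reads
#'
#' Pairs left and right clusters on the same host contig within
#' `pairing_window` into one integration call each; unpaired clusters are
#' emitted as one-sided calls. When split reads exist, the coordinate is
#' resolved jointly from the modal raw clip coordinate of each side,
#' undoing mapper extension through micro-homology between the insert
#' termini and the flanking host (the insert head constrains the
#' coordinate from the left-junction side, the insert tail from the
#' right; their intersection is almost surely unique). Without split
#' reads the coordinate is the midpoint between the innermost left/right
#' anchor bounds. Coordinates are 1-based positions of the last host base
#' before the insert.
#'
#' @param clusters Output of [cluster_anchors()].
#' @param splits Output of [find_split_reads()].
#' @param ref An [augment_reference()] result.
#' @param pairing_window Maximum distance (bp) between paired left/right
#'   cluster inner bounds.
#' @return Data frame of class `integration_calls`: `insert_name`,
#'   `host_contig`, `coordinate`, `left_support`, `right_support`,
#'   `split_support`, `one_sided`.
#' @export
call_integrations <- function(clusters, splits, ref,
                              pairing_window = 1000L) {
  empty <- data.frame(insert_name = character(0), host_contig = character(0),
                      coordinate = integer(0), left_support = integer(0),
                      right_support = integer(0), split_support = integer(0),
                      one_sided = logical(0), stringsAsFactors = FALSE)
  class(empty) <- c("integration_calls", "data.frame")
  if (!nrow(clusters)) return(empty)
  calls <- list()
  used_right <- logical(nrow(clusters))
  lefts <- which(clusters$side == "left")
  rights <- which(clusters$side == "right")
  pair_of <- rep(NA_integer_, nrow(clusters))
  for (li in lefts) {
    cand <- rights[clusters$host_contig[rights] ==
                     clusters$host_contig[li] & !used_right[rights]]
    if (!length(cand)) next
    d <- abs(clusters$inner[cand] - clusters$inner[li])
    cand <- cand[d <= pairing_window]
    if (!length(cand)) next
    ri <- cand[which.min(abs(clusters$inner[cand] - clusters$inner[li]))]
    used_right[ri] <- TRUE
    pair_of[li] <- ri
  }
  make_call <- function(li, ri) {
    contig <- clusters$host_contig[if (is.na(li)) ri else li]
    ins <- clusters$insert_name[if (is.na(li)) ri else li]
    lo <- min(clusters$lo[c(li, ri)], na.rm = TRUE) - pairing_window
    hi <- max(clusters$hi[c(li, ri)], na.rm = TRUE) + pairing_window
    sp <- splits[splits$host_contig == contig & splits$junction >= lo &
                   splits$junction <= hi, , drop = FALSE]
    host_seq <- ref$seqs[[contig]]
    ins_seq <- ref$seqs[[ins]]
    if (nrow(sp)) {
      qR <- sp$junction[sp$clip_side == "R"]
      qL <- sp$junction[sp$clip_side == "L"]
      qRm <- if (length(qR)) int_mode(qR) else NA_integer_
      qLm <- if (length(qL)) int_mode(qL) else NA_integer_
      cs <- if (is.null(sp$clip_seq)) rep(NA_character_, nrow(sp)) else
        sp$clip_seq
      coord <- resolve_junction(
        qRm, qLm, host_seq, ins_seq,
        clip_r = cs[sp$clip_side == "R" & sp$junction %in% qRm],
        clip_l = cs[sp$clip_side == "L" & sp$junction %in% qLm])
      split_support <- sum(qR == qRm) + sum(qL == qLm)
    } else {
      inner_l <- if (is.na(li)) NA_integer_ else clusters$inner[li]
      inner_r <- if (is.na(ri)) NA_integer_ else clusters$inner[ri]
      coord <- as.integer(floor(mean(c(inner_l, inner_r), na.rm = TRUE)))
      split_support <- 0L
    }
    data.frame(insert_name = ins, host_contig = contig,
               coordinate = as.integer(coord),
               left_support = if (is.na(li)) 0L else clusters$support[li],
               right_support = if (is.na(ri)) 0L else clusters$support[ri],
               split_support = as.integer(split_support),
               one_sided = is.na(li) || is.na(ri),
               stringsAsFactors = FALSE)
  }
  for (li in lefts)
    calls[[length(calls) + 1L]] <- make_call(li, pair_of[li])
  for (ri in rights[!used_right[rights]])
    calls[[length(calls) + 1L]] <- make_call(NA_integer_, ri)
  res <- do.call(rbind, calls)
  res <- res[order(res$host_contig, res$coordinate), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("integration_calls", "data.frame")
  res
}

#' Classify copy number from the insert/host depth ratio
#'
#' Pooled F1 heterozygotes carry a single-copy insert on one of two
#' haplotypes, so the expected insert-contig depth is half the host depth.
#' Calls are classed `single_copy_het` for ratios in `[0.25, 0.75]`,
#' `multi_copy_or_concatemer` above, and `partial_low_support` below.
#'
#' @param aln A `ki_alignments` table (the same alignments the calls came
#'   from).
#' @param calls An `integration_calls` data frame.
#' @param ref An [augment_reference()] result.
#' @param min_mapq Minimum MAPQ for depth counting.
#' @param het_band Ratio band classed as heterozygous single copy.
#' @return `calls` with `depth_ratio` and `copy_class` columns added.
#' @export
assess_copy_number <- function(aln, calls, ref, min_mapq = 20L,
                               het_band = c(0.25, 0.75)) {
  ok <- !aln$unmapped & aln$mapq >= min_mapq
  a <- aln[ok, , drop = FALSE]
  depth_of <- function(contigs) {
    bases <- sum(a$aln_len[a$contig %in% contigs])
    bases / sum(nchar(ref$seqs[contigs]))
  }
  host_depth <- depth_of(ref$host_names)
  if (host_depth <= 0) stop("zero host depth", call. = FALSE)
  ratio <- vapply(calls$insert_name, function(ins)
    depth_of(ins) / host_depth, numeric(1))
  calls$depth_ratio <- unname(ratio)
  calls$copy_class <- ifelse(
    ratio > het_band[2], "multi_copy_or_concatemer",
    ifelse(ratio >= het_band[1], "single_copy_het", "partial_low_support"))
  calls
}

#' Full WGS integration-verification pipeline
#'
#' From alignments (or raw synthetic read pairs) against an
#' insert-augmented reference to copy-number-classified integration calls.
#'
#' @param ref An [augment_reference()] result.
#' @param aln A `ki_alignments` table ([read_sam()] or
#'   [map_reads_naive()]); omit and pass `reads` to map internally.
#' @param reads Optional `read_pairs` to map with [map_reads_naive()].
#' @param min_mapq,cluster_window,min_support,pairing_window,min_clip
#'   Tuning parameters (defaults suit 150-bp pairs at 14-24x).
#' @return List of class `wgs_verification` with `calls`, `clusters`,
#'   `subthreshold`, `anchors`, and `alignments`.
#' @export
verify_wgs <- function(ref, aln = NULL, reads = NULL, min_mapq = 20L,
                       cluster_window = 500L, min_support = 3L,
                       pairing_window = 1000L, min_clip = 10L) {
  if (is.null(aln)) {
    if (is.null(reads)) stop("supply alignments or reads", call. = FALSE)
    aln <- map_reads_naive(reads, ref)
  }
  anchors <- collect_anchor_pairs(aln, ref, min_mapq = min_mapq)
  clusters <- cluster_anchors(anchors, cluster_window = cluster_window,
                              min_support = min_support)
  splits <- find_split_reads(aln, ref, min_clip = min_clip,
                             min_mapq = min_mapq)
  calls <- call_integrations(clusters, splits, ref,
                             pairing_window = pairing_window)
  if (nrow(calls))
    calls <- assess_copy_number(aln, calls, ref, min_mapq = min_mapq)
  structure(list(calls = calls, clusters = clusters,
                 subthreshold = attr(clusters, "subthreshold"),
                 anchors = anchors, alignments = aln),
            class = "wgs_verification")
}

#' Write integration calls as TSV (and optionally BED)
#'
#' @param calls An `integration_calls` data frame (with copy-number
#'   columns if available).
#' @param path Output TSV path.
#' @param bed Optional BED path of 1-bp call intervals.
#' @return `path`, invisibly.
#' @export
write_integration_calls <- function(calls, path, bed = NULL) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(bed) && nrow(calls)) {
    bed_df <- data.frame(calls$host_contig, calls$coordinate - 1L,
                         calls$coordinate, calls$insert_name)
    write.table(bed_df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
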