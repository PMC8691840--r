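## Moving mean with window 3 (edges use the available 2-frame window).
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out[1] <- mean(x[1:2]); out[n] <- mean(x[(n - 1):n])
  out
}

## Theil-Sen slope: median of pairwise slopes.
theil_sen <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  ij <- utils::combn(n, 2L)
  median((y[ij[2, ]] - y[ij[1, ]]) / (x[ij[2, ]] - x[ij[1, ]]))
}

## Robust local slope per frame over a sliding window of `win` frames.
local_slope <- function(y, win = 5L) {
  n <- length(y)
  half <- win %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    ## keep the window at `win` frames when possible
    if (hi - lo + 1L < win) {
      lo <- max(1L, hi - win + 1L); hi <- min(n, lo + win - 1L)
    }
    theil_sen(seq.int(lo, hi), y[lo:hi])
  }, numeric(1))
}

#' Locate the S/G2 transition from the width trace
#'
#' The S/G2 transition is the frame of peak pixel-intensity-distribution
#' width: the argmax of the (3-frame moving-mean) smoothed width trace,
#' first occurrence on ties.
#'
#' @param W Numeric width trace (or the data frame from [width_trace()]).
#' @return 1-based frame index of the peak.
#' @export
locate_sg2 <- function(W) {
  if (is.data.frame(W)) W <- W$W
  if (length(W) < 3L) stop("need at least 3 frames", call. = FALSE)
  which.max(smooth3(W))
}

#' Locate the onset of M phase from the normalized intensity trace
#'
#' M onset is the earliest frame whose normalized intensity has fallen by
#' at least `drop_frac` relative to the maximum over the preceding
#' `window` frames - the sharp drop of nuclear PCNA when the envelope
#' breaks down.
#'
#' @param I_norm Normalized intensity trace (or a trace data frame with an
#'   `I_norm` column).
#' @param drop_frac Minimum fractional drop.
#' @param window Look-back window in frames.
#' @return 1-based frame index, or `NA_integer_` if no such drop occurs.
#' @export
locate_m_onset <- function(I_norm, drop_frac = 0.3, window = 3L) {
  if (is.data.frame(I_norm)) I_norm <- I_norm$I_norm
  n <- length(I_norm)
  if (n < window + 1L) stop("need at least window + 1 frames", call. = FALSE)
  for (t in 2:n) {
    ref <- max(I_norm[max(1L, t - window):(t - 1L)])
    if (I_norm[t] <= (1 - drop_frac) * ref) return(t)
  }
  NA_integer_
}

#' Segment cell-cycle phases from PCNA traces
#'
#' Applies the reporter's decision rules in order: frames at or after the
#' M onset are `M`; frames strictly between the S/G2 transition and the M
#' onset are `G2`; frames up to the S/G2 transition with positive robust
#' intensity slope are `S`, refined to `lateS` when the speckle count
#' reaches `speckle_min`; a track with no detected division and negative
#' overall robust slope is all `G1`; anything else is `unclassified`.
#'
#' @param trace Normalized trace ([normalize_trace()] output).
#' @param W Width trace ([width_trace()] output or numeric).
#' @param speckles Integer per-frame speckle counts.
#' @param drop_frac,window Passed to [locate_m_onset()].
#' @param speckle_min Minimum speckles for a `lateS` call.
#' @param slope_window Sliding window (frames) for the robust slope.
#' @return A list of class `phase_segmentation`: `labels`, `t_SG2`/`t_M`
#'   (frame indices), `t_SG2_min`/`t_M_min` (minutes), `speckle_counts`,
#'   and `flags`.
#' @export
segment_phases <- function(trace, W, speckles, drop_frac = 0.3,
                           window = 3L, speckle_min = 3L,
                           slope_window = 5L) {
  I_norm <- trace$I_norm
  if (is.null(I_norm)) stop("trace must be normalized first", call. = FALSE)
  if (is.data.frame(W)) W <- W$W
  n <- length(I_norm)
  stopifnot(length(W) == n, length(speckles) == n)
  interval <- if (n > 1L) diff(trace$t_min[1:2]) else 0
  flags <- character(0)
  labels <- rep("unclassified", n)

  t_m <- locate_m_onset(I_norm, drop_frac, window)
  overall <- theil_sen(seq_len(n), I_norm)
  if (is.na(t_m) && overall < 0) {
    labels[] <- "G1"
    res <- list(labels = labels, t_SG2 = NA_integer_, t_M = NA_integer_,
                t_SG2_min = NA_real_, t_M_min = NA_real_,
                speckle_counts = speckles, flags = flags)
    class(res) <- "phase_segmentation"
    return(res)
  }

  t_sg2 <- locate_sg2(W)
  if (!is.na(t_m) && t_m < t_sg2) {
    flags <- c(flags, "M onset precedes S/G2 transition")
    warning("M onset (frame ", t_m, ") precedes the S/G2 transition (frame ",
            t_sg2, "); segmentation emitted with flag", call. = FALSE)
  }
  slope <- local_slope(I_norm, slope_window)
  for (f in seq_len(n)) {
    if (!is.na(t_m) && f >= t_m) labels[f] <- "M"
    else if (f > t_sg2) labels[f] <- "G2"
    else if (slope[f] > 0)
      labels[f] <- if (speckles[f] >= speckle_min) "lateS" else "S"
  }
  res <- list(labels = labels, t_SG2 = t_sg2,
              t_M = t_m,
              t_SG2_min = (t_sg2 - 1L) * interval,
              t_M_min = if (is.na(t_m)) NA_real_ else (t_m - 1L) * interval,
              speckle_counts = speckles, flags = flags)
  class(res) <- "phase_segmentation"
  res
}

#' @export
print.phase_segmentation <- function(x, ...) {
  tb <- table(factor(x$labels,
                     levels = c("G1", "S", "lateS", "G2", "M",
                                "unclassified")))
  cat("<phase_segmentation> ", length(x$labels), " frames: ",
      paste(names(tb)[tb > 0], tb[tb > 0], sep = "=", collapse = ", "),
      "\n  S/G2 at frame ", x$t_SG2,
      if (!is.na(x$t_SG2)) paste0(" (", x$t_SG2_min, " min)"),
      "; M onset at frame ", x$t_M,
      if (!is.na(x$t_M)) paste0(" (", x$t_M_min, " min)"), "\n", sep = "")
  invisible(x)
}

#' Full single-movie cell-cycle analysis
#'
#' Extracts the normalized intensity trace, the width trace, and the
#' speckle trace, then segments phases.
#'
#' @param movie A [pcna_movie()].
#' @param roi ROI table (see [extract_trace()]).
#' @param n_bins,occupancy_frac Width-trace parameters.
#' @param k_sigma,min_prominence,min_sep Speckle-detector parameters
#'   (`min_prominence = 500` suits 16-bit movies with the default
#'   simulator contrast).
#' @param ... Passed to [segment_phases()].
#' @return List of class `cellcycle_analysis` with `per_frame` (data
#'   frame: `frame`, `t_min`, `I`, `I_norm`, `W`, `speckles`, `label`)
#'   and `segmentation`.
#' @export
analyze_movie <- function(movie, roi, n_bins = 256L, occupancy_frac = 0.05,
                          k_sigma = 2, min_prominence = 500, min_sep = 2,
                          ...) {
  trace <- normalize_trace(extract_trace(movie, roi))
  W <- width_trace(movie, roi, n_bins, occupancy_frac)
  spk <- speckle_trace(movie, roi, k_sigma = k_sigma,
                       min_prominence = min_prominence, min_sep = min_sep)
  seg <- segment_phases(trace, W, spk, ...)
  per_frame <- data.frame(frame = trace$frame, t_min = trace$t_min,
                          I = trace$I, I_norm = trace$I_norm, W = W$W,
                          speckles = spk, label = seg$labels,
                          stringsAsFactors = FALSE)
  structure(list(per_frame = per_frame, segmentation = seg),
            class = "cellcycle_analysis")
}

#' Write cell-cycle analysis outputs
#'
#' Per-frame CSV plus a segmentation JSON (`t_SG2`, `t_M`, in frames and
#' minutes).
#'
#' @param analysis An [analyze_movie()] result.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_cellcycle_report <- function(analysis, dir, prefix = "cellcycle") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, "_per_frame.csv"))
  utils::write.csv(analysis$per_frame, csv, row.names = FALSE)
  js <- file.path(dir, paste0(prefix, "_segmentation.json"))
  seg <- analysis$segmentation
  jsonlite::write_json(
    list(t_SG2_frame = seg$t_SG2, t_SG2_min = seg$t_SG2_min,
         t_M_frame = seg$t_M, t_M_min = seg$t_M_min, flags = seg$flags),
    js, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(c(per_frame_csv = csv, segmentation_json = js))
}
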