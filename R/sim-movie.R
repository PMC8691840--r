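#' Build a phase schedule for a simulated dividing nucleus
#'
#' Frame labels for one cell-cycle track that starts in S phase (as the
#' reporter's dividing-cell tracks do), with the S/G2 transition at frame
#' `t_sg2` (last S frame) and M onset at frame `t_m`. With the default
#' 20-min frame interval the defaults put the S/G2 peak at 940 min and
#' the M-phase drop at 1200 min.
#'
#' @param n_frames Total frames.
#' @param t_sg2 Frame (1-based) of the S/G2 transition.
#' @param t_m First M-phase frame (1-based).
#' @param lates_len Number of late-S (speckled) frames ending at `t_sg2`.
#' @return Character vector of per-frame labels (`S`, `lateS`, `G2`, `M`).
#' @export
make_phase_schedule <- function(n_frames = 68L, t_sg2 = 48L, t_m = 61L,
                                lates_len = 14L) {
  stopifnot(t_sg2 >= lates_len + 1L, t_m > t_sg2, n_frames >= t_m)
  labels <- rep("S", n_frames)
  labels[(t_sg2 - lates_len + 1L):t_sg2] <- "lateS"
  if (t_m - 1L > t_sg2) labels[(t_sg2 + 1L):(t_m - 1L)] <- "G2"
  labels[t_m:n_frames] <- "M"
  labels
}

#' Simulate a single-nucleus PCNA time-lapse movie
#'
#' Emulates the intensity phenomenology of an endogenous PCNA reporter
#' within a circular nuclear ROI:
#'
#' * G1 (all-`G1` schedules): exponential decay of the nuclear mean at
#'   rate `g1_decay` per minute;
#' * S: linear-in-log rise of the nuclear mean (`s_rise` per frame);
#' * late S: bright replication-focus speckles plus a growing dispersed
#'   bright-pixel component (a fixed fraction of ROI pixels offset into a
#'   `[0.7, 1] * A_f` band, with `A_f` ramping up across late S and down
#'   across G2 and exceeding the speckle amplitude at its peak), so the
#'   pixel-intensity distribution is widest at the programmed S/G2 frame
#'   and narrows through G2;
#' * M: the nuclear mean drops sharply (factor `1 - m_drop` per frame
#'   over `m_drop_frames` frames).
#'
#' All pixels carry additive Gaussian camera noise, values are clamped to
#' the 16-bit range, and the ROI is circular and static.
#'
#' @param schedule Per-frame labels from [make_phase_schedule()], or
#'   `"G1"` repeated for a non-dividing track.
#' @param img_size Frame side length in pixels.
#' @param roi_radius Nuclear ROI radius in pixels.
#' @param base_intensity Initial nuclear mean intensity.
#' @param g1_decay G1 decay rate per minute.
#' @param s_rise Multiplicative S-phase rise per frame.
#' @param n_speckles Number of late-S replication foci.
#' @param speckle_amp Focus peak amplitude (intensity units).
#' @param disp_amp Peak amplitude of the dispersed bright-pixel component
#'   at the S/G2 frame.
#' @param disp_frac Fraction of ROI pixels carrying the dispersed
#'   component.
#' @param m_drop Fractional intensity drop per M frame.
#' @param m_drop_frames Number of frames over which the M drop plays out.
#' @param noise_sd Additive Gaussian camera noise SD.
#' @param frame_interval Minutes per frame.
#' @param background Extranuclear background level.
#' @param seed RNG seed.
#' @return A list of class `sim_movie` with `movie` (a [pcna_movie()]),
#'   `roi` (static circular ROI track), and `truth` (per-frame `labels`,
#'   `t_sg2`, `t_m`, per-frame programmed means `mu`, dispersion
#'   amplitudes `disp`, speckle positions, seed, and parameters).
#' @export
simulate_nucleus_movie <- function(schedule = make_phase_schedule(),
                                   img_size = 64L, roi_radius = 10,
                                   base_intensity = 3000,
                                   g1_decay = 0.0015, s_rise = 0.026,
                                   n_speckles = 6L, speckle_amp = 2600,
                                   disp_amp = 4000, disp_frac = 0.5,
                                   m_drop = 0.45, m_drop_frames = 2L,
                                   noise_sd = 25, frame_interval = 20,
                                   background = 100, seed = 1L) {
  n <- length(schedule)
  stopifnot(n >= 3L, all(schedule %in% c("G1", "S", "lateS", "G2", "M")))
  is_m <- schedule == "M"
  t_m <- if (any(is_m)) which(is_m)[1] else NA_integer_
  t_sg2 <- if (any(schedule %in% c("S", "lateS")))
    max(which(schedule %in% c("S", "lateS"))) else NA_integer_
  if (!is.na(t_m) && !is.na(t_sg2) && t_m <= t_sg2)
    stop("schedule frames non-monotone: M before the end of S",
         call. = FALSE)

  ## programmed nuclear mean
  mu <- numeric(n)
  mu[1] <- base_intensity
  for (f in 2:n) {
    mu[f] <- switch(schedule[f],
                    G1 = base_intensity *
                      exp(-g1_decay * (f - 1) * frame_interval),
                    S = ,
                    lateS = mu[f - 1] * (1 + s_rise),
                    G2 = mu[f - 1],
                    M = if (f - t_m < m_drop_frames)
                      mu[f - 1] * (1 - m_drop) else mu[f - 1])
  }
  if (schedule[1] == "M") mu[1] <- base_intensity * (1 - m_drop)

  ## dispersed bright-pixel amplitude: geometric tent peaking at the S/G2
  ## frame (rises through late S, falls through G2), so the programmed
  ## S/G2 frame is the unique argmax of the dispersion profile
  disp <- numeric(n)
  if (!is.na(t_sg2)) {
    ramp <- which(schedule %in% c("lateS", "G2"))
    disp[ramp] <- disp_amp * 0.7^abs(ramp - t_sg2)
  }

  with_seed(seed, {
    dims <- c(img_size, img_size)
    cx <- img_size / 2 + 0.5; cy <- img_size / 2 + 0.5
    mask <- roi_mask(dims, cx, cy, roi_radius)
    n_px <- sum(mask)
    ## speckle centers inside 70% of the ROI radius, mutually separated
    spk <- matrix(numeric(0), 0, 2)
    guard <- 0L
    while (nrow(spk) < n_speckles && guard < 1000L) {
      guard <- guard + 1L
      ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * 0.7 * roi_radius
      cand <- c(cy + rad * sin(ang), cx + rad * cos(ang))
      if (!nrow(spk) ||
          all((spk[, 1] - cand[1])^2 + (spk[, 2] - cand[2])^2 >= 25))
        spk <- rbind(spk, cand)
    }
    yy <- matrix(seq_len(dims[1]), dims[1], dims[2])
    xx <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
    spk_field <- matrix(0, dims[1], dims[2])
    for (i in seq_len(nrow(spk)))
      spk_field <- spk_field +
        exp(-((yy - spk[i, 1])^2 + (xx - spk[i, 2])^2) / (2 * 1.2^2))
    ## dispersed pixels avoid the foci so the two bright components
    ## never stack on one pixel
    disp_pool <- which(mask & spk_field < 0.02)
    disp_idx <- sample(disp_pool,
                       min(length(disp_pool),
                           max(1L, round(disp_frac * n_px))))

    frames <- vector("list", n)
    for (f in seq_len(n)) {
      img <- matrix(background, dims[1], dims[2])
      img[mask] <- mu[f]
      if (disp[f] > 0)
        img[disp_idx] <- img[disp_idx] +
          runif(length(disp_idx), 0.7 * disp[f], disp[f])
      if (schedule[f] == "lateS")
        img <- img + speckle_amp * spk_field * mask
      img <- img + rnorm(length(img), 0, noise_sd)
      frames[[f]] <- matrix(pmin(pmax(round(img), 0), 65535),
                            dims[1], dims[2])
    }
    roi <- data.frame(frame = seq_len(n), cx = cx, cy = cy, r = roi_radius)
    structure(
      list(movie = pcna_movie(frames, frame_interval),
           roi = roi,
           truth = list(kind = "movie", seed = seed, labels = schedule,
                        t_sg2 = t_sg2, t_m = t_m, mu = mu, disp = disp,
                        speckles = spk, n_px = n_px,
                        parameters = list(
                          img_size = img_size, roi_radius = roi_radius,
                          base_intensity = base_intensity,
                          g1_decay = g1_decay, s_rise = s_rise,
                          n_speckles = n_speckles,
                          speckle_amp = speckle_amp, disp_amp = disp_amp,
                          disp_frac = disp_frac, m_drop = m_drop,
                          m_drop_frames = m_drop_frames,
                          noise_sd = noise_sd,
                          frame_interval = frame_interval,
                          background = background))),
      class = "sim_movie")
  })
}

#' Write a movie as a multi-page 16-bit TIFF
#'
#' @param movie A [pcna_movie()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  tiff::writeTIFF(lapply(movie$frames, function(f) f / 65535), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a movie
#'
#' @param path TIFF path.
#' @param frame_interval Minutes per frame.
#' @return A [pcna_movie()].
#' @export
read_movie_tiff <- function(path, frame_interval = 20) {
  frames <- tiff::readTIFF(path, all = TRUE)
  pcna_movie(lapply(frames, function(f) round(f * 65535)), frame_interval)
}

#' Read / write circular ROI tracks as TSV
#'
#' Columns: `frame`, `cx`, `cy`, `r`.
#'
#' @param path TSV path.
#' @return For the reader, a data frame.
#' @export
read_roi_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_roi_tsv
#' @param roi ROI data frame.
#' @export
write_roi_tsv <- function(roi, path) {
  write.table(roi, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
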