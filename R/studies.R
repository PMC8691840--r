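#' Seeded WGS integration-recovery study
#'
#' Runs `n_runs` independent planted-insertion (or insertion-free)
#' simulations against one seeded host and cassette and scores the
#' integration caller on each: exact junction recovery, split-read
#' support, and copy-number classification. All per-run positions and
#' read seeds are derived deterministically from `seed`.
#'
#' @param n_runs Number of simulations.
#' @param scenario `"het"` (single-copy heterozygous), `"null"`
#'   (insertion-free), or `"concatemer"` (heterozygous 3x tandem).
#' @param host_len Host contig length (bp).
#' @param insert_len Cassette length (bp).
#' @param depth Total sequencing depth.
#' @param read_len Read length (bp).
#' @param error_rate Substitution error rate.
#' @param tandem_copies Tandem copies for the concatemer scenario.
#' @param seed Master seed; every run seed derives from it.
#' @return Data frame with one row per run: `run`, `position` (NA for
#'   null), `n_calls`, `coordinate`, `split_support`, `exact`,
#'   `depth_ratio`, `copy_class`.
#' @export
wgs_recovery_study <- function(n_runs = 100L,
                               scenario = c("het", "null", "concatemer"),
                               host_len = 100000L, insert_len = 714L,
                               depth = 20, read_len = 150L,
                               error_rate = 0.001, tandem_copies = 3L,
                               seed = 1L) {
  scenario <- match.arg(scenario)
  sub <- with_seed(seed, matrix(sample.int(.Machine$integer.max,
                                           2L * n_runs + 2L), ncol = 2L,
                                nrow = n_runs + 1L))
  host <- with_seed(sub[n_runs + 1L, 1L], random_dna(host_len, 0.45))
  ins <- with_seed(sub[n_runs + 1L, 2L], random_dna(insert_len, 0.5))
  ref <- augment_reference(c(chr1 = host), c(cassette = ins))
  margin <- max(5000L, insert_len * tandem_copies)
  out <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    if (scenario == "null") {
      position <- NA_integer_
      alleles <- c(hap1 = host, hap2 = host)
    } else {
      position <- with_seed(sub[i, 1L],
                            sample((margin + 1L):(host_len - margin), 1L))
      alleles <- plant_insertion(
        host, ins, position, "het",
        tandem_copies = if (scenario == "concatemer") tandem_copies else 1L)
    }
    reads <- simulate_read_pairs(alleles, depth = depth,
                                 read_len = read_len,
                                 error_rate = error_rate,
                                 seed = sub[i, 2L])
    calls <- verify_wgs(ref, reads = reads)$calls
    one <- nrow(calls) == 1L
    out[[i]] <- data.frame(
      run = i, position = position, n_calls = nrow(calls),
      coordinate = if (one) calls$coordinate else NA_integer_,
      split_support = if (one) calls$split_support else NA_integer_,
      exact = one && !is.na(position) && calls$split_support > 0L &&
        calls$coordinate == position,
      depth_ratio = if (one) calls$depth_ratio else NA_real_,
      copy_class = if (one) calls$copy_class else NA_character_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "parameters") <- list(scenario = scenario, host_len = host_len,
                                  insert_len = insert_len, depth = depth,
                                  read_len = read_len,
                                  error_rate = error_rate, seed = seed)
  res
}

#' Seeded cell-cycle phase-recovery study
#'
#' Simulates `n_runs` dividing-nucleus movies (study defaults: 68 frames
#' at 20 min, S/G2 at frame 48, M onset at frame 61) with per-run seeds
#' derived from `seed`, analyzes each with [analyze_movie()], and scores
#' landmark errors and frame-wise label agreement against the generator
#' truth.
#'
#' @param n_runs Number of movies.
#' @param schedule Phase schedule for every movie.
#' @param seed Master seed.
#' @param ... Passed to [simulate_nucleus_movie()].
#' @return Data frame with one row per movie: `run`, `t_sg2_true`,
#'   `t_sg2_est`, `t_m_true`, `t_m_est`, `sg2_err`, `m_err`, `agreement`.
#' @export
movie_recovery_study <- function(n_runs = 100L,
                                 schedule = make_phase_schedule(),
                                 seed = 1L, ...) {
  sub <- with_seed(seed, sample.int(.Machine$integer.max, n_runs))
  out <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    m <- simulate_nucleus_movie(schedule, seed = sub[i], ...)
    an <- analyze_movie(m$movie, m$roi)
    seg <- an$segmentation
    out[[i]] <- data.frame(
      run = i, t_sg2_true = m$truth$t_sg2, t_sg2_est = seg$t_SG2,
      t_m_true = m$truth$t_m, t_m_est = seg$t_M,
      sg2_err = abs(seg$t_SG2 - m$truth$t_sg2),
      m_err = abs(seg$t_M - m$truth$t_m),
      agreement = mean(an$per_frame$label == m$truth$labels))
  }
  res <- do.call(rbind, out)
  attr(res, "parameters") <- list(n_frames = length(schedule), seed = seed)
  res
}
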