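# Synthetic blockade and trace generator: ground truth for the whole
# pipeline. Inverts the forward response model — per-window signal levels
# time-dilated over the event duration plus Gaussian noise.

#' Simulation configuration
#'
#' Defaults mirror the acquisition conditions the pipeline targets: 250 kHz
#' sampling, blockades of 1-20 ms, mean fractional blockades of 0.05-0.5,
#' and baseline noise at 1% of the open-pore current.
#'
#' @param sampling_rate_hz Sampling rate (default 250 000).
#' @param open_pore_current_pa Open-pore current (default 100 pA).
#' @param duration_range_ms Blockade duration range, drawn uniformly
#'   (default 1-20 ms).
#' @param mean_blockade_range Range of the mean fractional blockade of an
#'   event, drawn uniformly (default 0.05-0.5).
#' @param fluctuation_amplitude Standard deviation of the intra-event
#'   fluctuations in fractional-current units (default 0.05): the clean
#'   per-window response is z-scored and scaled by this amplitude around the
#'   event's mean blockade level.
#' @param noise_sigma Additive Gaussian noise standard deviation as a
#'   fraction of the open-pore current (default 0.01), applied to the whole
#'   trace and to simulated events.
#' @param response_model Spectrum model generating the clean per-window
#'   signal (default [mv_model()]; any [theoretical_spectrum()] model works).
#' @param orientation_prob Probability that a molecule translocates in
#'   reverse orientation (default 0.5).
#' @param velocity_jitter Relative jitter of per-window dwell times
#'   (default 0, the uniform-velocity assumption; > 0 stress-tests
#'   discretization against non-uniform translocation).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(sampling_rate_hz = 250000,
                              open_pore_current_pa = 100,
                              duration_range_ms = c(1, 20),
                              mean_blockade_range = c(0.05, 0.5),
                              fluctuation_amplitude = 0.05,
                              noise_sigma = 0.01,
                              response_model = mv_model(),
                              orientation_prob = 0.5,
                              velocity_jitter = 0) {
  stopifnot(sampling_rate_hz > 0,
            diff(duration_range_ms) >= 0, duration_range_ms[1] > 0,
            diff(mean_blockade_range) >= 0, mean_blockade_range[1] > 0,
            fluctuation_amplitude >= 0, noise_sigma >= 0,
            orientation_prob >= 0, orientation_prob <= 1,
            velocity_jitter >= 0)
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 open_pore_current_pa = open_pore_current_pa,
                 duration_range_ms = duration_range_ms,
                 mean_blockade_range = mean_blockade_range,
                 fluctuation_amplitude = fluctuation_amplitude,
                 noise_sigma = noise_sigma,
                 response_model = response_model,
                 orientation_prob = orientation_prob,
                 velocity_jitter = velocity_jitter),
            class = "simulation_config")
}

# Clean fractional-blockade event series for one translocation.
# Returns list(values, clean_response, orientation, duration_ms).
.simulate_event_values <- function(sequence, config, k = 4) {
  n_pos <- nchar(sequence) + k - 1
  orientation <- if (stats::runif(1) < config$orientation_prob) "reverse"
                 else "forward"
  seq_used <- if (orientation == "reverse") .revseq(sequence) else sequence
  clean <- znormalize(theoretical_spectrum(config$response_model, seq_used))
  duration <- stats::runif(1, config$duration_range_ms[1],
                           config$duration_range_ms[2])
  n_samples <- round(duration * config$sampling_rate_hz / 1000)
  if (n_samples < n_pos)
    stop(sprintf(
      "event of %.3g ms (%d samples) cannot resolve %d read positions",
      duration, n_samples, n_pos))
  # time dilation: each read position occupies an equal share of the event
  # (uniform translocation velocity); optional dwell jitter
  if (config$velocity_jitter > 0) {
    w <- pmax(1e-6, 1 + stats::rnorm(n_pos, 0, config$velocity_jitter))
    pos <- rep(seq_len(n_pos),
               times = .apportion(n_samples, w))
  } else {
    pos <- rep(seq_len(n_pos), times = .apportion(n_samples, rep(1, n_pos)))
  }
  depth <- stats::runif(1, config$mean_blockade_range[1],
                        config$mean_blockade_range[2])
  values <- depth + config$fluctuation_amplitude * clean[pos]
  if (config$noise_sigma > 0)
    values <- values + stats::rnorm(n_samples, 0, config$noise_sigma)
  list(values = values, clean_response = clean, orientation = orientation,
       duration_ms = duration, depth = depth)
}

# Split n samples into length(w) integer counts proportional to weights w,
# each count >= 1, largest-remainder rounding.
.apportion <- function(n, w) {
  m <- length(w)
  stopifnot(n >= m)
  share <- w / sum(w) * (n - m)
  counts <- floor(share) + 1L
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- share - floor(share)
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  counts
}

#' Simulate a single blockade event
#'
#' Generates one nanospectrum for a protein: the response model's per-window
#' prediction (reversed with probability `orientation_prob`) is z-scored,
#' scaled by `fluctuation_amplitude` around a mean blockade depth drawn from
#' `mean_blockade_range`, time-dilated over a duration drawn from
#' `duration_range_ms` at the sampling rate, and overlaid with Gaussian
#' noise. Deterministic under `seed`.
#'
#' @param sequence Amino-acid sequence of the translocating protein.
#' @param config A [simulation_config()].
#' @param seed RNG seed.
#' @param source_id Provenance tag for the spectrum.
#' @param k Window size (default 4).
#' @return List with `spectrum` (a [nanospectrum()]) and `truth` (list:
#'   `orientation`, `duration_ms`, `depth`, `clean_response`).
#' @export
simulate_blockade <- function(sequence, config = simulation_config(),
                              seed = 1, source_id = "sim", k = 4) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ev <- .simulate_event_values(sequence, config, k = k)
  list(spectrum = nanospectrum(ev$values, ev$duration_ms,
                               source_id = source_id),
       truth = ev[c("orientation", "duration_ms", "depth", "clean_response")])
}

#' Simulate a raw current trace with embedded blockades
#'
#' An open-pore baseline with Gaussian noise in which `n_events` blockades
#' are embedded at random non-overlapping offsets; each event's source
#' protein is drawn uniformly from `proteins`. Raw currents are obtained by
#' inverting the fractional blockade: `I = I_open * (1 - f)`.
#'
#' @param proteins Data.frame with columns `id`, `sequence`, or a single
#'   sequence string.
#' @param n_events Number of blockades (>= 0).
#' @param config A [simulation_config()].
#' @param seed RNG seed.
#' @param gap_ms Mean open-pore gap between events (default 20 ms,
#'   exponential spacing with a 2 ms floor).
#' @param k Window size (default 4).
#' @return List with `trace` (a [raw_trace()]) and `truth` (data.frame:
#'   `protein_id`, `orientation`, `start_sample`, `end_sample`,
#'   `duration_ms`, `depth`).
#' @export
simulate_trace <- function(proteins, n_events, config = simulation_config(),
                           seed = 1, gap_ms = 20, k = 4) {
  stopifnot(n_events >= 0)
  if (is.character(proteins))
    proteins <- data.frame(id = "protein_1", sequence = proteins,
                           stringsAsFactors = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rate <- config$sampling_rate_hz
  gap_samples <- function() {
    ms <- max(2, stats::rexp(1, 1 / gap_ms))
    round(ms * rate / 1000)
  }
  segs <- list(rep(config$open_pore_current_pa, gap_samples()))
  truth <- vector("list", n_events)
  cursor <- length(segs[[1]])
  for (i in seq_len(n_events)) {
    pick <- sample(nrow(proteins), 1)
    ev <- .simulate_event_values(proteins$sequence[pick], config, k = k)
    ev_current <- config$open_pore_current_pa * (1 - ev$values)
    truth[[i]] <- data.frame(protein_id = proteins$id[pick],
                             orientation = ev$orientation,
                             start_sample = cursor + 1L,
                             end_sample = cursor + length(ev_current),
                             duration_ms = ev$duration_ms,
                             depth = ev$depth)
    gap <- rep(config$open_pore_current_pa, gap_samples())
    segs[[length(segs) + 1L]] <- ev_current
    segs[[length(segs) + 1L]] <- gap
    cursor <- cursor + length(ev_current) + length(gap)
  }
  samples <- unlist(segs)
  if (config$noise_sigma > 0)
    samples <- samples + stats::rnorm(length(samples),
                                      0, config$noise_sigma *
                                        config$open_pore_current_pa)
  list(trace = raw_trace(samples, sampling_rate_hz = rate,
                         open_pore_current_pa = config$open_pore_current_pa),
       truth = if (n_events > 0) do.call(rbind, truth) else
         data.frame(protein_id = character(), orientation = character(),
                    start_sample = integer(), end_sample = integer(),
                    duration_ms = numeric(), depth = numeric()))
}

#' Generate a random protein sequence
#'
#' Residues drawn i.i.d. from the 20-letter alphabet (uniform by default).
#'
#' @param length Protein length.
#' @param seed RNG seed.
#' @param weights Optional sampling weights over the 20 residues.
#' @return An amino-acid sequence string.
#' @export
random_protein <- function(length, seed = 1, weights = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  aas <- aa_properties()$residue
  paste(sample(aas, length, replace = TRUE, prob = weights), collapse = "")
}
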