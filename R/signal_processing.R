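# Raw-trace handling: blockade event detection, fractional blockade
# conversion, discretization and z-normalization.

#' Construct a raw pore-current trace
#'
#' A raw trace is a uniformly sampled current time series (pA) together with
#' its sampling rate and the open-pore current.
#'
#' @param samples Numeric vector of current samples (pA).
#' @param sampling_rate_hz Sampling rate in Hz (instrument default 250 kHz).
#' @param open_pore_current_pa Open-pore current in pA.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(samples, sampling_rate_hz = 250000, open_pore_current_pa) {
  stopifnot(length(samples) > 0, sampling_rate_hz > 0)
  if (!all(is.finite(samples))) stop("trace contains non-finite samples")
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz,
                 open_pore_current_pa = open_pore_current_pa),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("raw_trace: %d samples at %g kHz (%.1f ms), I_open = %g pA\n",
              length(x$samples), x$sampling_rate_hz / 1000,
              1000 * length(x$samples) / x$sampling_rate_hz,
              x$open_pore_current_pa))
  invisible(x)
}

#' Construct a nanospectrum
#'
#' A nanospectrum is one blockade event expressed as a series of fractional
#' blockade currents, together with the event duration in ms.
#'
#' @param values Numeric vector of fractional blockade currents
#'   (dimensionless, >= 0).
#' @param duration_ms Event duration in milliseconds.
#' @param source_id Provenance tag (free-form string).
#' @return An object of class `nanospectrum`.
#' @export
nanospectrum <- function(values, duration_ms, source_id = "") {
  stopifnot(length(values) > 0, duration_ms > 0)
  if (!all(is.finite(values))) stop("nanospectrum contains non-finite values")
  structure(list(values = as.numeric(values), duration_ms = duration_ms,
                 source_id = source_id),
            class = "nanospectrum")
}

#' @export
print.nanospectrum <- function(x, ...) {
  cat(sprintf("nanospectrum '%s': %d samples, %.2f ms, mean blockade %.3f\n",
              x$source_id, length(x$values), x$duration_ms, mean(x$values)))
  invisible(x)
}

#' Fractional blockade current
#'
#' The relative current drop caused by the molecule occluding the pore,
#' `|I - I_open| / I_open`. Scale-invariant: multiplying both currents by a
#' common factor leaves it unchanged.
#'
#' @param current Raw current(s) during the blockade (pA).
#' @param open_pore_current Open-pore current (pA), non-zero.
#' @return Dimensionless fractional blockade, same length as `current`.
#' @export
#' @examples
#' fractional_blockade(70, 100)  # 0.3
fractional_blockade <- function(current, open_pore_current) {
  if (open_pore_current == 0) stop("open_pore_current must be non-zero")
  abs(current - open_pore_current) / abs(open_pore_current)
}

# Population standard deviation (divide by N), the convention used throughout.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Detect blockade events in a raw trace
#'
#' Flags contiguous regions whose deviation from the open-pore baseline
#' exceeds `sigma_threshold` baseline-noise standard deviations and that last
#' at least `min_duration_ms`. The baseline is the median of the non-event
#' samples and the noise level their MAD; both are re-estimated once after an
#' initial detection pass. Event edges are extended to the first/last sample
#' still above half the detection threshold, so that flanks of the blockade
#' are not clipped. Each retained region is converted to fractional blockade
#' current against the trace's open-pore current.
#'
#' The noise level is first estimated from the first differences of the
#' trace (MAD of `diff(x)` over sqrt(2)), which is insensitive to the
#' fraction of time spent in blockades, and the baseline is anchored at the
#' upper current level since occlusion reduces the pore current.
#'
#' @param trace A [raw_trace()].
#' @param sigma_threshold Detection threshold in noise standard deviations
#'   (default 5).
#' @param min_duration_ms Minimum event duration in ms (default 1).
#' @param blockade_range Optional length-2 plausibility window on the mean
#'   fractional blockade of an event (e.g. `c(0.05, 0.5)`); events outside it
#'   are dropped. `NULL` (default) disables the filter.
#' @return List of [nanospectrum()] objects in temporal order; attribute
#'   `"boundaries"` carries a data.frame of start/end sample indices.
#' @export
detect_blockades <- function(trace, sigma_threshold = 5, min_duration_ms = 1,
                             blockade_range = NULL) {
  stopifnot(inherits(trace, "raw_trace"))
  x <- trace$samples
  if (!all(is.finite(x))) stop("trace contains non-finite samples")
  min_samples <- ceiling(min_duration_ms * trace$sampling_rate_hz / 1000)
  no_events <- structure(list(),
                         boundaries = data.frame(start = integer(),
                                                 end = integer()))
  if (length(x) < min_samples) return(no_events)

  find_runs <- function(baseline, sigma) {
    if (sigma <= 0) return(NULL)
    dev <- abs(x - baseline)
    above <- dev > sigma_threshold * sigma
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    # extend each run outwards while still above half the threshold
    half <- dev > (sigma_threshold / 2) * sigma
    for (i in seq_len(nrow(runs))) {
      s <- runs[i, 1]; e <- runs[i, 2]
      while (s > 1L && half[s - 1L]) s <- s - 1L
      while (e < length(x) && half[e + 1L]) e <- e + 1L
      runs[i, ] <- c(s, e)
    }
    # merge runs that overlap after extension or are separated by a gap
    # shorter than the minimum event duration (a blockade briefly grazing
    # the baseline is one event, not two)
    o <- order(runs[, 1])
    runs <- runs[o, , drop = FALSE]
    keep <- list(runs[1, ])
    for (i in seq_len(nrow(runs))[-1]) {
      last <- keep[[length(keep)]]
      if (runs[i, 1] <= last[2] + min_samples)
        keep[[length(keep)]] <- c(last[1], max(last[2], runs[i, 2]))
      else keep[[length(keep) + 1L]] <- runs[i, ]
    }
    do.call(rbind, keep)
  }

  # pass 1: difference-based noise estimate (robust to the event fraction)
  # and a baseline anchored at the open-pore (upper) level; pass 2:
  # estimates from the non-event samples
  sigma0 <- stats::mad(diff(x)) / sqrt(2)
  near_open <- x[abs(x - stats::quantile(x, 0.75)) <= 5 * sigma0]
  base0 <- if (length(near_open)) stats::median(near_open) else stats::median(x)
  runs <- find_runs(base0, sigma0)
  outside <- rep(TRUE, length(x))
  if (!is.null(runs))
    for (i in seq_len(nrow(runs))) outside[runs[i, 1]:runs[i, 2]] <- FALSE
  if (any(outside)) {
    baseline <- stats::median(x[outside])
    sigma <- max(stats::mad(x[outside]), sigma0)
    runs <- find_runs(baseline, sigma)
  }
  if (is.null(runs)) return(no_events)

  lens <- runs[, 2] - runs[, 1] + 1L
  runs <- runs[lens >= min_samples, , drop = FALSE]
  if (nrow(runs) == 0L) return(no_events)

  events <- list()
  bounds <- list()
  for (i in seq_len(nrow(runs))) {
    seg <- x[runs[i, 1]:runs[i, 2]]
    frac <- fractional_blockade(seg, trace$open_pore_current_pa)
    dur <- 1000 * length(seg) / trace$sampling_rate_hz
    if (!is.null(blockade_range)) {
      m <- mean(frac)
      if (m < blockade_range[1] || m > blockade_range[2]) next
    }
    events[[length(events) + 1L]] <-
      nanospectrum(frac, dur, source_id = sprintf("event_%03d", i))
    bounds[[length(bounds) + 1L]] <- data.frame(start = runs[i, 1], end = runs[i, 2])
  }
  attr(events, "boundaries") <- if (length(bounds)) do.call(rbind, bounds) else
    data.frame(start = integer(), end = integer())
  events
}

#' Discretize a nanospectrum into a fixed number of regions
#'
#' Splits the event samples into `n_points` contiguous regions of near-equal
#' size and returns the mean value of each region. When the sample count is
#' not divisible by `n_points`, the remainder is distributed one extra sample
#' to the earliest regions. For a candidate protein of length L under a
#' quadromer read, `n_points = L + 3`.
#'
#' @param spectrum A [nanospectrum()] or numeric vector.
#' @param n_points Number of regions (>= 1); must not exceed the sample count.
#' @return Numeric vector of length `n_points`.
#' @export
#' @examples
#' discretize(nanospectrum(1:12, 1), 4)  # 2 5 8 11
discretize <- function(spectrum, n_points) {
  v <- if (inherits(spectrum, "nanospectrum")) spectrum$values else as.numeric(spectrum)
  n_points <- as.integer(n_points)
  stopifnot(n_points >= 1)
  n <- length(v)
  if (n < n_points)
    stop(sprintf("cannot discretize %d samples into %d regions", n, n_points))
  base <- n %/% n_points
  extra <- n %% n_points
  sizes <- rep(base, n_points) + c(rep(1L, extra), rep(0L, n_points - extra))
  idx <- rep(seq_len(n_points), times = sizes)
  as.numeric(tapply(v, idx, mean))
}

#' Z-normalize a vector
#'
#' Subtracts the mean and divides by the population standard deviation
#' (divide by N). Idempotent up to floating tolerance and invariant to
#' positive affine transforms of the input.
#'
#' @param v Numeric vector of length >= 2 with non-zero standard deviation.
#' @return Z-scored numeric vector (mean 0, population sd 1).
#' @export
znormalize <- function(v) {
  v <- as.numeric(v)
  stopifnot(length(v) >= 2)
  s <- pop_sd(v)
  if (s == 0) stop("cannot z-normalize a constant vector (zero standard deviation)")
  (v - mean(v)) / s
}

#' Read/write raw traces and nanospectra
#'
#' Plain-text exchange formats. A raw-trace file is a single column of
#' current samples preceded by a header block of `# key=value` lines carrying
#' `sampling_rate_hz` and `open_pore_current_pa`. A nanospectrum file is a
#' TSV with columns `event_id`, `duration_ms`, `sample_index`,
#' `fractional_current`.
#'
#' @param trace A [raw_trace()].
#' @param path File path.
#' @return `read_raw_trace` returns a [raw_trace()]; `read_nanospectra`
#'   returns a list of [nanospectrum()] objects.
#' @export
write_raw_trace <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz=%.10g", trace$sampling_rate_hz),
               sprintf("# open_pore_current_pa=%.10g", trace$open_pore_current_pa)),
             con)
  writeLines(sprintf("%.10g", trace$samples), con)
  invisible(path)
}

#' @rdname write_raw_trace
#' @export
read_raw_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (!length(m)) stop("raw trace header missing ", key)
    as.numeric(sub(".*=", "", m[1]))
  }
  samples <- as.numeric(lines[!grepl("^#", lines) & nzchar(lines)])
  raw_trace(samples, sampling_rate_hz = get("sampling_rate_hz"),
            open_pore_current_pa = get("open_pore_current_pa"))
}

#' @rdname write_raw_trace
#' @param spectra List of [nanospectrum()] objects.
#' @export
write_nanospectra <- function(spectra, path) {
  if (inherits(spectra, "nanospectrum")) spectra <- list(spectra)
  rows <- lapply(spectra, function(s) {
    id <- if (nzchar(s$source_id)) s$source_id else "event"
    data.frame(event_id = id, duration_ms = s$duration_ms,
               sample_index = seq_along(s$values),
               fractional_current = s$values)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raw_trace
#' @export
read_nanospectra <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$event_id), function(d) {
    d <- d[order(d$sample_index), ]
    nanospectrum(d$fractional_current, d$duration_ms[1], source_id = d$event_id[1])
  })
}
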