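# Consensus averaging of repeated translocations, correlation diagnostics,
# and fluctuation-frequency protein length estimation.

#' Randomly partition nanospectra into clusters
#'
#' When all spectra come from one pure protein, random clusters of size 5-10
#' averaged into consensus spectra substantially improve the signal-to-noise
#' ratio over single translocations.
#'
#' @param spectra List of [nanospectrum()] objects.
#' @param cluster_size Target cluster size (>= 1); the final cluster may be
#'   smaller.
#' @param seed RNG seed.
#' @return List of clusters, each a list of nanospectra.
#' @export
random_partition <- function(spectra, cluster_size, seed = 1) {
  if (length(spectra) == 0) stop("no spectra to partition")
  stopifnot(cluster_size >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(length(spectra))
  idx <- split(perm, ceiling(seq_along(perm) / cluster_size))
  lapply(unname(idx), function(i) spectra[i])
}

# Resample a value series to `n` points by linear interpolation on the
# normalized event index.
.resample <- function(values, n) {
  if (length(values) == n) return(as.numeric(values))
  stats::approx(x = seq(0, 1, length.out = length(values)), y = values,
                xout = seq(0, 1, length.out = n))$y
}

#' Consensus of a cluster of nanospectra
#'
#' Members are resampled to a common length by linear interpolation,
#' z-normalized and averaged pointwise. Uncorrelated noise shrinks as
#' 1/sqrt(n) while the shared translocation signal is preserved. The
#' consensus duration is the median member duration.
#'
#' @param cluster List of [nanospectrum()] objects (or a single one).
#' @param length_out Common length to resample to; defaults to the median
#'   member sample count. Set to a candidate's `L + 3` when one is known.
#' @return A [nanospectrum()] consensus.
#' @export
consensus_spectrum <- function(cluster, length_out = NULL) {
  if (inherits(cluster, "nanospectrum")) cluster <- list(cluster)
  if (length(cluster) == 0) stop("empty cluster")
  lens <- vapply(cluster, function(s) length(s$values), integer(1))
  if (is.null(length_out)) length_out <- as.integer(round(stats::median(lens)))
  mat <- vapply(cluster, function(s) znormalize(.resample(s$values, length_out)),
                numeric(length_out))
  vals <- rowMeans(mat)
  durs <- vapply(cluster, `[[`, numeric(1), "duration_ms")
  ids <- vapply(cluster, `[[`, character(1), "source_id")
  nanospectrum(vals, stats::median(durs),
               source_id = paste0("consensus[", length(cluster), "]:", ids[1]))
}

#' Pairwise Pearson correlations between two sets of nanospectra
#'
#' Resamples all spectra to a common length and computes the full matrix of
#' Pearson coefficients. With `spectra_b` identical to `spectra_a` the
#' diagonal is 1 and off-diagonal entries are self-correlations; across two
#' different proteins the entries are cross-correlations, which fluctuate
#' around zero while same-protein correlations are systematically positive.
#'
#' @param spectra_a,spectra_b Lists of [nanospectrum()] objects
#'   (`spectra_b` defaults to `spectra_a`).
#' @param length_out Common resampling length; defaults to the median sample
#'   count over both sets.
#' @return Matrix of correlations with attributes `median_self` (median of
#'   the within-`spectra_a` upper triangle when the two sets are identical,
#'   else `NA`) and `median_cross` (median over all a-vs-b pairs when the
#'   sets differ). Constant spectra yield `NA` entries (flagged with a
#'   warning), never zero.
#' @export
correlation_matrix <- function(spectra_a, spectra_b = spectra_a,
                               length_out = NULL) {
  same <- identical(spectra_a, spectra_b)
  lens <- vapply(c(spectra_a, spectra_b), function(s) length(s$values),
                 integer(1))
  if (is.null(length_out)) length_out <- as.integer(round(stats::median(lens)))
  resample_all <- function(ss)
    vapply(ss, function(s) .resample(s$values, length_out),
           numeric(length_out))
  ma <- resample_all(spectra_a)
  mb <- resample_all(spectra_b)
  const <- c(apply(ma, 2, stats::sd) == 0, apply(mb, 2, stats::sd) == 0)
  if (any(const))
    warning("constant spectra present; their correlations are undefined (NA)")
  cm <- suppressWarnings(stats::cor(ma, mb))
  if (same) {
    attr(cm, "median_self") <- stats::median(cm[upper.tri(cm)], na.rm = TRUE)
    attr(cm, "median_cross") <- NA_real_
  } else {
    attr(cm, "median_self") <- NA_real_
    attr(cm, "median_cross") <- stats::median(cm, na.rm = TRUE)
  }
  cm
}

#' Fluctuation frequency of a blockade
#'
#' The number of local maxima of the (optionally smoothed) event series
#' divided by the blockade duration in ms. Because the pore reads about one
#' window per residue, longer proteins fluctuate more often within a blockade
#' of given duration, making this frequency a length-correlated summary that
#' requires no database search.
#'
#' @param spectrum A [nanospectrum()].
#' @param smoothing_window Moving-average window in samples. The default
#'   `NULL` uses `length / (2 * max_length)`, suppressing sub-residue noise
#'   peaks for proteins up to `max_length` residues; `1` disables smoothing.
#' @param max_length Longest plausible protein for the default smoothing
#'   window (default 200 residues).
#' @param min_prominence Minimum prominence for a local maximum to count: the
#'   rise from the higher of its two flanking minima, as a fraction of the
#'   event's fluctuation standard deviation (default 0.5). Shallow
#'   noise-driven wiggles within one residue dwell are thereby ignored;
#'   set to 0 to count every strict local maximum.
#' @return A list with `frequency_per_ms`, `n_peaks`, `duration_ms`,
#'   `source_id`.
#' @export
fluctuation_frequency <- function(spectrum, smoothing_window = NULL,
                                  max_length = 200, min_prominence = 0.5) {
  stopifnot(inherits(spectrum, "nanospectrum"))
  v <- spectrum$values
  if (length(v) < 3) stop("need at least 3 samples to count peaks")
  if (is.null(smoothing_window))
    smoothing_window <- max(1L, floor(length(v) / (2 * max_length)))
  if (smoothing_window > 1) {
    kern <- rep(1 / smoothing_window, smoothing_window)
    v <- as.numeric(stats::filter(v, kern, sides = 2))
    v <- v[!is.na(v)]
  }
  n_peaks <- .count_peaks(v, min_prominence * pop_sd(v))
  list(frequency_per_ms = n_peaks / spectrum$duration_ms,
       n_peaks = n_peaks, duration_ms = spectrum$duration_ms,
       source_id = spectrum$source_id)
}

# Count interior local maxima with prominence >= delta over the higher of
# the two flanking minima; a plateau counts once (its leftmost sample).
.count_peaks <- function(v, delta = 0) {
  if (length(v) < 3) return(0L)
  d <- diff(v)
  keep <- d != 0                       # collapse plateaus
  if (!any(keep)) return(0L)
  vals <- c(v[1], v[-1][keep])         # alternating-extremum skeleton values
  d <- d[keep]
  if (length(d) < 2) return(0L)
  s <- sign(d)
  turn <- which(s[-length(s)] != s[-1]) + 1L  # indices into vals of extrema
  ext_vals <- c(vals[1], vals[turn], vals[length(vals)])
  is_max <- c(FALSE, s[turn - 1L] > 0, FALSE)
  if (delta <= 0) return(sum(is_max))
  n <- 0L
  for (i in which(is_max)) {
    prom <- ext_vals[i] - max(ext_vals[i - 1L], ext_vals[i + 1L])
    if (prom >= delta) n <- n + 1L
  }
  n
}

#' Cluster spectra by fluctuation frequency with a Gaussian mixture
#'
#' Fits a one-dimensional Gaussian mixture (unequal variances) to the
#' fluctuation frequencies of a set of spectra and assigns each spectrum to
#' its maximum-responsibility component — separating nanospectra of proteins
#' of different lengths before any database search.
#'
#' @param frequencies Numeric vector of per-spectrum fluctuation frequencies
#'   (peaks per ms), or a list of results from [fluctuation_frequency()].
#' @param n_components Number of mixture components (>= 1).
#' @param seed RNG seed (retained for interface stability; the model-based
#'   initialisation is itself deterministic).
#' @return List with `assignment` (integer component per spectrum), `means`,
#'   `sds`, `proportions`, and the fitted `mclust` object as `fit`.
#' @export
length_clusters <- function(frequencies, n_components, seed = 1) {
  if (is.list(frequencies))
    frequencies <- vapply(frequencies, `[[`, numeric(1), "frequency_per_ms")
  stopifnot(n_components >= 1, length(frequencies) >= n_components)
  if (n_components > 1 && length(unique(frequencies)) == 1)
    stop("all frequencies identical; cannot fit ", n_components, " components")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit <- mclust::Mclust(frequencies, G = n_components, modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit))
    fit <- mclust::Mclust(frequencies, G = n_components, modelNames = "E",
                          verbose = FALSE)
  if (is.null(fit)) stop("Gaussian mixture fit failed (degenerate input?)")
  list(assignment = as.integer(fit$classification),
       means = as.numeric(fit$parameters$mean),
       sds = sqrt(as.numeric(fit$parameters$variance$sigmasq)),
       proportions = as.numeric(fit$parameters$pro),
       fit = fit)
}
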