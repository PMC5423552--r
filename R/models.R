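# Theoretical nanospectrum models: Mean Volume (MV), Support Vector
# Regression (SVR) on volume-group compositions, and Random Forest (RF) on
# per-position volume/hydrophilicity pairs.

#' Overlapping k-mer windows of a protein, including translocation edges
#'
#' For a protein of length L and window size k, the pore reads L - k + 1 full
#' k-mers plus 2(k - 1) shorter prefix/suffix substrings at the start and end
#' of the translocation, when fewer than k residues occupy the pore waist:
#' a schedule of L + k - 1 windows. Window i covers residues
#' max(1, i - k + 1) .. min(i, L). When `pad` is TRUE, short edge windows are
#' right/left-padded with the neutral pseudo-residue `-` to length k.
#'
#' @param sequence Amino-acid sequence string.
#' @param k Window size (default 4, a quadromer).
#' @param pad Pad edge windows to length k with `-`?
#' @return Character vector of L + k - 1 window strings.
#' @export
#' @examples
#' protein_windows("KLMNP", k = 3)  # K KL KLM LMN MNP NP P
protein_windows <- function(sequence, k = 4, pad = FALSE) {
  r <- .residues(sequence)
  n <- length(r)
  if (n < k) stop(sprintf("protein length %d is shorter than window size %d", n, k))
  vapply(seq_len(n + k - 1), function(i) {
    w <- r[max(1L, i - k + 1L):min(i, n)]
    if (pad && length(w) < k) {
      npad <- k - length(w)
      w <- if (i < k) c(rep("-", npad), w) else c(w, rep("-", npad))
    }
    paste(w, collapse = "")
  }, character(1))
}

#' Mean Volume model
#'
#' The simplest response model: the blockade level at each read position is
#' the mean crystallographic volume of the residues occupying the pore waist.
#' `mv_model()` returns a model object usable with [theoretical_spectrum()];
#' `mv_spectrum()` computes the spectrum directly.
#'
#' @param k Window size; the default 4 corresponds to a quadromer read.
#' @return `mv_model()`: an object of class `mv_model`. `mv_spectrum()`:
#'   numeric vector of length `nchar(sequence) + k - 1` of mean window
#'   volumes (nm^3); edge windows average over the residues present.
#' @export
#' @examples
#' mv_spectrum("KLMNP", k = 3)  # length 7: K KL KLM LMN MNP NP P
mv_model <- function(k = 4) {
  structure(list(k = k), class = c("mv_model", "spectrum_model"))
}

#' @rdname mv_model
#' @param sequence Amino-acid sequence string.
#' @export
mv_spectrum <- function(sequence, k = 4) {
  r <- .residues(sequence)
  n <- length(r)
  if (n < k) stop(sprintf("protein length %d is shorter than window size %d", n, k))
  cs <- cumsum(c(0, unname(aa_volume(r))))
  i <- seq_len(n + k - 1)
  a <- pmax(1L, i - k + 1L)
  b <- pmin(i, n)
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}

#' Predict a theoretical nanospectrum from a sequence
#'
#' Generic over the three model classes. All models return a vector of
#' length `nchar(sequence) + k - 1` (with the default quadromer read,
#' `L + 3`), matching the discretization length used for empirical spectra.
#'
#' @param model A model object from [mv_model()], [train_svr()] or
#'   [train_rf()].
#' @param sequence Amino-acid sequence string.
#' @param ... Unused.
#' @return Numeric vector of length `nchar(sequence) + k - 1`.
#' @export
theoretical_spectrum <- function(model, sequence, ...) {
  UseMethod("theoretical_spectrum")
}

#' @export
theoretical_spectrum.mv_model <- function(model, sequence, ...) {
  mv_spectrum(sequence, k = model$k)
}

#' @export
theoretical_spectrum.svr_model <- function(model, sequence, ...) {
  wins <- protein_windows(sequence, k = model$k, pad = TRUE)
  feats <- t(vapply(wins, composition_feature, integer(4)))
  unname(stats::predict(model$fit, feats))
}

#' @export
theoretical_spectrum.rf_model <- function(model, sequence, ...) {
  wins <- protein_windows(sequence, k = model$k, pad = TRUE)
  feats <- t(vapply(wins, .rf_feature_row, numeric(2 * model$k)))
  colnames(feats) <- model$feature_names
  unname(stats::predict(model$fit, feats))
}

# Flatten the per-position (volume, hydrophilicity) pairs of one k-mer into
# a single feature row (v1, h1, v2, h2, ...).
.rf_feature_row <- function(kmer) {
  as.numeric(t(pair_feature(kmer)))
}

#' Training pairs for the supervised models
#'
#' Builds (k-mer, signal) training pairs from an empirical nanospectrum of a
#' known protein: the protein is tiled into its L + k - 1 (padded) windows and
#' the spectrum is discretized into L + k - 1 points and z-normalized, so each
#' window is paired with the signal level observed while it occupied the pore
#' (index-by-index, under the uniform-translocation-velocity assumption).
#'
#' @param sequence Amino-acid sequence of the protein that generated the
#'   spectrum.
#' @param spectrum A [nanospectrum()] (typically a consensus of several
#'   translocations) or numeric vector.
#' @param k Window size (default 4).
#' @return A data.frame with columns `kmer` and `signal`.
#' @export
training_pairs <- function(sequence, spectrum, k = 4) {
  wins <- protein_windows(sequence, k = k, pad = TRUE)
  emp <- znormalize(discretize(spectrum, length(wins)))
  data.frame(kmer = wins, signal = emp, stringsAsFactors = FALSE)
}

#' Permutation augmentation of training pairs
#'
#' Expands a training set under the assumption that the blockade current does
#' not depend on the order of residues within the pore: each k-mer is
#' replicated `n_permutations` times with its residues uniformly permuted,
#' keeping the associated signal value unchanged.
#'
#' @param pairs Data.frame with columns `kmer`, `signal`.
#' @param n_permutations Permuted copies added per pair (default 10).
#' @param seed RNG seed for reproducibility.
#' @return Augmented data.frame of `nrow(pairs) * (1 + n_permutations)` rows.
#' @export
augment_permute <- function(pairs, n_permutations = 10, seed = 1) {
  stopifnot(n_permutations >= 0)
  if (n_permutations == 0) return(pairs)
  out <- vector("list", 1 + n_permutations)
  out[[1]] <- pairs
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (j in seq_len(n_permutations)) {
    perm <- pairs
    perm$kmer <- vapply(pairs$kmer, function(km) {
      r <- strsplit(km, "", fixed = TRUE)[[1]]
      paste(sample(r), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    out[[j + 1]] <- perm
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Train the SVR response model
#'
#' Epsilon-regression with a radial basis function kernel (libsvm via e1071)
#' on volume-group composition features. The defaults C = 1000,
#' gamma = 0.001, epsilon = 0.01 are the cross-validated settings for
#' sub-nanopore blockade data. Because the feature is the 4-group composition
#' of a quadromer, the model's input space has only 35 distinct points.
#'
#' @param pairs Data.frame with columns `kmer`, `signal` (see
#'   [training_pairs()]).
#' @param C Cost parameter.
#' @param gamma RBF kernel width.
#' @param epsilon Epsilon-insensitive loss width.
#' @param k Window size the pairs were generated with (default 4).
#' @return An object of class `svr_model` usable with
#'   [theoretical_spectrum()].
#' @export
train_svr <- function(pairs, C = 1000, gamma = 0.001, epsilon = 0.01, k = 4) {
  if (is.null(pairs) || nrow(pairs) == 0) stop("empty training set")
  feats <- t(vapply(pairs$kmer, composition_feature, integer(4)))
  fit <- e1071::svm(x = feats, y = pairs$signal, type = "eps-regression",
                    kernel = "radial", cost = C, gamma = gamma,
                    epsilon = epsilon, scale = FALSE)
  structure(list(fit = fit, k = k,
                 params = list(C = C, gamma = gamma, epsilon = epsilon)),
            class = c("svr_model", "spectrum_model"))
}

#' @rdname train_svr
#' @param model A trained `svr_model`.
#' @param sequence Amino-acid sequence string.
#' @export
svr_spectrum <- function(model, sequence) {
  stopifnot(inherits(model, "svr_model"))
  theoretical_spectrum(model, sequence)
}

#' Train the Random Forest response model
#'
#' Random-forest regression on ordered per-position (volume, hydrophilicity)
#' pairs. Hydrophilicity captures the effect of bound water on the effective
#' residue volume, which the volume-only models miss. Training sets are
#' usually expanded with [augment_permute()] first, making the learned
#' response approximately order-free.
#'
#' @param pairs Data.frame with columns `kmer`, `signal` (after any
#'   augmentation).
#' @param n_trees Number of trees (default 100).
#' @param seed RNG seed; fixing it makes training deterministic.
#' @param k Window size (default 4).
#' @return An object of class `rf_model` usable with
#'   [theoretical_spectrum()].
#' @export
train_rf <- function(pairs, n_trees = 100, seed = 1, k = 4) {
  if (is.null(pairs) || nrow(pairs) == 0) stop("empty training set")
  feats <- t(vapply(pairs$kmer, .rf_feature_row, numeric(2 * k)))
  colnames(feats) <- as.vector(t(outer(seq_len(k), c("volume", "hydro"),
                                       function(i, nm) paste0(nm, i))))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit <- randomForest::randomForest(x = feats, y = pairs$signal,
                                    ntree = n_trees)
  structure(list(fit = fit, k = k, feature_names = colnames(feats),
                 params = list(n_trees = n_trees, seed = seed)),
            class = c("rf_model", "spectrum_model"))
}

#' @rdname train_rf
#' @param model A trained `rf_model`.
#' @param sequence Amino-acid sequence string.
#' @export
rf_spectrum <- function(model, sequence) {
  stopifnot(inherits(model, "rf_model"))
  theoretical_spectrum(model, sequence)
}

#' Per-residue signed error profile of a model
#'
#' Measures model bias per amino acid: the signed error at a read position is
#' the empirical minus the theoretical value, and each residue's error is the
#' mean over all positions whose window contains that residue. Also fits the
#' linear trend of residue error against residue volume and against
#' hydrophilicity, reporting slope and p-value for a non-zero slope — a
#' volume-biased model under-predicts large residues and over-predicts small
#' ones, producing a non-zero slope.
#'
#' @param empirical Discretized, z-normalized empirical vector
#'   (length L + k - 1).
#' @param theoretical Model output for the same protein, z-normalized.
#' @param sequence The protein's amino-acid sequence.
#' @param k Window size (default 4).
#' @return A list with `profile` (data.frame: residue, mean_error, n_windows;
#'   residues absent from the protein have `NA` mean_error),
#'   `volume_slope`, `volume_p`, `hydrophilicity_slope`, `hydrophilicity_p`.
#' @export
signed_error <- function(empirical, theoretical, sequence, k = 4) {
  if (length(empirical) != length(theoretical))
    stop(sprintf("length mismatch: empirical %d vs theoretical %d",
                 length(empirical), length(theoretical)))
  wins <- protein_windows(sequence, k = k, pad = FALSE)
  if (length(wins) != length(empirical))
    stop("vector length does not match the window schedule of the sequence")
  err <- empirical - theoretical
  tab <- aa_properties()
  per <- lapply(tab$residue, function(res) {
    hit <- vapply(wins, function(w) grepl(res, w, fixed = TRUE), logical(1))
    data.frame(residue = res,
               mean_error = if (any(hit)) mean(err[hit]) else NA_real_,
               n_windows = sum(hit))
  })
  profile <- do.call(rbind, per)
  present <- !is.na(profile$mean_error)
  slope_fit <- function(xvals) {
    if (sum(present) < 3) return(c(NA_real_, NA_real_))
    fit <- stats::lm(profile$mean_error[present] ~ xvals[present])
    cf <- summary(fit)$coefficients
    c(cf[2, 1], cf[2, 4])
  }
  vs <- slope_fit(tab$volume_nm3)
  hs <- slope_fit(tab$hydrophilicity)
  list(profile = profile,
       volume_slope = vs[1], volume_p = vs[2],
       hydrophilicity_slope = hs[1], hydrophilicity_p = hs[2])
}
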