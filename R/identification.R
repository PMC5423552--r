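# Database search: R^2 scoring of nanospectra against candidate proteins,
# decoy databases and empirical p-values.

#' Coefficient of determination between observed and predicted spectra
#'
#' `R^2 = 1 - SS_res / SS_tot`, with the total sum of squares taken about the
#' mean of the observed vector. Both vectors are expected on a common
#' (z-normalized) scale; the value is at most 1 and can be negative when the
#' prediction is worse than the observed mean.
#'
#' @param observed Numeric vector (discretized, z-normalized nanospectrum).
#' @param predicted Numeric vector of equal length (model output).
#' @return Scalar R^2.
#' @export
r2_score <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop(sprintf("length mismatch: observed %d vs predicted %d",
                 length(observed), length(predicted)))
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  1 - ss_res / ss_tot
}

#' Read a protein database from FASTA
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Data.frame with columns `id` (first token of the description
#'   line) and `sequence`.
#' @export
read_fasta_db <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  data.frame(id = vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1),
             sequence = as.character(aas),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fasta_db
#' @param db Data.frame with columns `id`, `sequence`.
#' @export
write_fasta_db <- function(db, path) {
  aas <- Biostrings::AAStringSet(db$sequence)
  names(aas) <- db$id
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' Precompute normalized theoretical spectra for a database
#'
#' Computing model output for every candidate once and reusing it across many
#' spectra (or many consensus clusters) dominates the cost of a search; this
#' helper builds that cache.
#'
#' @param db Data.frame with columns `id`, `sequence`.
#' @param model A spectrum model ([mv_model()], [train_svr()], [train_rf()]).
#' @param both_orientations Also cache the reversed-sequence spectrum?
#' @return List (parallel to `db` rows) of lists with `forward` and
#'   optionally `reverse` z-normalized prediction vectors.
#' @export
precompute_spectra <- function(db, model, both_orientations = TRUE) {
  lapply(seq_len(nrow(db)), function(i) {
    seq_i <- db$sequence[i]
    out <- list(forward = znormalize(theoretical_spectrum(model, seq_i)))
    if (both_orientations)
      out$reverse <- znormalize(theoretical_spectrum(model, .revseq(seq_i)))
    out
  })
}

.revseq <- function(sequence) {
  paste(rev(strsplit(sequence, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Identify a nanospectrum against a protein database
#'
#' For each candidate protein the spectrum is discretized to the candidate's
#' read length (L + k - 1), z-normalized and scored by [r2_score()] against
#' the z-normalized model prediction; with `both_orientations` the
#' reversed-sequence prediction is also scored and the better orientation
#' kept (a molecule can thread through the pore N- or C-terminus first).
#' Candidates are ranked by decreasing R^2, ties broken by id.
#'
#' @param spectrum A [nanospectrum()] (or numeric vector of fractional
#'   blockade values).
#' @param db Data.frame with columns `id`, `sequence` (see
#'   [read_fasta_db()]).
#' @param model A spectrum model.
#' @param both_orientations Score both translocation orientations
#'   (default TRUE)?
#' @param theoretical Optional cache from [precompute_spectra()] for this
#'   `db`/`model`/orientation setting.
#' @param k Window size (default 4).
#' @return Data.frame of protein-nanospectrum matches, one row per scored
#'   candidate: `protein_id`, `r2`, `rank`, `orientation`. Candidates whose
#'   read length exceeds the spectrum's sample count are skipped with a
#'   warning.
#' @export
identify_protein <- function(spectrum, db, model, both_orientations = TRUE,
                             theoretical = NULL, k = 4) {
  stopifnot(nrow(db) >= 1)
  vals <- if (inherits(spectrum, "nanospectrum")) spectrum$values else
    as.numeric(spectrum)
  if (is.null(theoretical))
    theoretical <- precompute_spectra(db, model, both_orientations)
  # spectra are re-discretized per candidate length; cache by length
  disc_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(db))
  skipped <- character()
  for (i in seq_len(nrow(db))) {
    len <- nchar(db$sequence[i]) + k - 1
    if (length(vals) < len) {
      skipped <- c(skipped, db$id[i])
      next
    }
    key <- as.character(len)
    obs <- disc_cache[[key]]
    if (is.null(obs)) {
      obs <- znormalize(discretize(vals, len))
      disc_cache[[key]] <- obs
    }
    r2_f <- r2_score(obs, theoretical[[i]]$forward)
    if (both_orientations && !is.null(theoretical[[i]]$reverse)) {
      r2_r <- r2_score(obs, theoretical[[i]]$reverse)
      if (r2_r > r2_f) {
        rows[[i]] <- data.frame(protein_id = db$id[i], r2 = r2_r,
                                orientation = "reverse")
        next
      }
    }
    rows[[i]] <- data.frame(protein_id = db$id[i], r2 = r2_f,
                            orientation = "forward")
  }
  if (length(skipped))
    warning("skipped ", length(skipped),
            " candidate(s) longer than the spectrum allows: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no candidate could be scored against this spectrum")
  res <- res[order(-res$r2, res$protein_id), ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res[, c("protein_id", "r2", "rank", "orientation")]
}

#' Generate a decoy database for a protein
#'
#' Decoys are uniform random shuffles of the source sequence: same length,
#' identical residue multiset. Scoring a spectrum against the true protein
#' and its decoys calibrates the match p-value empirically.
#'
#' @param sequence Source amino-acid sequence.
#' @param n Number of decoys.
#' @param seed RNG seed (decoys are deterministic given the seed).
#' @param source_id Id recorded for provenance.
#' @return Data.frame with columns `id` (`decoy_00001`, ...) and `sequence`;
#'   attributes `source_id` and `seed`.
#' @export
generate_decoys <- function(sequence, n, seed = 1, source_id = "source") {
  stopifnot(n >= 1)
  r <- .residues(sequence)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) paste(sample(r), collapse = ""),
                 character(1))
  structure(data.frame(id = sprintf("decoy_%05d", seq_len(n)),
                       sequence = seqs, stringsAsFactors = FALSE),
            source_id = source_id, seed = seed)
}

#' Empirical p-value of a protein-nanospectrum match
#'
#' The p-value is the fraction of decoys whose R^2 against the spectrum is
#' strictly greater than the true protein's (ties do not count against the
#' match). The pseudocount variant `(r + 1) / (N + 1)` is reported alongside;
#' it never returns an exact zero and is the better-behaved estimator at
#' small decoy counts.
#'
#' @param spectrum A [nanospectrum()] or numeric vector.
#' @param sequence The true (matched) protein sequence.
#' @param decoys Decoy database from [generate_decoys()].
#' @param model A spectrum model.
#' @param both_orientations Score both orientations (default TRUE)?
#' @param theoretical Optional [precompute_spectra()] cache for the decoys.
#' @param k Window size (default 4).
#' @return List with `p_value`, `p_value_pseudocount`, `r2_true`,
#'   `n_decoys`, `n_higher`.
#' @export
pvalue <- function(spectrum, sequence, decoys, model,
                   both_orientations = TRUE, theoretical = NULL, k = 4) {
  if (is.null(decoys) || nrow(decoys) == 0) stop("empty decoy set")
  db <- rbind(data.frame(id = ".__true__", sequence = sequence,
                         stringsAsFactors = FALSE),
              decoys[, c("id", "sequence")])
  if (!is.null(theoretical)) {
    true_theo <- precompute_spectra(
      data.frame(id = ".__true__", sequence = sequence), model,
      both_orientations)
    theoretical <- c(true_theo, theoretical)
  }
  res <- identify_protein(spectrum, db, model,
                          both_orientations = both_orientations,
                          theoretical = theoretical, k = k)
  r2_true <- res$r2[res$protein_id == ".__true__"]
  n_higher <- sum(res$r2 > r2_true & res$protein_id != ".__true__")
  n <- nrow(decoys)
  list(p_value = n_higher / n,
       p_value_pseudocount = (n_higher + 1) / (n + 1),
       r2_true = r2_true, n_decoys = n, n_higher = n_higher)
}

#' Write a table of protein-nanospectrum matches
#'
#' @param matches Data.frame as returned by [identify_protein()], optionally
#'   with extra columns (`spectrum_id`, `p_value`).
#' @param path Output TSV path.
#' @export
write_prnm <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
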