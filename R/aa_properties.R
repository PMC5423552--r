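# Amino-acid physical property tables and k-mer feature encodings shared by
# all nanospectrum models.

.aa_env <- new.env(parent = emptyenv())

#' Amino-acid property table
#'
#' Returns the residue property table used throughout the package: one row per
#' proteinogenic amino acid with its crystallographic volume (nm^3), a
#' hydrophilicity scale value (Kyte-Doolittle hydropathy by default) and the
#' volume group implied by the thresholds 0.11, 0.15 and 0.2 nm^3.
#'
#' The default table ships with the package as a plain TSV
#' (`system.file("extdata", "aa_properties.tsv", package = "nanospectra")`).
#' An alternative table — e.g. a different hydrophilicity scale — can be
#' substituted for the whole session with [use_aa_properties()].
#'
#' @return A data.frame with columns `residue`, `volume_nm3`, `hydrophilicity`
#'   and `group` (factor with levels Minuscule, Small, Intermediate, Large).
#' @export
#' @examples
#' head(aa_properties())
aa_properties <- function() {
  if (is.null(.aa_env$table)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "nanospectra")
    use_aa_properties(path)
  }
  .aa_env$table
}

#' Substitute an alternative amino-acid property table
#'
#' @param path Path to a TSV with columns `residue`, `volume_nm3`,
#'   `hydrophilicity` and optionally `group` (recomputed from the volume
#'   thresholds if absent).
#' @return The loaded table, invisibly.
#' @export
use_aa_properties <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "volume_nm3", "hydrophilicity")
  if (!all(need %in% names(tab)))
    stop("property table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) != 20L || anyDuplicated(tab$residue))
    stop("property table must contain exactly the 20 proteinogenic residues")
  tab$group <- factor(.group_from_volume(tab$volume_nm3), levels = VOLUME_GROUPS)
  rownames(tab) <- tab$residue
  .aa_env$table <- tab
  .aa_env$volume <- stats::setNames(tab$volume_nm3, tab$residue)
  .aa_env$hydro <- stats::setNames(tab$hydrophilicity, tab$residue)
  .aa_env$group <- stats::setNames(as.character(tab$group), tab$residue)
  invisible(tab)
}

#' @rdname volume_group
#' @format NULL
#' @export
VOLUME_GROUPS <- c("Large", "Intermediate", "Small", "Minuscule")

# Volume thresholds (nm^3) separating the four groups.
.group_from_volume <- function(v) {
  ifelse(v > 0.2, "Large",
         ifelse(v > 0.15, "Intermediate",
                ifelse(v > 0.11, "Small", "Minuscule")))
}

# Split a k-mer string into residue characters, validating against the table.
# The pad character "-" (pseudo-residue with zero volume and hydrophilicity,
# used for the short prefix/suffix windows at translocation start/end) is
# allowed when `allow_pad` is TRUE.
.residues <- function(kmer, allow_pad = FALSE) {
  stopifnot(is.character(kmer), length(kmer) == 1L)
  r <- strsplit(kmer, "", fixed = TRUE)[[1]]
  known <- names(.aa_lookup("volume"))
  bad <- setdiff(r, c(known, if (allow_pad) "-"))
  if (length(bad))
    stop("unknown residue symbol(s): ", paste(unique(bad), collapse = ", "))
  r
}

.aa_lookup <- function(what) {
  if (is.null(.aa_env$table)) aa_properties()
  .aa_env[[what]]
}

#' Residue volume and hydrophilicity lookup
#'
#' `aa_volume()` returns crystallographic residue volumes in nm^3;
#' `aa_hydrophilicity()` returns the hydrophilicity scale value. Both are
#' vectorised over one-letter codes and fail loudly on any symbol that is not
#' one of the 20 proteinogenic residues.
#'
#' @param residue Character vector of one-letter residue codes.
#' @return Numeric vector, named by residue.
#' @export
#' @examples
#' aa_volume("G") < 0.11   # Minuscule
#' aa_volume("W") > 0.2    # Large
aa_volume <- function(residue) {
  v <- .aa_lookup("volume")
  bad <- setdiff(residue, names(v))
  if (length(bad))
    stop("unknown residue symbol(s): ", paste(unique(bad), collapse = ", "))
  v[residue]
}

#' @rdname aa_volume
#' @export
aa_hydrophilicity <- function(residue) {
  h <- .aa_lookup("hydro")
  bad <- setdiff(residue, names(h))
  if (length(bad))
    stop("unknown residue symbol(s): ", paste(unique(bad), collapse = ", "))
  h[residue]
}

#' Volume group of a residue
#'
#' Assigns each residue to one of four volume groups using half-open
#' thresholds on the crystallographic volume: Minuscule (<= 0.11 nm^3),
#' Small (0.11, 0.15], Intermediate (0.15, 0.2] and Large (> 0.2 nm^3).
#'
#' @param residue Character vector of one-letter residue codes.
#' @return Character vector of group labels, named by residue.
#' @export
#' @examples
#' volume_group("Q")  # "Intermediate"
#' volume_group("D")  # "Small"
volume_group <- function(residue) {
  g <- .aa_lookup("group")
  bad <- setdiff(residue, names(g))
  if (length(bad))
    stop("unknown residue symbol(s): ", paste(unique(bad), collapse = ", "))
  g[residue]
}

#' Volume-group composition feature of a k-mer
#'
#' Encodes a k-mer as the counts of its residues in each of the four volume
#' groups, ordered (Large, Intermediate, Small, Minuscule). The order of
#' residues within the k-mer does not matter, only the composition; e.g.
#' `"GQLD"` maps to `(0, 2, 1, 1)`. Pad characters `"-"` (short windows at the
#' start/end of a translocation) contribute to no group.
#'
#' @param kmer A single k-mer string.
#' @return Named integer vector of length 4 summing to the number of
#'   non-pad residues.
#' @export
#' @examples
#' composition_feature("GQLD")  # 0 Large, 2 Intermediate, 1 Small, 1 Minuscule
composition_feature <- function(kmer) {
  r <- .residues(kmer, allow_pad = TRUE)
  r <- r[r != "-"]
  counts <- table(factor(volume_group(r), levels = VOLUME_GROUPS))
  stats::setNames(as.integer(counts), VOLUME_GROUPS)
}

#' Enumerate all distinct composition features
#'
#' All multisets of size `k` over `groups` categories — the feature space of
#' the composition-based regression model. Its cardinality is the
#' stars-and-bars count `choose(k + groups - 1, groups - 1)`; for quadromers
#' over four volume groups that is 35, versus 20^4 = 160 000 raw quadromers.
#'
#' @param k Window (k-mer) size, >= 1.
#' @param groups Number of categories, >= 1.
#' @return Integer matrix with `groups` columns; one row per composition,
#'   rows summing to `k`.
#' @export
#' @examples
#' nrow(enumerate_compositions(4, 4))  # 35
enumerate_compositions <- function(k, groups = 4L) {
  stopifnot(k >= 1, groups >= 1)
  rec <- function(remaining, slots) {
    if (slots == 1L) return(matrix(remaining, ncol = 1L))
    do.call(rbind, lapply(0:remaining, function(i)
      cbind(i, rec(remaining - i, slots - 1L))))
  }
  m <- rec(as.integer(k), as.integer(groups))
  dimnames(m) <- NULL
  m
}

#' Per-position (volume, hydrophilicity) feature of a k-mer
#'
#' Encodes a k-mer as an ordered sequence of (volume, hydrophilicity) pairs,
#' one per position — the feature representation used by the random-forest
#' model. Pad characters `"-"` map to the neutral pair (0, 0).
#'
#' @param kmer A single k-mer string.
#' @return Numeric matrix with one row per position and columns `volume`,
#'   `hydrophilicity`.
#' @export
pair_feature <- function(kmer) {
  r <- .residues(kmer, allow_pad = TRUE)
  v <- ifelse(r == "-", 0, unname(aa_volume(replace(r, r == "-", "G"))))
  h <- ifelse(r == "-", 0, unname(aa_hydrophilicity(replace(r, r == "-", "G"))))
  cbind(volume = v, hydrophilicity = h)
}
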