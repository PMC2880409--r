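# Biochemical feature table: hydrophobicity index (H), side-chain pKa (K)
# and molecular mass (M) per amino acid, with min-max scaling to [0, 1].

FEATURE_NAMES <- c("H", "K", "M")
STANDARD_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AMBIGUITY_AA <- c("X", "B", "Z", "J", "U", "O")

#' Load the biochemical feature table
#'
#' Reads a tab-separated table mapping amino-acid letters to the three
#' biochemical features used for residue encoding: hydrophobicity index (H,
#' Kyte-Doolittle scale by default), side-chain pKa (K, 0 for residues without
#' an ionizable side chain) and monoisotopic residue mass (M, Da). The default
#' table ships with the package; an alternative scale can be supplied as a
#' file with columns \code{letter}, \code{H}, \code{K}, \code{M} covering the
#' 20 standard amino acids.
#'
#' @param path path to a feature table file, or NULL for the packaged default.
#' @return a data.frame with rownames the amino-acid letters (20 standard
#'   plus ambiguity codes mapped to per-feature means) and columns H, K, M;
#'   attribute \code{"range"} holds the per-feature (min, max) over the 20
#'   standard amino acids, used for scaling.
#' @examples
#' tab <- featureTable()
#' tab["R", ]   # arginine: hydrophilic, high pKa
#' @export
featureTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hkm_features.tsv", package = "nabind")
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("letter", FEATURE_NAMES)
  if (!all(need %in% names(raw)))
    stop("feature table must have columns letter, H, K, M")
  raw$letter <- toupper(raw$letter)
  missing <- setdiff(STANDARD_AA, raw$letter)
  if (length(missing))
    stop("feature table is missing amino acids: ",
         paste(missing, collapse = ", "))
  tab <- raw[match(STANDARD_AA, raw$letter), FEATURE_NAMES]
  rownames(tab) <- STANDARD_AA
  rng <- vapply(tab, range, numeric(2))
  if (any(rng[2, ] - rng[1, ] <= 0))
    stop("degenerate feature column: a feature is constant over amino acids")
  # ambiguity codes take the per-feature mean over the 20 standard residues
  amb <- as.data.frame(lapply(tab, mean))
  for (a in AMBIGUITY_AA) tab[a, ] <- amb
  attr(tab, "range") <- rng
  tab
}

#' Min-max scale a feature table to [0, 1]
#'
#' Each feature is independently mapped so that its minimum over the 20
#' standard amino acids becomes 0 and its maximum 1; the map is strictly
#' increasing, so ranks are preserved. Applying it to an already scaled table
#' is the identity.
#'
#' @param table a feature table from \code{\link{featureTable}}.
#' @return the table with all values scaled to [0, 1]; attribute
#'   \code{"range"} is updated to the unit interval per feature.
#' @export
normalizeFeatureTable <- function(table) {
  rng <- attr(table, "range")
  if (is.null(rng))
    rng <- vapply(table[STANDARD_AA, ], range, numeric(2))
  span <- rng[2, ] - rng[1, ]
  if (any(span <= 0))
    stop("degenerate feature column: cannot scale a constant feature")
  out <- table
  for (j in seq_along(FEATURE_NAMES))
    out[[j]] <- (table[[j]] - rng[1, j]) / span[j]
  attr(out, "range") <- rbind(rep(0, 3), rep(1, 3))
  dimnames(attr(out, "range")) <- dimnames(rng)
  out
}

#' Feature values of a single residue
#'
#' @param aa a single upper-case amino-acid letter; unknown letters and
#'   ambiguity codes return the per-feature mean over the standard residues.
#' @param table feature table (raw or scaled) from \code{\link{featureTable}}.
#' @param scaled if TRUE, min-max scale the returned values with the table's
#'   per-feature bounds.
#' @return named numeric(3): H, K, M.
#' @examples
#' residueFeatures("G", featureTable(), scaled = TRUE)["M"]  # lightest: 0
#' @export
residueFeatures <- function(aa, table, scaled = FALSE) {
  if (!is.character(aa) || length(aa) != 1L || !grepl("^[A-Za-z]$", aa))
    stop("invalid residue: expected a single letter, got ",
         deparse(substitute(aa)))
  aa <- toupper(aa)
  tab <- if (scaled) normalizeFeatureTable(table) else table
  row <- if (aa %in% rownames(tab)) tab[aa, ] else tab["X", ]
  v <- as.numeric(row)
  names(v) <- FEATURE_NAMES
  v
}

# Feature lookup matrix for fast vectorized encoding: rows A..Z domain.
featureLookup <- function(table, scaled = TRUE) {
  tab <- if (scaled) normalizeFeatureTable(table) else table
  m <- as.matrix(tab)
  all_letters <- LETTERS
  out <- m[rep("X", 26), , drop = FALSE]
  rownames(out) <- all_letters
  known <- intersect(rownames(m), all_letters)
  out[known, ] <- m[known, ]
  out
}
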