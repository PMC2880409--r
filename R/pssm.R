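# Position-specific scoring matrix (PSSM) parsing, writing and scaling.
#
# The ASCII matrix emitted by PSI-BLAST (-out_ascii_pssm) carries, per query
# position, 20 integer log-odds substitution scores in the fixed column order
# ARNDCQEGHILKMFPSTWYV, followed by a second block of weighted percentages
# that is ignored here.

PSSM_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read an ASCII PSSM matrix file
#'
#' Parses the plain-text matrix written by PSI-BLAST. Only the first score
#' block (20 log-odds columns) is used; the trailing information-content and
#' pseudocount fields are ignored.
#'
#' @param path path to the ASCII PSSM file.
#' @param id query identifier to attach; defaults to the file name.
#' @return a \linkS4class{PSSMProfile}.
#' @export
readPSSM <- function(path, id = NULL) {
  if (!file.exists(path))
    stop("PSSM file not found: ", path)
  if (is.null(id))
    id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  # data rows start with a position index followed by a residue letter
  isData <- grepl("^\\s*[0-9]+\\s+[A-Za-z*]\\s", lines)
  rows <- which(isData)
  if (length(rows) == 0L)
    stop("no PSSM data rows found in ", path)
  n <- length(rows)
  scores <- matrix(0, n, 20, dimnames = list(NULL, PSSM_ALPHABET))
  residues <- character(n)
  for (k in seq_len(n)) {
    tok <- strsplit(trimws(lines[rows[k]]), "\\s+")[[1]]
    if (length(tok) < 22L)
      stop("malformed PSSM row at line ", rows[k], ": expected >= 22 fields, got ",
           length(tok))
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (any(is.na(vals)))
      stop("malformed PSSM row at line ", rows[k], ": non-numeric score")
    scores[k, ] <- vals
    residues[k] <- toupper(tok[2])
  }
  new("PSSMProfile", id = id, scores = scores, residues = residues)
}

#' Write a PSSMProfile as an ASCII matrix file
#'
#' Emits the same layout \code{\link{readPSSM}} consumes (two header lines, a
#' column-letter line, one row per position with the 20 log-odds scores), so
#' synthetic profiles can travel through the identical file interface as real
#' search output.
#'
#' @param profile a \linkS4class{PSSMProfile}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePSSM <- function(profile, path) {
  stopifnot(is(profile, "PSSMProfile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste0("            ", paste(sprintf("%3s", PSSM_ALPHABET),
                                            collapse = " "))), con)
  sc <- pssmScores(profile)
  for (i in seq_len(nrow(sc))) {
    writeLines(sprintf("%5d %s  %s", i, profile@residues[i],
                       paste(sprintf("%3d", as.integer(round(sc[i, ]))),
                             collapse = " ")), con)
  }
  invisible(path)
}

#' Logistic scaling of PSSM scores to (0, 1)
#'
#' Maps a raw log-odds score x to 1 / (1 + exp(-x)): strictly increasing,
#' symmetric about 0 (which maps to 0.5), so score ordering is preserved at
#' every position while the SVM sees values commensurate with the [0, 1]
#' biochemical features.
#'
#' @param raw numeric vector or matrix of raw PSSM scores.
#' @return values in (0, 1), same shape as \code{raw}.
#' @examples
#' scalePssmScores(c(-2, 0, 2))
#' @export
scalePssmScores <- function(raw) {
  if (any(!is.finite(raw)))
    stop("raw PSSM scores must be finite")
  1 / (1 + exp(-raw))
}
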