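# Conservation descriptors of evolutionary information.
#
# For a query sequence p with aligned homologues B_p = {b_1, ..., b_j}, each
# query position i collects the residues aligned to it (the query residue
# included, gaps and ambiguity codes in homologues excluded). Per position
# and per biochemical feature X in {H, K, M} the descriptor is the mean and
# the population standard deviation of X over those observed residues: six
# numbers per position. A well-conserved column has a small sigma; binding
# residues tend to be conserved, so the descriptors carry signal that the
# general-purpose PSSM log-odds scores do not fully capture.

GAP_CHARS <- c("-", ".")

asAlignmentMatrix <- function(msa) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa))
    msa <- Biostrings::readAAStringSet(msa)
  if (is(msa, "XStringSet"))
    msa <- as.matrix(msa)
  if (!is.matrix(msa))
    stop("alignment must be an aligned-FASTA path, an AAStringSet or a matrix")
  toupper(msa)
}

#' Collect per-column residue observations for a query
#'
#' For each position of the query sequence, gathers the query residue plus
#' every non-gap, unambiguous homologue residue aligned to that position.
#' Input is either a multiple alignment whose first record is the query, or a
#' table of pairwise local alignments in query/subject coordinates (as
#' produced by tabular PSI-BLAST output with aligned sequence text). With
#' pairwise input, duplicate subjects are collapsed and, per subject, only
#' its best-scoring alignment contributes at each query position; positions
#' outside every alignment span carry the query residue alone.
#'
#' @param query the ungapped query sequence (character string).
#' @param msa an aligned-FASTA path, AAStringSet or character matrix; the
#'   first row must be the (gapped) query.
#' @param pairwise a data.frame of pairwise alignments with columns
#'   \code{sid}, \code{qstart}, \code{qend}, \code{qseq}, \code{sseq} and
#'   optionally \code{score} (higher wins; input order breaks ties).
#' @return a list of character vectors, one per query position; element 1 of
#'   each vector is the query residue.
#' @export
buildColumnObservations <- function(query, msa = NULL, pairwise = NULL) {
  query <- toupper(query)
  qres <- strsplit(query, "")[[1]]
  n <- length(qres)
  obs <- lapply(qres, function(a) a)

  dropAmbiguous <- function(x)
    unname(x[x %in% STANDARD_AA])

  if (!is.null(msa)) {
    m <- asAlignmentMatrix(msa)
    qrow <- m[1, ]
    qpos <- which(!qrow %in% GAP_CHARS)
    if (paste(qrow[qpos], collapse = "") != query)
      stop("alignment query row does not match the query sequence")
    if (nrow(m) > 1L) {
      hom <- m[-1, , drop = FALSE]
      for (i in seq_len(n)) {
        col <- hom[, qpos[i]]
        obs[[i]] <- c(qres[i], dropAmbiguous(col[!col %in% GAP_CHARS]))
      }
    }
  }

  if (!is.null(pairwise) && nrow(pairwise) > 0L) {
    need <- c("sid", "qstart", "qend", "qseq", "sseq")
    if (!all(need %in% names(pairwise)))
      stop("pairwise alignments need columns ",
           paste(need, collapse = ", "))
    if (!is.null(pairwise$score))
      pairwise <- pairwise[order(-as.numeric(pairwise$score)), , drop = FALSE]
    covered <- list()  # per subject: logical coverage of query positions
    for (r in seq_len(nrow(pairwise))) {
      sid <- as.character(pairwise$sid[r])
      if (is.null(covered[[sid]])) covered[[sid]] <- logical(n)
      qa <- strsplit(toupper(pairwise$qseq[r]), "")[[1]]
      sa <- strsplit(toupper(pairwise$sseq[r]), "")[[1]]
      if (length(qa) != length(sa))
        stop("pairwise row ", r, ": aligned texts differ in length")
      qi <- as.integer(pairwise$qstart[r]) - 1L
      for (k in seq_along(qa)) {
        if (qa[k] %in% GAP_CHARS) next
        qi <- qi + 1L
        if (qi > n || qres[qi] != qa[k])
          stop("pairwise row ", r, ": query text disagrees with query ",
               "sequence at position ", qi)
        if (covered[[sid]][qi]) next  # a better-scoring HSP already covers it
        covered[[sid]][qi] <- TRUE
        s <- sa[k]
        if (!s %in% GAP_CHARS && s %in% STANDARD_AA)
          obs[[qi]] <- c(obs[[qi]], s)
      }
    }
  }

  obs
}

#' Mean and standard deviation of a feature over one alignment column
#'
#' The population form: mean is the arithmetic average of the feature values
#' of the observed residues, and sigma the square root of the average squared
#' deviation (normalized by the observation count). A single observation
#' yields sigma = 0.
#'
#' @param observations character vector of residue letters at one position.
#' @param feature one of \code{"H"}, \code{"K"}, \code{"M"}.
#' @param table feature table from \code{\link{featureTable}} (raw units).
#' @return named numeric(2): mean, sd.
#' @examples
#' columnFeatureStats(c("A", "R"), "K", featureTable())
#' @export
columnFeatureStats <- function(observations, feature = c("H", "K", "M"),
                               table) {
  feature <- match.arg(feature)
  if (length(observations) == 0L)
    stop("empty column: at least one observation is required")
  vals <- vapply(observations, function(a)
    residueFeatures(a, table)[feature], numeric(1))
  m <- mean(vals)
  s <- sqrt(mean((vals - m)^2))
  c(mean = m, sd = s)
}

#' Build a ConservationProfile from column observations
#'
#' Applies \code{\link{columnFeatureStats}} for each of H, K, M at every
#' query position.
#'
#' @param query the query sequence (character string) or a
#'   \linkS4class{LabeledSequence}.
#' @param observations output of \code{\link{buildColumnObservations}}; if
#'   NULL, the degenerate query-only observations are used (all sigma 0).
#' @param table feature table (raw units); default the packaged table.
#' @param id profile identifier.
#' @return a \linkS4class{ConservationProfile} (stats in raw feature units).
#' @export
conservationProfile <- function(query, observations = NULL,
                                table = featureTable(), id = "query") {
  if (is(query, "LabeledSequence")) {
    id <- query@id
    query <- seqString(query)
  }
  if (is.null(observations))
    observations <- buildColumnObservations(query)
  n <- nchar(query)
  if (length(observations) != n)
    stop("observations cover ", length(observations),
         " positions but the query has ", n)
  lut <- featureLookup(table, scaled = FALSE)
  stats <- matrix(0, n, 6,
                  dimnames = list(NULL, c("H_mean", "H_sd", "K_mean", "K_sd",
                                          "M_mean", "M_sd")))
  for (i in seq_len(n)) {
    vals <- lut[observations[[i]], , drop = FALSE]
    m <- colMeans(vals)
    s <- sqrt(colMeans(sweep(vals, 2, m)^2))
    stats[i, ] <- c(m["H"], s["H"], m["K"], s["K"], m["M"], s["M"])
  }
  new("ConservationProfile", id = id, stats = stats,
      nobs = vapply(observations, length, integer(1)))
}

# Scale raw conservation stats to [0, 1] with the feature table's own bounds:
# means by the same min-max map as single-residue features, sigmas by the
# feature's raw range (a column cannot deviate more than the full range).
scaledConservationStats <- function(profile, table = featureTable()) {
  rng <- attr(table, "range")
  stats <- profileStats(profile)
  out <- stats
  for (j in seq_along(FEATURE_NAMES)) {
    span <- rng[2, j] - rng[1, j]
    out[, 2 * j - 1] <- (stats[, 2 * j - 1] - rng[1, j]) / span
    out[, 2 * j] <- stats[, 2 * j] / span
  }
  pmin(pmax(out, 0), 1)
}

#' Read tabular pairwise alignments
#'
#' Reads the tab-separated alignment format consumed by
#' \code{\link{buildColumnObservations}}: query id, subject id, query start /
#' end, subject start / end, aligned query text, aligned subject text, and an
#' optional score column.
#'
#' @param path path to the tab-separated file (no header, 8 or 9 columns).
#' @return a data.frame with columns qid, sid, qstart, qend, sstart, send,
#'   qseq, sseq (and score when present).
#' @export
readPairwiseAlignments <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 8L)
    stop("pairwise alignment table needs at least 8 columns, found ",
         ncol(tab))
  names(tab)[1:8] <- c("qid", "sid", "qstart", "qend", "sstart", "send",
                       "qseq", "sseq")
  if (ncol(tab) >= 9L) names(tab)[9] <- "score"
  tab
}

#' Run a PSI-BLAST search to produce a PSSM and homologue alignments
#'
#' Thin wrapper over the external \code{psiblast} executable: three
#' iterations with E-value and inclusion threshold 1e-5, capturing the ASCII
#' PSSM and tabular alignments with aligned sequence text. The rest of the
#' package never requires this step; precomputed PSSM and alignment files are
#' accepted everywhere.
#'
#' @param queryFasta path to a single-record FASTA query.
#' @param database path to a formatted protein BLAST database.
#' @param outPrefix output path prefix (writes PREFIX.pssm, PREFIX.aln.tsv).
#' @param iterations number of search iterations (default 3).
#' @param evalue E-value and inclusion threshold (default 1e-5).
#' @return list with elements \code{pssm} and \code{alignments} (paths).
#' @export
runPsiBlast <- function(queryFasta, database, outPrefix, iterations = 3,
                        evalue = 1e-5) {
  exe <- Sys.which("psiblast")
  if (!nzchar(exe))
    stop("psiblast executable not found on PATH; supply a precomputed ",
         "PSSM/alignment instead, or install BLAST+")
  if (!file.exists(queryFasta))
    stop("query FASTA not found: ", queryFasta)
  pssm <- paste0(outPrefix, ".pssm")
  aln <- paste0(outPrefix, ".aln.tsv")
  status <- system2(exe, c(
    "-query", shQuote(queryFasta), "-db", shQuote(database),
    "-num_iterations", iterations, "-evalue", format(evalue),
    "-inclusion_ethresh", format(evalue),
    "-out_ascii_pssm", shQuote(pssm),
    "-outfmt", shQuote("6 qseqid sseqid qstart qend sstart send qseq sseq bitscore"),
    "-out", shQuote(aln)), stdout = FALSE, stderr = FALSE)
  if (status != 0L)
    stop("psiblast exited with status ", status,
         " (is the database formatted with makeblastdb?)")
  list(pssm = pssm, alignments = aln)
}
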