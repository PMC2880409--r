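# Sliding-window instance encoding.
#
# Each residue is represented by a block of scaled features; an instance is
# the concatenation of the blocks of w consecutive residues centered on the
# target residue. Within a block the order is fixed: [H, K, M], then the six
# conservation descriptors [H_mean, H_sd, K_mean, K_sd, M_mean, M_sd], then
# the 20 logistic-scaled PSSM scores — restricted to the active groups. In
# training mode a sequence of n residues yields n - w + 1 instances (the
# target centered, terminal residues unpredicted); prediction mode yields one
# instance per residue using all-zero padding blocks at the termini.

GROUP_WIDTHS <- c(hkm = 3L, descriptors = 6L, pssm = 20L)

blockWidth <- function(featureGroups) {
  sum(GROUP_WIDTHS[featureGroups])
}

#' Length of an encoded window vector
#'
#' @param window odd window size.
#' @param featureGroups subset of \code{c("hkm", "descriptors", "pssm")}.
#' @return integer: window times the per-residue block width (3 for hkm, 6
#'   for descriptors, 20 for pssm).
#' @examples
#' windowVectorLength(11, c("hkm", "descriptors", "pssm"))  # 319
#' @export
windowVectorLength <- function(window,
                               featureGroups = c("hkm", "descriptors", "pssm")) {
  featureGroups <- match.arg(featureGroups, several.ok = TRUE)
  as.integer(window) * blockWidth(featureGroups)
}

#' Enumerate window instances of a labelled sequence
#'
#' Training mode slides an odd window of size w along the sequence with the
#' target residue in the middle, yielding max(0, n - w + 1) instances
#' labelled by the target residue; prediction mode yields one window per
#' residue (n instances) with terminal windows padded.
#'
#' @param x a \linkS4class{LabeledSequence}.
#' @param window odd window size (default 11).
#' @param mode \code{"training"} or \code{"prediction"}.
#' @return a data.frame with columns \code{position} (target residue),
#'   \code{start}, \code{end} (window bounds, may exceed [1, n] in
#'   prediction mode) and \code{label} (NA in prediction mode).
#' @export
extractInstances <- function(x, window = 11L, mode = c("training", "prediction")) {
  mode <- match.arg(mode)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer")
  n <- nchar(seqString(x))
  h <- (window - 1L) %/% 2L
  if (mode == "training") {
    if (n < window) {
      warning("sequence '", x@id, "' is shorter than the window (", n, " < ",
              window, "); no training instances")
      targets <- integer(0)
    } else {
      targets <- seq.int(h + 1L, n - h)
    }
    labels <- bindingLabels(x)[targets]
  } else {
    targets <- seq_len(n)
    labels <- rep(NA_real_, n)
  }
  data.frame(position = targets, start = targets - h, end = targets + h,
             label = labels)
}

# Per-residue block matrix (n x blockWidth), all values scaled to [0, 1].
residueBlocks <- function(sequence, featureGroups, pssm = NULL,
                          conservation = NULL, table = featureTable()) {
  res <- strsplit(toupper(sequence), "")[[1]]
  n <- length(res)
  parts <- list()
  if ("hkm" %in% featureGroups) {
    lut <- featureLookup(table, scaled = TRUE)
    idx <- match(res, rownames(lut))
    idx[is.na(idx)] <- match("X", rownames(lut))
    parts$hkm <- lut[idx, , drop = FALSE]
  }
  if ("descriptors" %in% featureGroups) {
    if (is.null(conservation))
      stop("encoding needs a ConservationProfile for the 'descriptors' group")
    if (nrow(profileStats(conservation)) != n)
      stop("conservation profile covers ", nrow(profileStats(conservation)),
           " positions but the sequence has ", n)
    parts$descriptors <- scaledConservationStats(conservation, table)
  }
  if ("pssm" %in% featureGroups) {
    if (is.null(pssm))
      stop("encoding needs a PSSMProfile for the 'pssm' group")
    if (nrow(pssmScores(pssm)) != n)
      stop("PSSM covers ", nrow(pssmScores(pssm)),
           " positions but the sequence has ", n)
    parts$pssm <- scalePssmScores(pssmScores(pssm))
  }
  m <- do.call(cbind, parts[featureGroups[featureGroups %in% names(parts)]])
  rownames(m) <- NULL
  pmin(pmax(m, 0), 1)
}

#' Encode one window into an instance vector
#'
#' Concatenates the per-residue feature blocks of the window left to right;
#' positions outside the sequence contribute all-zero padding blocks.
#'
#' @param blocks per-residue block matrix from the source sequence
#'   (n x block width, as built by \code{\link{encodeInstances}}).
#' @param start,end window bounds in sequence coordinates (may exceed
#'   [1, n]; out-of-range positions are padding).
#' @return numeric vector of length (end - start + 1) * ncol(blocks).
#' @export
encodeWindow <- function(blocks, start, end) {
  n <- nrow(blocks)
  bw <- ncol(blocks)
  pos <- start:end
  out <- matrix(0, length(pos), bw)
  inside <- pos >= 1L & pos <= n
  out[inside, ] <- blocks[pos[inside], , drop = FALSE]
  as.numeric(t(out))
}

#' Encode a labelled sequence into windowed SVM instances
#'
#' The full encoding pipeline for one sequence: build per-residue blocks from
#' the active feature groups, slide the window, and stack the window vectors
#' into an \linkS4class{InstanceSet}.
#'
#' @param x a \linkS4class{LabeledSequence}, or a plain character sequence
#'   (prediction mode only).
#' @param pssm a \linkS4class{PSSMProfile} (required when \code{"pssm"} is an
#'   active group).
#' @param conservation a \linkS4class{ConservationProfile} (required when
#'   \code{"descriptors"} is active).
#' @param window odd window size (default 11).
#' @param featureGroups subset of \code{c("hkm", "descriptors", "pssm")}.
#' @param mode \code{"training"} or \code{"prediction"}.
#' @param table feature table (raw units).
#' @return an \linkS4class{InstanceSet}.
#' @export
encodeInstances <- function(x, pssm = NULL, conservation = NULL,
                            window = 11L,
                            featureGroups = c("hkm", "descriptors", "pssm"),
                            mode = c("training", "prediction"),
                            table = featureTable()) {
  mode <- match.arg(mode)
  featureGroups <- match.arg(featureGroups, several.ok = TRUE)
  featureGroups <- intersect(c("hkm", "descriptors", "pssm"), featureGroups)
  if (is.character(x)) {
    if (mode == "training")
      stop("training mode needs a LabeledSequence, not a bare string")
    x <- LabeledSequence("query", x, rep(-1, nchar(x)), source = "query")
  }
  inst <- extractInstances(x, window, mode)
  blocks <- residueBlocks(seqString(x), featureGroups, pssm, conservation,
                          table)
  m <- matrix(0, nrow(inst), as.integer(window) * ncol(blocks))
  for (k in seq_len(nrow(inst)))
    m[k, ] <- encodeWindow(blocks, inst$start[k], inst$end[k])
  new("InstanceSet", x = m, y = as.numeric(inst$label),
      seqid = rep(x@id, nrow(inst)), position = as.integer(inst$position),
      window = as.integer(window), featureGroups = featureGroups)
}

#' Combine instance sets row-wise
#'
#' @param ... \linkS4class{InstanceSet} objects sharing one encoding
#'   descriptor (window and feature groups).
#' @return a single \linkS4class{InstanceSet}.
#' @export
bindInstanceSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "InstanceSet"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (s@window != ref@window ||
        !identical(s@featureGroups, ref@featureGroups))
      stop("instance sets have differing encoding descriptors")
  }
  new("InstanceSet",
      x = do.call(rbind, lapply(sets, instanceMatrix)),
      y = unlist(lapply(sets, instanceLabels)),
      seqid = unlist(lapply(sets, function(s) s@seqid)),
      position = unlist(lapply(sets, function(s) s@position)),
      window = ref@window, featureGroups = ref@featureGroups)
}

#' Write / read an instance set as a dense matrix with a JSON-like sidecar
#'
#' The matrix travels as a tab-separated file (label, seqid, position, then
#' the feature columns); the encoding descriptor (window, feature groups)
#' goes to a small sidecar so a reader can refuse mismatched encodings.
#'
#' @param instances an \linkS4class{InstanceSet}.
#' @param prefix output path prefix (writes PREFIX.tsv and PREFIX.meta).
#' @return invisibly, the paths written.
#' @export
writeInstanceSet <- function(instances, prefix) {
  tsv <- paste0(prefix, ".tsv")
  meta <- paste0(prefix, ".meta")
  df <- data.frame(label = instanceLabels(instances),
                   seqid = instances@seqid,
                   position = instances@position)
  df <- cbind(df, as.data.frame(instanceMatrix(instances)))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("window\t", instances@window),
               paste0("featureGroups\t",
                      paste(instances@featureGroups, collapse = ","))), meta)
  invisible(c(tsv, meta))
}

#' @rdname writeInstanceSet
#' @export
readInstanceSet <- function(prefix) {
  tsv <- paste0(prefix, ".tsv")
  meta <- utils::read.delim(paste0(prefix, ".meta"), header = FALSE,
                            row.names = 1)
  df <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  new("InstanceSet",
      x = as.matrix(df[, -(1:3), drop = FALSE]),
      y = as.numeric(df$label),
      seqid = as.character(df$seqid),
      position = as.integer(df$position),
      window = as.integer(meta["window", 1]),
      featureGroups = strsplit(as.character(meta["featureGroups", 1]),
                               ",")[[1]])
}
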