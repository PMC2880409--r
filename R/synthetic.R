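# Deterministic synthetic-data generators.
#
# Three generators cover the pipeline's three input kinds without any
# downloads: a toy protein-DNA/RNA complex with known interface geometry
# (for the structural labelling rule), homologue alignments with planted
# column conservation (for the conservation descriptors), and labelled
# sequence datasets emulating the field's study conditions: ~15% binding
# residues, binding sites enriched for basic/polar residues and conserved
# among homologues, non-binding regions enriched for hydrophobic residues.
# All outputs are pure functions of (spec, seed).

# Composition weight increments (on a uniform base of 1) applied at binding
# vs non-binding positions; basic/polar letters up at interfaces, acidic and
# hydrophobic letters up elsewhere.
BINDING_ENRICH <- c(R = 4, K = 4, H = 2, N = 1, Q = 1, S = 1, T = 1, Y = 1)
BACKGROUND_ENRICH <- c(I = 2, L = 2, V = 2, A = 1.5, F = 1.5, M = 1,
                       D = 1, E = 1)

compositionWeights <- function(binding, signal) {
  w <- stats::setNames(rep(1, 20), STANDARD_AA)
  add <- if (binding) BINDING_ENRICH else BACKGROUND_ENRICH
  w[names(add)] <- w[names(add)] + signal * add
  w / sum(w)
}

#' Synthetic study conditions
#'
#' Bundles the parameters of the synthetic dataset generator. The defaults
#' are the package's study conditions: 60 sequences of 120 residues, a 15%
#' binding-residue fraction laid out in contiguous patches, 30 homologues
#' per sequence, per-position mutation rates of 0.10 at binding positions
#' versus 0.40 elsewhere (binding sites are conserved), a 5% gap rate
#' outside binding positions, and full-strength composition enrichment.
#' \code{signal = 0} switches every label-feature coupling off (uniform
#' composition, equal mutation rates): a null model whose cross-validated
#' AUC should sit at chance.
#'
#' @param nSequences number of sequences.
#' @param length residues per sequence.
#' @param positiveFraction target binding-residue fraction.
#' @param nHomologs homologues per alignment.
#' @param bindingMutationRate,backgroundMutationRate per-position homologue
#'   mutation rates at binding / non-binding positions (signal = 1).
#' @param gapRate homologue gap probability at non-binding positions.
#' @param signal signal strength in [0, 1]: scales composition enrichment
#'   and the conservation contrast; 0 = null model, 1 = default conditions.
#' @param seed integer seed; same spec and seed give identical output.
#' @return a list of class \code{"synthSpec"}.
#' @export
synthSpec <- function(nSequences = 60L, length = 120L,
                      positiveFraction = 0.15, nHomologs = 30L,
                      bindingMutationRate = 0.10,
                      backgroundMutationRate = 0.40,
                      gapRate = 0.05, signal = 1, seed = 7L) {
  stopifnot(signal >= 0, signal <= 1, positiveFraction >= 0,
            positiveFraction <= 1)
  midRate <- (bindingMutationRate + backgroundMutationRate) / 2
  structure(list(
    nSequences = as.integer(nSequences), length = as.integer(length),
    positiveFraction = positiveFraction, nHomologs = as.integer(nHomologs),
    bindingMutationRate = midRate + signal * (bindingMutationRate - midRate),
    backgroundMutationRate = midRate +
      signal * (backgroundMutationRate - midRate),
    gapRate = gapRate, signal = signal, seed = as.integer(seed)),
    class = "synthSpec")
}

# Non-overlapping binding patches totalling round(f * n) positions.
plantBindingPatches <- function(n, fraction) {
  total <- round(fraction * n)
  labels <- rep(-1, n)
  left <- total
  guard <- 0L
  while (left > 0L && guard < 1000L) {
    guard <- guard + 1L
    len <- min(left, sample(4:8, 1L))
    start <- sample.int(n - len + 1L, 1L)
    span <- start:(start + len - 1L)
    if (any(labels[span] == 1)) next
    labels[span] <- 1
    left <- left - len
  }
  if (left > 0L) {  # fall back to scattering the remainder
    free <- which(labels == -1)
    labels[sample(free, left)] <- 1
  }
  labels
}

sampleSequence <- function(labels, signal) {
  wPos <- compositionWeights(TRUE, signal)
  wNeg <- compositionWeights(FALSE, signal)
  n <- length(labels)
  res <- character(n)
  res[labels == 1] <- sample(STANDARD_AA, sum(labels == 1), replace = TRUE,
                             prob = wPos)
  res[labels == -1] <- sample(STANDARD_AA, sum(labels == -1), replace = TRUE,
                              prob = wNeg)
  paste(res, collapse = "")
}

#' Synthetic homologue alignment with planted conservation
#'
#' Homologues are copies of the query mutated independently per position at
#' the given rates (mutant residues drawn uniformly from the 20 letters),
#' with gaps inserted at the given per-position rates. No insertions are
#' generated, so alignment columns coincide with query positions. Lower
#' mutation rates at selected positions plant column conservation there.
#'
#' @param query the query sequence (character string).
#' @param nHomologs number of homologue rows.
#' @param mutationRate scalar or per-position vector of mutation
#'   probabilities.
#' @param gapRate scalar or per-position vector of gap probabilities.
#' @param seed integer seed.
#' @return an aligned \code{Biostrings::AAStringSet}; the first record is
#'   the query.
#' @export
synthAlignment <- function(query, nHomologs = 30L, mutationRate = 0.3,
                           gapRate = 0, seed = 1L) {
  qres <- strsplit(toupper(query), "")[[1]]
  n <- length(qres)
  mutationRate <- rep_len(mutationRate, n)
  gapRate <- rep_len(gapRate, n)
  set.seed(as.integer(seed))
  rows <- vapply(seq_len(nHomologs), function(j) {
    r <- qres
    mut <- stats::runif(n) < mutationRate
    r[mut] <- sample(STANDARD_AA, sum(mut), replace = TRUE)
    gap <- stats::runif(n) < gapRate
    r[gap] <- "-"
    paste(r, collapse = "")
  }, "")
  out <- Biostrings::AAStringSet(c(query, rows))
  names(out) <- c("query", sprintf("hom%03d", seq_len(nHomologs)))
  out
}

#' Synthetic PSSM from an alignment
#'
#' Per-column log-odds of residue frequencies against a uniform background,
#' with a pseudocount of 1: score = round(2 * log2((count + 1) /
#' (nobs + 20) / 0.05)), matching the integer half-bit convention of real
#' search output. This makes the PSSM input path exercisable without the
#' external search tool.
#'
#' @param query the query sequence.
#' @param observations column observations from
#'   \code{\link{buildColumnObservations}} (or NULL to build them from
#'   \code{msa}).
#' @param msa an aligned \code{AAStringSet} whose first record is the query
#'   (used when \code{observations} is NULL).
#' @param id profile identifier.
#' @return a \linkS4class{PSSMProfile} with integer scores.
#' @export
synthPSSM <- function(query, observations = NULL, msa = NULL,
                      id = "synthetic") {
  if (is.null(observations))
    observations <- buildColumnObservations(query, msa = msa)
  n <- length(observations)
  scores <- matrix(0L, n, 20, dimnames = list(NULL, PSSM_ALPHABET))
  for (i in seq_len(n)) {
    counts <- table(factor(observations[[i]], levels = PSSM_ALPHABET))
    freq <- (as.numeric(counts) + 1) / (sum(counts) + 20)
    scores[i, ] <- as.integer(round(2 * log2(freq / 0.05)))
  }
  new("PSSMProfile", id = id, scores = scores,
      residues = strsplit(toupper(query), "")[[1]])
}

#' Synthetic labelled dataset with profiles
#'
#' Generates the full study-condition fixture: labelled sequences with
#' binding patches at the target class balance, a homologue alignment per
#' sequence with conservation planted at binding positions, the resulting
#' conservation profiles, and synthetic PSSMs computed from the alignments.
#'
#' @param spec a \code{\link{synthSpec}}.
#' @param table feature table used for the conservation profiles.
#' @return a list of records, each with elements \code{labeled}
#'   (\linkS4class{LabeledSequence}), \code{alignment} (AAStringSet),
#'   \code{conservation} (\linkS4class{ConservationProfile}) and
#'   \code{pssm} (\linkS4class{PSSMProfile}).
#' @export
synthDataset <- function(spec = synthSpec(), table = featureTable()) {
  stopifnot(inherits(spec, "synthSpec"))
  set.seed(spec$seed)
  seqSeeds <- sample.int(.Machine$integer.max %/% 2L, spec$nSequences)
  lapply(seq_len(spec$nSequences), function(i) {
    set.seed(seqSeeds[i])
    labels <- plantBindingPatches(spec$length, spec$positiveFraction)
    sequence <- sampleSequence(labels, spec$signal)
    ls <- LabeledSequence(sprintf("synth%03d", i), sequence, labels)
    rates <- ifelse(labels == 1, spec$bindingMutationRate,
                    spec$backgroundMutationRate)
    # the gap contrast is itself a label-feature coupling, so it scales
    # with the signal: at signal = 0 gaps are label-independent
    gaps <- ifelse(labels == 1, (1 - spec$signal) * spec$gapRate,
                   spec$gapRate)
    aln <- synthAlignment(sequence, spec$nHomologs, rates, gaps,
                          seed = seqSeeds[i])
    obs <- buildColumnObservations(sequence, msa = aln)
    list(labeled = ls, alignment = aln,
         conservation = conservationProfile(sequence, obs, table,
                                            id = ls@id),
         pssm = synthPSSM(sequence, observations = obs, id = ls@id))
  })
}

#' Encode a synthetic dataset into one instance set
#'
#' @param dataset output of \code{\link{synthDataset}}.
#' @param window odd window size.
#' @param featureGroups active feature groups.
#' @param mode \code{"training"} or \code{"prediction"}.
#' @param table feature table.
#' @return a combined \linkS4class{InstanceSet}.
#' @export
encodeDataset <- function(dataset, window = 11L,
                          featureGroups = c("hkm", "descriptors", "pssm"),
                          mode = "training", table = featureTable()) {
  sets <- lapply(dataset, function(rec)
    encodeInstances(rec$labeled, pssm = rec$pssm,
                    conservation = rec$conservation, window = window,
                    featureGroups = featureGroups, mode = mode,
                    table = table))
  bindInstanceSets(sets)
}

#' Synthetic protein-nucleic acid complex with known interface geometry
#'
#' Writes a toy PDB-format complex: a protein chain on a straight backbone
#' with 3.8 Angstrom CA spacing (one CA and one CB heavy atom per residue),
#' and a nucleic chain whose phosphate atoms are placed at controlled
#' distances from chosen residues -- contact residues at
#' \code{contactDistance} (within the 3.5 Angstrom rule by default),
#' everything else far away. Chemically naive, but the distances are exact
#' and fully controllable, which is what the labelling rule needs.
#'
#' @param nResidues protein chain length.
#' @param contactResidues indices of residues planted in contact; default
#'   5 drawn at random.
#' @param contactDistance scalar or per-contact vector of planted
#'   CA-to-phosphate distances in Angstrom (default 3.0; use 3.5 to probe
#'   the inclusive boundary).
#' @param target \code{"dna"} or \code{"rna"}: residue names used for the
#'   nucleic chain.
#' @param seed integer seed (sequence letters and default contact choice).
#' @param out output PDB path.
#' @return list with \code{path}, \code{truth} (per-residue +1/-1 under the
#'   3.5 Angstrom rule given the planted distances), \code{contactResidues}
#'   and \code{sequence}.
#' @export
synthComplex <- function(nResidues = 30L, contactResidues = NULL,
                         contactDistance = 3.0, target = c("dna", "rna"),
                         seed = 1L, out = tempfile(fileext = ".pdb")) {
  target <- match.arg(target)
  set.seed(as.integer(seed))
  nResidues <- as.integer(nResidues)
  if (is.null(contactResidues))
    contactResidues <- sort(sample.int(nResidues, min(5L, nResidues)))
  contactResidues <- as.integer(contactResidues)
  contactDistance <- rep_len(contactDistance, length(contactResidues))
  seqletters <- sample(STANDARD_AA, nResidues, replace = TRUE)
  aa3 <- bio3d::aa123(seqletters)

  fmtAtom <- function(serial, name, resname, chain, resno, x, y, z, element) {
    sprintf("ATOM  %5d  %-3s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, " ", resname, chain, resno, " ", x, y, z, 1, 0,
            element)
  }

  lines <- character(0)
  serial <- 0L
  # protein chain A: CA along x at 3.8 A spacing, CB on the far side (-y)
  for (i in seq_len(nResidues)) {
    x <- 3.8 * (i - 1L)
    serial <- serial + 1L
    lines <- c(lines, fmtAtom(serial, "CA", aa3[i], "A", i, x, 0, 0, "C"))
    serial <- serial + 1L
    lines <- c(lines, fmtAtom(serial, "CB", aa3[i], "A", i, x, -1.5, 0, "C"))
  }
  # nucleic chain B: one phosphate over each contact residue at the planted
  # distance, plus distant backbone atoms so the chain is non-trivial
  nucNames <- if (target == "dna") c("DA", "DC", "DG", "DT") else
    c("A", "C", "G", "U")
  resno <- 0L
  for (k in seq_along(contactResidues)) {
    i <- contactResidues[k]
    resno <- resno + 1L
    serial <- serial + 1L
    lines <- c(lines, fmtAtom(serial, "P", nucNames[(resno - 1L) %% 4L + 1L],
                              "B", resno, 3.8 * (i - 1L),
                              contactDistance[k], 0, "P"))
  }
  for (j in 1:4) {
    resno <- resno + 1L
    serial <- serial + 1L
    lines <- c(lines, fmtAtom(serial, "P", nucNames[(resno - 1L) %% 4L + 1L],
                              "B", resno, 3.8 * j, 30, 0, "P"))
  }
  writeLines(c(lines, "END"), out)

  truth <- rep(-1, nResidues)
  truth[contactResidues[contactDistance <= 3.5]] <- 1
  list(path = out, truth = truth, contactResidues = contactResidues,
       sequence = paste(seqletters, collapse = ""))
}
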