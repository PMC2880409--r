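# Independent brute-force oracles used to check the package's fast paths.

# Mann-Whitney concordance AUC: probability that a random positive outscores
# a random negative, ties counted half. O(n+ * n-) pair enumeration.
aucPairwiseOracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  total <- 0
  for (p in pos)
    for (q in neg)
      total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Two-pass population mean / sd of feature values for a residue column.
columnStatsOracle <- function(residues, feature, table) {
  vals <- vapply(residues, function(a) table[a, feature], numeric(1))
  m <- sum(vals) / length(vals)
  s2 <- sum((vals - m)^2) / length(vals)
  c(mean = m, sd = sqrt(s2))
}

# Direct arithmetic Matthews correlation.
mccOracle <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# All-pairs distance labelling of a toy complex, straight from the PDB text:
# no shared code with the package's labelling path.
bruteForceLabels <- function(pdbPath, cutoff = 3.5) {
  lines <- grep("^ATOM", readLines(pdbPath), value = TRUE)
  chain <- substr(lines, 22, 22)
  resno <- as.integer(substr(lines, 23, 26))
  xyz <- cbind(as.numeric(substr(lines, 31, 38)),
               as.numeric(substr(lines, 39, 46)),
               as.numeric(substr(lines, 47, 54)))
  protRows <- which(chain == "A")
  nucXYZ <- xyz[chain == "B", , drop = FALSE]
  resnos <- sort(unique(resno[protRows]))
  vapply(resnos, function(r) {
    rows <- protRows[resno[protRows] == r]
    dmin <- Inf
    for (i in rows)
      for (j in seq_len(nrow(nucXYZ)))
        dmin <- min(dmin, sqrt(sum((xyz[i, ] - nucXYZ[j, ])^2)))
    if (dmin <= cutoff) 1 else -1
  }, numeric(1))
}

# Tiny separable instance set on a w = 1 hkm encoding (3 columns in [0, 1]).
separableToySet <- function(nPerClass = 20, seed = 1) {
  set.seed(seed)
  pos <- matrix(runif(nPerClass * 3, 0.7, 1.0), ncol = 3)
  neg <- matrix(runif(nPerClass * 3, 0.0, 0.3), ncol = 3)
  new("InstanceSet", x = rbind(pos, neg),
      y = rep(c(1, -1), each = nPerClass),
      seqid = rep(c("p", "n"), each = nPerClass),
      position = rep(seq_len(nPerClass), 2),
      window = 1L, featureGroups = "hkm")
}

# Hand-written ASCII PSSM fixture in the search tool's matrix layout.
writePssmFixture <- function(path, scores, residues) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed, weighted",
               paste0("            ",
                      paste(sprintf("%3s", strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]),
                            collapse = " "))), con)
  for (i in seq_len(nrow(scores)))
    writeLines(sprintf("%5d %s  %s", i, residues[i],
                       paste(sprintf("%3d", scores[i, ]), collapse = " ")),
               con)
}
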