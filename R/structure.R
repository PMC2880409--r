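# Structure-derived labelling of nucleic-acid-binding residues.
#
# A residue is labelled as binding when any of its side-chain or backbone
# heavy atoms lies within an inclusive 3.5 Angstrom cutoff of any atom of a
# DNA (or RNA) chain in the complex. Hydrogens, heteroatoms and waters are
# excluded; only the first model of multi-model files is used.

DNA_RESIDUES <- c("DA", "DC", "DG", "DT", "DI")
RNA_RESIDUES <- c("A", "C", "G", "U", "I")
WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

# Drop hydrogens (element H, or atom names that start with H after digits),
# waters and HETATM records from a bio3d atom table.
heavyAtomTable <- function(atom) {
  keep <- atom$type == "ATOM" & !(atom$resid %in% WATER_RESIDUES)
  elesy <- atom$elesy
  if (!is.null(elesy) && any(nzchar(trimws(elesy)), na.rm = TRUE)) {
    isH <- trimws(elesy) %in% c("H", "D")
    isH[is.na(isH)] <- FALSE
  } else {
    stripped <- sub("^[0-9]*", "", trimws(atom$elety))
    isH <- startsWith(stripped, "H")
  }
  atom[keep & !isH, , drop = FALSE]
}

readStructure <- function(structure) {
  if (is.character(structure)) {
    if (!file.exists(structure))
      stop("structure file not found: ", structure)
    pdb <- tryCatch(bio3d::read.pdb(structure, multi = FALSE, verbose = FALSE),
                    error = function(e)
                      stop("unparseable structure file: ", conditionMessage(e)))
  } else if (inherits(structure, "pdb")) {
    pdb <- structure
  } else {
    stop("expected a PDB file path or a bio3d pdb object")
  }
  pdb
}

#' Classify the chains of a protein-nucleic acid complex
#'
#' Assigns each chain of a structure one kind: \code{protein} (residues
#' predominantly standard amino acids), \code{dna} (deoxynucleotide residue
#' names DA/DC/DG/DT), \code{rna} (ribonucleotide names A/C/G/U) or
#' \code{other}. The kind is determined solely from residue names; waters
#' and hydrogens are ignored.
#'
#' @param structure path to a PDB file, or a \code{bio3d} pdb object.
#' @return a list of chain records, each a list with \code{chain_id},
#'   \code{kind}, and \code{atoms} (a data.frame of heavy atoms with
#'   \code{resid}, \code{resno}, \code{elety}, \code{x}, \code{y}, \code{z}).
#' @examples
#' pdbfile <- synthComplex(nResidues = 12, contactResidues = c(3, 7),
#'                         seed = 1, out = tempfile(fileext = ".pdb"))$path
#' kinds <- vapply(classifyChains(pdbfile), `[[`, "", "kind")
#' @export
classifyChains <- function(structure) {
  pdb <- readStructure(structure)
  atom <- heavyAtomTable(pdb$atom)
  if (nrow(atom) == 0L)
    stop("empty structure: no heavy atoms in any chain")
  chains <- unique(atom$chain)
  lapply(chains, function(ch) {
    a <- atom[atom$chain == ch, , drop = FALSE]
    resids <- a$resid[!duplicated(paste(a$resno, a$insert))]
    aa3 <- bio3d::aa.table$aa3
    frac <- function(set) mean(resids %in% set)
    kind <- if (frac(aa3[1:20]) >= 0.5 || mean(resids %in% rownames(bio3d::aa.table)) >= 0.5)
      "protein"
    else if (frac(DNA_RESIDUES) >= 0.5) "dna"
    else if (frac(RNA_RESIDUES) >= 0.5) "rna"
    else "other"
    list(chain_id = ch, kind = kind,
         atoms = a[, c("resid", "resno", "insert", "elety", "x", "y", "z")])
  })
}

#' Minimum inter-atomic distance between two atom sets
#'
#' @param residueAtoms numeric matrix (n x 3) of atom coordinates in Angstrom.
#' @param nucleicAtoms numeric matrix (m x 3) of atom coordinates.
#' @return the minimum Euclidean distance over all atom pairs (Angstrom).
#' @examples
#' minResidueDistance(rbind(c(0, 0, 0)), rbind(c(0, 0, 3)))  # 3
#' @export
minResidueDistance <- function(residueAtoms, nucleicAtoms) {
  a <- as.matrix(residueAtoms)
  b <- as.matrix(nucleicAtoms)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("no atoms: both atom sets must be non-empty")
  if (ncol(a) != 3L || ncol(b) != 3L)
    stop("atom coordinates must be n x 3 matrices")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("atom coordinates must be finite")
  # squared cross-distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Label the nucleic-acid-binding residues of a complex structure
#'
#' Applies the structural contact rule: a protein residue is a binding site
#' (+1) when the minimum distance from its heavy atoms to any atom of any
#' chain of the target nucleic kind is at most \code{cutoff}; all other
#' residues are non-binding (-1). Each protein chain is labelled against the
#' union of all target-kind chains.
#'
#' @param structure path to a PDB file, or a \code{bio3d} pdb object.
#' @param target \code{"dna"} or \code{"rna"}: which nucleic-acid partner
#'   defines the binding sites.
#' @param cutoff inclusive contact distance in Angstrom (default 3.5).
#' @return a list of \linkS4class{LabeledSequence}, one per protein chain;
#'   attribute \code{"contacts"} holds a data.frame (structure, chain,
#'   position, residue, label, min_distance).
#' @export
labelBindingResidues <- function(structure, target = c("dna", "rna"),
                                 cutoff = 3.5) {
  target <- match.arg(target)
  pdb <- readStructure(structure)
  sid <- if (is.character(structure))
    sub("\\.(pdb|ent)$", "", basename(structure)) else "structure"
  chains <- classifyChains(pdb)
  kinds <- vapply(chains, `[[`, "", "kind")
  prot <- chains[kinds == "protein"]
  nuc <- chains[kinds == target]
  if (length(prot) == 0L)
    stop("structure contains no protein chain")
  if (length(nuc) == 0L)
    stop("no nucleic partner: structure has no ", target, " chain")
  nucXYZ <- do.call(rbind, lapply(nuc, function(ch)
    as.matrix(ch$atoms[, c("x", "y", "z")])))

  contacts <- list()
  out <- lapply(prot, function(ch) {
    a <- ch$atoms
    key <- paste(a$resno, a$insert)
    resKeys <- unique(key)
    nres <- length(resKeys)
    seqv <- character(nres)
    dmin <- numeric(nres)
    for (i in seq_len(nres)) {
      rows <- a[key == resKeys[i], , drop = FALSE]
      seqv[i] <- suppressWarnings(bio3d::aa321(rows$resid[1]))
      dmin[i] <- minResidueDistance(as.matrix(rows[, c("x", "y", "z")]),
                                    nucXYZ)
    }
    seqv[is.na(seqv) | !seqv %in% c(STANDARD_AA)] <- "X"
    labels <- ifelse(dmin <= cutoff, 1, -1)
    contacts[[length(contacts) + 1L]] <<- data.frame(
      structure = sid, chain = ch$chain_id, position = seq_len(nres),
      residue = seqv, label = labels, min_distance = dmin,
      stringsAsFactors = FALSE)
    LabeledSequence(paste(sid, ch$chain_id, sep = "_"),
                    paste(seqv, collapse = ""), labels,
                    source = paste(sid, ch$chain_id, sep = "_"))
  })
  attr(out, "contacts") <- do.call(rbind, contacts)
  out
}

#' Write labelled sequences as FASTA plus a label track and contact table
#'
#' Produces \code{PREFIX.fasta} (sequences), \code{PREFIX.labels.txt} (per
#' record: a header line, the sequence line and a '+'/'-' label line), and,
#' when a contact table is attached, \code{PREFIX.contacts.tsv}.
#'
#' @param labeled a list of \linkS4class{LabeledSequence} (e.g. from
#'   \code{\link{labelBindingResidues}}).
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writeLabeledSequences <- function(labeled, prefix) {
  seqs <- Biostrings::AAStringSet(vapply(labeled, seqString, ""))
  names(seqs) <- vapply(labeled, function(x) x@id, "")
  fa <- paste0(prefix, ".fasta")
  Biostrings::writeXStringSet(seqs, fa)
  lab <- paste0(prefix, ".labels.txt")
  con <- file(lab, "w")
  on.exit(close(con))
  for (x in labeled) {
    writeLines(c(paste0(">", x@id), seqString(x),
                 paste(ifelse(bindingLabels(x) == 1, "+", "-"),
                       collapse = "")), con)
  }
  paths <- c(fa, lab)
  contacts <- attr(labeled, "contacts")
  if (!is.null(contacts)) {
    tsv <- paste0(prefix, ".contacts.tsv")
    utils::write.table(contacts, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, tsv)
  }
  invisible(paths)
}

#' Read labelled sequences from a label-track file
#'
#' Inverse of the label track written by \code{\link{writeLabeledSequences}}:
#' per record a \code{>id} header, the sequence line and a '+'/'-' line.
#'
#' @param path path to a \code{.labels.txt} file.
#' @return a list of \linkS4class{LabeledSequence}.
#' @export
readLabeledSequences <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3L != 0L)
    stop("malformed label track: expected header/sequence/label triples")
  idx <- seq(1L, length(lines), by = 3L)
  lapply(idx, function(i) {
    if (!startsWith(lines[i], ">"))
      stop("malformed label track at line ", i, ": missing '>' header")
    labs <- strsplit(lines[i + 2L], "")[[1]]
    if (!all(labs %in% c("+", "-")))
      stop("malformed label line for record ", sub("^>", "", lines[i]))
    LabeledSequence(sub("^>", "", lines[i]), lines[i + 1L],
                    ifelse(labs == "+", 1, -1),
                    source = sub("^>", "", lines[i]))
  })
}
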