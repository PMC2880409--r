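test_that("a query without homologues gives singleton columns", {
  obs <- buildColumnObservations("ARNDK")
  expect_length(obs, 5)
  expect_true(all(lengths(obs) == 1))
  expect_equal(vapply(obs, `[`, "", 1), strsplit("ARNDK", "")[[1]])
})

test_that("gaps and ambiguity codes in homologues are excluded", {
  msa <- Biostrings::AAStringSet(c(q = "ARND", h1 = "A-ND", h2 = "AXNE"))
  obs <- buildColumnObservations("ARND", msa = msa)
  expect_equal(lengths(obs), c(3L, 1L, 3L, 3L))  # gap and X dropped
  expect_equal(sort(obs[[4]]), c("D", "D", "E"))
})

test_that("a gapped query row maps alignment columns onto query positions", {
  msa <- Biostrings::AAStringSet(c(q = "AR-ND", h = "ARQNE"))
  obs <- buildColumnObservations("ARND", msa = msa)
  expect_length(obs, 4)
  expect_equal(obs[[4]], c("D", "E"))  # the Q insertion contributes nowhere
  expect_error(buildColumnObservations("ARNK", msa = msa), "does not match")
})

test_that("with pairwise input the best HSP wins per position", {
  # two overlapping HSPs of one subject disagree on position 3
  pw <- data.frame(sid = c("s1", "s1"), qstart = c(1, 3), qend = c(4, 6),
                   qseq = c("ARND", "NDKL"), sseq = c("ARKD", "QDKL"),
                   score = c(50, 80))
  obs <- buildColumnObservations("ARNDKL", pairwise = pw)
  # the higher-scoring HSP (score 80) covers 3..6 and contributes Q at 3
  expect_equal(obs[[3]], c("N", "Q"))
  expect_equal(obs[[1]], c("A", "A"))   # only HSP 1 covers position 1
  expect_equal(obs[[5]], c("K", "K"))
  # hand enumeration of observation counts
  expect_equal(lengths(obs), c(2L, 2L, 2L, 2L, 2L, 2L))
})

test_that("column statistics are the population mean and sd", {
  tab <- featureTable()
  # alanine (pKa 0) and arginine (pKa 12.48): two-point population sd
  st <- columnFeatureStats(c("A", "R"), "K", tab)
  expect_equal(st[["mean"]], 12.48 / 2)
  expect_equal(st[["sd"]], 12.48 / 2)
  # singleton column
  st1 <- columnFeatureStats("W", "M", tab)
  expect_equal(st1[["mean"]], tab["W", "M"])
  expect_equal(st1[["sd"]], 0)
  expect_error(columnFeatureStats(character(0), "H", tab), "empty column")
})

test_that("column statistics match a two-pass oracle on random columns", {
  tab <- featureTable()
  set.seed(42)
  for (rep in 1:50) {
    col <- sample(nabind:::STANDARD_AA, sample(1:30, 1), replace = TRUE)
    f <- sample(c("H", "K", "M"), 1)
    got <- columnFeatureStats(col, f, tab)
    want <- columnStatsOracle(col, f, tab)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
    # sd^2 equals mean of squares minus square of mean
    vals <- vapply(col, function(a) tab[a, f], numeric(1))
    expect_equal(got[["sd"]]^2, mean(vals^2) - mean(vals)^2,
                 tolerance = 1e-9)
  }
})

test_that("adding a consensus residue to a conserved column never increases sd", {
  tab <- featureTable()
  set.seed(13)
  for (rep in 1:20) {
    # conserved column: one letter holds a clear majority (>= 70%)
    consensus <- sample(nabind:::STANDARD_AA, 1)
    nCons <- sample(7:14, 1)
    nDev <- sample(0:floor(nCons * 0.4), 1)
    col <- c(rep(consensus, nCons),
             sample(nabind:::STANDARD_AA, nDev, replace = TRUE))
    f <- sample(c("H", "K", "M"), 1)
    before <- columnFeatureStats(col, f, tab)[["sd"]]
    after <- columnFeatureStats(c(col, consensus), f, tab)[["sd"]]
    expect_lte(after, before + 1e-12)
  }
})

test_that("a fully conserved alignment has sigma 0 and query means", {
  q <- "KRKAYW"
  aln <- synthAlignment(q, nHomologs = 8, mutationRate = 0, seed = 2)
  cp <- conservationProfile(q, buildColumnObservations(q, msa = aln))
  st <- profileStats(cp)
  expect_true(all(st[, c("H_sd", "K_sd", "M_sd")] == 0))
  tab <- featureTable()
  qres <- strsplit(q, "")[[1]]
  expect_equal(unname(st[, "K_mean"]), unname(tab[qres, "K"]))
  expect_equal(columnCounts(cp), rep(9L, 6))
})

test_that("scaled conservation stats share the feature-table bounds", {
  ds <- synthDataset(synthSpec(nSequences = 2, length = 40, seed = 21))
  sc <- nabind:::scaledConservationStats(ds[[1]]$conservation)
  expect_true(all(sc >= 0 & sc <= 1))
  # scaling preserves the ordering of the raw means
  raw <- profileStats(ds[[1]]$conservation)
  expect_equal(order(raw[, "M_mean"]), order(sc[, "M_mean"]))
})

test_that("the external search wrapper yields a parsable PSSM and alignments", {
  dir <- tempfile(); dir.create(dir)
  ds <- synthDataset(synthSpec(nSequences = 4, length = 60, seed = 3))
  seqs <- Biostrings::AAStringSet(vapply(ds, function(r) seqString(r$labeled), ""))
  names(seqs) <- paste0("s", 1:4)
  Biostrings::writeXStringSet(seqs, file.path(dir, "db.fasta"))
  Biostrings::writeXStringSet(seqs[1], file.path(dir, "q.fasta"))
  system2("makeblastdb", c("-in", file.path(dir, "db.fasta"),
                           "-dbtype", "prot"), stdout = FALSE, stderr = FALSE)
  res <- runPsiBlast(file.path(dir, "q.fasta"), file.path(dir, "db.fasta"),
                     file.path(dir, "out"))
  prof <- readPSSM(res$pssm)
  expect_equal(nrow(pssmScores(prof)), 60)
  aln <- readPairwiseAlignments(res$alignments)
  expect_true("s1" %in% aln$sid)   # the query itself is in the database
  obs <- buildColumnObservations(as.character(seqs[[1]]), pairwise = aln)
  expect_length(obs, 60)
  expect_gte(max(lengths(obs)), 2)
  # a missing database is an environment error, not a crash elsewhere
  expect_error(runPsiBlast(file.path(dir, "q.fasta"),
                           file.path(dir, "nodb"), file.path(dir, "x")),
               "status")
})
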