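test_that("training mode yields n - w + 1 centered windows", {
  ls11 <- LabeledSequence("a", strrep("A", 11), rep(-1, 11))
  inst <- extractInstances(ls11, window = 11, mode = "training")
  expect_equal(nrow(inst), 1)
  expect_equal(inst$position, 6)

  ls100 <- LabeledSequence("b", strrep("K", 100),
                           c(rep(1, 15), rep(-1, 85)))
  expect_equal(nrow(extractInstances(ls100, 11, "training")), 90)

  short <- LabeledSequence("c", strrep("G", 10), rep(-1, 10))
  expect_warning(got <- extractInstances(short, 11, "training"), "shorter")
  expect_equal(nrow(got), 0)
  expect_equal(nrow(extractInstances(short, 11, "prediction")), 10)
  expect_error(extractInstances(ls11, window = 10), "odd")
})

test_that("vector lengths follow the active feature groups", {
  expect_equal(windowVectorLength(11), 319)
  expect_equal(windowVectorLength(11, "hkm"), 33)
  expect_equal(windowVectorLength(11, c("hkm", "descriptors")), 99)
  expect_equal(windowVectorLength(1, "pssm"), 20)
})

test_that("encoded blocks decode back to per-residue features", {
  q <- "ACDEFGHIKLMNPQRSTVWY"
  ls <- LabeledSequence("q", q, rep(c(1, -1), 10))
  inst <- encodeInstances(ls, window = 5, featureGroups = "hkm",
                          mode = "training")
  m <- instanceMatrix(inst)
  expect_equal(ncol(m), 15)
  lut <- nabind:::featureLookup(featureTable(), scaled = TRUE)
  qres <- strsplit(q, "")[[1]]
  for (k in seq_len(nrow(m))) {
    centre <- inst@position[k]
    # middle block (columns 7-9) is the target residue's own features
    expect_equal(unname(m[k, 7:9]), unname(lut[qres[centre], ]))
  }
  # shifting the window by one shifts blocks by one block width
  expect_equal(unname(m[1, 4:15]), unname(m[2, 1:12]))
})

test_that("prediction-mode padding contributes all-zero blocks", {
  ls <- LabeledSequence("p", "KRKRW", rep(1, 5))
  inst <- encodeInstances(ls, window = 5, featureGroups = "hkm",
                          mode = "prediction")
  m <- instanceMatrix(inst)
  expect_equal(nrow(m), 5)
  # first residue: two pad blocks on the left
  expect_equal(unname(m[1, 1:6]), rep(0, 6))
  # last residue: two pad blocks on the right
  expect_equal(unname(m[5, 10:15]), rep(0, 6))
  expect_true(all(is.na(instanceLabels(inst))))
})

test_that("profile-dependent groups demand matching profiles", {
  ls <- LabeledSequence("q", strrep("A", 20), rep(-1, 20))
  expect_error(encodeInstances(ls, window = 5,
                               featureGroups = c("hkm", "descriptors")),
               "ConservationProfile")
  expect_error(encodeInstances(ls, window = 5,
                               featureGroups = c("hkm", "pssm")),
               "PSSMProfile")
  wrong <- conservationProfile(strrep("A", 10))
  expect_error(encodeInstances(ls, conservation = wrong, window = 5,
                               featureGroups = "descriptors"),
               "10 positions")
})

test_that("a constant window with query-only profiles repeats one block", {
  q <- strrep("R", 9)
  cp <- conservationProfile(q)
  ps <- synthPSSM(q, buildColumnObservations(q))
  ls <- LabeledSequence("r", q, rep(1, 9))
  inst <- encodeInstances(ls, pssm = ps, conservation = cp, window = 9,
                          mode = "training")
  v <- instanceMatrix(inst)[1, ]
  blocks <- matrix(v, nrow = 9, byrow = TRUE)
  for (r in 2:9) expect_equal(blocks[r, ], blocks[1, ])
  # sigma entries (block positions 5, 7, 9 within 4..9) are zero
  expect_equal(unname(blocks[1, c(5, 7, 9)]), rep(0, 3))
})

test_that("instance counts sum over a dataset as sum of (n_i - w + 1)", {
  ds <- synthDataset(synthSpec(nSequences = 5, length = 50, seed = 8))
  inst <- encodeDataset(ds, window = 11, featureGroups = "hkm")
  expect_equal(nrow(instanceMatrix(inst)), 5 * (50 - 11 + 1))
  # labels come from the centre residue
  labs <- bindingLabels(ds[[2]]$labeled)
  sel <- inst@seqid == ds[[2]]$labeled@id
  expect_equal(instanceLabels(inst)[sel], labs[6:45])
})

test_that("instance sets round-trip through the TSV + sidecar writer", {
  ds <- synthDataset(synthSpec(nSequences = 2, length = 30, seed = 9))
  inst <- encodeDataset(ds, window = 5,
                        featureGroups = c("hkm", "descriptors"))
  prefix <- tempfile()
  writeInstanceSet(inst, prefix)
  back <- readInstanceSet(prefix)
  expect_equal(unname(instanceMatrix(back)), unname(instanceMatrix(inst)),
               tolerance = 1e-9)
  expect_equal(instanceLabels(back), instanceLabels(inst))
  expect_equal(back@window, inst@window)
  expect_equal(back@featureGroups, inst@featureGroups)
  # descriptor mismatch is refused when combining
  other <- encodeDataset(ds, window = 5, featureGroups = "hkm")
  expect_error(bindInstanceSets(inst, other), "descriptor")
})
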