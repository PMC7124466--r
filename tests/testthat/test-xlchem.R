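test_that("isotopic mass delta matches the H/D label arithmetic", {
  expect_equal(isotopicMassDelta(8), 8.0502, tolerance = 5e-4)
  expect_identical(isotopicMassDelta(0), 0)
  expect_equal(isotopicMassDelta(4), 4 * (2.0141018 - 1.0078250),
               tolerance = 5e-4)
  expect_error(isotopicMassDelta(-1), "non-negative")
})

test_that("crosslinker spec validity enforces mass conservation and label", {
  expect_s4_class(crosslinkerSpec(), "CrosslinkerSpec")
  expect_error(crosslinkerSpec(shortArmMass = 50), "conserve")
  expect_error(crosslinkerSpec(labelMassDelta = 8.06), "inconsistent")
  expect_error(crosslinkerSpec(armLabelSplit = c(3L, 3L)), "armLabelSplit")
  # cleavage adjustment shifts the conservation constraint
  xl <- crosslinkerSpec(spacerMassLight = 100, shortArmMass = 41,
                        longArmMass = 60, cleavageAdjustment = 1)
  expect_equal(xl@shortArmMass + xl@longArmMass,
               xl@spacerMassLight + xl@cleavageAdjustment)
})

test_that("tryptic digestion applies cleavage and missed-cleavage rules", {
  expect_identical(
    digestTryptic("AAKAARAA", 0, prolineRule = FALSE)$sequence,
    c("AAK", "AAR", "AA"))
  d1 <- digestTryptic("AAKAARAA", 1, prolineRule = FALSE)
  expect_setequal(d1$sequence, c("AAK", "AAR", "AA", "AAKAAR", "AARAA"))
  expect_identical(d1$startPos[d1$sequence == "AARAA"], 4L)
  expect_identical(digestTryptic("AKPAA", 0, prolineRule = TRUE)$sequence,
                   "AKPAA")
  expect_error(digestTryptic(""), "non-empty")
  expect_error(digestTryptic("AXZ"), "unknown residue")
})

test_that("digestion equals the exhaustive window-enumeration oracle", {
  set.seed(402)
  for (rep in 1:20) {
    prot <- randomProteinSeq(sample(30:120, 1))
    mm <- sample(0:3, 1)
    pr <- sample(c(TRUE, FALSE), 1)
    got <- digestTryptic(prot, mm, prolineRule = pr)
    expect_identical(sort(paste0(got$sequence, "@", got$startPos)),
                     exhaustiveDigestOracle(prot, mm, pr),
                     label = sprintf("protein rep %d", rep))
  }
})

test_that("peptide masses follow residue tables with fixed CAM-C", {
  expect_equal(peptideMass("G"), 75.03203, tolerance = 1e-5)
  expect_equal(peptideMass("AG"), 146.06914, tolerance = 1e-5)
  # carbamidomethylated cysteine is built into the residue table
  expect_equal(peptideMass("C") - peptideMass("A"),
               103.00919 + 57.02146 - 71.03711, tolerance = 1e-5)
  expect_error(peptideMass(""), "non-empty")
  expect_error(peptideMass("AXB"), "unknown residue")
})

test_that("species precursor masses are assembled per link kind", {
  xl <- toyXl()
  inter <- linkSpecies("inter", "AAAK", 4, "P1", seqB = "GGGK", siteB = 4,
                       protB = "P2")
  mA <- peptideMass("AAAK"); mB <- peptideMass("GGGK")
  expect_equal(speciesPrecursorMass(inter, xl), mA + mB + 100)
  heavy <- linkSpecies("inter", "AAAK", 4, "P1", seqB = "GGGK", siteB = 4,
                       protB = "P2", label = "heavy")
  expect_equal(speciesPrecursorMass(heavy, xl) -
                 speciesPrecursorMass(inter, xl),
               8.0502, tolerance = 5e-4)
  loop <- linkSpecies("loop", "AKGK", 2, siteB = 4)
  expect_equal(speciesPrecursorMass(loop, xl), peptideMass("AKGK") + 100)
  de <- linkSpecies("deadend", "AAAK", 4, quench = "hydrolyzed")
  expect_equal(speciesPrecursorMass(de, xl),
               mA + 100 + 18.010565, tolerance = 1e-5)
  bad <- linkSpecies("deadend", "AAAK", 4, quench = "nosuch")
  expect_error(speciesPrecursorMass(bad, xl), "quench")
})

test_that("heavy minus light equals the label delta for every kind", {
  xl <- crosslinkerSpec()
  mk <- list(
    linkSpecies("inter", "AAAK", 4, "P1", seqB = "GGGK", siteB = 4,
                protB = "P2"),
    linkSpecies("intra", "AAAK", 4, "P1", seqB = "GGGKR", siteB = 4,
                protB = "P1"),
    linkSpecies("loop", "AKGK", 2, siteB = 4),
    linkSpecies("deadend", "AAAK", 4, quench = "ammonium"))
  for (sp in mk) {
    h <- sp; h@label <- "heavy"
    expect_equal(speciesPrecursorMass(h, xl) - speciesPrecursorMass(sp, xl),
                 xl@labelMassDelta, tolerance = 1e-9)
  }
})

test_that("link species validity rejects malformed combinations", {
  expect_error(linkSpecies("inter", "AAAK", 4, "P1", seqB = "GGGK",
                           siteB = 4, protB = "P1"), "different proteins")
  expect_error(linkSpecies("loop", "AKGK", 4, siteB = 2), "siteA < siteB")
  expect_error(linkSpecies("inter", "AAAK", 9, "P1", seqB = "GGGK",
                           siteB = 4, protB = "P2"), "out of range")
})

test_that("decoy shuffling preserves the tryptic skeleton", {
  d <- shuffleDecoyProtein("ACDKEFGR", seed = 5)
  expect_identical(nchar(d), 8L)
  expect_identical(substr(d, 4, 4), "K")
  expect_identical(substr(d, 8, 8), "R")
  expect_setequal(strsplit(substr(d, 1, 3), "")[[1]], c("A", "C", "D"))
  expect_setequal(strsplit(substr(d, 5, 7), "")[[1]], c("E", "F", "G"))
  expect_identical(shuffleDecoyProtein("K", 1), "K")
  expect_identical(shuffleDecoyProtein("ACDKEFGR", 5),
                   shuffleDecoyProtein("ACDKEFGR", 5))
})

test_that("decoys preserve length, boundaries, multisets, C-termini", {
  set.seed(77)
  for (rep in 1:25) {
    prot <- randomProteinSeq(sample(40:200, 1))
    dec <- shuffleDecoyProtein(prot, seed = rep)
    expect_identical(nchar(dec), nchar(prot))
    pT <- digestTryptic(prot, 0, prolineRule = FALSE)
    pD <- digestTryptic(dec, 0, prolineRule = FALSE)
    expect_identical(pD$startPos, pT$startPos)
    expect_identical(nchar(pD$sequence), nchar(pT$sequence))
    for (i in seq_len(nrow(pT))) {
      expect_identical(sort(strsplit(pD$sequence[i], "")[[1]]),
                       sort(strsplit(pT$sequence[i], "")[[1]]))
      nT <- nchar(pT$sequence[i])
      expect_identical(substr(pD$sequence[i], nT, nT),
                       substr(pT$sequence[i], nT, nT))
    }
  }
})

test_that("target-decoy database doubles entries deterministically", {
  prot <- c(P1 = "AAKAARAA", P2 = "GGKGGRGG", P3 = "MMKMMRMM")
  db <- buildTargetDecoyDb(prot, seed = 3)
  expect_length(db, 6L)
  expect_identical(names(db)[4:6], c("DECOY_P1", "DECOY_P2", "DECOY_P3"))
  expect_error(buildTargetDecoyDb(character(0)), "no target")
  expect_error(buildTargetDecoyDb(c(P1 = "AAK", P1 = "GGK")), "duplicate")
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  buildTargetDecoyDb(prot, outPath = f1, seed = 3)
  buildTargetDecoyDb(prot, outPath = f2, seed = 3)
  expect_identical(readLines(f1), readLines(f2))
  # decoy peptide length distribution equals target's
  lensT <- sort(nchar(digestTryptic(prot[["P1"]], 0)$sequence))
  lensD <- sort(nchar(digestTryptic(db[["DECOY_P1"]], 0)$sequence))
  expect_identical(lensD, lensT)
})

test_that("FASTA round trip and config reading work", {
  prot <- c("sp|Q1|TEST" = paste(rep("ACDEFGHIK", 10), collapse = ""))
  f <- tempfile(fileext = ".fasta")
  writeFastaProteins(prot, f)
  back <- readFastaProteins(f)
  expect_identical(unname(back), unname(prot))
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("name: toy", "spacer_mass_light: 100.0",
               "short_arm_mass: 40.0", "long_arm_mass: 60.0",
               "max_calpha_span: 35"), cfg)
  xl <- readCrosslinkerConfig(cfg)
  expect_equal(xl@spacerMassLight, 100)
  expect_equal(xl@maxCalphaSpan, 35)
  expect_equal(xl@labelMassDelta, isotopicMassDelta(8))
})
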