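test_that("peptide index annotates masses, decoys and reactive sites", {
  db <- c(P1 = "AAKAAKGGR", DECOY_P1 = "AKAAAKGGR")
  idx <- buildPeptideIndex(db, maxMissed = 1, minLength = 3)
  expect_true(all(c("mass", "isDecoy", "reactiveSites") %in% names(idx)))
  expect_true(any(idx$isDecoy))
  row <- idx[idx$sequence == "AAKAAK" & idx$proteinId == "P1", ]
  expect_identical(row$reactiveSites[[1]], c(1L, 3L, 6L))  # N-term + 2 K
  row2 <- idx[idx$sequence == "AAKGGR" & idx$proteinId == "P1", ]
  expect_identical(row2$reactiveSites[[1]], 3L)
})

test_that("candidate enumeration matches the precursor within tolerance", {
  xl <- toyXl()
  expect_identical(
    enumerateCandidates(1200, buildPeptideIndex(character(0) |>
                                                  stats::setNames(character(0)),
                                                xl), xl), list())
  db <- c(P1 = "AAADKR", P2 = "GGGWKR")
  idx <- buildPeptideIndex(db, xl, maxMissed = 1, minLength = 4)
  pepA <- idx[idx$sequence == "AAADKR", ]
  pepB <- idx[idx$sequence == "GGGWKR", ]
  target <- pepA$mass + pepB$mass + 100
  cands <- enumerateCandidates(target, idx, xl, tolPpm = 5)
  expect_true(length(cands) >= 1L)
  kinds <- vapply(cands, function(s) s@kind, character(1))
  expect_true(all(kinds == "inter"))
  seqs <- sort(c(cands[[1]]@seqA, cands[[1]]@seqB))
  expect_identical(seqs, c("AAADKR", "GGGWKR"))
})

test_that("candidate enumeration equals the brute-force oracle", {
  set.seed(31)
  prots <- vapply(1:6, function(i) randomProteinSeq(60), character(1))
  names(prots) <- sprintf("P%d", 1:6)
  db <- buildTargetDecoyDb(prots, seed = 31)
  xl <- crosslinkerSpec()
  idx <- buildPeptideIndex(db, xl, maxMissed = 1, minLength = 4)
  expect_lte(nrow(idx), 400)
  for (rep in 1:8) {
    i <- sample(nrow(idx), 1); j <- sample(nrow(idx), 1)
    prec <- idx$mass[i] + idx$mass[j] + xl@spacerMassLight +
      sample(c(0, xl@labelMassDelta), 1)
    got <- sort(unique(vapply(enumerateCandidates(prec, idx, xl, 10),
                              candidateKey, character(1))))
    expect_identical(got, exhaustiveCandidateOracle(prec, idx, xl, 10),
                     label = sprintf("rep %d", rep))
  }
})

test_that("fragment matching scores follow the binomial-tail oracle", {
  xl <- toyXl()
  sp <- linkSpecies("inter", "AAADKR", 5, "P1", seqB = "GGGWKR", siteB = 5,
                    protB = "P2")
  ions <- theoreticalFragmentIons(sp, xl)
  full <- ms2Spectrum(1L, 500, 4L, 10, ions$mz,
                      rep(1e4, nrow(ions)))
  r <- scoreSpectrumMatch(full, sp, xl)
  expect_equal(r$matchedFraction, 1)
  empty <- ms2Spectrum(2L, 500, 4L, 10, numeric(0), numeric(0))
  r0 <- scoreSpectrumMatch(empty, sp, xl)
  expect_equal(r0$matchedFraction, 0)
  expect_equal(r0$score, 0)
  # exactly half the ions present: score equals the closed-form tail
  half <- ions$mz[seq(1, nrow(ions), by = 2)]
  hs <- ms2Spectrum(3L, 500, 4L, 10, half, rep(1e4, length(half)))
  rh <- scoreSpectrumMatch(hs, sp, xl)
  k <- length(half); n <- nrow(ions)
  expect_equal(rh$matchedFraction, k / n)
  span <- max(half) - min(half)
  p <- min(0.99, length(half) * 2 * 0.02 / span)
  expect_equal(rh$score,
               -pbinom(k - 1, n, p, lower.tail = FALSE, log.p = TRUE) /
                 log(10),
               tolerance = 1e-9)
})

test_that("a planted spectrum is recovered at rank 1 with decoy flags", {
  set.seed(8)
  gt <- simulateGroundTruth(3, 200, nInter = 3, nIntra = 0, nLoop = 0,
                            nDeadend = 0, seed = 8)
  xl <- crosslinkerSpec()
  ms2 <- emitMs2Spectra(gt, xl, seed = 8)
  idx <- buildPeptideIndex(buildTargetDecoyDb(gt@proteins, seed = 8), xl,
                           maxMissed = 2)
  psms <- searchDataset(ms2$spectra, idx, xl)
  expect_identical(nrow(psms), length(ms2$spectra))
  truthSeqs <- unlist(gt@speciesTable[, c("seqA", "seqB")])
  expect_true(all(psms$seqA %in% truthSeqs))
  expect_false(any(psms$isDecoy))
  expect_identical(psms$isDecoy, psms$isDecoyA | psms$isDecoyB)
  # a spectrum assigned to a decoy peptide must be decoy-class
  dIdx <- idx[idx$isDecoy & lengths(idx$reactiveSites) > 0, ][1, ]
  deSp <- linkSpecies("deadend", dIdx$sequence, dIdx$reactiveSites[[1]][1],
                      dIdx$proteinId, dIdx$startPos)
  M <- speciesPrecursorMass(deSp, xl)
  ions <- theoreticalFragmentIons(deSp, xl)
  spec <- ms2Spectrum(999L, (M + 3 * 1.007276) / 3, 3L, 50, ions$mz,
                      rep(1e4, nrow(ions)))
  got <- searchDataset(list(spec), idx, xl)
  expect_true(got$isDecoy[1])
})

test_that("shifting the precursor by the label delta flips only the label", {
  set.seed(9)
  gt <- simulateGroundTruth(3, 200, nInter = 2, nIntra = 0, nLoop = 0,
                            nDeadend = 0, seed = 9)
  xl <- crosslinkerSpec()
  idx <- buildPeptideIndex(buildTargetDecoyDb(gt@proteins, seed = 9), xl,
                           maxMissed = 2)
  sp <- gt@species[[1]]
  ionsL <- theoreticalFragmentIons(sp, xl)
  spH <- sp; spH@label <- "heavy"
  ionsH <- theoreticalFragmentIons(spH, xl)
  z <- 4L
  mkS <- function(M, ions) ms2Spectrum(1L, (M + z * 1.007276) / z, z, 50,
                                       ions$mz, rep(1e4, nrow(ions)))
  pL <- searchDataset(list(mkS(speciesPrecursorMass(sp, xl), ionsL)),
                      idx, xl)
  pH <- searchDataset(list(mkS(speciesPrecursorMass(spH, xl), ionsH)),
                      idx, xl)
  expect_identical(pL$label, "light")
  expect_identical(pH$label, "heavy")
  same <- c("seqA", "seqB", "siteA", "siteB", "protA", "protB", "linkType")
  expect_identical(pL[, same], pH[, same])
})

test_that("ties at rank 1 break deterministically", {
  # two spectra searched twice give identical assignments
  set.seed(10)
  gt <- simulateGroundTruth(3, 200, nInter = 2, nIntra = 1, nLoop = 1,
                            nDeadend = 1, seed = 10)
  xl <- crosslinkerSpec()
  ms2 <- emitMs2Spectra(gt, xl, seed = 10)
  idx <- buildPeptideIndex(buildTargetDecoyDb(gt@proteins, seed = 10), xl,
                           maxMissed = 2)
  p1 <- searchDataset(ms2$spectra, idx, xl)
  p2 <- searchDataset(ms2$spectra, idx, xl)
  expect_identical(p1, p2)
})

test_that("Kojak-style result tables map onto the PSM schema", {
  p <- tempfile(fileext = ".txt")
  writeLines(c(
    "Kojak version 1.5.5",
    paste("Scan Number", "Ret Time", "Obs Mass", "Charge", "PSM Mass",
          "PPM Error", "Score", "dScore", "Peptide #1", "Link #1",
          "Protein #1", "Peptide #2", "Link #2", "Protein #2",
          "Linker Mass", sep = "\t"),
    paste("101", "42.1", "3211.5", "4", "3211.49", "2.1", "3.5", "1.2",
          "AAK[x]DR", "3", "P1", "GGKWR", "3", "P2", "500.0",
          sep = "\t"),
    paste("102", "43.0", "2211.5", "3", "2211.49", "1.0", "2.5", "0.2",
          "MMKLR", "3", "DECOY_P3", "-", "-", "-", "508.05",
          sep = "\t")), p)
  psms <- readKojak(p, crosslinkerSpec(spacerMassLight = 500,
                                       shortArmMass = 200,
                                       longArmMass = 300))
  expect_identical(nrow(psms), 2L)
  expect_identical(psms$seqA[1], "AAKDR")
  expect_identical(psms$linkType[1], "inter")
  expect_identical(psms$label, c("light", "heavy"))
  expect_identical(psms$linkType[2], "single")
  expect_true(psms$isDecoy[2])
  expect_false(psms$isDecoy[1])
  # and the imported table feeds the PIN builder
  pin <- buildPinTable(within(psms, {
    tic <- 0; basePeakMz <- 0; basePeakIntensity <- 0
  }))
  expect_identical(nrow(pin), 2L)
})
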