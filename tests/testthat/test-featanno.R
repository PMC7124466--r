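test_that("cleavage products follow the arm arithmetic", {
  xl <- toyXl()  # spacer 100, short 40, long 60, adjustment 0
  sp <- linkSpecies("inter", "AAAK", 4, "P1", seqB = "GGGK", siteB = 4,
                    protB = "P2")
  prod <- theoreticalCleavageProducts(sp, xl, charges = 1L)
  mA <- peptideMass("AAAK"); mB <- peptideMass("GGGK")
  expect_setequal(round(prod$neutralMass, 5),
                  round(c(mA + 40, mA + 60, mB + 40, mB + 60), 5))
  expect_identical(prod$productId,
                   c("A_short", "A_long", "B_short", "B_long"))
  expect_equal(prod$mz, prod$neutralMass + 1.007276)
  # loop-links have no mass-shifted diagnostic product
  expect_identical(
    nrow(theoreticalCleavageProducts(linkSpecies("loop", "AKGK", 2,
                                                 siteB = 4), xl)), 0L)
  de <- theoreticalCleavageProducts(
    linkSpecies("deadend", "AAAK", 4), xl, charges = 1L)
  expect_identical(de$productId, c("A_short", "A_long"))
})

test_that("complementary products conserve the precursor mass", {
  xl <- crosslinkerSpec()
  set.seed(21)
  for (rep in 1:50) {
    a <- randomProteinSeq(sample(5:15, 1))
    b <- randomProteinSeq(sample(5:15, 1))
    lab <- sample(c("light", "heavy"), 1)
    sp <- linkSpecies("inter", a, 1, "P1", seqB = b, siteB = 1,
                      protB = "P2", label = lab)
    prod <- theoreticalCleavageProducts(sp, xl, charges = 1L)
    prec <- speciesPrecursorMass(sp, xl)
    m <- stats::setNames(prod$neutralMass, prod$productId)
    expect_equal(m[["A_short"]] + m[["B_long"]], prec, tolerance = 1e-9)
    expect_equal(m[["A_long"]] + m[["B_short"]], prec, tolerance = 1e-9)
  }
})

test_that("heavy products shift by the per-arm label share", {
  xl <- crosslinkerSpec()
  sp <- linkSpecies("inter", "AAAK", 4, "P1", seqB = "GGGK", siteB = 4,
                    protB = "P2")
  spH <- sp; spH@label <- "heavy"
  pL <- theoreticalCleavageProducts(sp, xl, 1L)
  pH <- theoreticalCleavageProducts(spH, xl, 1L)
  shift <- pH$neutralMass - pL$neutralMass
  d1 <- isotopicMassDelta(1)
  expect_equal(shift, c(4, 4, 4, 4) * d1, tolerance = 1e-9)
  # a complementary pair carries the full label delta
  expect_equal(shift[1] + shift[2], xl@labelMassDelta, tolerance = 1e-9)
})

test_that("cleavage annotation flags products at inclusive tolerance", {
  xl <- toyXl()
  sp <- linkSpecies("inter", "AAAK", 4, "P1", seqB = "GGGK", siteB = 4,
                    protB = "P2")
  prod <- theoreticalCleavageProducts(sp, xl, charges = 1L)
  full <- ms2Spectrum(1L, 500, 4L, 10, prod$mz, rep(5e4, 4))
  ev <- annotateCleavage(full, sp, xl)
  expect_equal(ev$nCleavageProducts, 4)
  expect_equal(unlist(ev[, c("cleavShortA", "cleavLongA", "cleavShortB",
                             "cleavLongB")]), rep(1, 4),
               ignore_attr = TRUE)
  expect_equal(ev$intShortA, 5e4)
  empty <- ms2Spectrum(2L, 500, 4L, 10, numeric(0), numeric(0))
  expect_equal(annotateCleavage(empty, sp, xl)$nCleavageProducts, 0)
  # a peak at exactly predicted m/z + tolerance is found
  one <- ms2Spectrum(3L, 500, 4L, 10, prod$mz[1] + 0.02, 1e4)
  ev1 <- annotateCleavage(one, sp, xl, tol = 0.02)
  expect_equal(ev1$cleavShortA, 1)
  expect_equal(ev1$nCleavageProducts, 1)
})

test_that("dead-end signature requires both remnant ions", {
  xl <- toyXl()
  de <- linkSpecies("deadend", "AAAK", 4)
  prod <- theoreticalCleavageProducts(de, xl, charges = 1L)
  both <- ms2Spectrum(1L, 400, 3L, 10, prod$mz, c(1e4, 1e4))
  expect_equal(annotateCleavage(both, de, xl)$deadendSignature, 1)
  onlyShort <- ms2Spectrum(2L, 400, 3L, 10, prod$mz[1], 1e4)
  expect_equal(annotateCleavage(onlyShort, de, xl)$deadendSignature, 0)
})

test_that("MS1 evidence attaches by mass and RT with label agreement", {
  delta <- isotopicMassDelta(8)
  f <- rbind(feat(3000, 3, 50, 1e5), feat(3000 + delta, 3, 49.8, 1.2e5))
  f$featureId <- 1:2
  f$envelope <- vapply(f$monoisotopicMass, function(m) {
    env <- predictIsotopeEnvelope(m)
    paste(sprintf("%.5g", env / max(env)), collapse = ";")
  }, character(1))
  mps <- pairMultiplets(f)
  psm <- function(mass, rt, label) data.frame(
    precursorNeutralMass = mass, rt = rt, label = label)
  p <- attachMs1Evidence(rbind(
    psm(3000, 50.1, "light"),          # light member, agrees
    psm(3000 + delta, 49.9, "heavy"),  # heavy member, agrees
    psm(3000, 50.1, "heavy"),          # light member, disagrees
    psm(4000, 50.0, "light")), mps)    # no multiplet
  expect_equal(p$ms1EvidenceMissing, c(0, 0, 0, 1))
  expect_equal(p$labelAgreement, c(1, 1, 0, 0))
  expect_equal(p$labelAgreementMissing, c(0, 0, 0, 1))
  expect_equal(p$hlLog2Ratio[1], log2(1.2), tolerance = 1e-9)
  expect_equal(p$partnerRtDelta[1], -0.2, tolerance = 1e-9)
  expect_equal(p$isotopePatternMatch[1:3], rep(1, 3))
  expect_equal(p$hlLog2Ratio[4], 0)
})

test_that("partner corroboration requires the opposite label", {
  xl <- crosslinkerSpec()
  base <- data.frame(
    linkType = "inter", seqA = "AAAK", siteA = 4L, protA = "P1",
    seqB = "GGGK", siteB = 4L, protB = "P2",
    precursorNeutralMass = 1000, label = "light",
    stringsAsFactors = FALSE)
  h <- base; h$label <- "heavy"
  h$precursorNeutralMass <- 1000 + xl@labelMassDelta
  both <- computeMetaFeatures(rbind(base, h), xl)
  expect_equal(both$partnerCorroborated, c(1, 1))
  lone <- computeMetaFeatures(base, xl)
  expect_equal(lone$partnerCorroborated, 0)
  twiceSame <- computeMetaFeatures(rbind(base, base), xl)
  expect_equal(twiceSame$partnerCorroborated, c(0, 0))
  # same pair, opposite label, wrong mass gap: not corroborated
  hOff <- h; hOff$precursorNeutralMass <- 1000 + xl@labelMassDelta + 1
  off <- computeMetaFeatures(rbind(base, hOff), xl)
  expect_equal(off$partnerCorroborated, c(0, 0))
})

test_that("the PIN table has the fixed 41+5 schema and round-trips", {
  expect_length(pinFeatureNames(), 41L)
  psms <- data.frame(
    specId = c("s1", "s2", "s3"), scanId = 1:3,
    precursorCharge = c(3L, 4L, 5L),
    precursorNeutralMass = c(2000, 2500, 3000),
    massErrorPpm = c(1, -2, 0.5),
    linkType = c("inter", "intra", "inter"),
    label = c("light", "heavy", "light"),
    seqA = c("AAAK", "GGGK", "MMMK"), siteA = 4L,
    seqB = c("WWWK", "YYYK", "HHHK"), siteB = 4L,
    protA = c("P1", "P2", "DECOY_P3"), protB = c("P4", "P2", "P5"),
    score = c(3, 2, 1), deltaScore = c(1, 0.5, 0.1),
    isDecoy = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  pin <- buildPinTable(psms)
  expect_identical(names(pin)[1:3], c("SpecId", "Label", "ScanNr"))
  expect_identical(names(pin)[4:44], pinFeatureNames())
  expect_identical(names(pin)[45:46], c("Peptide", "Proteins"))
  expect_identical(pin$Label, c(1L, 1L, -1L))
  expect_identical(pin$Peptide[1], "AAAK(4)--WWWK(4)")
  expect_identical(pin$Proteins[1], "P1;P4")
  # missing evidence encoded as 0 with indicator 1
  expect_equal(pin$ms1EvidenceMissing, rep(1, 3))
  expect_equal(pin$hlLog2Ratio, rep(0, 3))
  p <- tempfile(fileext = ".pin")
  writePin(pin, p)
  back <- readPin(p)
  expect_identical(names(back), names(pin))
  expect_equal(back$score, pin$score)
  expect_identical(back$Peptide, pin$Peptide)
  # NaN in a feature is a hard error
  bad <- psms; bad$massErrorPpm[2] <- NaN
  expect_error(buildPinTable(bad), "non-finite")
})

test_that("true PSMs separate from false PSMs in the planted evidence", {
  xl <- crosslinkerSpec()
  gt <- simulateGroundTruth(4, 250, nInter = 8, nIntra = 4, nLoop = 0,
                            nDeadend = 0, seed = 15)
  ms1 <- emitMs1FeatureTable(gt, xl, seed = 15)
  mps <- pairMultiplets(ms1$features)
  ms2 <- emitMs2Spectra(gt, xl, ms1 = ms1, cleavageProductProb = 0.9,
                        nFalseSpectra = 15, noisePeaks = 20, seed = 15)
  idx <- buildPeptideIndex(buildTargetDecoyDb(gt@proteins, seed = 15), xl,
                           maxMissed = 2)
  psms <- searchDataset(ms2$spectra, idx, xl)
  psms <- computeMetaFeatures(
    attachMs1Evidence(annotatePsmCleavage(psms, ms2$spectra, xl), mps), xl)
  ann <- ms2$annotations
  isTrue <- ann$isTrue[match(psms$scanId, ann$scanId)]
  expect_gt(mean(psms$nCleavageProducts[isTrue & psms$linkType %in%
                                          c("inter", "intra")]),
            mean(psms$nCleavageProducts[!isTrue]))
  expect_gt(mean(psms$partnerCorroborated[isTrue]),
            mean(psms$partnerCorroborated[!isTrue]))
})
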