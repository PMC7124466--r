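delta8 <- isotopicMassDelta(8)

test_that("pair classification applies every criterion inclusively", {
  c0 <- pairCriteria()
  l <- feat(1200, 3, 50, 1e5, 3e4)
  h <- feat(1200 + delta8, 3, 49.8, 1.4e5, 3e4)
  expect_true(classifyPair(l, h, c0)$accepted)
  # RT offset above the window upper bound is rejected
  hLate <- feat(1200 + delta8, 3, 50.2, 1e5, 3e4)
  cl <- classifyPair(l, hLate, c0)
  expect_false(cl$accepted)
  expect_identical(cl$diagnostics$failed, "rtWindow")
  # tolerance boundary is inclusive
  hEdge <- feat(1200 + c0@delta + c0@deltaTol, 3, 49.8, 1e5, 3e4)
  expect_true(classifyPair(l, hEdge, c0)$accepted)
  # observed delta of 8.0602 sits inside the +/- 0.01 window
  h2 <- feat(1200 + 8.0602, 3, 49.8, 1e5, 3e4)
  expect_true(classifyPair(l, h2, c0)$accepted)
  # RT window boundaries inclusive
  expect_true(classifyPair(l, feat(1200 + delta8, 3, 49.6, 1e5, 3e4),
                           c0)$accepted)
  expect_true(classifyPair(l, feat(1200 + delta8, 3, 50.05, 1e5, 3e4),
                           c0)$accepted)
  # intensity floor and log2 ratio
  expect_identical(
    classifyPair(l, feat(1200 + delta8, 3, 49.8, 1e5, 2e4),
                 c0)$diagnostics$failed, "minIntensity")
  expect_identical(
    classifyPair(l, feat(1200 + delta8, 3, 49.8, 5e5, 3e4),
                 c0)$diagnostics$failed, "log2Ratio")
})

test_that("zero intensity rejects with a diagnostic, not an error", {
  l <- feat(1200, 3, 50, 0, 3e4)
  h <- feat(1200 + delta8, 3, 49.8, 1e5, 3e4)
  cl <- classifyPair(l, h, pairCriteria())
  expect_false(cl$accepted)
  expect_true("log2Ratio" %in% cl$diagnostics$failed)
})

test_that("charge mismatch is a precondition error", {
  expect_error(classifyPair(feat(1200, 3), feat(1208, 4), pairCriteria()),
               "charge")
})

test_that("pipeline preset bounds the relative intensity difference", {
  cp <- pairCriteria("pipeline")
  l <- feat(1200, 3, 50, 1e5, 1e3)   # below acquisition floor: irrelevant
  hOk <- feat(1200 + delta8, 3, 49.8, 1.1e5, 1e3)
  hBad <- feat(1200 + delta8, 3, 49.8, 2e5, 1e3)
  expect_true(classifyPair(l, hOk, cp)$accepted)
  expect_identical(classifyPair(l, hBad, cp)$diagnostics$failed,
                   "relativeIntensity")
})

test_that("multiplet chaining finds doublets, triplets, quadruplets", {
  expect_identical(pairMultiplets(feat(1200, 3)[0, ]), list())
  tri <- rbind(feat(2000, 3, 50), feat(2000 + delta8, 3, 49.9),
               feat(2000 + 2 * delta8, 3, 49.8))
  mp <- pairMultiplets(tri)
  expect_length(mp, 1L)
  expect_identical(mp[[1]]@order, 3L)
  expect_equal(mp[[1]]@deltas, rep(delta8, 2), tolerance = 1e-9)
  quin <- do.call(rbind, lapply(0:4, function(k)
    feat(2000 + k * delta8, 3, 50 - 0.05 * k)))
  mp5 <- pairMultiplets(quin)
  # chain of 5 splits greedily from the light end: one quadruplet, the
  # leftover single feature cannot form a multiplet
  expect_identical(vapply(mp5, function(m) m@order, integer(1)), 4L)
})

test_that("multiplet set is invariant to input row order", {
  f <- randomFeatureSet(120, seed = 9)
  mp1 <- pairMultiplets(f)
  perm <- sample(nrow(f))
  mp2 <- pairMultiplets(f[perm, ])
  sig <- function(mps) sort(vapply(mps, function(m)
    paste(sort(m@members$featureId), collapse = "-"), character(1)))
  expect_identical(sig(mp2), sig(mp1))
})

test_that("accepted pairs equal the exhaustive oracle on random sets", {
  for (seed in 1:10) {
    f <- randomFeatureSet(sample(40:200, 1), seed = seed)
    got <- findDoubletPairs(f)
    expect_identical(pairKeySet(got), pairKeySet(exhaustivePairOracle(f)),
                     label = sprintf("seed %d", seed))
  }
})

test_that("conflict resolution keeps each feature in one multiplet", {
  # one light feature with two in-window heavy partners: smaller mass
  # error wins
  l <- feat(1500, 3, 50)
  h1 <- feat(1500 + delta8 + 0.004, 3, 49.9)
  h2 <- feat(1500 + delta8 + 0.001, 3, 49.9)
  mp <- pairMultiplets(rbind(l, h1, h2))
  expect_length(mp, 1L)
  expect_equal(mp[[1]]@members$monoisotopicMass[2], 1500 + delta8 + 0.001)
  f <- randomFeatureSet(150, seed = 4)
  ids <- unlist(lapply(pairMultiplets(f), function(m) m@members$featureId))
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("inclusion lists keep charge >= 3 and emit both partners", {
  doubletZ2 <- pairMultiplets(rbind(feat(1200, 2), feat(1200 + delta8, 2,
                                                        49.9)))
  expect_identical(nrow(buildInclusionList(doubletZ2)), 0L)
  dz3 <- pairMultiplets(rbind(feat(1200, 3), feat(1208.0502, 3, 49.9)))
  incl <- buildInclusionList(dz3, rtPad = 0.5)
  expect_identical(nrow(incl), 2L)
  expect_equal(incl$mz, c(401.00728, 403.69068), tolerance = 1e-5)
  expect_equal(diff(incl$mz), 8.0502 / 3, tolerance = 1e-5)
  # per-member RT extent padded by rtPad (light apex 50, heavy apex 49.9)
  expect_equal(incl$rtStart, c(49, 48.9))
  expect_true(all(incl$mz > 0))
  # heavy - light m/z spacing is delta / z
  f <- randomFeatureSet(100, seed = 12)
  mps <- pairMultiplets(f)
  for (m in mps) {
    z <- m@members$charge[1]
    if (z < 3) next
    il <- buildInclusionList(list(m), rtPad = 0)
    expect_equal(diff(sort(il$mz)),
                 diff(m@members$monoisotopicMass) / z, tolerance = 1e-6)
  }
})

test_that("kronik tables round-trip through the TSV dialect", {
  f <- randomFeatureSet(30, seed = 2)
  p <- tempfile(fileext = ".tsv")
  writeKronik(f, p)
  back <- readKronik(p)
  expect_equal(back$monoisotopicMass, f$monoisotopicMass)
  expect_identical(back$charge, f$charge)
  expect_equal(back$summedIntensity, f$summedIntensity)
  # header variants resolved through the column map
  p2 <- tempfile(fileext = ".tsv")
  df <- data.frame(`My Mass` = f$monoisotopicMass, Charge = f$charge,
                   `Best RTime` = f$rtApex, `First RTime` = f$rtStart,
                   `Last RTime` = f$rtEnd,
                   `Summed Intensity` = f$summedIntensity,
                   `Best Intensity` = f$maxIntensity, check.names = FALSE)
  write.table(df, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  back2 <- readKronik(p2, columnMap = list(monoisotopicMass = "My Mass"))
  expect_equal(back2$monoisotopicMass, f$monoisotopicMass)
  expect_error(readKronik(p2), "cannot locate")
  # inclusion CSV writer emits the instrument dialect header
  incl <- data.frame(mz = 401.00728, charge = 3L, rtStart = 49, rtEnd = 51)
  pc <- tempfile(fileext = ".csv")
  writeInclusionList(incl, pc)
  expect_match(readLines(pc, n = 1), "Mass \\[m/z\\]")
})
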