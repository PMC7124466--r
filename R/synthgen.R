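.sampleProtein <- function(length, kFreq = 0.08, rFreq = 0.05) {
  others <- setdiff(AMINO_ACIDS, c("K", "R"))
  probs <- c(rep((1 - kFreq - rFreq) / length(others), length(others)),
             kFreq, rFreq)
  paste(sample(c(others, "K", "R"), length, replace = TRUE, prob = probs),
        collapse = "")
}

.eligiblePeptides <- function(proteins, maxMissed = 2L, minLen = 6L,
                              maxLen = 25L) {
  peps <- do.call(rbind, lapply(names(proteins), function(acc)
    digestTryptic(proteins[[acc]], maxMissed = maxMissed,
                  proteinId = acc)))
  len <- nchar(peps$sequence)
  peps <- peps[len >= minLen & len <= maxLen, , drop = FALSE]
  # a linkable site must be an internal K (a crosslinked K blocks trypsin,
  # so planted peptides carry it as a missed cleavage)
  peps$kSites <- lapply(peps$sequence, function(s) {
    res <- strsplit(s, "")[[1]]
    sites <- which(res == "K")
    as.integer(sites[sites < length(res)])
  })
  peps <- peps[vapply(peps$kSites, length, integer(1)) > 0L, , drop = FALSE]
  rownames(peps) <- NULL
  peps
}

#' Simulate a ground-truthed crosslinking experiment
#'
#' Generates random proteins with realistic residue frequencies (lysine
#' boosted to 8% so every protein carries linkable sites) and plants the
#' requested numbers of inter-protein, intra-protein, loop and dead-end
#' crosslinked species on internal lysines of tryptic peptides (a
#' crosslinked lysine blocks trypsin, so planted peptides carry it as a
#' missed cleavage). Deterministic for a given seed.
#'
#' @param nProteins number of proteins.
#' @param meanLength protein length (residues; each protein drawn within
#'   +/- 20% of this).
#' @param nInter,nIntra,nLoop,nDeadend species counts to plant.
#' @param seed integer seed.
#' @return a \code{\linkS4class{GroundTruth}}.
#' @export
simulateGroundTruth <- function(nProteins = 5L, meanLength = 300L,
                                nInter = 10L, nIntra = 10L, nLoop = 5L,
                                nDeadend = 5L, seed = 1L) {
  set.seed(seed)
  proteins <- character(nProteins)
  for (i in seq_len(nProteins)) {
    repeat {
      p <- .sampleProtein(round(stats::runif(1, 0.8, 1.2) * meanLength))
      if (lengths(regmatches(p, gregexpr("K", p))) >= 2L) break
    }
    proteins[i] <- p
  }
  names(proteins) <- sprintf("SYN%03d", seq_len(nProteins))
  peps <- .eligiblePeptides(proteins)
  if (!nrow(peps))
    stop("unsatisfiable: no peptide with an internal lysine was produced; ",
         "increase meanLength or nProteins")
  if (nInter > 0L && length(unique(peps$proteinId)) < 2L)
    stop("unsatisfiable: inter-protein links need at least 2 proteins ",
         "with eligible peptides")
  pickPep <- function(rows) rows[sample.int(length(rows), 1L)]
  pick1 <- function(x) x[sample.int(length(x), 1L)]
  species <- list()
  seen <- character()
  addSpecies <- function(sp) {
    k <- .speciesKey(sp)
    if (k %in% seen) return(FALSE)
    seen <<- c(seen, k)
    species[[length(species) + 1L]] <<- sp
    TRUE
  }
  mkFromRow <- function(i) list(seq = peps$sequence[i],
                                prot = peps$proteinId[i],
                                start = peps$startPos[i],
                                sites = peps$kSites[[i]])
  tries <- 0L
  want <- c(inter = nInter, intra = nIntra, loop = nLoop,
            deadend = nDeadend)
  have <- c(inter = 0L, intra = 0L, loop = 0L, deadend = 0L)
  loopRows <- which(vapply(peps$kSites, length, integer(1)) >= 2L)
  while (any(have < want)) {
    tries <- tries + 1L
    if (tries > 5000L)
      stop("unsatisfiable species counts after 5000 draws: still need ",
           paste(sprintf("%s=%d", names(want), want - have)[have < want],
                 collapse = ", "))
    kind <- names(want)[which(have < want)[1]]
    ok <- FALSE
    if (kind == "inter") {
      i <- pickPep(seq_len(nrow(peps)))
      jPool <- which(peps$proteinId != peps$proteinId[i])
      if (!length(jPool)) next
      j <- pickPep(jPool)
      a <- mkFromRow(i); b <- mkFromRow(j)
      ok <- addSpecies(linkSpecies("inter", a$seq, pick1(a$sites),
                                   a$prot, a$start, seqB = b$seq,
                                   siteB = pick1(b$sites),
                                   protB = b$prot, startB = b$start))
    } else if (kind == "intra") {
      i <- pickPep(seq_len(nrow(peps)))
      jPool <- which(peps$proteinId == peps$proteinId[i] &
                       (peps$startPos + nchar(peps$sequence) <=
                          peps$startPos[i] |
                          peps$startPos >= peps$startPos[i] +
                          nchar(peps$sequence[i])))
      if (!length(jPool)) next
      j <- pickPep(jPool)
      a <- mkFromRow(i); b <- mkFromRow(j)
      ok <- addSpecies(linkSpecies("intra", a$seq, pick1(a$sites),
                                   a$prot, a$start, seqB = b$seq,
                                   siteB = pick1(b$sites),
                                   protB = b$prot, startB = b$start))
    } else if (kind == "loop") {
      if (!length(loopRows))
        stop("unsatisfiable: no peptide with 2 internal lysines for ",
             "loop-links")
      i <- pickPep(loopRows)
      a <- mkFromRow(i)
      ss <- sort(a$sites[sample.int(length(a$sites), 2L)])
      ok <- addSpecies(linkSpecies("loop", a$seq, ss[1], a$prot, a$start,
                                   siteB = ss[2]))
    } else {
      i <- pickPep(seq_len(nrow(peps)))
      a <- mkFromRow(i)
      ok <- addSpecies(linkSpecies("deadend", a$seq, pick1(a$sites),
                                   a$prot, a$start,
                                   quench = sample(c("hydrolyzed",
                                                     "ammonium"), 1L)))
    }
    if (ok) have[kind] <- have[kind] + 1L
  }
  tab <- do.call(rbind, lapply(seq_along(species), function(i) {
    s <- species[[i]]
    data.frame(speciesId = i, kind = s@kind, seqA = s@seqA,
               protA = s@protA, startA = s@startA, siteA = s@siteA,
               seqB = s@seqB, protB = s@protB, startB = s@startB,
               siteB = s@siteB, quench = s@quench,
               stringsAsFactors = FALSE)
  }))
  new("GroundTruth", proteins = proteins, species = species,
      speciesTable = tab, seed = as.integer(seed))
}

.withLabel <- function(species, label) {
  s <- species
  s@label <- label
  s
}

#' Emit a deconvoluted MS1 feature table with planted multiplet pairs
#'
#' Every planted species yields a co-eluting light/heavy feature pair
#' satisfying all pairing criteria (mass delta within tolerance, RT offset
#' in the window, balanced intensities above the floor); a chosen fraction
#' of pairs instead break exactly one named criterion; unpaired noise
#' features are added with masses kept away from the pairing window of any
#' other feature. Each planted feature carries an isotope-envelope column
#' consistent with the averagine prediction.
#'
#' @param gt a \code{\linkS4class{GroundTruth}}.
#' @param xl a \code{\linkS4class{CrosslinkerSpec}}.
#' @param nNoiseFeatures unpaired decoy-like features to add.
#' @param violationFraction fraction of pairs that violate one criterion.
#' @param seed integer seed.
#' @param rtRange apex retention-time range (minutes).
#' @return list with \code{features} (standard feature data.frame, plus
#'   \code{featureId} and \code{envelope}) and \code{annotations}
#'   (\code{featureId}, \code{speciesId}, \code{role} light/heavy/noise,
#'   \code{violated} criterion name or "").
#' @export
emitMs1FeatureTable <- function(gt, xl = crosslinkerSpec(),
                                nNoiseFeatures = 0L,
                                violationFraction = 0, seed = 1L,
                                rtRange = c(10, 100)) {
  set.seed(seed)
  ns <- length(gt@species)
  nViol <- round(violationFraction * ns)
  violIdx <- if (nViol > 0L) sample.int(ns, nViol) else integer()
  violKinds <- c("massDelta", "rtWindow", "log2Ratio", "minIntensity")
  rows <- list(); anns <- list()
  fid <- 0L
  addFeature <- function(mass, z, apex, s, e, summed, mx, envelope,
                         speciesId, role, violated) {
    fid <<- fid + 1L
    rows[[fid]] <<- data.frame(
      featureId = fid, monoisotopicMass = mass, charge = z, rtApex = apex,
      rtStart = s, rtEnd = e, summedIntensity = summed, maxIntensity = mx,
      envelope = envelope, stringsAsFactors = FALSE)
    anns[[fid]] <<- data.frame(featureId = fid, speciesId = speciesId,
                               role = role, violated = violated,
                               stringsAsFactors = FALSE)
  }
  envString <- function(mass) {
    env <- predictIsotopeEnvelope(mass) * stats::runif(5, 0.97, 1.03)
    paste(sprintf("%.5g", env / max(env)), collapse = ";")
  }
  for (i in seq_len(ns)) {
    sp <- gt@species[[i]]
    mLight <- speciesPrecursorMass(.withLabel(sp, "light"), xl)
    z <- sample(3:5, 1L)
    apex <- stats::runif(1, rtRange[1], rtRange[2])
    offset <- stats::runif(1, -0.35, 0.02)
    sumL <- stats::rlnorm(1, log(2e5), 0.5)
    l2 <- max(-1.8, min(1.8, stats::rnorm(1, 0, 0.5)))
    sumH <- sumL * 2^l2
    mxL <- max(26000, 0.3 * sumL); mxH <- max(26000, 0.3 * sumH)
    dJitter <- stats::runif(1, -0.004, 0.004)
    mHeavy <- mLight + xl@labelMassDelta + dJitter
    violated <- ""
    if (i %in% violIdx) {
      violated <- violKinds[1L + (match(i, violIdx) - 1L) %% 4L]
      if (violated == "massDelta") mHeavy <- mHeavy + 0.05
      if (violated == "rtWindow") offset <- 0.3
      if (violated == "log2Ratio") sumH <- sumL * 2^3.2
      if (violated == "minIntensity") { mxL <- 10000; mxH <- 10000 }
    }
    addFeature(mLight, z, apex, apex - 0.5, apex + 0.5, sumL, mxL,
               envString(mLight), i, "light", violated)
    addFeature(mHeavy, z, apex + offset, apex + offset - 0.5,
               apex + offset + 0.5, sumH, mxH, envString(mHeavy), i,
               "heavy", violated)
  }
  if (nNoiseFeatures > 0L) {
    existing <- vapply(rows, function(r)
      r$monoisotopicMass + 1i * r$charge, complex(1))
    guard <- xl@labelMassDelta
    nAdded <- 0L
    while (nAdded < nNoiseFeatures) {
      mass <- stats::runif(1, 800, 6000)
      z <- sample(2:5, 1L)
      same <- Re(existing)[Im(existing) == z]
      if (any(abs(abs(same - mass) - guard) < 0.05)) next
      apex <- stats::runif(1, rtRange[1], rtRange[2])
      env <- stats::runif(5)
      addFeature(mass, z, apex, apex - 0.5, apex + 0.5,
                 stats::rlnorm(1, log(1e5), 1), 30000,
                 paste(sprintf("%.5g", env / max(env)), collapse = ";"),
                 NA_integer_, "noise", "")
      existing <- c(existing, mass + 1i * z)
      nAdded <- nAdded + 1L
    }
  }
  list(features = do.call(rbind, rows), annotations = do.call(rbind, anns))
}

#' Emit MS2 spectra for the planted species
#'
#' One spectrum per planted species and label (light and heavy): b/y
#' fragment ions subsampled at \code{fragmentCoverage}, each crosslinker
#' cleavage product included with probability \code{cleavageProductProb}
#' (singly charged), optional uniform-m/z noise peaks, and a precursor m/z
#' consistent with the species mass and label. Optional decoy-like false
#' spectra carry random peaks at a precursor mass offset from a real
#' species. When the MS1 emission is supplied, charges and retention times
#' are taken from the corresponding planted features so MS1 and MS2
#' evidence agree.
#'
#' @param gt a \code{\linkS4class{GroundTruth}}.
#' @param xl a \code{\linkS4class{CrosslinkerSpec}}.
#' @param ms1 optional result of \code{\link{emitMs1FeatureTable}}.
#' @param fragmentCoverage fraction of b/y ions present.
#' @param cleavageProductProb per-product inclusion probability.
#' @param noisePeaks noise peaks per spectrum.
#' @param nFalseSpectra decoy-like spectra with no true species.
#' @param seed integer seed.
#' @return list with \code{spectra} (list of
#'   \code{\linkS4class{Ms2Spectrum}}) and \code{annotations}
#'   (\code{scanId}, \code{speciesId}, \code{label}, \code{isTrue}).
#' @export
emitMs2Spectra <- function(gt, xl = crosslinkerSpec(), ms1 = NULL,
                           fragmentCoverage = 1, cleavageProductProb = 1,
                           noisePeaks = 0L, nFalseSpectra = 0L, seed = 1L) {
  stopifnot(fragmentCoverage >= 0, fragmentCoverage <= 1,
            cleavageProductProb >= 0, cleavageProductProb <= 1)
  set.seed(seed)
  spectra <- list(); anns <- list()
  scan <- 0L
  addSpectrum <- function(premz, z, rt, mz, inten, speciesId, label,
                          isTrue) {
    scan <<- scan + 1L
    spectra[[scan]] <<- ms2Spectrum(scan, premz, z, rt, mz, inten)
    anns[[scan]] <<- data.frame(scanId = scan, speciesId = speciesId,
                                label = label, isTrue = isTrue,
                                stringsAsFactors = FALSE)
  }
  featOf <- function(speciesId, role) {
    if (is.null(ms1)) return(NULL)
    fid <- ms1$annotations$featureId[
      ms1$annotations$speciesId %in% speciesId &
        ms1$annotations$role == role]
    if (!length(fid)) return(NULL)
    ms1$features[ms1$features$featureId == fid[1], ]
  }
  for (i in seq_along(gt@species)) {
    for (label in c("light", "heavy")) {
      sp <- .withLabel(gt@species[[i]], label)
      M <- speciesPrecursorMass(sp, xl)
      f <- featOf(i, label)
      z <- if (!is.null(f)) f$charge else sample(3:7, 1L)
      rt <- if (!is.null(f)) f$rtApex else stats::runif(1, 10, 100)
      frag <- theoreticalFragmentIons(sp, xl)
      keep <- stats::runif(nrow(frag)) <= fragmentCoverage
      mz <- frag$mz[keep]
      inten <- stats::runif(sum(keep), 1e4, 1e5)
      prod <- theoreticalCleavageProducts(sp, xl, charges = 1L)
      if (nrow(prod)) {
        keepP <- stats::runif(nrow(prod)) <= cleavageProductProb
        mz <- c(mz, prod$mz[keepP])
        inten <- c(inten, stats::runif(sum(keepP), 2e4, 2e5))
      }
      if (noisePeaks > 0L) {
        mz <- c(mz, stats::runif(noisePeaks, 200, 1500))
        inten <- c(inten, stats::runif(noisePeaks, 1e2, 1e3))
      }
      addSpectrum((M + z * PROTON_MASS) / z, z, rt, mz, inten, i, label,
                  TRUE)
    }
  }
  if (nFalseSpectra > 0L) {
    masses <- vapply(gt@species, function(s)
      speciesPrecursorMass(.withLabel(s, "light"), xl), numeric(1))
    for (k in seq_len(nFalseSpectra)) {
      M <- sample(masses, 1L) + stats::runif(1, -0.5, 0.5)
      z <- sample(3:7, 1L)
      nPk <- max(20L, noisePeaks)
      addSpectrum((M + z * PROTON_MASS) / z, z, stats::runif(1, 10, 100),
                  stats::runif(nPk, 200, 1500),
                  stats::runif(nPk, 1e2, 1e4), NA_integer_, "none", FALSE)
    }
  }
  list(spectra = spectra, annotations = do.call(rbind, anns))
}

#' Simulate an annotated PSM feature table with known truth labels
#'
#' Draws a PIN-schema table directly, for calibration studies of the
#' rescorer: true-target PSMs carry signal in the search score and in the
#' crosslinker-specific evidence (cleavage products, partner corroboration,
#' MS1 agreement); false-target PSMs and decoy PSMs are drawn from one
#' common null distribution, making them exchangeable, which is the
#' assumption target-decoy FDR estimation rests on. The logical attribute
#' \code{"isTrue"} records the ground truth.
#'
#' @param nTrue true target PSMs.
#' @param nFalse false target PSMs.
#' @param nDecoy decoy PSMs (defaults to \code{nFalse}).
#' @param seed integer seed.
#' @param scoreSignal mean search-score separation (standard deviations).
#' @return PIN data.frame with attribute \code{isTrue}.
#' @export
simulatePsmFeatures <- function(nTrue = 500L, nFalse = 5000L,
                                nDecoy = nFalse, seed = 1L,
                                scoreSignal = 2.2) {
  set.seed(seed)
  n <- nTrue + nFalse + nDecoy
  isTrue <- c(rep(TRUE, nTrue), rep(FALSE, nFalse + nDecoy))
  isDecoy <- c(rep(FALSE, nTrue + nFalse), rep(TRUE, nDecoy))
  mix <- function(true, null) ifelse(isTrue, true, null)
  score <- mix(stats::rnorm(n, scoreSignal, 1), stats::rnorm(n, 0, 1))
  deltaScore <- mix(abs(stats::rnorm(n, 1, 0.5)),
                    abs(stats::rnorm(n, 0, 0.3)))
  scoreA <- mix(stats::rnorm(n, 1.5, 1), stats::rnorm(n, 0, 1))
  scoreB <- mix(stats::rnorm(n, 1.5, 1), stats::rnorm(n, 0, 1))
  matchedFraction <- mix(stats::rbeta(n, 8, 4), stats::rbeta(n, 2, 8))
  cleavP <- ifelse(isTrue, 0.75, 0.08)
  cleavShortA <- stats::rbinom(n, 1, cleavP)
  cleavLongA <- stats::rbinom(n, 1, cleavP)
  cleavShortB <- stats::rbinom(n, 1, cleavP)
  cleavLongB <- stats::rbinom(n, 1, cleavP)
  nCleav <- cleavShortA + cleavLongA + cleavShortB + cleavLongB
  corro <- stats::rbinom(n, 1, ifelse(isTrue, 0.7, 0.03))
  ms1Missing <- stats::rbinom(n, 1, ifelse(isTrue, 0.1, 0.8))
  hlLog2 <- ifelse(ms1Missing == 1, 0, stats::rnorm(n, 0, 0.5))
  rtDelta <- ifelse(ms1Missing == 1, 0, stats::runif(n, -0.4, 0.05))
  patt <- ifelse(ms1Missing == 1, 0,
                 stats::rbinom(n, 1, ifelse(isTrue, 0.9, 0.2)))
  agree <- ifelse(ms1Missing == 1, 0,
                  stats::rbinom(n, 1, ifelse(isTrue, 0.95, 0.5)))
  charge <- sample(3:6, n, replace = TRUE)
  lenA <- sample(6:25, n, replace = TRUE)
  lenB <- sample(6:25, n, replace = TRUE)
  massErr <- stats::rnorm(n, 0, 3)
  linkType <- sample(c("inter", "intra"), n, replace = TRUE)
  pin <- data.frame(
    SpecId = sprintf("sim%06d", seq_len(n)),
    Label = ifelse(isDecoy, -1L, 1L),
    ScanNr = seq_len(n),
    score = score, deltaScore = deltaScore, scoreA = scoreA,
    scoreB = scoreB, rankA = 1, rankB = 1,
    matchedFraction = matchedFraction, precursorDeconvScore = 0,
    massErrorPpm = massErr, absMassErrorPpm = abs(massErr),
    labelHeavy = stats::rbinom(n, 1, 0.5),
    charge3 = as.numeric(charge == 3), charge4 = as.numeric(charge == 4),
    charge5plus = as.numeric(charge >= 5),
    precursorNeutralMass = stats::runif(n, 1500, 6000),
    lnTIC = log1p(stats::rlnorm(n, 13, 1)),
    basePeakMz = stats::runif(n, 300, 1200),
    lnBasePeakIntensity = log1p(stats::rlnorm(n, 11, 1)),
    lengthA = lenA, lengthB = lenB, totalLength = lenA + lenB,
    lengthDiff = abs(lenA - lenB),
    internalCleavageSitesA = stats::rbinom(n, 2, 0.4),
    internalCleavageSitesB = stats::rbinom(n, 2, 0.4),
    isInter = as.numeric(linkType == "inter"),
    isIntra = as.numeric(linkType == "intra"), isLoop = 0,
    hlLog2Ratio = hlLog2, partnerRtDelta = rtDelta,
    isotopePatternMatch = patt, ms1EvidenceMissing = ms1Missing,
    cleavShortA = cleavShortA, cleavLongA = cleavLongA,
    cleavShortB = cleavShortB, cleavLongB = cleavLongB,
    nCleavageProducts = nCleav,
    lnCleavageIntensity = ifelse(nCleav > 0,
                                 log1p(stats::rlnorm(n, 10, 1)), 0),
    deadendSignature = 0, partnerCorroborated = corro,
    labelAgreement = agree,
    labelAgreementMissing = ms1Missing,
    Peptide = sprintf("PEP%06d(1)--PEP%06d(1)", seq_len(n), seq_len(n)),
    Proteins = ifelse(isDecoy, "DECOY_SYN000;DECOY_SYN001",
                      "SYN000;SYN001"),
    stringsAsFactors = FALSE)
  attr(pin, "isTrue") <- isTrue
  pin
}

#' Write a ground-truth bundle to JSON
#'
#' @param gt a \code{\linkS4class{GroundTruth}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGroundTruthJSON <- function(gt, path) {
  payload <- list(seed = gt@seed,
                  proteins = as.list(gt@proteins),
                  species = gt@speciesTable)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a ground-truth bundle from JSON
#'
#' @param path file written by \code{\link{writeGroundTruthJSON}}.
#' @return a \code{\linkS4class{GroundTruth}}.
#' @export
readGroundTruthJSON <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- payload$species
  species <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    if (r$kind %in% c("inter", "intra"))
      linkSpecies(r$kind, r$seqA, r$siteA, r$protA, r$startA,
                  seqB = r$seqB, siteB = r$siteB, protB = r$protB,
                  startB = r$startB)
    else if (r$kind == "loop")
      linkSpecies("loop", r$seqA, r$siteA, r$protA, r$startA,
                  siteB = r$siteB)
    else
      linkSpecies("deadend", r$seqA, r$siteA, r$protA, r$startA,
                  quench = r$quench)
  })
  new("GroundTruth", proteins = unlist(payload$proteins),
      species = species, speciesTable = tab,
      seed = as.integer(payload$seed))
}
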