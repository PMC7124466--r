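#' Theoretical crosslinker cleavage products of a species
#'
#' CID cleavage of the crosslinker leaves a short- or long-arm remnant on a
#' peptide. Inter/intra links yield 4 complementary products (pepA+short,
#' pepA+long, pepB+short, pepB+long); dead-ends yield the 2-ion signature
#' {pep+short, pep+long}; loop-links yield none (ring opening leaves the
#' precursor mass unchanged). For heavy species each arm is shifted by its
#' configured share of the label sites, so a complementary product pair is
#' shifted by the full label delta.
#'
#' @param species a \code{\linkS4class{LinkSpecies}}.
#' @param xl a \code{\linkS4class{CrosslinkerSpec}}.
#' @param charges charge states for which m/z values are emitted.
#' @return data.frame with columns \code{productId}, \code{neutralMass},
#'   \code{mz}, \code{charge}.
#' @export
theoreticalCleavageProducts <- function(species, xl = crosslinkerSpec(),
                                        charges = 1:3) {
  d1 <- MASS_H2 - MASS_H1
  heavy <- species@label == "heavy"
  armShort <- xl@shortArmMass + if (heavy) xl@armLabelSplit[1] * d1 else 0
  armLong <- xl@longArmMass + if (heavy) xl@armLabelSplit[2] * d1 else 0
  neutrals <- numeric(0); ids <- character(0)
  if (species@kind %in% c("inter", "intra")) {
    mA <- peptideMass(species@seqA); mB <- peptideMass(species@seqB)
    neutrals <- c(mA + armShort, mA + armLong, mB + armShort, mB + armLong)
    ids <- c("A_short", "A_long", "B_short", "B_long")
  } else if (species@kind == "deadend") {
    mA <- peptideMass(species@seqA)
    neutrals <- c(mA + armShort, mA + armLong)
    ids <- c("A_short", "A_long")
  }
  if (!length(neutrals))
    return(data.frame(productId = character(), neutralMass = numeric(),
                      mz = numeric(), charge = integer()))
  out <- do.call(rbind, lapply(charges, function(z) data.frame(
    productId = ids, neutralMass = neutrals,
    mz = (neutrals + z * PROTON_MASS) / z, charge = as.integer(z))))
  rownames(out) <- NULL
  out
}

#' Annotate a spectrum with crosslinker cleavage-product evidence
#'
#' Checks the spectrum for the predicted cleavage-product ions of the
#' assigned species over charge states 1 to precursor charge minus 1
#' (inclusive mass tolerance). Each product is flagged found when any
#' predicted charge state matches, with the maximum matched peak intensity
#' recorded.
#'
#' @param spectrum an \code{\linkS4class{Ms2Spectrum}}.
#' @param species the assigned \code{\linkS4class{LinkSpecies}}.
#' @param xl a \code{\linkS4class{CrosslinkerSpec}}.
#' @param tol fragment tolerance (Da, default 0.02).
#' @param charges charge states searched; default 1 to precursor charge - 1.
#' @return one-row data.frame: \code{cleavShortA}, \code{cleavLongA},
#'   \code{cleavShortB}, \code{cleavLongB} (0/1), matching
#'   \code{int*} intensities, \code{nCleavageProducts},
#'   \code{deadendSignature} (0/1).
#' @export
annotateCleavage <- function(spectrum, species, xl = crosslinkerSpec(),
                             tol = 0.02, charges = NULL) {
  if (is.null(charges))
    charges <- seq_len(max(1L, spectrum@precursorCharge - 1L))
  prod <- theoreticalCleavageProducts(species, xl, charges)
  found <- stats::setNames(numeric(4),
                           c("A_short", "A_long", "B_short", "B_long"))
  inten <- found
  if (nrow(prod) && length(spectrum@mz)) {
    hits <- .countMatches(prod$mz, spectrum@mz, tol)
    for (k in which(hits)) {
      id <- prod$productId[k]
      found[id] <- 1
      near <- which(abs(spectrum@mz - prod$mz[k]) <= tol + 1e-12)
      if (length(near))
        inten[id] <- max(inten[id], max(spectrum@intensity[near]))
    }
  }
  applicable <- if (species@kind %in% c("inter", "intra"))
    c("A_short", "A_long", "B_short", "B_long")
  else if (species@kind == "deadend") c("A_short", "A_long")
  else character(0)
  n <- sum(found[applicable])
  deadendSig <- as.numeric(species@kind == "deadend" &&
                             all(found[c("A_short", "A_long")] == 1))
  data.frame(cleavShortA = found[["A_short"]],
             cleavLongA = found[["A_long"]],
             cleavShortB = found[["B_short"]],
             cleavLongB = found[["B_long"]],
             intShortA = inten[["A_short"]], intLongA = inten[["A_long"]],
             intShortB = inten[["B_short"]], intLongB = inten[["B_long"]],
             nCleavageProducts = n, deadendSignature = deadendSig)
}

.psmSpecies <- function(psm) {
  if (psm$linkType %in% c("inter", "intra"))
    linkSpecies(psm$linkType, psm$seqA, psm$siteA, psm$protA, psm$startA,
                seqB = psm$seqB, siteB = psm$siteB, protB = psm$protB,
                startB = psm$startB, label = psm$label)
  else if (psm$linkType == "loop")
    linkSpecies("loop", psm$seqA, psm$siteA, psm$protA, psm$startA,
                siteB = psm$siteB, label = psm$label)
  else
    linkSpecies("deadend", psm$seqA, psm$siteA, psm$protA, psm$startA,
                label = psm$label,
                quench = if (nzchar(psm$quench)) psm$quench else "hydrolyzed")
}

#' Annotate a PSM table with cleavage-product evidence
#'
#' Runs \code{\link{annotateCleavage}} for every PSM against its spectrum
#' (matched by scan id) and binds the evidence columns to the table.
#'
#' @param psms PSM data.frame.
#' @param spectra list of \code{\linkS4class{Ms2Spectrum}}.
#' @param xl a \code{\linkS4class{CrosslinkerSpec}}.
#' @param tol fragment tolerance (Da).
#' @return annotated PSM data.frame.
#' @export
annotatePsmCleavage <- function(psms, spectra, xl = crosslinkerSpec(),
                                tol = 0.02) {
  scanIds <- vapply(spectra, function(s) s@scanId, integer(1))
  ev <- do.call(rbind, lapply(seq_len(nrow(psms)), function(i) {
    k <- match(psms$scanId[i], scanIds)
    if (is.na(k))
      stop("no spectrum with scan id ", psms$scanId[i])
    annotateCleavage(spectra[[k]], .psmSpecies(psms[i, ]), xl, tol)
  }))
  cbind(psms, ev)
}

#' Predicted isotope envelope for an average peptide of a given mass
#'
#' Poisson approximation to the averagine isotope distribution: the
#' probability of k extra neutrons is \code{dpois(k, lambda)} with
#' \code{lambda = 4.7e-4 * mass}.
#'
#' @param mass neutral monoisotopic mass (Da).
#' @param nPeaks number of isotopologue peaks returned.
#' @return numeric vector of relative intensities summing to < 1.
#' @export
predictIsotopeEnvelope <- function(mass, nPeaks = 5L) {
  stats::dpois(0:(nPeaks - 1L), lambda = 4.7e-4 * mass)
}

.cosineSim <- function(a, b) {
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Attach MS1 multiplet evidence to PSMs
#'
#' Links each PSM to an isotopic-multiplet member when the PSM precursor
#' neutral mass matches the member mass within \code{tolPpm} and the PSM
#' retention time falls inside the member's RT extent (nearest mass wins on
#' ambiguity). Sets the heavy/light intensity ratio and partner RT delta
#' from the multiplet diagnostics, an isotope-pattern-match flag (cosine
#' >= 0.95 between the member's observed envelope, when the feature table
#' provides one, and the averagine prediction; otherwise 0 with its missing
#' indicator raised), the MS1/MS2 label-agreement meta-flag (PSM label vs
#' the member's position in the multiplet), and missing-evidence
#' indicators for unmatched PSMs.
#'
#' @param psms PSM data.frame.
#' @param multiplets list of \code{\linkS4class{IsotopicMultiplet}}.
#' @param tolPpm precursor-to-feature mass tolerance (ppm).
#' @return PSM data.frame with MS1 evidence columns appended.
#' @export
attachMs1Evidence <- function(psms, multiplets, tolPpm = 10) {
  n <- nrow(psms)
  hlLog2Ratio <- numeric(n); partnerRtDelta <- numeric(n)
  isotopePatternMatch <- numeric(n); ms1EvidenceMissing <- rep(1, n)
  labelAgreement <- numeric(n); labelAgreementMissing <- rep(1, n)
  memberPosition <- rep(NA_integer_, n); multipletId <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    mass <- psms$precursorNeutralMass[i]
    rt <- psms$rt[i]
    best <- NULL; bestErr <- Inf
    for (m in seq_along(multiplets)) {
      mem <- multiplets[[m]]@members
      for (k in seq_len(nrow(mem))) {
        err <- abs(mem$monoisotopicMass[k] - mass)
        if (err <= mass * tolPpm * 1e-6 &&
            !is.na(rt) && rt >= mem$rtStart[k] && rt <= mem$rtEnd[k] &&
            err < bestErr) {
          best <- list(m = m, k = k); bestErr <- err
        }
      }
    }
    if (is.null(best)) next
    mp <- multiplets[[best$m]]
    k <- best$k
    dRow <- if (k == 1L) 1L else k - 1L
    hlLog2Ratio[i] <- mp@diagnostics$log2Ratio[dRow]
    partnerRtDelta[i] <- mp@diagnostics$rtDelta[dRow]
    ms1EvidenceMissing[i] <- 0
    env <- mp@members$envelope[k]
    if (!is.null(env) && !is.na(env) && nzchar(env)) {
      obs <- as.numeric(strsplit(env, ";")[[1]])
      pred <- predictIsotopeEnvelope(mp@members$monoisotopicMass[k],
                                     length(obs))
      isotopePatternMatch[i] <- as.numeric(.cosineSim(obs, pred) >= 0.95)
    }
    labelAgreement[i] <- as.numeric(
      (psms$label[i] == "light" && k == 1L) ||
        (psms$label[i] == "heavy" && k > 1L))
    labelAgreementMissing[i] <- 0
    memberPosition[i] <- k; multipletId[i] <- best$m
  }
  cbind(psms, hlLog2Ratio = hlLog2Ratio, partnerRtDelta = partnerRtDelta,
        isotopePatternMatch = isotopePatternMatch,
        ms1EvidenceMissing = ms1EvidenceMissing,
        labelAgreement = labelAgreement,
        labelAgreementMissing = labelAgreementMissing,
        memberPosition = memberPosition, multipletId = multipletId)
}

.psmPairKey <- function(psms) {
  paste(psms$linkType, psms$seqA, psms$siteA, psms$protA,
        psms$seqB, psms$siteB, psms$protB, sep = "|")
}

#' Compute meta-features over a PSM table
#'
#' Adds the partner-corroboration meta-flag: a PSM is corroborated when
#' another PSM exists with the identical peptide pair and linked sites, the
#' opposite label, and a precursor mass differing by the crosslinker label
#' delta within tolerance.
#'
#' @param psms PSM data.frame.
#' @param xl a \code{\linkS4class{CrosslinkerSpec}}.
#' @param tol absolute mass tolerance (Da) on the precursor difference.
#' @return PSM data.frame with a \code{partnerCorroborated} column.
#' @export
computeMetaFeatures <- function(psms, xl = crosslinkerSpec(), tol = 0.02) {
  key <- .psmPairKey(psms)
  corro <- numeric(nrow(psms))
  for (i in seq_len(nrow(psms))) {
    mates <- which(key == key[i] & psms$label != psms$label[i])
    if (!length(mates)) next
    diff <- abs(abs(psms$precursorNeutralMass[mates] -
                      psms$precursorNeutralMass[i]) - xl@labelMassDelta)
    if (any(diff <= tol)) corro[i] <- 1
  }
  cbind(psms, partnerCorroborated = corro)
}

#' Names of the 41 validation feature dimensions, in PIN column order
#'
#' The fixed feature schema written by \code{\link{buildPinTable}}: search
#' scores and ranks, precursor diagnostics, spectrum summary statistics,
#' peptide properties, link-type indicators, MS1 multiplet evidence,
#' crosslinker cleavage-product evidence, meta-features, and
#' missing-evidence indicators.
#'
#' @return character vector of length 41.
#' @export
pinFeatureNames <- function() {
  c("score", "deltaScore", "scoreA", "scoreB", "rankA", "rankB",
    "matchedFraction", "precursorDeconvScore", "massErrorPpm",
    "absMassErrorPpm", "labelHeavy", "charge3", "charge4", "charge5plus",
    "precursorNeutralMass", "lnTIC", "basePeakMz", "lnBasePeakIntensity",
    "lengthA", "lengthB", "totalLength", "lengthDiff",
    "internalCleavageSitesA", "internalCleavageSitesB",
    "isInter", "isIntra", "isLoop",
    "hlLog2Ratio", "partnerRtDelta", "isotopePatternMatch",
    "ms1EvidenceMissing",
    "cleavShortA", "cleavLongA", "cleavShortB", "cleavLongB",
    "nCleavageProducts", "lnCleavageIntensity", "deadendSignature",
    "partnerCorroborated", "labelAgreement", "labelAgreementMissing")
}

.internalKR <- function(seqs) {
  vapply(seqs, function(s) {
    if (!nzchar(s)) return(0)
    res <- strsplit(s, "")[[1]]
    sum(res[-length(res)] %in% c("K", "R"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Build the Percolator input (PIN) table from annotated PSMs
#'
#' Emits the 5 identification columns (\code{SpecId}, \code{Label} = +1
#' target / -1 decoy, \code{ScanNr}, and trailing \code{Peptide},
#' \code{Proteins}) around the fixed 41-dimension feature block
#' (\code{\link{pinFeatureNames}}). Evidence a PSM does not carry is
#' encoded as 0 with its paired missing-evidence indicator set to 1, so the
#' schema is identical whatever evidence is available. Any NaN/NA in a
#' feature is a hard error.
#'
#' @param psms annotated PSM data.frame (output of the annotation chain;
#'   columns that are absent fall back to their missing-evidence defaults).
#' @return PIN data.frame.
#' @export
buildPinTable <- function(psms) {
  n <- nrow(psms)
  col <- function(nm, default) {
    if (nm %in% names(psms)) psms[[nm]] else rep(default, n)
  }
  feat <- data.frame(
    score = psms$score,
    deltaScore = psms$deltaScore,
    scoreA = col("scoreA", 0), scoreB = col("scoreB", 0),
    rankA = as.numeric(col("rankA", 1L)),
    rankB = as.numeric(col("rankB", 1L)),
    matchedFraction = col("matchedFraction", 0),
    precursorDeconvScore = col("precursorDeconvScore", 0),
    massErrorPpm = psms$massErrorPpm,
    absMassErrorPpm = abs(psms$massErrorPpm),
    labelHeavy = as.numeric(psms$label == "heavy"),
    charge3 = as.numeric(psms$precursorCharge == 3L),
    charge4 = as.numeric(psms$precursorCharge == 4L),
    charge5plus = as.numeric(psms$precursorCharge >= 5L),
    precursorNeutralMass = psms$precursorNeutralMass,
    lnTIC = log1p(col("tic", 0)),
    basePeakMz = col("basePeakMz", 0),
    lnBasePeakIntensity = log1p(col("basePeakIntensity", 0)),
    lengthA = nchar(psms$seqA),
    lengthB = nchar(psms$seqB),
    totalLength = nchar(psms$seqA) + nchar(psms$seqB),
    lengthDiff = abs(nchar(psms$seqA) - nchar(psms$seqB)),
    internalCleavageSitesA = .internalKR(psms$seqA),
    internalCleavageSitesB = .internalKR(psms$seqB),
    isInter = as.numeric(psms$linkType == "inter"),
    isIntra = as.numeric(psms$linkType == "intra"),
    isLoop = as.numeric(psms$linkType == "loop"),
    hlLog2Ratio = col("hlLog2Ratio", 0),
    partnerRtDelta = col("partnerRtDelta", 0),
    isotopePatternMatch = col("isotopePatternMatch", 0),
    ms1EvidenceMissing = col("ms1EvidenceMissing", 1),
    cleavShortA = col("cleavShortA", 0),
    cleavLongA = col("cleavLongA", 0),
    cleavShortB = col("cleavShortB", 0),
    cleavLongB = col("cleavLongB", 0),
    nCleavageProducts = col("nCleavageProducts", 0),
    lnCleavageIntensity = log1p(col("intShortA", 0) + col("intLongA", 0) +
                                  col("intShortB", 0) + col("intLongB", 0)),
    deadendSignature = col("deadendSignature", 0),
    partnerCorroborated = col("partnerCorroborated", 0),
    labelAgreement = col("labelAgreement", 0),
    labelAgreementMissing = col("labelAgreementMissing", 1))
  stopifnot(identical(names(feat), pinFeatureNames()))
  bad <- vapply(feat, function(x) any(!is.finite(x)), logical(1))
  if (any(bad))
    stop("non-finite feature value(s) in: ",
         paste(names(feat)[bad], collapse = ", "),
         " (encoding bug: missing evidence must be 0 + indicator)")
  pep <- ifelse(nzchar(psms$seqB),
                sprintf("%s(%d)--%s(%d)", psms$seqA, psms$siteA,
                        psms$seqB, psms$siteB),
                ifelse(psms$linkType == "loop",
                       sprintf("%s(%d,%d)", psms$seqA, psms$siteA,
                               psms$siteB),
                       sprintf("%s(%d)", psms$seqA, psms$siteA)))
  prots <- ifelse(nzchar(psms$protB),
                  paste(psms$protA, psms$protB, sep = ";"), psms$protA)
  cbind(data.frame(SpecId = psms$specId,
                   Label = ifelse(psms$isDecoy, -1L, 1L),
                   ScanNr = psms$scanId, stringsAsFactors = FALSE),
        feat,
        data.frame(Peptide = pep, Proteins = prots,
                   stringsAsFactors = FALSE))
}

#' Write a PIN table (tab-separated, header first)
#'
#' @param pin PIN data.frame from \code{\link{buildPinTable}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePin <- function(pin, path) {
  utils::write.table(pin, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a PIN table written by \code{\link{writePin}}
#'
#' @param path PIN file.
#' @return PIN data.frame.
#' @export
readPin <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
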