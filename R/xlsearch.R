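#' Build a searchable peptide index from a protein database
#'
#' Digests every protein (tryptic, up to \code{maxMissed} missed cleavages),
#' computes monoisotopic masses, flags decoy entries by accession prefix,
#' and annotates crosslinker-reactive sites: positions of reactive residues
#' (K by default) plus position 1 of protein N-terminal peptides.
#'
#' @param db named character vector of protein sequences (targets +
#'   decoys), or a FASTA path.
#' @param xl a \code{\linkS4class{CrosslinkerSpec}}.
#' @param maxMissed maximum missed cleavages (default 3).
#' @param prolineRule tryptic proline rule flag (default TRUE).
#' @param minLength,maxLength peptide length bounds retained in the index.
#' @param decoyPrefix decoy accession prefix.
#' @return data.frame with columns \code{sequence}, \code{proteinId},
#'   \code{startPos}, \code{missedCleavages}, \code{mass}, \code{isDecoy},
#'   and a list-column \code{reactiveSites}.
#' @export
buildPeptideIndex <- function(db, xl = crosslinkerSpec(), maxMissed = 3L,
                              prolineRule = TRUE, minLength = 4L,
                              maxLength = 40L, decoyPrefix = "DECOY_") {
  if (is.character(db) && length(db) == 1L && file.exists(db))
    db <- readFastaProteins(db)
  if (length(db) == 0L)
    return(data.frame(sequence = character(), proteinId = character(),
                      startPos = integer(), missedCleavages = integer(),
                      mass = numeric(), isDecoy = logical(),
                      reactiveSites = I(list())))
  peps <- do.call(rbind, lapply(names(db), function(acc)
    digestTryptic(db[[acc]], maxMissed = maxMissed,
                  prolineRule = prolineRule, proteinId = acc)))
  len <- nchar(peps$sequence)
  peps <- peps[len >= minLength & len <= maxLength, , drop = FALSE]
  # one protein context per distinct peptide occurrence; drop exact dupes
  key <- paste(peps$sequence, peps$proteinId, peps$startPos)
  peps <- peps[!duplicated(key), , drop = FALSE]
  peps$mass <- vapply(peps$sequence, peptideMass, numeric(1), USE.NAMES = FALSE)
  peps$isDecoy <- isDecoyAccession(peps$proteinId, decoyPrefix)
  peps$reactiveSites <- lapply(seq_len(nrow(peps)), function(i) {
    res <- strsplit(peps$sequence[i], "")[[1]]
    sites <- which(res %in% xl@reactiveResidues)
    if (peps$startPos[i] == 1L) sites <- union(1L, sites)
    sort(as.integer(sites))
  })
  rownames(peps) <- NULL
  peps
}

.canonicalPair <- function(i, j, index) {
  ki <- paste(index$sequence[i], index$proteinId[i], index$startPos[i])
  kj <- paste(index$sequence[j], index$proteinId[j], index$startPos[j])
  if (ki <= kj) c(i, j) else c(j, i)
}

#' Enumerate crosslinked-species candidates for a precursor mass
#'
#' Returns every inter/intra pair, loop, and dead-end species (light and
#' heavy, all reactive-site placements) whose neutral precursor mass matches
#' the query within the ppm tolerance. Unordered peptide pairs are emitted
#' once, in canonical order.
#'
#' @param precursorMass neutral precursor mass (Da).
#' @param index peptide index from \code{\link{buildPeptideIndex}}.
#' @param xl a \code{\linkS4class{CrosslinkerSpec}}.
#' @param tolPpm precursor tolerance (parts per million, default 10).
#' @return list of \code{\linkS4class{LinkSpecies}}.
#' @export
enumerateCandidates <- function(precursorMass, index, xl = crosslinkerSpec(),
                                tolPpm = 10) {
  out <- list()
  if (!nrow(index)) return(out)
  tol <- precursorMass * tolPpm * 1e-6
  nSites <- vapply(index$reactiveSites, length, integer(1))
  ord <- order(index$mass)
  masses <- index$mass[ord]
  emit <- function(sp) out[[length(out) + 1L]] <<- sp
  mkPep <- function(i) list(seq = index$sequence[i],
                            prot = index$proteinId[i],
                            start = index$startPos[i])
  for (label in c("light", "heavy")) {
    offset <- xl@spacerMassLight +
      if (label == "heavy") xl@labelMassDelta else 0
    # dead-ends
    for (q in names(xl@deadendMasses)) {
      target <- precursorMass - offset - xl@deadendMasses[[q]]
      lo <- findInterval(target - tol, masses) + 1L
      hi <- findInterval(target + tol, masses)
      if (hi >= lo) for (k in lo:hi) {
        i <- ord[k]
        if (nSites[i] == 0L) next
        for (s in index$reactiveSites[[i]]) {
          p <- mkPep(i)
          emit(linkSpecies("deadend", p$seq, s, p$prot, p$start,
                           label = label, quench = q))
        }
      }
    }
    # loops
    target <- precursorMass - offset
    lo <- findInterval(target - tol, masses) + 1L
    hi <- findInterval(target + tol, masses)
    if (hi >= lo) for (k in lo:hi) {
      i <- ord[k]
      sites <- index$reactiveSites[[i]]
      if (length(sites) < 2L) next
      p <- mkPep(i)
      for (a in seq_len(length(sites) - 1L))
        for (b in (a + 1L):length(sites))
          emit(linkSpecies("loop", p$seq, sites[a], p$prot, p$start,
                           siteB = sites[b], label = label))
    }
    # inter/intra pairs (two-pointer on the sorted mass array)
    for (k1 in seq_along(ord)) {
      i <- ord[k1]
      if (nSites[i] == 0L) next
      rest <- target - masses[k1]
      if (rest < masses[k1] - tol - 1e-9) break
      lo2 <- max(k1, findInterval(rest - tol, masses) + 1L)
      hi2 <- findInterval(rest + tol, masses)
      if (hi2 < lo2) next
      for (k2 in lo2:hi2) {
        j <- ord[k2]
        if (nSites[j] == 0L) next
        if (k2 == k1 && FALSE) next
        pr <- .canonicalPair(i, j, index)
        if (k2 > k1 || i == j) {
          a <- pr[1]; b <- pr[2]
          pa <- mkPep(a); pb <- mkPep(b)
          kind <- if (pa$prot == pb$prot) "intra" else "inter"
          for (sa in index$reactiveSites[[a]])
            for (sb in index$reactiveSites[[b]])
              emit(linkSpecies(kind, pa$seq, sa, pa$prot, pa$start,
                               seqB = pb$seq, siteB = sb, protB = pb$prot,
                               startB = pb$start, label = label))
        }
      }
    }
  }
  out
}

#' Theoretical singly charged b/y fragment ions of a crosslinked species
#'
#' For inter/intra links the partner peptide plus the (label-adjusted)
#' spacer is treated as a fixed mass on the linked residue of each peptide.
#' For loop-links, fragments that would cleave inside the bridged region do
#' not exist and are omitted; fragments containing both sites carry the full
#' spacer. Dead-ends carry spacer + quench adduct at the linked site.
#'
#' @param species a \code{\linkS4class{LinkSpecies}}.
#' @param xl a \code{\linkS4class{CrosslinkerSpec}}.
#' @return data.frame with columns \code{peptide} ("A"/"B"), \code{ion}
#'   (e.g. "b3", "y5"), \code{mz} (singly charged).
#' @export
theoreticalFragmentIons <- function(species, xl = crosslinkerSpec()) {
  delta <- if (species@label == "heavy") xl@labelMassDelta else 0
  ionSeries <- function(seq, modMass, site, site2 = NA_integer_) {
    res <- strsplit(seq, "")[[1]]
    n <- length(res)
    if (n < 2L)
      return(data.frame(ion = character(), mz = numeric()))
    m <- RESIDUE_MASSES[res]
    pre <- cumsum(m)
    i <- seq_len(n - 1L)
    firstPos <- n - i + 1L  # first residue position covered by y_i
    if (is.na(site2)) {
      bmz <- pre[i] + PROTON_MASS + ifelse(i >= site, modMass, 0)
      ymz <- (pre[n] - pre[n - i]) + WATER_MASS + PROTON_MASS +
        ifelse(site >= firstPos, modMass, 0)
      bKeep <- rep(TRUE, n - 1L)
      yKeep <- rep(TRUE, n - 1L)
    } else {
      # loop-link: fragments cleaving inside the bridged region do not
      # exist; fragments containing both sites carry the full spacer
      bKeep <- !(i >= site & i < site2)
      bmz <- pre[i] + PROTON_MASS + ifelse(i >= site2, modMass, 0)
      yKeep <- !(site < firstPos & firstPos <= site2)
      ymz <- (pre[n] - pre[n - i]) + WATER_MASS + PROTON_MASS +
        ifelse(site >= firstPos, modMass, 0)
    }
    data.frame(
      ion = c(paste0("b", i[bKeep], recycle0 = TRUE),
              paste0("y", i[yKeep], recycle0 = TRUE)),
      mz = unname(c(bmz[bKeep], ymz[yKeep])))
  }
  if (species@kind %in% c("inter", "intra")) {
    modA <- peptideMass(species@seqB) + xl@spacerMassLight + delta
    modB <- peptideMass(species@seqA) + xl@spacerMassLight + delta
    a <- ionSeries(species@seqA, modA, species@siteA)
    b <- ionSeries(species@seqB, modB, species@siteB)
    out <- rbind(
      if (nrow(a)) cbind(peptide = "A", a),
      if (nrow(b)) cbind(peptide = "B", b))
  } else if (species@kind == "loop") {
    a <- ionSeries(species@seqA, xl@spacerMassLight + delta,
                   species@siteA, species@siteB)
    out <- if (nrow(a)) cbind(peptide = "A", a) else
      data.frame(peptide = character(), ion = character(), mz = numeric())
  } else {
    mod <- xl@spacerMassLight + xl@deadendMasses[[species@quench]] + delta
    a <- ionSeries(species@seqA, mod, species@siteA)
    out <- if (nrow(a)) cbind(peptide = "A", a) else
      data.frame(peptide = character(), ion = character(), mz = numeric())
  }
  if (is.null(out))
    out <- data.frame(peptide = character(), ion = character(),
                      mz = numeric())
  rownames(out) <- NULL
  out
}

.countMatches <- function(theoMz, obsMz, fragTol) {
  if (!length(theoMz) || !length(obsMz)) return(logical(length(theoMz)))
  idx <- findInterval(theoMz, obsMz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(obsMz))
  abs(obsMz[lo] - theoMz) <= fragTol + 1e-12 |
    abs(obsMz[hi] - theoMz) <= fragTol + 1e-12
}

#' Score a candidate species against an MS2 spectrum
#'
#' Matches the theoretical singly charged b/y ions of the candidate against
#' the observed peaks (inclusive tolerance) and scores the match count with
#' the negative log10 of a binomial tail: under the null, each theoretical
#' ion matches a random peak with probability \code{p = n_peaks * 2 * tol /
#' span}. A spectrum matching no ions scores 0.
#'
#' @param spectrum an \code{\linkS4class{Ms2Spectrum}}.
#' @param species candidate \code{\linkS4class{LinkSpecies}}.
#' @param xl a \code{\linkS4class{CrosslinkerSpec}}.
#' @param fragTol fragment tolerance (Da, default 0.02).
#' @return list: \code{score}, \code{matchedFraction}, \code{scoreA},
#'   \code{scoreB}, \code{nTheoretical}, \code{nMatched}.
#' @export
scoreSpectrumMatch <- function(spectrum, species, xl = crosslinkerSpec(),
                               fragTol = 0.02) {
  ions <- theoreticalFragmentIons(species, xl)
  nT <- nrow(ions)
  if (nT == 0L)
    return(list(score = 0, matchedFraction = 0, scoreA = 0, scoreB = 0,
                nTheoretical = 0L, nMatched = 0L))
  hits <- .countMatches(ions$mz, spectrum@mz, fragTol)
  span <- if (length(spectrum@mz) >= 2L)
    max(spectrum@mz) - min(spectrum@mz) else 0
  p <- if (span > 0) min(0.99, length(spectrum@mz) * 2 * fragTol / span)
  else 0.01
  tailScore <- function(k, n) {
    if (k == 0L || n == 0L) return(0)
    min(300, -stats::pbinom(k - 1L, n, p, lower.tail = FALSE,
                            log.p = TRUE) / log(10))
  }
  kA <- sum(hits[ions$peptide == "A"]); nA <- sum(ions$peptide == "A")
  kB <- sum(hits[ions$peptide == "B"]); nB <- sum(ions$peptide == "B")
  list(score = tailScore(sum(hits), nT),
       matchedFraction = sum(hits) / nT,
       scoreA = tailScore(kA, nA), scoreB = tailScore(kB, nB),
       nTheoretical = nT, nMatched = as.integer(sum(hits)))
}

.speciesKey <- function(s) {
  paste(s@kind, s@label, s@seqA, s@siteA, s@protA, s@startA,
        s@seqB, s@siteB, s@protB, s@startB, s@quench, sep = "|")
}

.psmLinkType <- function(kind) {
  if (kind == "deadend") "single" else kind
}

#' Search MS2 spectra for crosslinked peptide-spectrum matches
#'
#' For each spectrum with precursor charge in \code{chargeRange} (+3 to +7
#' by default), candidate species are enumerated at the precursor tolerance,
#' scored, and the best-scoring candidate retained with the score gap to the
#' runner-up. Ties at rank 1 are broken by higher matched fraction, then by
#' a lexicographic species key. Spectra with no candidates are omitted and
#' counted in the \code{"searchLog"} attribute of the result.
#'
#' @param spectra list of \code{\linkS4class{Ms2Spectrum}}.
#' @param index peptide index (targets + decoys) from
#'   \code{\link{buildPeptideIndex}}.
#' @param xl a \code{\linkS4class{CrosslinkerSpec}}.
#' @param tolPpm precursor tolerance (ppm).
#' @param fragTol fragment tolerance (Da).
#' @param chargeRange precursor charges searched.
#' @return PSM data.frame (one row per assigned spectrum) with
#'   identification, score, and decoy columns; attribute \code{searchLog}
#'   records skipped-spectrum counts.
#' @export
searchDataset <- function(spectra, index, xl = crosslinkerSpec(),
                          tolPpm = 10, fragTol = 0.02, chargeRange = 3:7) {
  rows <- list()
  nNoCand <- 0L; nBadCharge <- 0L
  for (sp in spectra) {
    if (!(sp@precursorCharge %in% chargeRange)) {
      nBadCharge <- nBadCharge + 1L
      next
    }
    neutral <- precursorNeutralMass(sp)
    cands <- enumerateCandidates(neutral, index, xl, tolPpm)
    if (!length(cands)) {
      nNoCand <- nNoCand + 1L
      next
    }
    scored <- lapply(cands, scoreSpectrumMatch, spectrum = sp, xl = xl,
                     fragTol = fragTol)
    sc <- vapply(scored, `[[`, numeric(1), "score")
    mf <- vapply(scored, `[[`, numeric(1), "matchedFraction")
    keys <- vapply(cands, .speciesKey, character(1))
    o <- order(-sc, -mf, keys)
    best <- o[1]
    s <- cands[[best]]
    theo <- speciesPrecursorMass(s, xl)
    rows[[length(rows) + 1L]] <- data.frame(
      specId = sprintf("scan%d", sp@scanId),
      scanId = sp@scanId, rt = sp@rt,
      precursorMz = sp@precursorMz, precursorCharge = sp@precursorCharge,
      precursorNeutralMass = neutral, theoreticalMass = theo,
      massErrorPpm = (neutral - theo) / theo * 1e6,
      linkType = .psmLinkType(s@kind), label = s@label,
      seqA = s@seqA, protA = s@protA, startA = s@startA, siteA = s@siteA,
      seqB = s@seqB, protB = s@protB, startB = s@startB, siteB = s@siteB,
      quench = if (s@kind == "deadend") s@quench else "",
      score = sc[best],
      deltaScore = if (length(o) > 1L) sc[best] - sc[o[2]] else sc[best],
      scoreA = scored[[best]]$scoreA, scoreB = scored[[best]]$scoreB,
      rankA = 1L, rankB = 1L,
      matchedFraction = mf[best], nCandidates = length(cands),
      tic = sp@tic, basePeakMz = sp@basePeakMz,
      basePeakIntensity = sp@basePeakIntensity,
      isDecoyA = isDecoyAccession(s@protA),
      isDecoyB = nzchar(s@protB) && isDecoyAccession(s@protB),
      stringsAsFactors = FALSE)
  }
  psms <- if (length(rows)) do.call(rbind, rows) else .emptyPsmFrame()
  psms$isDecoy <- psms$isDecoyA | psms$isDecoyB
  attr(psms, "searchLog") <- list(nSpectra = length(spectra),
                                  nAssigned = nrow(psms),
                                  nNoCandidates = nNoCand,
                                  nChargeExcluded = nBadCharge)
  psms
}

.emptyPsmFrame <- function() {
  data.frame(specId = character(), scanId = integer(), rt = numeric(),
             precursorMz = numeric(), precursorCharge = integer(),
             precursorNeutralMass = numeric(), theoreticalMass = numeric(),
             massErrorPpm = numeric(), linkType = character(),
             label = character(), seqA = character(), protA = character(),
             startA = integer(), siteA = integer(), seqB = character(),
             protB = character(), startB = integer(), siteB = integer(),
             quench = character(), score = numeric(),
             deltaScore = numeric(), scoreA = numeric(), scoreB = numeric(),
             rankA = integer(), rankB = integer(),
             matchedFraction = numeric(), nCandidates = integer(),
             tic = numeric(), basePeakMz = numeric(),
             basePeakIntensity = numeric(), isDecoyA = logical(),
             isDecoyB = logical(), stringsAsFactors = FALSE)
}

.kojakAliases <- list(
  scanId = c("Scan Number", "ScanNr", "scannr"),
  rt = c("Ret Time", "RTime", "rt"),
  precursorNeutralMass = c("Obs Mass", "ObsMass"),
  precursorCharge = c("Charge", "charge"),
  theoreticalMass = c("PSM Mass", "PSMMass"),
  massErrorPpm = c("PPM Error", "ppmError"),
  score = c("Score", "score"),
  deltaScore = c("dScore", "deltaScore"),
  seqA = c("Peptide #1", "Peptide1"),
  siteA = c("Link #1", "Link1"),
  protA = c("Protein #1", "Protein1"),
  seqB = c("Peptide #2", "Peptide2"),
  siteB = c("Link #2", "Link2"),
  protB = c("Protein #2", "Protein2"),
  linkerMass = c("Linker Mass", "LinkerMass"))

#' Import a Kojak-style crosslink search result table
#'
#' Reads a Kojak 1.5.x-style tab-separated results file and maps it onto
#' the package's PSM schema. Peptide strings are stripped of modification
#' annotations; link type is derived from the peptide/link columns; the
#' light/heavy label is assigned by whichever form of the crosslinker mass
#' is closer to the reported linker mass. Diagnostic columns that the file
#' does not carry are filled with absent-value defaults so downstream
#' feature building keeps a fixed schema.
#'
#' @param path Kojak results file (TSV; a leading "Kojak version" banner
#'   line is skipped automatically).
#' @param xl a \code{\linkS4class{CrosslinkerSpec}}.
#' @param columnMap optional named list overriding the built-in header
#'   aliases.
#' @return PSM data.frame in the \code{\link{searchDataset}} schema.
#' @export
readKojak <- function(path, xl = crosslinkerSpec(), columnMap = NULL) {
  first <- readLines(path, n = 1L)
  skip <- if (grepl("Kojak", first, ignore.case = TRUE) &&
              !grepl("\t", first)) 1L else 0L
  raw <- utils::read.delim(path, skip = skip, check.names = FALSE,
                           stringsAsFactors = FALSE)
  aliases <- .kojakAliases
  for (nm in names(columnMap)) aliases[[nm]] <- columnMap[[nm]]
  pick <- function(nm, default) {
    hit <- intersect(aliases[[nm]], names(raw))
    if (length(hit)) raw[[hit[1]]] else rep(default, nrow(raw))
  }
  stripMods <- function(x)
    gsub("[^A-Z]", "", toupper(gsub("\\[[^]]*\\]", "", x)))
  seqA <- stripMods(pick("seqA", ""))
  seqBraw <- pick("seqB", "-")
  seqB <- ifelse(seqBraw %in% c("-", ""), "", stripMods(seqBraw))
  siteA <- suppressWarnings(as.integer(pick("siteA", NA)))
  siteBraw <- pick("siteB", NA)
  siteB <- suppressWarnings(as.integer(ifelse(siteBraw %in% c("-", ""),
                                              NA, siteBraw)))
  protA <- vapply(strsplit(as.character(pick("protA", "")), ";"),
                  function(x) trimws(x[1]), character(1))
  protBraw <- as.character(pick("protB", "-"))
  protB <- ifelse(protBraw %in% c("-", ""), "",
                  vapply(strsplit(protBraw, ";"),
                         function(x) trimws(x[1]), character(1)))
  linkerMass <- suppressWarnings(as.numeric(pick("linkerMass", NA)))
  heavyDist <- abs(linkerMass - (xl@spacerMassLight + xl@labelMassDelta))
  lightDist <- abs(linkerMass - xl@spacerMassLight)
  label <- ifelse(!is.na(linkerMass) & heavyDist < lightDist,
                  "heavy", "light")
  linkType <- ifelse(nzchar(seqB),
                     ifelse(protA == protB, "intra", "inter"),
                     ifelse(!is.na(siteB), "loop", "single"))
  out <- data.frame(
    specId = sprintf("scan%d", as.integer(pick("scanId", NA))),
    scanId = as.integer(pick("scanId", NA)),
    rt = as.numeric(pick("rt", NA)),
    precursorMz = NA_real_,
    precursorCharge = as.integer(pick("precursorCharge", NA)),
    precursorNeutralMass = as.numeric(pick("precursorNeutralMass", NA)),
    theoreticalMass = as.numeric(pick("theoreticalMass", NA)),
    massErrorPpm = as.numeric(pick("massErrorPpm", NA)),
    linkType = linkType, label = label,
    seqA = seqA, protA = protA, startA = NA_integer_, siteA = siteA,
    seqB = seqB, protB = protB, startB = NA_integer_, siteB = siteB,
    quench = "", score = as.numeric(pick("score", 0)),
    deltaScore = as.numeric(pick("deltaScore", 0)),
    scoreA = 0, scoreB = 0, rankA = 1L, rankB = 1L,
    matchedFraction = 0, nCandidates = NA_integer_,
    tic = 0, basePeakMz = 0, basePeakIntensity = 0,
    isDecoyA = isDecoyAccession(protA),
    isDecoyB = nzchar(protB) & isDecoyAccession(protB),
    stringsAsFactors = FALSE)
  out$isDecoy <- out$isDecoyA | out$isDecoyB
  out
}

#' Write a PSM table as TSV
#'
#' @param psms PSM data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePsmTable <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
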