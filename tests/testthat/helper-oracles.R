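# Independent brute-force oracles, kept free of the implementation paths
# they check.

# exhaustive O(n^2) enumeration of accepted light/heavy pairs, computing
# every criterion directly from the definitions
exhaustivePairOracle <- function(features, criteria = pairCriteria()) {
  n <- nrow(features)
  m <- features$monoisotopicMass
  z <- features$charge
  rt <- features$rtApex
  si <- features$summedIntensity
  mx <- features$maxIntensity
  out <- list()
  for (i in seq_len(n)) {
    ok <- z == z[i]
    dm <- m - m[i] - criteria@delta
    ok <- ok & abs(dm) <= criteria@deltaTol
    rtd <- rt - rt[i]
    ok <- ok & rtd >= criteria@rtWindow[1] & rtd <= criteria@rtWindow[2]
    if (criteria@mode == "acquisition") {
      l2 <- suppressWarnings(log2(si / si[i]))
      ok <- ok & si > 0 & si[i] > 0 & is.finite(l2) &
        abs(l2) <= criteria@maxAbsLog2Ratio &
        mx >= criteria@minMaxIntensity & mx[i] >= criteria@minMaxIntensity
    } else {
      rel <- abs(si - si[i]) / ((si + si[i]) / 2)
      ok <- ok & (si + si[i]) > 0 & rel <= criteria@relativeIntensityTol
    }
    ok[i] <- FALSE
    js <- which(ok)
    if (length(js))
      out[[length(out) + 1L]] <- data.frame(light = i, heavy = js)
  }
  if (!length(out))
    return(data.frame(light = integer(), heavy = integer()))
  do.call(rbind, out)
}

pairKeySet <- function(pairs) {
  sort(paste(pairs$light, pairs$heavy))
}

# exhaustive candidate enumeration: every species whose precursor mass
# matches, built from first principles
exhaustiveCandidateOracle <- function(precursorMass, index, xl, tolPpm) {
  tol <- precursorMass * tolPpm * 1e-6
  keys <- character()
  nSites <- vapply(index$reactiveSites, length, integer(1))
  for (label in c("light", "heavy")) {
    offset <- xl@spacerMassLight +
      if (label == "heavy") xl@labelMassDelta else 0
    for (q in names(xl@deadendMasses)) {
      for (i in seq_len(nrow(index))) {
        if (nSites[i] == 0L) next
        if (abs(index$mass[i] + offset + xl@deadendMasses[[q]] -
                precursorMass) <= tol)
          for (s in index$reactiveSites[[i]])
            keys <- c(keys, paste("deadend", label, index$sequence[i],
                                  s, q))
      }
    }
    for (i in seq_len(nrow(index))) {
      if (nSites[i] < 2L) next
      if (abs(index$mass[i] + offset - precursorMass) <= tol) {
        ss <- index$reactiveSites[[i]]
        for (a in seq_len(length(ss) - 1L))
          for (b in (a + 1L):length(ss))
            keys <- c(keys, paste("loop", label, index$sequence[i],
                                  ss[a], ss[b]))
      }
    }
    for (i in seq_len(nrow(index))) {
      if (nSites[i] == 0L) next
      for (j in i:nrow(index)) {
        if (nSites[j] == 0L) next
        if (abs(index$mass[i] + index$mass[j] + offset -
                precursorMass) > tol) next
        ki <- paste(index$sequence[i], index$proteinId[i],
                    index$startPos[i])
        kj <- paste(index$sequence[j], index$proteinId[j],
                    index$startPos[j])
        a <- if (ki <= kj) i else j
        b <- if (ki <= kj) j else i
        for (sa in index$reactiveSites[[a]])
          for (sb in index$reactiveSites[[b]])
            keys <- c(keys, paste("pair", label, index$sequence[a], sa,
                                  index$proteinId[a], index$startPos[a],
                                  index$sequence[b], sb,
                                  index$proteinId[b], index$startPos[b]))
      }
    }
  }
  sort(unique(keys))
}

candidateKey <- function(sp) {
  if (sp@kind %in% c("inter", "intra"))
    paste("pair", sp@label, sp@seqA, sp@siteA, sp@protA, sp@startA,
          sp@seqB, sp@siteB, sp@protB, sp@startB)
  else if (sp@kind == "loop")
    paste("loop", sp@label, sp@seqA, sp@siteA, sp@siteB)
  else
    paste("deadend", sp@label, sp@seqA, sp@siteA, sp@quench)
}

# brute-force tryptic peptide enumeration over all substrings
exhaustiveDigestOracle <- function(sequence, maxMissed, prolineRule) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  isSite <- vapply(seq_len(n - 1L), function(i)
    res[i] %in% c("K", "R") && (!prolineRule || res[i + 1L] != "P"),
    logical(1))
  peps <- character()
  for (i in seq_len(n)) for (j in i:n) {
    startOk <- i == 1L || isSite[i - 1L]
    endOk <- j == n || isSite[j]
    if (!startOk || !endOk) next
    internal <- if (j > i) sum(isSite[i:(j - 1L)]) else 0L
    if (internal <= maxMissed)
      peps <- c(peps, paste0(paste(res[i:j], collapse = ""), "@", i))
  }
  sort(peps)
}
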