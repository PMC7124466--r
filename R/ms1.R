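#' Construct MS1 pairing criteria
#'
#' Two presets are provided. \code{"acquisition"} reproduces the criteria
#' used when evaluating doublet detection on instrument data: mass delta
#' 8.0502 +/- 0.01 Da, heavy-light apex RT offset in [-0.4, 0.05] min,
#' |log2(heavy/light summed intensity)| <= 2, and both maximum intensities
#' >= 25000 counts. \code{"pipeline"} keeps the mass and RT tolerances but
#' bounds the relative summed-intensity difference (20%) instead of the
#' log2-ratio/intensity-floor pair. All boundaries are inclusive.
#'
#' @param preset \code{"acquisition"} (default) or \code{"pipeline"}.
#' @param delta,deltaTol expected mass difference and tolerance (Da).
#' @param rtWindow numeric(2) heavy-light apex RT window (minutes).
#' @param maxAbsLog2Ratio log2 summed-intensity ratio bound.
#' @param minMaxIntensity per-feature maximum-intensity floor (counts).
#' @param relativeIntensityTol relative intensity difference bound
#'   (\code{"pipeline"} mode).
#' @return a \code{\linkS4class{PairCriteria}}.
#' @export
pairCriteria <- function(preset = c("acquisition", "pipeline"),
                         delta = isotopicMassDelta(8), deltaTol = 0.01,
                         rtWindow = c(-0.4, 0.05), maxAbsLog2Ratio = 2,
                         minMaxIntensity = 25000,
                         relativeIntensityTol = 0.20) {
  preset <- match.arg(preset)
  new("PairCriteria", delta = delta, deltaTol = deltaTol,
      rtWindow = rtWindow, maxAbsLog2Ratio = maxAbsLog2Ratio,
      minMaxIntensity = minMaxIntensity,
      relativeIntensityTol = relativeIntensityTol, mode = preset)
}

.featureCols <- c("monoisotopicMass", "charge", "rtApex", "rtStart", "rtEnd",
                  "summedIntensity", "maxIntensity")

.checkFeatureFrame <- function(features) {
  miss <- setdiff(.featureCols, names(features))
  if (length(miss))
    stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  invisible(features)
}

#' Classify a candidate light/heavy MS1 feature pair
#'
#' Applies every pairing criterion (see \code{\link{pairCriteria}}) to an
#' ordered (light, heavy) pair of deconvoluted features and returns the
#' verdict together with per-criterion diagnostics. A zero summed intensity
#' yields a rejection with a diagnostic, not an error. Both features must
#' share one charge state.
#'
#' @param light,heavy one-row data.frames or named lists with the standard
#'   feature fields (\code{monoisotopicMass}, \code{charge}, \code{rtApex},
#'   \code{summedIntensity}, \code{maxIntensity}).
#' @param criteria a \code{\linkS4class{PairCriteria}}.
#' @return list with \code{accepted} (flag) and \code{diagnostics} (list:
#'   \code{massDelta}, \code{massError}, \code{rtDelta}, \code{log2Ratio},
#'   \code{relativeIntensityDiff}, \code{failed} character vector of the
#'   criteria that failed).
#' @export
classifyPair <- function(light, heavy, criteria = pairCriteria()) {
  if (light$charge != heavy$charge)
    stop("light and heavy features must share one charge state")
  massDelta <- heavy$monoisotopicMass - light$monoisotopicMass
  massError <- massDelta - criteria@delta
  rtDelta <- heavy$rtApex - light$rtApex
  l2 <- if (light$summedIntensity > 0 && heavy$summedIntensity > 0)
    log2(heavy$summedIntensity / light$summedIntensity) else Inf
  rel <- {
    mn <- (light$summedIntensity + heavy$summedIntensity) / 2
    if (mn > 0) abs(heavy$summedIntensity - light$summedIntensity) / mn
    else Inf
  }
  eps <- 1e-9   # keep inclusive boundaries inclusive under rounding
  failed <- character()
  if (abs(massError) > criteria@deltaTol + eps)
    failed <- c(failed, "massDelta")
  if (rtDelta < criteria@rtWindow[1] - eps ||
      rtDelta > criteria@rtWindow[2] + eps)
    failed <- c(failed, "rtWindow")
  if (criteria@mode == "acquisition") {
    if (!is.finite(l2) || abs(l2) > criteria@maxAbsLog2Ratio + eps)
      failed <- c(failed, "log2Ratio")
    if (light$maxIntensity < criteria@minMaxIntensity ||
        heavy$maxIntensity < criteria@minMaxIntensity)
      failed <- c(failed, "minIntensity")
  } else {
    if (!is.finite(rel) || rel > criteria@relativeIntensityTol + eps)
      failed <- c(failed, "relativeIntensity")
  }
  list(accepted = length(failed) == 0L,
       diagnostics = list(massDelta = massDelta, massError = massError,
                          rtDelta = rtDelta, log2Ratio = l2,
                          relativeIntensityDiff = rel, failed = failed))
}

#' Find all accepted light/heavy feature pairs
#'
#' Enumerates every ordered pair of equal-charge features whose mass
#' difference lies in the pairing window and applies the full pairing
#' criteria. This is the pair relation that \code{\link{pairMultiplets}}
#' resolves into disjoint multiplets.
#'
#' @param features feature data.frame (see \code{\link{readKronik}}).
#' @param criteria a \code{\linkS4class{PairCriteria}}.
#' @return data.frame with columns \code{light}, \code{heavy} (row indices
#'   into \code{features}), \code{massError}, \code{rtDelta},
#'   \code{log2Ratio}.
#' @export
findDoubletPairs <- function(features, criteria = pairCriteria()) {
  .checkFeatureFrame(features)
  empty <- data.frame(light = integer(), heavy = integer(),
                      massError = numeric(), rtDelta = numeric(),
                      log2Ratio = numeric())
  n <- nrow(features)
  if (n < 2L) return(empty)
  out <- vector("list", 0L)
  for (z in unique(features$charge)) {
    idx <- which(features$charge == z)
    if (length(idx) < 2L) next
    m <- features$monoisotopicMass[idx]
    ord <- order(m)
    idx <- idx[ord]; m <- m[ord]
    lo <- findInterval(m + criteria@delta - criteria@deltaTol - 1e-12, m)
    hi <- findInterval(m + criteria@delta + criteria@deltaTol + 1e-12, m)
    for (i in seq_along(idx)) {
      if (hi[i] <= lo[i]) next
      for (j in (lo[i] + 1L):hi[i]) {
        cl <- classifyPair(features[idx[i], ], features[idx[j], ], criteria)
        if (cl$accepted)
          out[[length(out) + 1L]] <- data.frame(
            light = idx[i], heavy = idx[j],
            massError = cl$diagnostics$massError,
            rtDelta = cl$diagnostics$rtDelta,
            log2Ratio = cl$diagnostics$log2Ratio)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chain accepted feature pairs into disjoint isotopic multiplets
#'
#' Resolves the accepted-pair relation of \code{\link{findDoubletPairs}}
#' into maximal chains (doublets, triplets, quadruplets): conflicts where a
#' feature pairs with several candidates are settled greedily by smallest
#' absolute mass error, then smallest absolute RT delta (with deterministic
#' mass-based tie-breaks), each feature ends up with at most one lighter and
#' one heavier partner, and chains longer than four members are split
#' greedily from the light end. The result is invariant to the input row
#' order of \code{features}.
#'
#' @param features feature data.frame.
#' @param criteria a \code{\linkS4class{PairCriteria}}.
#' @return list of \code{\linkS4class{IsotopicMultiplet}}.
#' @export
pairMultiplets <- function(features, criteria = pairCriteria()) {
  pairs <- findDoubletPairs(features, criteria)
  if (!nrow(pairs)) return(list())
  o <- order(abs(pairs$massError), abs(pairs$rtDelta),
             features$monoisotopicMass[pairs$light],
             features$monoisotopicMass[pairs$heavy])
  pairs <- pairs[o, ]
  n <- nrow(features)
  nextUp <- rep(NA_integer_, n)   # heavier partner of each feature
  prevDn <- rep(NA_integer_, n)   # lighter partner
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    l <- pairs$light[k]; h <- pairs$heavy[k]
    if (is.na(nextUp[l]) && is.na(prevDn[h])) {
      nextUp[l] <- h; prevDn[h] <- l; keep[k] <- TRUE
    }
  }
  pairs <- pairs[keep, ]
  heads <- which(!is.na(nextUp) & is.na(prevDn))
  # deterministic output order: by light-member mass
  heads <- heads[order(features$monoisotopicMass[heads])]
  out <- list()
  for (h in heads) {
    chain <- h
    while (!is.na(nextUp[chain[length(chain)]]))
      chain <- c(chain, nextUp[chain[length(chain)]])
    while (length(chain) >= 2L) {
      take <- chain[seq_len(min(4L, length(chain)))]
      chain <- chain[-seq_len(min(4L, length(chain)))]
      members <- features[take, , drop = FALSE]
      rownames(members) <- NULL
      diag <- do.call(rbind, lapply(seq_len(length(take) - 1L), function(i) {
        r <- pairs[pairs$light == take[i] & pairs$heavy == take[i + 1L], ]
        data.frame(massError = r$massError[1], rtDelta = r$rtDelta[1],
                   log2Ratio = r$log2Ratio[1])
      }))
      out[[length(out) + 1L]] <- new(
        "IsotopicMultiplet", members = members,
        order = length(take),
        deltas = diff(members$monoisotopicMass), diagnostics = diag)
      if (length(chain) == 1L) break
    }
  }
  out
}

#' Build a targeted-acquisition inclusion list from multiplets
#'
#' Emits one entry per member (light and heavy alike) of every multiplet
#' whose charge state is 3 or greater; charge-2 multiplets are excluded.
#' Entries carry \code{(M + z * 1.007276) / z}, the charge, and the member's
#' RT extent padded by \code{rtPad}, and are deduplicated on (m/z rounded to
#' 4 decimals, charge).
#'
#' @param multiplets list of \code{\linkS4class{IsotopicMultiplet}}.
#' @param rtPad minutes added on both sides of each member's RT extent.
#' @param minCharge minimum charge state retained (default 3).
#' @return data.frame with columns \code{mz}, \code{charge},
#'   \code{rtStart}, \code{rtEnd}.
#' @export
buildInclusionList <- function(multiplets, rtPad = 0.5, minCharge = 3L) {
  rows <- list()
  for (mp in multiplets) {
    z <- mp@members$charge[1]
    if (z < minCharge) next
    for (i in seq_len(nrow(mp@members))) {
      f <- mp@members[i, ]
      rows[[length(rows) + 1L]] <- data.frame(
        mz = (f$monoisotopicMass + z * PROTON_MASS) / z,
        charge = z,
        rtStart = max(0, f$rtStart - rtPad),
        rtEnd = f$rtEnd + rtPad)
    }
  }
  if (!length(rows))
    return(data.frame(mz = numeric(), charge = integer(),
                      rtStart = numeric(), rtEnd = numeric()))
  out <- do.call(rbind, rows)
  key <- paste(sprintf("%.4f", out$mz), out$charge)
  out <- out[!duplicated(key), ]
  out <- out[order(out$mz, out$charge), ]
  rownames(out) <- NULL
  out
}

#' Write an inclusion list as an instrument-importable CSV
#'
#' Columns: \code{Mass [m/z]}, \code{Formula [M]}, \code{Species},
#' \code{CS [z]}, \code{Polarity}, \code{Start [min]}, \code{End [min]}.
#'
#' @param inclusion data.frame from \code{\link{buildInclusionList}}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeInclusionList <- function(inclusion, path) {
  df <- data.frame(
    `Mass [m/z]` = sprintf("%.5f", inclusion$mz),
    `Formula [M]` = "", Species = "", `CS [z]` = inclusion$charge,
    Polarity = "Positive",
    `Start [min]` = sprintf("%.2f", inclusion$rtStart),
    `End [min]` = sprintf("%.2f", inclusion$rtEnd),
    check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.kronikAliases <- list(
  monoisotopicMass = c("Monoisotopic Mass", "monoisotopic mass", "Mass",
                       "monoisotopicMass"),
  charge = c("Charge", "charge", "z"),
  rtApex = c("Best RTime", "Best RT", "rtApex", "Apex RT"),
  rtStart = c("First RTime", "First RT", "rtStart"),
  rtEnd = c("Last RTime", "Last RT", "rtEnd"),
  summedIntensity = c("Summed Intensity", "summedIntensity", "Sum Intensity"),
  maxIntensity = c("Best Intensity", "Max Intensity", "maxIntensity"))

#' Read a persistent-feature table (Kronik-style TSV)
#'
#' Maps header variants onto the standard feature columns
#' (\code{monoisotopicMass}, \code{charge}, \code{rtApex}, \code{rtStart},
#' \code{rtEnd}, \code{summedIntensity}, \code{maxIntensity}); additional
#' columns (e.g. an \code{envelope} column of semicolon-joined isotope
#' intensities) are carried through.
#'
#' @param path TSV file.
#' @param columnMap optional named list overriding the built-in header
#'   aliases, e.g. \code{list(rtApex = "My RT Column")}.
#' @return feature data.frame.
#' @export
readKronik <- function(path, columnMap = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  aliases <- .kronikAliases
  for (nm in names(columnMap)) aliases[[nm]] <- columnMap[[nm]]
  out <- raw
  for (nm in names(aliases)) {
    hit <- intersect(aliases[[nm]], names(raw))
    if (!length(hit))
      stop("cannot locate a column for '", nm, "' in ", path)
    names(out)[names(out) == hit[1]] <- nm
  }
  out$charge <- as.integer(out$charge)
  .checkFeatureFrame(out)
  out
}

#' Write a feature table in Kronik-style TSV
#'
#' @param features feature data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeKronik <- function(features, path) {
  .checkFeatureFrame(features)
  df <- features
  hdr <- c(monoisotopicMass = "Monoisotopic Mass", charge = "Charge",
           rtApex = "Best RTime", rtStart = "First RTime",
           rtEnd = "Last RTime", summedIntensity = "Summed Intensity",
           maxIntensity = "Best Intensity")
  for (nm in names(hdr)) names(df)[names(df) == nm] <- hdr[[nm]]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
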