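#' Target-decoy competition q-values
#'
#' Conservative (d+1)/t estimator: entries are sorted by decreasing score;
#' at each target's score threshold the estimated FDR is (number of decoys
#' at or above the threshold + 1) / max(1, number of targets at or above).
#' q-values are the running minimum taken from the bottom of the ranking,
#' so they are monotone non-increasing in score. Decoys receive the q-value
#' of the next better-scoring target (1 if none exists).
#'
#' @param scores numeric scores (larger is better).
#' @param isDecoy logical vector, same length.
#' @return numeric q-values in the input order.
#' @export
tdcQvalues <- function(scores, isDecoy) {
  stopifnot(length(scores) == length(isDecoy))
  if (!any(!isDecoy)) stop("q-value estimation needs at least one target")
  n <- length(scores)
  # ties: decoys ranked above targets at equal score (conservative)
  o <- order(-scores, !isDecoy)
  dec <- isDecoy[o]
  cumD <- cumsum(dec)
  cumT <- cumsum(!dec)
  fdr <- (cumD + 1) / pmax(1, cumT)
  ti <- which(!dec)
  qTarget <- rev(cummin(rev(fdr[ti])))
  q <- numeric(n)
  q[o[ti]] <- pmin(1, qTarget)
  # decoys: q of the next better target
  di <- which(dec)
  if (length(di)) {
    nBetterTargets <- findInterval(di, ti)  # targets ranked above this decoy
    qd <- ifelse(nBetterTargets == 0L, 1,
                 pmin(1, qTarget[pmax(1L, nBetterTargets)]))
    q[o[di]] <- qd
  }
  q
}

.standardizeFeatures <- function(X) {
  keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
  if (!all(keep))
    warning("dropping constant feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  scale(X)
}

.bestSingleFeature <- function(X, isDecoy, qThreshold) {
  bestCount <- -1L; bestJ <- 1L; bestSign <- 1
  for (j in seq_len(ncol(X))) {
    for (sgn in c(1, -1)) {
      q <- tdcQvalues(sgn * X[, j], isDecoy)
      cnt <- sum(q <= qThreshold & !isDecoy)
      if (cnt > bestCount) {
        bestCount <- cnt; bestJ <- j; bestSign <- sgn
      }
    }
  }
  list(feature = bestJ, sign = bestSign, count = bestCount)
}

.ridgeDiscriminant <- function(X, y, lambda) {
  p <- ncol(X)
  XtX <- crossprod(X) + diag(lambda, p)
  drop(solve(XtX, crossprod(X, y)))
}

#' Semi-supervised target-decoy rescoring of a PIN table
#'
#' A cross-validated, iterative linear rescorer in the spirit of
#' semi-supervised PSM validation: features are standardized (constant
#' columns dropped with a warning); the initial ranking direction is the
#' single feature (and sign) that maximizes targets accepted at
#' \code{qInit}; within each of \code{nFolds} cross-validation folds the
#' training split is iterated \code{nIters} times, each round labelling as
#' positives the targets at q <= \code{qInit} under the current score and
#' as negatives all decoys, then refitting a ridge-regularized
#' least-squares linear discriminant; the held-out fold is scored by the
#' trained direction. Held-out scores are normalized per fold (decoy
#' median 0, unit scale) before merging, and final q-values come from
#' \code{\link{tdcQvalues}} on the merged scores. Deterministic for a given
#' seed. With fewer than 20 targets or 20 decoys the rescorer falls back to
#' the initial single-feature ranking (with a message).
#'
#' @param pin PIN data.frame (\code{\link{buildPinTable}} schema).
#' @param nFolds cross-validation folds (default 3).
#' @param nIters training iterations per fold (default 10; 0 keeps the
#'   initial direction).
#' @param qInit q-value threshold defining training positives.
#' @param lambda ridge penalty (default 1).
#' @param seed integer RNG seed for fold assignment.
#' @return data.frame: \code{SpecId}, \code{ScanNr}, \code{isDecoy},
#'   \code{discriminantScore}, \code{qValue}, plus \code{Peptide},
#'   \code{Proteins} and (when present in the PIN) the link-type
#'   indicators resolved into a \code{linkType} column.
#' @export
semiSupervisedRescore <- function(pin, nFolds = 3L, nIters = 10L,
                                  qInit = 0.01, lambda = 1, seed = 1L) {
  featNames <- intersect(pinFeatureNames(), names(pin))
  if (!length(featNames)) stop("pin carries no known feature columns")
  X <- as.matrix(pin[, featNames, drop = FALSE])
  storage.mode(X) <- "double"
  isDecoy <- pin$Label == -1L
  Xs <- .standardizeFeatures(X)
  n <- nrow(Xs)
  init <- .bestSingleFeature(Xs, isDecoy, qInit)
  initScore <- init$sign * Xs[, init$feature]
  fallback <- sum(!isDecoy) < 20L || sum(isDecoy) < 20L
  if (fallback) {
    message("too few targets or decoys for semi-supervised training; ",
            "falling back to best-single-feature ranking")
    score <- initScore
  } else if (nIters == 0L) {
    # no training: the ranking is the initial direction itself
    score <- initScore
  } else {
    set.seed(seed)
    fold <- integer(n)
    fold[!isDecoy] <- sample(rep_len(seq_len(nFolds), sum(!isDecoy)))
    fold[isDecoy] <- sample(rep_len(seq_len(nFolds), sum(isDecoy)))
    score <- numeric(n)
    p <- ncol(Xs)
    for (f in seq_len(nFolds)) {
      tr <- fold != f
      w <- numeric(p); w[init$feature] <- init$sign
      trIdx <- which(tr)
      for (it in seq_len(nIters)) {
        s <- drop(Xs[trIdx, , drop = FALSE] %*% w)
        qtr <- tdcQvalues(s, isDecoy[trIdx])
        posIdx <- trIdx[!isDecoy[trIdx] & qtr <= qInit]
        negIdx <- trIdx[isDecoy[trIdx]]
        if (length(posIdx) < 5L) break
        Z <- Xs[c(posIdx, negIdx), , drop = FALSE]
        y <- c(rep(1, length(posIdx)), rep(-1, length(negIdx)))
        w <- .ridgeDiscriminant(Z, y, lambda)
        nw <- sqrt(sum(w^2))
        if (nw > 0) w <- w / nw
      }
      ho <- which(fold == f)
      s <- drop(Xs[ho, , drop = FALSE] %*% w)
      dmed <- stats::median(s[isDecoy[ho]])
      sc <- stats::sd(s)
      score[ho] <- (s - dmed) / if (is.finite(sc) && sc > 0) sc else 1
    }
  }
  q <- tdcQvalues(score, isDecoy)
  out <- data.frame(SpecId = pin$SpecId, ScanNr = pin$ScanNr,
                    isDecoy = isDecoy, discriminantScore = score,
                    qValue = q, Peptide = pin$Peptide,
                    Proteins = pin$Proteins, stringsAsFactors = FALSE)
  if (all(c("isInter", "isIntra", "isLoop") %in% names(pin)))
    out$linkType <- ifelse(pin$isInter == 1, "inter",
                           ifelse(pin$isIntra == 1, "intra",
                                  ifelse(pin$isLoop == 1, "loop", "single")))
  out
}

#' Filter rescored PSMs at an FDR threshold
#'
#' Accepts target PSMs with q-value <= threshold (inclusive). By default
#' q-values are re-estimated within each link-type stratum (inter, intra,
#' loop, single analysed as separate tables) from the discriminant scores;
#' \code{stratify = FALSE} pools all link types.
#'
#' @param results data.frame from \code{\link{semiSupervisedRescore}} (needs
#'   \code{discriminantScore}, \code{isDecoy}, and, for stratified
#'   filtering, \code{linkType}).
#' @param threshold q-value cutoff (default 0.02).
#' @param stratify re-estimate q per link type (default TRUE when a
#'   \code{linkType} column is present).
#' @return the accepted target subset, with an updated \code{qValue}
#'   column and \code{accepted} flag attribute for the full table available
#'   via \code{attr(, "allResults")}.
#' @export
filterAtFdr <- function(results, threshold = 0.02,
                        stratify = !is.null(results$linkType)) {
  if (!nrow(results)) {
    results$accepted <- logical(0)
    return(results)
  }
  q <- results$qValue
  if (stratify) {
    if (is.null(results$linkType))
      stop("stratified filtering needs a linkType column")
    for (lt in unique(results$linkType)) {
      idx <- results$linkType == lt
      if (any(!results$isDecoy[idx]))
        q[idx] <- tdcQvalues(results$discriminantScore[idx],
                             results$isDecoy[idx])
      else q[idx] <- 1
    }
  }
  results$qValue <- q
  results$accepted <- q <= threshold & !results$isDecoy
  out <- results[results$accepted, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "allResults") <- results
  out
}

#' Aggregate accepted PSMs to unique residue-pair links
#'
#' Resolves each PSM's linked sites to protein coordinates
#' (\code{startPos + site - 1}), orders the two (protein, residue) ends
#' canonically, and collapses PSMs to unique residue-pair links. Links are
#' inter-protein when the accessions differ and intra-protein otherwise;
#' PSMs whose peptides map to protein groups (semicolon-joined accessions)
#' are flagged ambiguous and keyed by the group, so they are never double
#' counted.
#'
#' @param psms accepted PSM data.frame (needs \code{protA}, \code{startA},
#'   \code{siteA}, \code{protB}, \code{startB}, \code{siteB}, \code{seqA},
#'   \code{seqB}, \code{linkType}; loop/single PSMs are ignored).
#' @return data.frame of links: \code{proteinA}, \code{residueA},
#'   \code{proteinB}, \code{residueB}, \code{linkClass}
#'   (\code{"inter"}/\code{"intra"}), \code{ambiguous}, \code{nPsms},
#'   \code{nPeptidePairs}, plus a \code{psmRows} list-column of
#'   contributing PSM row indices.
#' @export
aggregateLinks <- function(psms) {
  sel <- which(psms$linkType %in% c("inter", "intra"))
  if (!length(sel))
    return(data.frame(proteinA = character(), residueA = integer(),
                      proteinB = character(), residueB = integer(),
                      linkClass = character(), ambiguous = logical(),
                      nPsms = integer(), nPeptidePairs = integer()))
  sub <- psms[sel, , drop = FALSE]
  resA <- sub$startA + sub$siteA - 1L
  resB <- sub$startB + sub$siteB - 1L
  endA <- paste0(sub$protA, ":", resA)
  endB <- paste0(sub$protB, ":", resB)
  swap <- endB < endA
  pA <- ifelse(swap, sub$protB, sub$protA)
  rA <- ifelse(swap, resB, resA)
  pB <- ifelse(swap, sub$protA, sub$protB)
  rB <- ifelse(swap, resA, resB)
  pepKey <- ifelse(swap, paste(sub$seqB, sub$seqA), paste(sub$seqA, sub$seqB))
  key <- paste(pA, rA, pB, rB)
  ambiguous <- grepl(";", sub$protA) | grepl(";", sub$protB)
  grp <- split(seq_len(nrow(sub)), key)
  out <- do.call(rbind, lapply(names(grp), function(k) {
    rows <- grp[[k]]
    data.frame(proteinA = pA[rows[1]], residueA = rA[rows[1]],
               proteinB = pB[rows[1]], residueB = rB[rows[1]],
               linkClass = if (pA[rows[1]] == pB[rows[1]]) "intra"
               else "inter",
               ambiguous = any(ambiguous[rows]),
               nPsms = length(rows),
               nPeptidePairs = length(unique(pepKey[rows])),
               stringsAsFactors = FALSE)
  }))
  out$psmRows <- lapply(names(grp), function(k) sel[grp[[k]]])
  o <- order(-out$nPsms, out$proteinA, out$residueA, out$proteinB,
             out$residueB)
  out <- out[o, ]
  rownames(out) <- NULL
  out
}

#' Aggregate residue-pair links to protein-protein interactions
#'
#' One record per unordered protein pair: total PSMs, unique residue pairs,
#' unique peptide pairs, and per-fraction PSM tallies, sorted by total PSM
#' count (descending).
#'
#' @param links data.frame from \code{\link{aggregateLinks}} (inter-protein
#'   links; intra links yield same-protein records).
#' @param psms the PSM table the links were aggregated from (used for
#'   peptide identity and fraction labels).
#' @param fractions optional character vector of fraction labels parallel
#'   to \code{psms} rows; when absent a \code{fraction} column of
#'   \code{psms} is used if present.
#' @return data.frame: \code{proteinA}, \code{proteinB}, \code{nPsmsTotal},
#'   \code{nUniqueResiduePairs}, \code{nUniquePeptidePairs}, one
#'   \code{psms.<fraction>} column per fraction.
#' @export
aggregatePpis <- function(links, psms, fractions = NULL) {
  if (!nrow(links))
    return(data.frame(proteinA = character(), proteinB = character(),
                      nPsmsTotal = integer(),
                      nUniqueResiduePairs = integer(),
                      nUniquePeptidePairs = integer()))
  if (is.null(fractions))
    fractions <- if (!is.null(psms$fraction)) psms$fraction
  else rep("all", nrow(psms))
  ppiKey <- paste(links$proteinA, links$proteinB, sep = "\r")
  grp <- split(seq_len(nrow(links)), ppiKey)
  fracLevels <- sort(unique(fractions))
  out <- do.call(rbind, lapply(names(grp), function(k) {
    rows <- grp[[k]]
    psmRows <- unlist(links$psmRows[rows])
    pepKeys <- paste(pmin(psms$seqA[psmRows], psms$seqB[psmRows]),
                     pmax(psms$seqA[psmRows], psms$seqB[psmRows]))
    rec <- data.frame(proteinA = links$proteinA[rows[1]],
                      proteinB = links$proteinB[rows[1]],
                      nPsmsTotal = length(psmRows),
                      nUniqueResiduePairs = length(rows),
                      nUniquePeptidePairs = length(unique(pepKeys)),
                      stringsAsFactors = FALSE)
    tal <- table(factor(fractions[psmRows], levels = fracLevels))
    for (fl in fracLevels) rec[[paste0("psms.", fl)]] <- as.integer(tal[fl])
    rec
  }))
  out <- out[order(-out$nPsmsTotal, out$proteinA, out$proteinB), ]
  rownames(out) <- NULL
  out
}
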