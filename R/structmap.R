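#' Read C-alpha coordinates from a PDB or mmCIF file
#'
#' Extracts one row per residue C-alpha atom, using author chain ids and
#' residue numbering.
#'
#' @param path structure file; format chosen by extension (.pdb/.ent vs
#'   .cif) unless overridden.
#' @param format \code{"auto"}, \code{"pdb"} or \code{"cif"}.
#' @return data.frame with columns \code{chain}, \code{resno},
#'   \code{resid} (3-letter residue name), \code{x}, \code{y}, \code{z}.
#' @export
readStructureCa <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif"
  else "pdb"
  pdb <- if (format == "cif") bio3d::read.cif(path) else
    bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, elety = "CA")
  at <- pdb$atom[sel$atom, , drop = FALSE]
  out <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                    x = at$x, y = at$y, z = at$z,
                    stringsAsFactors = FALSE)
  # one CA per (chain, residue): keep the first altloc
  out <- out[!duplicated(paste(out$chain, out$resno)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.caDistance <- function(ca, chain1, res1, chain2, res2) {
  i <- which(ca$chain == chain1 & ca$resno == res1)
  j <- which(ca$chain == chain2 & ca$resno == res2)
  if (!length(i) || !length(j)) return(NA_real_)
  sqrt(sum((c(ca$x[i[1]], ca$y[i[1]], ca$z[i[1]]) -
              c(ca$x[j[1]], ca$y[j[1]], ca$z[j[1]]))^2))
}

#' Map residue-pair crosslinks onto a structure
#'
#' Computes the Euclidean C-alpha/C-alpha distance of each link. When an
#' accession maps to several equivalent chains (homodimers and higher
#' copies), the distance is evaluated over all chain-pair combinations and
#' the minimum is reported. Links whose residues lack a C-alpha in every
#' equivalent chain are returned separately with a reason.
#'
#' @param links data.frame with \code{proteinA}, \code{residueA},
#'   \code{proteinB}, \code{residueB} (\code{\link{aggregateLinks}} output
#'   works directly).
#' @param ca C-alpha table from \code{\link{readStructureCa}}.
#' @param chainMap data.frame with columns \code{accession}, \code{chain};
#'   repeat an accession once per equivalent chain.
#' @param xl a \code{\linkS4class{CrosslinkerSpec}} providing the maximum
#'   C-alpha span.
#' @return list with \code{mapped} (data.frame: link ends, \code{chainA},
#'   \code{chainB}, \code{calphaDistance}, \code{withinSpan}) and
#'   \code{unmapped} (data.frame: link ends, \code{reason}).
#' @export
mapLinksToStructure <- function(links, ca, chainMap,
                                xl = crosslinkerSpec()) {
  mapped <- list(); unmapped <- list()
  for (i in seq_len(nrow(links))) {
    pa <- links$proteinA[i]; pb <- links$proteinB[i]
    ra <- links$residueA[i]; rb <- links$residueB[i]
    chainsA <- chainMap$chain[chainMap$accession == pa]
    chainsB <- chainMap$chain[chainMap$accession == pb]
    if (!length(chainsA) || !length(chainsB)) {
      unmapped[[length(unmapped) + 1L]] <- data.frame(
        proteinA = pa, residueA = ra, proteinB = pb, residueB = rb,
        reason = "no-chain-mapping", stringsAsFactors = FALSE)
      next
    }
    best <- Inf; bestPair <- c(NA_character_, NA_character_)
    for (c1 in chainsA) for (c2 in chainsB) {
      if (pa == pb && ra == rb && c1 == c2) {
        d <- 0
      } else {
        d <- .caDistance(ca, c1, ra, c2, rb)
      }
      if (!is.na(d) && d < best) {
        best <- d; bestPair <- c(c1, c2)
      }
    }
    if (!is.finite(best)) {
      unmapped[[length(unmapped) + 1L]] <- data.frame(
        proteinA = pa, residueA = ra, proteinB = pb, residueB = rb,
        reason = "no-CA", stringsAsFactors = FALSE)
      next
    }
    mapped[[length(mapped) + 1L]] <- data.frame(
      proteinA = pa, residueA = ra, proteinB = pb, residueB = rb,
      chainA = bestPair[1], chainB = bestPair[2], calphaDistance = best,
      withinSpan = best <= xl@maxCalphaSpan, stringsAsFactors = FALSE)
  }
  list(mapped = if (length(mapped)) do.call(rbind, mapped) else
    data.frame(proteinA = character(), residueA = integer(),
               proteinB = character(), residueB = integer(),
               chainA = character(), chainB = character(),
               calphaDistance = numeric(), withinSpan = logical()),
    unmapped = if (length(unmapped)) do.call(rbind, unmapped) else
      data.frame(proteinA = character(), residueA = integer(),
                 proteinB = character(), residueB = integer(),
                 reason = character()))
}

#' Random residue-pair distance baseline
#'
#' Samples uniform random residue pairs from the structure (optionally
#' restricted to crosslinkable residues: lysines and chain N-termini) and
#' returns their C-alpha distances, as the null distribution against which
#' observed link distances are compared.
#'
#' @param ca C-alpha table from \code{\link{readStructureCa}}.
#' @param nPairs number of random pairs (>= 1).
#' @param restrictToLinkable sample only K residues and chain N-termini.
#' @param seed integer seed (deterministic sample).
#' @return numeric vector of \code{nPairs} distances (Angstrom).
#' @export
randomPairDistanceBaseline <- function(ca, nPairs, restrictToLinkable = FALSE,
                                       seed = 1L) {
  if (nPairs < 1L) stop("nPairs must be >= 1")
  pool <- seq_len(nrow(ca))
  if (restrictToLinkable) {
    isNterm <- !duplicated(ca$chain)
    pool <- which(ca$resid == "LYS" | isNterm)
  }
  if (length(pool) < 2L)
    stop("structure has fewer than 2 eligible residues")
  set.seed(seed)
  i <- sample(pool, nPairs, replace = TRUE)
  j <- sample(pool, nPairs, replace = TRUE)
  redraw <- which(i == j)
  while (length(redraw)) {
    j[redraw] <- sample(pool, length(redraw), replace = TRUE)
    redraw <- redraw[i[redraw] == j[redraw]]
  }
  sqrt((ca$x[i] - ca$x[j])^2 + (ca$y[i] - ca$y[j])^2 +
         (ca$z[i] - ca$z[j])^2)
}

#' Histogram of C-alpha distances at fixed bin width
#'
#' @param distances numeric vector (Angstrom).
#' @param binWidth bin width (default 2 Angstrom).
#' @return data.frame with \code{binStart}, \code{binEnd}, \code{count}.
#' @export
distanceHistogram <- function(distances, binWidth = 2) {
  if (!length(distances))
    return(data.frame(binStart = numeric(), binEnd = numeric(),
                      count = integer()))
  breaks <- seq(0, ceiling(max(distances) / binWidth) * binWidth + binWidth,
                by = binWidth)
  h <- graphics::hist(distances, breaks = breaks, plot = FALSE,
                      right = FALSE)
  data.frame(binStart = h$breaks[-length(h$breaks)],
             binEnd = h$breaks[-1], count = h$counts)
}

#' Write mapped links as TSV
#'
#' @param mapping result of \code{\link{mapLinksToStructure}}.
#' @param path output path for the mapped table; unmapped links are written
#'   alongside with a \code{.unmapped.tsv} suffix when any exist.
#' @return the path, invisibly.
#' @export
writeMappedLinks <- function(mapping, path) {
  utils::write.table(mapping$mapped, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (nrow(mapping$unmapped))
    utils::write.table(mapping$unmapped,
                       sub("\\.tsv$", "", path) |>
                         paste0(".unmapped.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-link pseudo-bond commands for molecular viewers
#'
#' Emits one \code{distance} command per mapped link in PyMOL syntax, so
#' the accepted links can be drawn on the structure.
#'
#' @param mapped mapped-link data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePseudobonds <- function(mapped, path) {
  lines <- sprintf(
    "distance xl_%03d, chain %s and resi %d and name CA, chain %s and resi %d and name CA",
    seq_len(nrow(mapped)), mapped$chainA, mapped$residueA,
    mapped$chainB, mapped$residueB)
  writeLines(lines, path)
  invisible(path)
}
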