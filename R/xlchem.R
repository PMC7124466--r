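#' Heavy-light mass difference of an isotope-coded reagent
#'
#' The mass delta between the heavy (deuterated) and light forms of the
#' crosslinker is the number of label sites times the monoisotopic mass
#' difference between the heavy and light isotope. For the default H/D pair
#' and 8 sites this gives 8.0502 Da, the doublet spacing the whole pipeline
#' keys on.
#'
#' @param nSites number of label positions (>= 0).
#' @param isotopePair numeric(2), (light, heavy) isotope monoisotopic masses;
#'   defaults to 1H/2H.
#' @return mass difference in Da.
#' @examples
#' isotopicMassDelta(8) # 8.0502
#' @export
isotopicMassDelta <- function(nSites, isotopePair = c(MASS_H1, MASS_H2)) {
  if (!is.numeric(nSites) || length(nSites) != 1L || is.na(nSites) ||
      nSites < 0)
    stop("nSites must be a single non-negative number")
  nSites * (isotopePair[2] - isotopePair[1])
}

#' Construct a crosslinker chemical model
#'
#' Builds a \code{\linkS4class{CrosslinkerSpec}}. The label mass delta is
#' derived from \code{nLabelSites} unless given explicitly. The packaged
#' defaults describe the geometry of an 8-deuterium, biotin-taggable,
#' CID-cleavable amine-reactive reagent but use placeholder spacer and arm
#' masses (the vendor values are not public); real analyses should supply
#' the reagent's masses via the arguments or a config file
#' (\code{\link{readCrosslinkerConfig}}).
#'
#' @param name reagent name.
#' @param spacerMassLight neutral mass added by the intact light spacer (Da).
#' @param shortArmMass,longArmMass cleavage remnant masses (Da, light form);
#'   must satisfy \code{short + long == spacer + cleavageAdjustment}.
#' @param nLabelSites number of heavy-label positions (default 8).
#' @param labelMassDelta optional explicit heavy-light delta (Da).
#' @param armLabelSplit integer(2), label sites on (short, long) arm.
#' @param cleavageAdjustment cleavage mass-balance constant (Da, default 0).
#' @param reactiveResidues reactive residue codes (default K; protein
#'   N-termini are always reactive too).
#' @param deadendMasses named quench adduct masses (Da).
#' @param maxCalphaSpan maximum bridgeable C-alpha distance (Angstrom).
#' @return a validated \code{CrosslinkerSpec}.
#' @export
crosslinkerSpec <- function(name = "XL-H8D8-placeholder",
                            spacerMassLight = 500.0,
                            shortArmMass = 200.0,
                            longArmMass = 300.0,
                            nLabelSites = 8L,
                            labelMassDelta = NULL,
                            armLabelSplit = c(4L, 4L),
                            cleavageAdjustment = 0,
                            reactiveResidues = "K",
                            deadendMasses = c(hydrolyzed = WATER_MASS,
                                              ammonium = AMMONIA_MASS),
                            maxCalphaSpan = 38) {
  nLabelSites <- as.integer(nLabelSites)
  if (is.null(labelMassDelta))
    labelMassDelta <- isotopicMassDelta(nLabelSites)
  new("CrosslinkerSpec", name = name, reactiveResidues = reactiveResidues,
      spacerMassLight = spacerMassLight, nLabelSites = nLabelSites,
      labelMassDelta = labelMassDelta, shortArmMass = shortArmMass,
      longArmMass = longArmMass, armLabelSplit = as.integer(armLabelSplit),
      cleavageAdjustment = cleavageAdjustment, deadendMasses = deadendMasses,
      maxCalphaSpan = maxCalphaSpan)
}

#' Read a crosslinker definition from a YAML key-value file
#'
#' Recognized keys mirror the arguments of \code{\link{crosslinkerSpec}}
#' (snake_case also accepted): \code{name}, \code{spacer_mass_light},
#' \code{short_arm_mass}, \code{long_arm_mass}, \code{n_label_sites},
#' \code{arm_label_split}, \code{cleavage_adjustment},
#' \code{reactive_residues}, \code{deadend_masses} (mapping),
#' \code{max_calpha_span}.
#'
#' @param path YAML file path.
#' @return a \code{\linkS4class{CrosslinkerSpec}}.
#' @export
readCrosslinkerConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  get2 <- function(a, b, default) {
    v <- cfg[[a]]
    if (is.null(v)) v <- cfg[[b]]
    if (is.null(v)) default else v
  }
  de <- get2("deadendMasses", "deadend_masses",
             list(hydrolyzed = WATER_MASS, ammonium = AMMONIA_MASS))
  crosslinkerSpec(
    name = get2("name", "name", "unnamed-crosslinker"),
    spacerMassLight = get2("spacerMassLight", "spacer_mass_light", 500.0),
    shortArmMass = get2("shortArmMass", "short_arm_mass", 200.0),
    longArmMass = get2("longArmMass", "long_arm_mass", 300.0),
    nLabelSites = get2("nLabelSites", "n_label_sites", 8L),
    armLabelSplit = unlist(get2("armLabelSplit", "arm_label_split",
                                c(4L, 4L))),
    cleavageAdjustment = get2("cleavageAdjustment", "cleavage_adjustment", 0),
    reactiveResidues = unlist(get2("reactiveResidues", "reactive_residues",
                                   "K")),
    deadendMasses = unlist(de),
    maxCalphaSpan = get2("maxCalphaSpan", "max_calpha_span", 38))
}

#' Construct a crosslinked species
#'
#' @param kind \code{"inter"}, \code{"intra"}, \code{"loop"} or
#'   \code{"deadend"}.
#' @param seqA,seqB peptide sequences (\code{seqB} only for inter/intra).
#' @param protA,protB protein accessions.
#' @param startA,startB 1-based peptide start positions in the proteins.
#' @param siteA,siteB 1-based linked residue indices within the peptides.
#' @param label \code{"light"} or \code{"heavy"}.
#' @param quench dead-end quench type.
#' @return a validated \code{\linkS4class{LinkSpecies}}.
#' @export
linkSpecies <- function(kind, seqA, siteA, protA = "PA", startA = 1L,
                        seqB = "", siteB = NA_integer_, protB = "PB",
                        startB = 1L, label = "light",
                        quench = "hydrolyzed") {
  new("LinkSpecies", kind = kind, seqA = seqA, protA = protA,
      startA = as.integer(startA), siteA = as.integer(siteA), seqB = seqB,
      protB = if (nzchar(seqB)) protB else "", startB = as.integer(startB),
      siteB = as.integer(siteB), label = label, quench = quench)
}

.trypticCleavageSites <- function(residues, prolineRule) {
  n <- length(residues)
  if (n == 0L) return(integer())
  sites <- which(residues %in% c("K", "R"))
  sites <- sites[sites < n]
  if (prolineRule && length(sites))
    sites <- sites[residues[sites + 1L] != "P"]
  sites
}

#' Tryptic digestion of a protein sequence
#'
#' Cleaves C-terminally to K and R (optionally skipping sites followed by
#' proline) and enumerates all peptides with 0 to \code{maxMissed} missed
#' cleavages, reporting 1-based start positions.
#'
#' @param proteinSequence residue string.
#' @param maxMissed maximum missed cleavages (default 3).
#' @param prolineRule if \code{TRUE} (default), K/R followed by P is not cut.
#' @param proteinId optional accession recorded in the output.
#' @return data.frame with columns \code{sequence}, \code{proteinId},
#'   \code{startPos}, \code{missedCleavages}.
#' @examples
#' digestTryptic("AAKAARAA", maxMissed = 1, prolineRule = FALSE)
#' @export
digestTryptic <- function(proteinSequence, maxMissed = 3L,
                          prolineRule = TRUE, proteinId = NA_character_) {
  if (!is.character(proteinSequence) || length(proteinSequence) != 1L ||
      !nzchar(proteinSequence))
    stop("proteinSequence must be a non-empty string")
  if (maxMissed < 0L) stop("maxMissed must be >= 0")
  res <- strsplit(proteinSequence, "")[[1]]
  bad <- setdiff(unique(res), AMINO_ACIDS)
  if (length(bad))
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  n <- length(res)
  bounds <- c(0L, .trypticCleavageSites(res, prolineRule), n)
  bounds <- unique(bounds)
  nseg <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (i in seq_len(nseg)) {
    for (k in 0:maxMissed) {
      j <- i + k
      if (j > nseg) break
      from <- bounds[i] + 1L
      to <- bounds[j + 1L]
      out[[length(out) + 1L]] <- list(
        sequence = paste(res[from:to], collapse = ""),
        startPos = from, missedCleavages = k)
    }
  }
  data.frame(
    sequence = vapply(out, `[[`, character(1), "sequence"),
    proteinId = proteinId,
    startPos = vapply(out, `[[`, integer(1), "startPos"),
    missedCleavages = vapply(out, `[[`, integer(1), "missedCleavages"),
    stringsAsFactors = FALSE)
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus water. Cysteine carries fixed
#' carbamidomethylation. Additional modifications can be supplied as a
#' numeric vector of mass deltas (positions are irrelevant for the total).
#'
#' @param sequence peptide residue string.
#' @param mods optional numeric vector of modification mass deltas (Da).
#' @return neutral monoisotopic mass (Da).
#' @examples
#' peptideMass("G") # 75.03203
#' @export
peptideMass <- function(sequence, mods = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  res <- strsplit(sequence, "")[[1]]
  m <- RESIDUE_MASSES[res]
  if (anyNA(m))
    stop("unknown residue(s): ",
         paste(unique(res[is.na(m)]), collapse = ", "))
  sum(m) + WATER_MASS + sum(mods)
}

#' Neutral precursor mass of a crosslinked species
#'
#' Inter/intra: \code{m(A) + m(B) + spacer}; loop: \code{m(A) + spacer};
#' dead-end: \code{m(A) + spacer + quench adduct}. Heavy species add the
#' label mass delta.
#'
#' @param species a \code{\linkS4class{LinkSpecies}}.
#' @param xl a \code{\linkS4class{CrosslinkerSpec}}.
#' @return neutral monoisotopic mass (Da).
#' @export
speciesPrecursorMass <- function(species, xl) {
  m <- peptideMass(species@seqA) + xl@spacerMassLight
  if (species@kind %in% c("inter", "intra"))
    m <- m + peptideMass(species@seqB)
  if (species@kind == "deadend") {
    q <- xl@deadendMasses[species@quench]
    if (is.na(q))
      stop("unknown dead-end quench type: ", species@quench)
    m <- m + unname(q)
  }
  if (species@label == "heavy") m <- m + xl@labelMassDelta
  m
}

#' Shuffle a protein into a search decoy, preserving its tryptic skeleton
#'
#' The protein is split at every K/R position (strict cleavage, no proline
#' exception, zero missed cleavages); within each resulting peptide all
#' residues except the C-terminal one are permuted. Protein length, the
#' positions of all cleavage sites, every peptide's C-terminal residue, and
#' per-peptide residue multisets are preserved, so the decoy database has the
#' same peptide count, length distribution and composition as the target.
#' When a peptide has at least two distinct shuffleable residues, the shuffle
#' is retried (up to 10 times) to avoid returning the target sequence.
#'
#' @param proteinSequence residue string.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return shuffled decoy sequence.
#' @export
shuffleDecoyProtein <- function(proteinSequence, seed = 1L) {
  if (!is.character(proteinSequence) || length(proteinSequence) != 1L ||
      !nzchar(proteinSequence))
    stop("proteinSequence must be a non-empty string")
  res <- strsplit(proteinSequence, "")[[1]]
  n <- length(res)
  sites <- which(res %in% c("K", "R"))
  bounds <- unique(c(0L, sites[sites < n], n))
  out <- res
  set.seed(seed)
  for (i in seq_len(length(bounds) - 1L)) {
    from <- bounds[i] + 1L
    to <- bounds[i + 1L] - 1L   # C-terminal residue stays fixed
    if (to <= from) next
    seg <- res[from:to]
    shuffled <- sample(seg)
    if (length(unique(seg)) >= 2L) {
      tries <- 0L
      while (identical(shuffled, seg) && tries < 10L) {
        shuffled <- sample(seg)
        tries <- tries + 1L
      }
    }
    out[from:to] <- shuffled
  }
  paste(out, collapse = "")
}

#' Build a concatenated target-decoy protein database
#'
#' Reads a target FASTA (or named character vector), generates one shuffled
#' decoy per target with \code{\link{shuffleDecoyProtein}}, prefixes decoy
#' accessions, and optionally writes the concatenated database as FASTA
#' (wrapped at 60 columns).
#'
#' @param input FASTA path or named character vector of protein sequences.
#' @param outPath optional output FASTA path.
#' @param seed integer seed for the shuffles (deterministic output).
#' @param decoyPrefix accession prefix for decoy entries.
#' @return named character vector of target then decoy sequences,
#'   invisibly when \code{outPath} is given.
#' @export
buildTargetDecoyDb <- function(input, outPath = NULL, seed = 1L,
                               decoyPrefix = "DECOY_") {
  prot <- if (is.character(input) && length(input) == 1L && file.exists(input))
    readFastaProteins(input) else input
  if (length(prot) == 0L) stop("no target proteins supplied")
  if (is.null(names(prot)) || any(!nzchar(names(prot))))
    stop("all proteins must be named")
  acc <- vapply(strsplit(names(prot), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(acc))
    stop("duplicate accessions in target database: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  decoys <- vapply(seq_along(prot), function(i)
    shuffleDecoyProtein(prot[[i]], seed = seed + i), character(1))
  names(decoys) <- paste0(decoyPrefix, names(prot))
  db <- c(prot, decoys)
  if (!is.null(outPath)) {
    writeFastaProteins(db, outPath)
    return(invisible(db))
  }
  db
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFastaProteins <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  stats::setNames(as.character(ss), names(ss))
}

#' Write protein sequences to FASTA (60-column wrap)
#'
#' @param proteins named character vector of sequences.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeFastaProteins <- function(proteins, path) {
  ss <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Test whether an accession marks a decoy entry
#'
#' @param accession character vector.
#' @param decoyPrefix decoy accession prefix.
#' @return logical vector.
#' @export
isDecoyAccession <- function(accession, decoyPrefix = "DECOY_") {
  startsWith(accession, decoyPrefix)
}
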