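#' @import methods
NULL

#' Chemical model of an isotope-coded, cleavable, amine-reactive crosslinker
#'
#' Describes the reagent chemistry the pipeline needs: which residues react,
#' the neutral mass the intact (light) spacer adds when two peptides are
#' bridged, the isotopic coding (number of deuterium label sites and the
#' derived light/heavy mass delta), the remnant masses the two gas-phase
#' cleavage products leave on a peptide (short and long arm), dead-end quench
#' adduct masses, and the maximum C-alpha/C-alpha span the reagent can bridge
#' in a structure.
#'
#' Invariants checked by the validity method: the arm masses are conserved
#' (\code{shortArmMass + longArmMass == spacerMassLight + cleavageAdjustment}),
#' the label delta equals \code{nLabelSites * (m(2H) - m(1H))} within 5e-4 Da,
#' the per-arm label split sums to \code{nLabelSites}, and all masses except
#' the cleavage adjustment are positive.
#'
#' @slot name reagent name.
#' @slot reactiveResidues character vector of reactive residue codes
#'   (protein N-termini are always considered reactive in addition).
#' @slot spacerMassLight neutral mass (Da) added by the intact light spacer.
#' @slot nLabelSites integer number of heavy-isotope label positions.
#' @slot labelMassDelta heavy minus light mass difference (Da).
#' @slot shortArmMass,longArmMass remnant masses (Da) left on a peptide by
#'   the short and long cleavage arm (light form).
#' @slot armLabelSplit integer(2): how many label sites sit on the short and
#'   long arm respectively.
#' @slot cleavageAdjustment mass balance constant (Da) of the cleavage
#'   reaction; 0 for homolytic bookkeeping.
#' @slot deadendMasses named numeric of quench adduct masses (Da), e.g.
#'   \code{c(hydrolyzed = 18.0106, ammonium = 17.0265)}.
#' @slot maxCalphaSpan maximum bridgeable C-alpha distance (Angstrom).
#' @export
setClass("CrosslinkerSpec", representation(
  name = "character",
  reactiveResidues = "character",
  spacerMassLight = "numeric",
  nLabelSites = "integer",
  labelMassDelta = "numeric",
  shortArmMass = "numeric",
  longArmMass = "numeric",
  armLabelSplit = "integer",
  cleavageAdjustment = "numeric",
  deadendMasses = "numeric",
  maxCalphaSpan = "numeric"
))

setValidity("CrosslinkerSpec", function(object) {
  msg <- character()
  d1 <- MASS_H2 - MASS_H1
  if (object@nLabelSites < 0L)
    msg <- c(msg, "nLabelSites must be >= 0")
  if (abs(object@labelMassDelta - object@nLabelSites * d1) > 5e-4)
    msg <- c(msg, "labelMassDelta inconsistent with nLabelSites (> 5e-4 Da)")
  cons <- object@shortArmMass + object@longArmMass -
    (object@spacerMassLight + object@cleavageAdjustment)
  if (abs(cons) > 1e-6)
    msg <- c(msg, "arm masses do not conserve spacer + cleavageAdjustment")
  if (length(object@armLabelSplit) != 2L ||
      sum(object@armLabelSplit) != object@nLabelSites)
    msg <- c(msg, "armLabelSplit must have length 2 and sum to nLabelSites")
  pos <- c(object@spacerMassLight, object@shortArmMass, object@longArmMass,
           object@deadendMasses, object@maxCalphaSpan)
  if (any(pos <= 0))
    msg <- c(msg, "all masses except cleavageAdjustment must be > 0")
  if (is.null(names(object@deadendMasses)) ||
      any(!nzchar(names(object@deadendMasses))))
    msg <- c(msg, "deadendMasses must be a named vector")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CrosslinkerSpec", function(object) {
  cat("CrosslinkerSpec:", object@name, "\n")
  cat("  reactive residues:", paste(object@reactiveResidues, collapse = ","),
      "+ protein N-terminus\n")
  cat(sprintf("  spacer (light) %.4f Da; label delta %.4f Da (%d sites)\n",
              object@spacerMassLight, object@labelMassDelta,
              object@nLabelSites))
  cat(sprintf("  arms: short %.4f / long %.4f Da (label split %d/%d)\n",
              object@shortArmMass, object@longArmMass,
              object@armLabelSplit[1], object@armLabelSplit[2]))
  cat("  dead-end quench masses:",
      paste(sprintf("%s=%.4f", names(object@deadendMasses),
                    object@deadendMasses), collapse = ", "), "\n")
  cat(sprintf("  max C-alpha span %.1f A\n", object@maxCalphaSpan))
})

#' Acceptance criteria for light/heavy MS1 feature pairing
#'
#' Two presets exist (see \code{\link{pairCriteria}}): the
#' acquisition-evaluation criteria (mass delta within tolerance, heavy-light
#' retention-time offset inside an asymmetric window, |log2 heavy/light
#' summed-intensity ratio| bounded, both maximum intensities above a floor)
#' and the pipeline criteria which replace the log2-ratio/floor pair with a
#' relative summed-intensity difference bound.
#'
#' @slot delta expected heavy-light mass difference (Da).
#' @slot deltaTol mass tolerance (Da).
#' @slot rtWindow numeric(2), allowed heavy minus light apex RT (minutes).
#' @slot maxAbsLog2Ratio bound on |log2(heavy/light summed intensity)|.
#' @slot minMaxIntensity floor on the per-feature maximum intensity (counts).
#' @slot relativeIntensityTol relative summed-intensity difference bound used
#'   by the \code{"pipeline"} mode.
#' @slot mode \code{"acquisition"} or \code{"pipeline"}.
#' @export
setClass("PairCriteria", representation(
  delta = "numeric", deltaTol = "numeric", rtWindow = "numeric",
  maxAbsLog2Ratio = "numeric", minMaxIntensity = "numeric",
  relativeIntensityTol = "numeric", mode = "character"
))

setValidity("PairCriteria", function(object) {
  msg <- character()
  if (object@deltaTol <= 0) msg <- c(msg, "deltaTol must be > 0")
  if (length(object@rtWindow) != 2L || object@rtWindow[1] > object@rtWindow[2])
    msg <- c(msg, "rtWindow must be (lower, upper) with lower <= upper")
  if (!object@mode %in% c("acquisition", "pipeline"))
    msg <- c(msg, "mode must be 'acquisition' or 'pipeline'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PairCriteria", function(object) {
  cat(sprintf(
    "PairCriteria (%s): delta %.4f +/- %.4f Da; RT window [%.2f, %.2f] min\n",
    object@mode, object@delta, object@deltaTol,
    object@rtWindow[1], object@rtWindow[2]))
  if (object@mode == "acquisition")
    cat(sprintf("  |log2 H/L| <= %g; max intensity >= %g\n",
                object@maxAbsLog2Ratio, object@minMaxIntensity))
  else
    cat(sprintf("  relative summed-intensity difference <= %g\n",
                object@relativeIntensityTol))
})

#' A crosslinked species: two peptides, a loop, or a dead-end
#'
#' Inter- and intra-protein links carry two peptides and one reactive site on
#' each; loop-links carry one peptide with two sites; dead-ends carry one
#' peptide, one site, and a quench type. The label slot records whether the
#' species carries the light or heavy form of the crosslinker.
#'
#' @slot kind one of \code{"inter"}, \code{"intra"}, \code{"loop"},
#'   \code{"deadend"}.
#' @slot seqA,seqB peptide sequences (\code{seqB} empty for loop/dead-end).
#' @slot protA,protB protein accessions.
#' @slot startA,startB 1-based start of each peptide in its protein.
#' @slot siteA,siteB 1-based linked residue index within each peptide
#'   (for loops both indices refer to \code{seqA}).
#' @slot label \code{"light"} or \code{"heavy"}.
#' @slot quench dead-end quench type (name into the crosslinker's
#'   \code{deadendMasses}); ignored for other kinds.
#' @export
setClass("LinkSpecies", representation(
  kind = "character", seqA = "character", protA = "character",
  startA = "integer", siteA = "integer",
  seqB = "character", protB = "character", startB = "integer",
  siteB = "integer", label = "character", quench = "character"
))

setValidity("LinkSpecies", function(object) {
  msg <- character()
  if (!object@kind %in% c("inter", "intra", "loop", "deadend"))
    msg <- c(msg, "kind must be inter/intra/loop/deadend")
  if (!object@label %in% c("light", "heavy"))
    msg <- c(msg, "label must be light or heavy")
  if (!nzchar(object@seqA)) msg <- c(msg, "seqA must be non-empty")
  nA <- nchar(object@seqA)
  if (object@siteA < 1L || object@siteA > nA)
    msg <- c(msg, "siteA out of range")
  if (object@kind %in% c("inter", "intra")) {
    if (!nzchar(object@seqB)) msg <- c(msg, paste(object@kind,
      "links need two peptides"))
    else if (object@siteB < 1L || object@siteB > nchar(object@seqB))
      msg <- c(msg, "siteB out of range")
    if (object@kind == "intra" && object@protA != object@protB)
      msg <- c(msg, "intra links must join peptides of the same protein")
    if (object@kind == "inter" && object@protA == object@protB)
      msg <- c(msg, "inter links must join different proteins")
  } else {
    if (nzchar(object@seqB)) msg <- c(msg, "loop/dead-end carry one peptide")
    if (object@kind == "loop") {
      if (is.na(object@siteB) || object@siteB <= object@siteA ||
          object@siteB > nA)
        msg <- c(msg, "loop needs two distinct sites on seqA (siteA < siteB)")
    } else if (!is.na(object@siteB)) {
      msg <- c(msg, "dead-end has a single site")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "LinkSpecies", function(object) {
  lab <- sprintf("[%s]", object@label)
  if (object@kind %in% c("inter", "intra"))
    cat(sprintf("%s %s %s:%s(K%d) -- %s:%s(K%d)\n", object@kind, lab,
                object@protA, object@seqA, object@siteA,
                object@protB, object@seqB, object@siteB))
  else if (object@kind == "loop")
    cat(sprintf("loop %s %s:%s(%d..%d)\n", lab, object@protA, object@seqA,
                object@siteA, object@siteB))
  else
    cat(sprintf("dead-end(%s) %s %s:%s(%d)\n", object@quench, lab,
                object@protA, object@seqA, object@siteA))
})

#' A chained set of isotopically coded MS1 features
#'
#' An ordered chain of 2 to 4 co-eluting, equal-charge deconvoluted MS1
#' features in which consecutive members are separated by the crosslinker
#' label mass delta (within tolerance). Member 1 is the lightest.
#'
#' @slot members data.frame of member features (light to heaviest), with the
#'   standard feature columns (see \code{\link{readKronik}}).
#' @slot order integer 2, 3 or 4.
#' @slot deltas consecutive mass differences (Da), length \code{order - 1}.
#' @slot diagnostics data.frame with one row per consecutive link: columns
#'   \code{massError}, \code{rtDelta}, \code{log2Ratio}.
#' @export
setClass("IsotopicMultiplet", representation(
  members = "data.frame", order = "integer", deltas = "numeric",
  diagnostics = "data.frame"
))

setValidity("IsotopicMultiplet", function(object) {
  msg <- character()
  n <- nrow(object@members)
  if (object@order != n) msg <- c(msg, "order must equal number of members")
  if (n < 2L || n > 4L) msg <- c(msg, "multiplets have 2-4 members")
  if (length(object@deltas) != n - 1L)
    msg <- c(msg, "need order - 1 consecutive deltas")
  if (n >= 2L && length(unique(object@members$charge)) != 1L)
    msg <- c(msg, "all members must share one charge state")
  if (length(msg)) msg else TRUE
})

setMethod("show", "IsotopicMultiplet", function(object) {
  cat(sprintf("IsotopicMultiplet order %d, z=%d, masses %s\n", object@order,
              object@members$charge[1],
              paste(sprintf("%.4f", object@members$monoisotopicMass),
                    collapse = " / ")))
})

#' A centroided MS2 spectrum
#'
#' @slot scanId integer scan number.
#' @slot precursorMz,precursorCharge precursor ion m/z and charge.
#' @slot rt retention time (minutes).
#' @slot mz,intensity peak arrays; \code{mz} must be sorted ascending.
#' @slot tic,basePeakMz,basePeakIntensity summary statistics (computed by the
#'   constructor when missing).
#' @export
setClass("Ms2Spectrum", representation(
  scanId = "integer", precursorMz = "numeric", precursorCharge = "integer",
  rt = "numeric", mz = "numeric", intensity = "numeric", tic = "numeric",
  basePeakMz = "numeric", basePeakIntensity = "numeric"
))

setValidity("Ms2Spectrum", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (is.unsorted(object@mz)) msg <- c(msg, "peaks must be sorted by m/z")
  if (any(object@intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  if (object@precursorCharge < 1L) msg <- c(msg, "precursorCharge must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Ms2Spectrum", function(object) {
  cat(sprintf(
    "Ms2Spectrum scan %d: %d peaks, precursor %.4f m/z z=%d, RT %.2f min\n",
    object@scanId, length(object@mz), object@precursorMz,
    object@precursorCharge, object@rt))
})

#' Ground truth bundle produced by the synthetic-data generator
#'
#' @slot proteins named character vector of protein sequences.
#' @slot species list of planted \code{\linkS4class{LinkSpecies}} (label-free
#'   identities; the generator emits both light and heavy forms of each).
#' @slot speciesTable data.frame summary of the planted species.
#' @slot seed integer seed the bundle was generated from.
#' @export
setClass("GroundTruth", representation(
  proteins = "character", species = "list", speciesTable = "data.frame",
  seed = "integer"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (is.null(names(object@proteins)) || any(!nzchar(names(object@proteins))))
    msg <- c(msg, "proteins must be a named character vector")
  if (!all(vapply(object@species, is, logical(1), "LinkSpecies")))
    msg <- c(msg, "species must all be LinkSpecies")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  kinds <- table(factor(vapply(object@species, function(s) s@kind,
                               character(1)),
                        levels = c("inter", "intra", "loop", "deadend")))
  cat(sprintf(
    "GroundTruth: %d proteins; species inter=%d intra=%d loop=%d deadend=%d (seed %d)\n",
    length(object@proteins), kinds["inter"], kinds["intra"], kinds["loop"],
    kinds["deadend"], object@seed))
})
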