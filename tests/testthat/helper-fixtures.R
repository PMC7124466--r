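# Shared fixtures: all built in code, no files.

# a crosslinker with round numbers for arithmetic checks
toyXl <- function() {
  crosslinkerSpec(name = "toy", spacerMassLight = 100,
                  shortArmMass = 40, longArmMass = 60)
}

# one MS1 feature row
feat <- function(mass, charge = 3L, rtApex = 50, summed = 1e5,
                 mx = 3e4, rtHalf = 0.5) {
  data.frame(monoisotopicMass = mass, charge = as.integer(charge),
             rtApex = rtApex, rtStart = rtApex - rtHalf,
             rtEnd = rtApex + rtHalf, summedIntensity = summed,
             maxIntensity = mx)
}

# a random feature table mixing planted near-pairs and scatter, exercising
# all criterion boundaries
randomFeatureSet <- function(n, seed) {
  set.seed(seed)
  delta <- isotopicMassDelta(8)
  nPair <- floor(n / 4)
  rows <- list()
  for (k in seq_len(nPair)) {
    m <- runif(1, 800, 5000)
    z <- sample(2:5, 1)
    rt <- runif(1, 5, 110)
    sumL <- rlnorm(1, 11, 1.5)
    rows[[length(rows) + 1L]] <- feat(m, z, rt, sumL,
                                      runif(1, 1e4, 1e5))
    rows[[length(rows) + 1L]] <- feat(
      m + delta + runif(1, -0.02, 0.02), z,
      rt + runif(1, -0.6, 0.3), sumL * 2^rnorm(1, 0, 1.5),
      runif(1, 1e4, 1e5))
  }
  nRand <- n - 2 * nPair
  for (k in seq_len(nRand))
    rows[[length(rows) + 1L]] <- feat(runif(1, 800, 5000),
                                      sample(2:5, 1), runif(1, 5, 110),
                                      rlnorm(1, 11, 1.5),
                                      runif(1, 1e4, 1e5))
  out <- do.call(rbind, rows)
  out$featureId <- seq_len(nrow(out))
  out
}

# random valid protein sequence
randomProteinSeq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(xlmspipe:::RESIDUE_MASSES), len, replace = TRUE),
        collapse = "")
}

# minimal PDB text from a table of CA atoms
writeFixturePdb <- function(atoms, path) {
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(atoms)), atoms$resid, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z)
  writeLines(c(lines, "END"), path)
  path
}
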