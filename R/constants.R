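# Physical constants (monoisotopic, Da). Proton mass follows the usual
# proteomics convention of 1.007276 for m/z arithmetic.

PROTON_MASS <- 1.007276
WATER_MASS <- 18.0105646863
AMMONIA_MASS <- 17.0265491015
MASS_H1 <- 1.00782503207
MASS_H2 <- 2.01410177785
CARBAMIDOMETHYL_MASS <- 57.02146372

# Residue monoisotopic masses. C carries fixed carbamidomethylation, applied
# at table level so every downstream mass uses the modified residue.
RESIDUE_MASSES <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918448 + 57.02146372,
  L = 113.08406398, I = 113.08406398, N = 114.04292744, D = 115.02694302,
  Q = 128.05857751, K = 128.09496302, E = 129.04259309, M = 131.04048509,
  H = 137.05891186, F = 147.06841392, R = 156.10111102, Y = 163.06332853,
  W = 186.07931295
)

AMINO_ACIDS <- names(RESIDUE_MASSES)
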