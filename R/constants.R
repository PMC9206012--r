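# Physicochemical reference tables used by protein_properties().
# Values are the standard published sets (as used by ExPASy ProtParam):
# Kyte-Doolittle hydropathy, average residue masses, Guruprasad DIWV
# dipeptide instability weights, Bjellqvist pKa values, Ikai aliphatic
# coefficients.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residues usable as "any amino acid" linker without ever creating a C2H2
# anchor: the 18 standard residues minus C and H.
AA_NON_ANCHOR <- setdiff(AA_STANDARD, c("C", "H"))

# Kyte & Doolittle (1982) hydropathy.
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Average (isotope-averaged) residue masses in Da; a peptide of length L
# weighs sum(residues) + one water (18.01524 Da).
AA_RESIDUE_MASS <- c(
  A =  71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G =  57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P =  97.1167, Q = 128.1307, R = 156.1875,
  S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760
)
MASS_WATER <- 18.01524

# Guruprasad, Reddy & Pandit (1990) dipeptide instability weight values.
# Row = first residue of the dipeptide, column = second. Order follows
# DIWV_AA_ORDER on both axes.
DIWV_AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
DIWV <- matrix(c(
  # A      C      D      E      F      G      H      I      K      L      M      N      P      Q      R      S      T      V      W      Y
      1, 44.94, -7.49,     1,     1,     1, -7.49,     1,     1,     1,     1,     1, 20.26,     1,     1,     1,     1,     1,     1,     1,
      1,     1, 20.26,     1,     1,     1,  33.6,     1,     1, 20.26,  33.6,     1, 20.26, -6.54,     1,     1,  33.6, -6.54, 24.68,     1,
      1,     1,     1,     1, -6.54,     1,     1,     1, -7.49,     1,     1,     1,     1,     1, -6.54, 20.26, -14.03,    1,     1,     1,
      1, 44.94, 20.26,  33.6,     1,     1, -6.54, 20.26,     1,     1,     1,     1, 20.26, 20.26,     1, 20.26,     1,     1, -14.03,    1,
      1,     1, 13.34,     1,     1,     1,     1,     1, -14.03,    1,     1,     1, 20.26,     1,     1,     1,     1,     1,     1, 33.601,
  -7.49,     1,     1, -6.54,     1, 13.34,     1, -7.49, -7.49,     1,     1, -7.49,     1,     1,     1,     1, -7.49,     1, 13.34, -7.49,
      1,     1,     1,     1, -9.37, -9.37,     1, 44.94, 24.68,     1,     1, 24.68, -1.88,     1,     1,     1, -6.54,     1, -1.88, 44.94,
      1,     1,     1, 44.94,     1,     1, 13.34,     1, -7.49, 20.26,     1,     1, -1.88,     1,     1,     1,     1, -7.49,     1,     1,
      1,     1,     1,     1,     1, -7.49,     1, -7.49,     1, -7.49,  33.6,     1, -6.54, 24.64,  33.6,     1,     1, -7.49,     1,     1,
      1,     1,     1,     1,     1,     1,     1,     1, -7.49,     1,     1,     1, 20.26,  33.6, 20.26,     1,     1,     1, 24.68,     1,
  13.34,     1,     1,     1,     1,     1, 58.28,     1,     1,     1, -1.88,     1, 44.94, -6.54, -6.54, 44.94, -1.88,     1,     1, 24.68,
      1, -1.88,     1,     1, -14.03, -14.03,    1, 44.94, 24.68,     1,     1,     1, -1.88, -6.54,     1,     1, -7.49,     1, -9.37,     1,
  20.26, -6.54, -6.54, 18.38, 20.26,     1,     1,     1,     1,     1, -6.54,     1, 20.26, 20.26, -6.54, 20.26,     1, 20.26, -1.88,     1,
      1, -6.54, 20.26, 20.26, -6.54,     1,     1,     1,     1,     1,     1,     1, 20.26, 20.26,     1, 44.94,     1, -6.54,     1, -6.54,
      1,     1,     1,     1,     1, -7.49, 20.26,     1,     1,     1,     1, 13.34, 20.26, 20.26, 58.28, 44.94,     1,     1, 58.28, -6.54,
      1,  33.6,     1, 20.26,     1,     1,     1,     1,     1,     1,     1,     1, 44.94, 20.26, 20.26, 20.26,     1,     1,     1,     1,
      1,     1,     1, 20.26, 13.34, -7.49,     1,     1,     1,     1,     1, -14.03,    1, -6.54,     1,     1,     1,     1, -14.03,    1,
      1,     1, -14.03,    1,     1, -7.49,     1,     1, -1.88,     1,     1,     1, 20.26,     1,     1,     1, -7.49,     1,     1, -6.54,
 -14.03,     1,     1,     1,     1, -9.37, 24.68,     1,     1, 13.34, 24.68, 13.34,     1,     1,     1,     1, -14.03, -7.49,     1,     1,
  24.68,     1, 24.68, -6.54,     1, -7.49, 13.34,     1,     1,     1, 44.94,     1, 13.34,     1, -15.91,     1, -7.49,     1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(DIWV_AA_ORDER, DIWV_AA_ORDER))

# Bjellqvist pKa set (the one ProtParam uses for pI). Side chains plus
# residue-specific terminal values.
PKA_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PKA_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PKA_NTERM_BY_RESIDUE <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36,
                          T = 6.82, V = 7.44, E = 7.7)
PKA_CTERM_BY_RESIDUE <- c(D = 4.55, E = 4.75)

# Ikai (1980) aliphatic index coefficients.
ALIPHATIC_COEF <- c(V = 2.9, I = 3.9, L = 3.9)

# IUPAC nucleotide ambiguity codes -> the set of bases they stand for.
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
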