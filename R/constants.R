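# Physicochemical and substitution-model constants used across the package.

# The 20 standard amino acids, one-letter codes, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# IUPAC one-letter protein alphabet incl. ambiguity codes; '*' = stop, '-' = gap.
AA_IUPAC <- c(AA20, "B", "Z", "J", "U", "O", "X", "*", "-")

# IUPAC DNA alphabet incl. ambiguity codes.
DNA_IUPAC <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")

# Average isotopic masses of the free amino acids (Da); residue mass in a
# chain is the free mass minus one water per peptide bond.
AA_MONOMER_MASS <- c(
  A = 89.0932,  C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G = 75.0666,  H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.2010,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885)

WATER_MASS <- 18.01524

# Kyte-Doolittle hydropathy index.
KYTE_DOOLITTLE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Bjellqvist pKa set (the set behind the ExPASy ProtParam pI).
# Side chains plus free termini; N/C-terminal residue-specific overrides.
PKA_BJELLQVIST <- list(
  positive = c(Nterm = 7.50, K = 10.00, R = 12.00, H = 5.98),
  negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00),
  nterm_override = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                     V = 7.44, E = 7.70, G = 7.50),
  cterm_override = c(D = 4.55, E = 4.75))

# Jones-Taylor-Thornton (JTT) empirical amino-acid replacement model:
# lower-triangle exchangeabilities (column-major order) and equilibrium
# frequencies, residue order a r n d c q e g h i l k m f p s t w y v.
JTT_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

JTT_RATES <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

JTT_FREQS <- c(
  0.07674792325, 0.05169094831, 0.04264495736, 0.05154394846, 0.01980298020,
  0.04075195925, 0.06182993817, 0.07315192685, 0.02294397706, 0.05376094624,
  0.09190390810, 0.05867594132, 0.02382597617, 0.04012595987, 0.05090094910,
  0.06876493124, 0.05856494144, 0.01426098574, 0.03210196790, 0.06600493400)
names(JTT_FREQS) <- JTT_ORDER

# Gapped Karlin-Altschul parameters for BLOSUM62 (gap open 11 / extend 1),
# used to convert raw local-alignment scores to E-values.
BLOSUM62_GAPPED_LAMBDA <- 0.267
BLOSUM62_GAPPED_K <- 0.041
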