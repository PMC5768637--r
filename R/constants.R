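# Physico-chemical constants used across modules. Values are standard
# compilation values; sources noted inline.

# Fixed symbol orders used when normalising matrices.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA_ALPHABET <- c("A", "C", "G", "T")

PHOSPHATASE_FAMILIES <- c(
  "PhoA", "PhoK", "AcpA", "PhoD", "PhoX", "PhoN", "AphA", "NSAPc"
)
ALKALINE_FAMILIES <- c("PhoA", "PhoK", "PhoD", "PhoX")

# Average (isotope-weighted) residue masses in Da, as used by ProtParam.
AA_AVERAGE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Bjellqvist pKa set (the ProtParam defaults).  N-terminal pKa depends on the
# first residue; unlisted residues use the default.
PKA_BJELLQVIST <- list(
  cterm = 3.55,
  nterm_default = 7.50,
  nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
            E = 7.70),
  side = c(C = 9.00, D = 4.05, E = 4.45, H = 5.98, K = 10.00, R = 12.00,
           Y = 10.00)
)

# EMBOSS iep defaults, selectable as an alternative.
PKA_EMBOSS <- list(
  cterm = 3.60,
  nterm_default = 8.60,
  nterm = c(),
  side = c(C = 8.50, D = 3.90, E = 4.10, H = 6.50, K = 10.80, R = 12.50,
           Y = 10.10)
)

# Robinson & Robinson (1991) background amino-acid frequencies.
AA_BACKGROUND <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)
AA_BACKGROUND <- AA_BACKGROUND[AA_ALPHABET]

# Van der Waals radii (Angstrom); Bondi (1964) for the common elements,
# supplemented for metals seen as phosphatase co-factors.
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
  CA = 2.31, MG = 1.73, ZN = 1.39, FE = 2.05, MN = 2.05, "NA" = 2.27,
  K = 2.75, CL = 1.75
)

# Orthophosphoric acid dissociation constants at 25 C (critical compilation
# values) and the water ion product.
PHOSPHORIC_PKA <- c(pKa1 = 2.148, pKa2 = 7.199, pKa3 = 12.35)
KW_25C <- 1e-14

# Hydroxyapatite Ca5(PO4)3OH solubility product (log10), after Fujita et al.
LOGK_HYDROXYAPATITE <- -57.74

# Davies equation Debye-Huckel slope at 25 C.
DAVIES_A <- 0.509

# Default detection limits below which a saturation index is not reported
# (instrumental errors of the colorimetric assays: mol/L).
DETECTION_LIMIT_PI <- 0.85e-6
DETECTION_LIMIT_CA <- 50e-6

# BLOSUM62 ungapped-to-gapped Karlin-Altschul parameters for gap costs 11/1
# (the standard values distributed with BLAST+).
BLAST_GAPPED_LAMBDA <- 0.267
BLAST_GAPPED_K <- 0.041
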