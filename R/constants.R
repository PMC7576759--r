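# Embedded reference tables: BLOSUM62, Kyte-Doolittle hydropathy, and the
# per-codon-position translation-error frequencies.

.BLOSUM62_AAS <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")

.BLOSUM62 <- matrix(c(
   4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,
  -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3,
  -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,
  -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,
   0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
  -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,
  -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,
   0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3,
  -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,
  -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3,
  -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1,
  -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,
  -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1,
  -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1,
  -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2,
   1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,
   0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,
  -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3,
  -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1,
   0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4),
  nrow = 20, byrow = TRUE,
  dimnames = list(.BLOSUM62_AAS, .BLOSUM62_AAS))

#' The BLOSUM62 amino-acid substitution matrix
#'
#' @return Symmetric 20x20 integer matrix of BLOSUM62 log-odds scores, rows
#'   and columns named by one-letter amino-acid codes.
#' @export
blosum62 <- function() .BLOSUM62

#' BLOSUM62 score of an amino-acid mutation
#'
#' @param wt,mut Amino acids (one- or three-letter codes).
#' @return Integer vector of scores.
#' @export
blosum_score <- function(wt, mut) {
  wt <- .norm_aa(wt); mut <- .norm_aa(mut)
  .BLOSUM62[cbind(wt, mut)]
}

.KYTE_DOOLITTLE <- c(
  I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
  E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

#' Kyte-Doolittle hydropathy of amino acids
#'
#' @param aa Amino acids (one- or three-letter codes); default: all 20.
#' @return Named numeric vector of hydropathy values.
#' @export
kyte_doolittle <- function(aa = AMINO_ACIDS) {
  aa <- .norm_aa(aa)
  .KYTE_DOOLITTLE[aa]
}

# Frequencies of codon-anticodon mispairing at the three codon positions.
.TRANSLATION_ERRORS <- c(I = 0.313, II = 0.062, III = 0.625)

#' Per-position translation-error frequencies
#'
#' Frequencies with which codon-anticodon mispairing during translation hits
#' codon positions I, II and III: (31.3%, 6.2%, 62.5%). Base II is read the
#' most accurately, base III the least.
#'
#' @return Named numeric vector of length 3 summing to 1.
#' @export
translation_error_model <- function() .TRANSLATION_ERRORS

# Hydrophobic residues whose core fraction the composition profile tracks.
HYDROPHOBIC_AAS <- c("V", "I", "L", "F")
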