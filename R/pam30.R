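# The PAM30 substitution matrix (standard published values), embedded as a
# constant so short-peptide alignment needs no external tool.

PAM30_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' The PAM30 amino-acid substitution matrix
#'
#' 20 x 20 integer matrix of PAM30 scores over the standard amino acids, as
#' used for short-peptide local alignment (with affine gap costs
#' open 5 / extend 2).
#'
#' @return Integer matrix with amino-acid dimnames.
#' @export
pam30_matrix <- function() PAM30

PAM30 <- matrix(c(
  c(  6,  -7,  -4,  -3,  -6,  -4,  -2,  -2,  -7,  -5,  -6,  -7,  -5,  -8,  -2,   0,  -1, -13,  -8,  -2),
  c( -7,   8,  -6, -10,  -8,  -2,  -9,  -9,  -2,  -5,  -8,   0,  -4,  -9,  -4,  -3,  -6,  -2, -10,  -8),
  c( -4,  -6,   8,   2, -11,  -3,  -2,  -3,   0,  -5,  -7,  -1,  -9,  -9,  -6,   0,  -2,  -8,  -4,  -8),
  c( -3, -10,   2,   8, -14,  -2,   2,  -3,  -4,  -7, -12,  -4, -11, -15,  -8,  -4,  -5, -15, -11,  -8),
  c( -6,  -8, -11, -14,  10, -14, -14,  -9,  -7,  -6, -15, -14, -13, -13,  -8,  -3,  -8, -15,  -4,  -6),
  c( -4,  -2,  -3,  -2, -14,   8,   1,  -7,   1,  -8,  -5,  -3,  -4, -13,  -3,  -5,  -5, -13, -12,  -7),
  c( -2,  -9,  -2,   2, -14,   1,   8,  -4,  -5,  -5,  -9,  -4,  -7, -14,  -5,  -4,  -6, -17,  -8,  -6),
  c( -2,  -9,  -3,  -3,  -9,  -7,  -4,   6,  -9, -11, -10,  -7,  -8,  -9,  -6,  -2,  -6, -15, -14,  -5),
  c( -7,  -2,   0,  -4,  -7,   1,  -5,  -9,   9,  -9,  -6,  -6, -10,  -6,  -4,  -6,  -7,  -7,  -3,  -6),
  c( -5,  -5,  -5,  -7,  -6,  -8,  -5, -11,  -9,   8,  -1,  -6,  -1,  -2,  -8,  -7,  -2, -14,  -6,   2),
  c( -6,  -8,  -7, -12, -15,  -5,  -9, -10,  -6,  -1,   7,  -8,   1,  -3,  -7,  -8,  -7,  -6,  -7,  -2),
  c( -7,   0,  -1,  -4, -14,  -3,  -4,  -7,  -6,  -6,  -8,   7,  -2, -14,  -6,  -4,  -3, -12,  -9,  -9),
  c( -5,  -4,  -9, -11, -13,  -4,  -7,  -8, -10,  -1,   1,  -2,  11,  -4,  -8,  -5,  -4, -13, -11,  -1),
  c( -8,  -9,  -9, -15, -13, -13, -14,  -9,  -6,  -2,  -3, -14,  -4,   9, -10,  -6,  -9,  -4,   2,  -8),
  c( -2,  -4,  -6,  -8,  -8,  -3,  -5,  -6,  -4,  -8,  -7,  -6,  -8, -10,   8,  -2,  -4, -14, -13,  -6),
  c(  0,  -3,   0,  -4,  -3,  -5,  -4,  -2,  -6,  -7,  -8,  -4,  -5,  -6,  -2,   6,   0,  -5,  -7,  -6),
  c( -1,  -6,  -2,  -5,  -8,  -5,  -6,  -6,  -7,  -2,  -7,  -3,  -4,  -9,  -4,   0,   7, -13,  -6,  -3),
  c(-13,  -2,  -8, -15, -15, -13, -17, -15,  -7, -14,  -6, -12, -13,  -4, -14,  -5, -13,  13,  -5, -15),
  c( -8, -10,  -4, -11,  -4, -12,  -8, -14,  -3,  -6,  -7,  -9, -11,   2, -13,  -7,  -6,  -5,  10,  -7),
  c( -2,  -8,  -8,  -8,  -6,  -7,  -6,  -5,  -6,   2,  -2,  -9,  -1,  -8,  -6,  -6,  -3, -15,  -7,   7)),
  nrow = 20, byrow = TRUE, dimnames = list(PAM30_AA, PAM30_AA))
storage.mode(PAM30) <- "integer"
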