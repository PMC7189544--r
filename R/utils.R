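# Internal sequence helpers. All nucleotide work in the package runs through
# these so that the alphabet and strand conventions live in one place.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Reverse complement of nucleotide strings
#'
#' Vectorised over `x`; `N` is its own complement.
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# uppercase + validate a peptide vector
check_peptides <- function(x, arg = "peptide") {
  x <- toupper(x)
  bad <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")), x)
  if (any(bad)) {
    abort(sprintf("%s contains non-amino-acid characters: %s",
                  arg, paste(head(x[bad], 3), collapse = ", ")))
  }
  x
}

check_nt <- function(x, arg = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N}", arg))
  }
  x
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

random_peptides <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA20, len, replace = TRUE), collapse = "")
  }, character(1))
}

# one codon per amino acid, used by the generators to reverse-translate
# planted peptides into coding sequences
CODON1 <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT"
)

# deterministic reverse translation (first codon per residue)
reverse_translate <- function(peptide) {
  aa <- strsplit(check_peptides(peptide), "")[[1]]
  paste(CODON1[aa], collapse = "")
}

`%||%` <- rlang::`%||%`
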