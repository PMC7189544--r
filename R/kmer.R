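# Canonical k-mer counting over read sets. A word and its reverse complement
# are merged under the lexicographically smaller of the two ("canonical"
# form), so counts are strand-symmetric; windows containing N are skipped.

#' Canonicalise nucleotide words under reverse complement
#' @param words Character vector of equal-length nucleotide words.
#' @return The lexicographic minimum of each word and its reverse complement.
#' @export
canonical_kmer <- function(words) {
  rc <- revcomp(words)
  ifelse(words <= rc, words, rc)
}

#' Count canonical k-mers of a read set
#'
#' Counts every k-length window of every read under reverse-complement
#' canonicalisation. The total satisfies
#' `sum(counts) = sum(max(0, len - k + 1)) - (number of N-containing windows)`.
#'
#' @param reads Tibble with a `sequence` column, or a character vector.
#' @param k Word length (default 24, the arbitration word size).
#' @return Object of class `kmer_table`: list with `k`, `counts` (a keyed
#'   data.table `word` -> `n`), `total_words`.
#' @export
build_kmer_table <- function(reads, k = 24) {
  if (k < 1) abort("build_kmer_table: k must be >= 1")
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  seqs <- check_nt(seqs)
  nwin <- pmax(0L, nchar(seqs) - as.integer(k) + 1L)
  if (!sum(nwin)) {
    counts <- data.table::data.table(word = character(), n = integer(), key = "word")
    return(structure(list(k = as.integer(k), counts = counts, total_words = 0L),
                     class = "kmer_table"))
  }
  starts <- sequence(nwin)
  words <- substring(rep(seqs, nwin), starts, starts + k - 1L)
  words <- words[!grepl("N", words, fixed = TRUE)]
  uw <- unique(words)
  canon <- setNames(canonical_kmer(uw), uw)
  dt <- data.table::data.table(word = unname(canon[words]))
  counts <- dt[, list(n = .N), by = "word"]
  data.table::setkeyv(counts, "word")
  structure(list(k = as.integer(k), counts = counts,
                 total_words = length(words)),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: k = %d, %d distinct canonical words, %d total\n",
              x$k, nrow(x$counts), x$total_words))
  invisible(x)
}

#' Look up counts of (canonicalised) words in a k-mer table
#' @param table A `kmer_table`.
#' @param words Character vector of k-length words (any strand).
#' @return Integer vector of counts (0 for absent words).
#' @export
kmer_count <- function(table, words) {
  if (!length(words)) return(integer(0))
  if (any(nchar(words) != table$k)) abort("kmer_count: word length != k")
  canon <- canonical_kmer(toupper(words))
  hit <- table$counts[data.table::data.table(word = canon), on = "word"]
  out <- hit$n
  out[is.na(out)] <- 0L
  out
}

#' Minimal k-mer occurrence of coding sequences
#'
#' For each coding sequence (>= k nucleotides), the minimum over its k-length
#' windows of the table counts; 0 as soon as any window is absent. This is
#' the arbitration metric (`r_overlap` when computed on an RNA-seq sample's
#' table).
#'
#' @param table A `kmer_table`.
#' @param mcs Character vector of coding sequences, each of length >= k.
#' @return Integer vector of minimal occurrences.
#' @export
kmer_min_count <- function(table, mcs) {
  k <- table$k
  if (!length(mcs)) return(integer(0))
  if (any(nchar(mcs) < k)) abort(sprintf("coding sequence shorter than k = %d", k))
  vapply(toupper(mcs), function(s) {
    nwin <- nchar(s) - k + 1L
    w <- substring(s, seq_len(nwin), seq_len(nwin) + k - 1L)
    min(kmer_count(table, w))
  }, integer(1), USE.NAMES = FALSE)
}
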