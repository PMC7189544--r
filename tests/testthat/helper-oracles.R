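# Independent oracles: deliberately naive re-implementations used to verify
# the package's optimised code paths. They share no code with R/.

# standard genetic code as a plain named vector
ORACLE_CODONS <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste0, collapse = "")
  setNames(aas, codons)
})

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3
  if (n == 0) return("")
  codons <- substring(nt, 3 * seq_len(n) - 2, 3 * seq_len(n))
  paste(ORACLE_CODONS[codons], collapse = "")
}

oracle_six_frames <- function(nt) {
  rc <- oracle_revcomp(nt)
  c(F1 = oracle_translate(substring(nt, 1)),
    F2 = oracle_translate(substring(nt, 2)),
    F3 = oracle_translate(substring(nt, 3)),
    R1 = oracle_translate(substring(rc, 1)),
    R2 = oracle_translate(substring(rc, 2)),
    R3 = oracle_translate(substring(rc, 3)))
}

# naive dictionary k-mer counter with revcomp canonicalisation
oracle_kmer_counts <- function(seqs, k) {
  env <- new.env(hash = TRUE)
  total <- 0L
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    for (i in seq_len(L - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      rc <- oracle_revcomp(w)
      cw <- if (w <= rc) w else rc
      env[[cw]] <- (env[[cw]] %||% 0L) + 1L
      total <- total + 1L
    }
  }
  counts <- unlist(as.list(env))
  list(counts = counts[order(names(counts))], total = total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# end-to-end ERE-proteome oracle: naive per-read six-frame + prefix splice
oracle_ere_entries <- function(seqs, min_len = 8) {
  out <- character(0)
  for (s in seqs) {
    for (seg in strsplit(s, "N+")[[1]]) {
      if (nchar(seg) < 3 * min_len) next
      for (aa in oracle_six_frames(seg)) {
        pref <- sub("\\*.*$", "", aa)
        if (nchar(pref) >= min_len) out <- c(out, pref)
      }
    }
  }
  out
}

# exhaustive local-alignment enumerator under affine gaps: explores every
# monotone path that starts and ends with an aligned column (leading and
# trailing gaps are strictly score-decreasing, so the optimum is covered)
oracle_local_align <- function(q, s, mat, gap_open, gap_extend) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  best <- 0
  recurse <- function(i, j, score, last) {
    # path currently ends after aligning q[i] with s[j] (last == "M") or
    # after a gap; record only match-terminated prefixes
    if (last == "M") best <<- max(best, score)
    if (i >= m && j >= n) return(invisible())
    if (i < m && j < n) {
      recurse(i + 1, j + 1, score + mat[qc[i + 1], sc[j + 1]], "M")
    }
    if (i < m) {
      cost <- if (last == "X") gap_extend else gap_open + gap_extend
      recurse(i + 1, j, score - cost, "X")
    }
    if (j < n) {
      cost <- if (last == "Y") gap_extend else gap_open + gap_extend
      recurse(i, j + 1, score - cost, "Y")
    }
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      recurse(i, j, mat[qc[i], sc[j]], "M")
    }
  }
  best
}

# brute-force Kendall tau-b by pair counting
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

oracle_pearson <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) /
    sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
}

# SAM flag bit oracle
oracle_flag_bit <- function(flag, bit) (flag %/% bit) %% 2 == 1
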