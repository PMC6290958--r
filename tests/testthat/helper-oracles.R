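# Shared test helpers and independent oracles.

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Full (unbanded) affine-gap global alignment score, plain-R Gotoh.
# Independent oracle for the banded C++ aligner on small sequences.
brute_align_score <- function(x, y, match = 1, mismatch = -2,
                              gap_open = -6, gap_ext = -1) {
  m <- nchar(x); n <- nchar(y)
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)  # gap in read (consumes x)
  Y <- matrix(NEG, m + 1, n + 1)  # gap in ref (consumes y)
  M[1, 1] <- 0
  for (i in 2:(m + 1)) X[i, 1] <- gap_open + gap_ext * (i - 1)
  for (j in 2:(n + 1)) Y[1, j] <- gap_open + gap_ext * (j - 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- if (xs[i - 1] == ys[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + gap_open + gap_ext, X[i - 1, j] + gap_ext)
      Y[i, j] <- max(M[i, j - 1] + gap_open + gap_ext, Y[i, j - 1] + gap_ext)
    }
  }
  max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
}

# Exhaustive Youden scan: every distinct value, every midpoint, sentinels
# beyond the finite range, and the infinities. Independent of youdenCutoff.
brute_youden <- function(lr, outcome) {
  fin <- sort(unique(lr[is.finite(lr)]))
  cand <- c(-Inf, Inf, fin)
  if (length(fin) >= 1) cand <- c(cand, fin[1] - 1, fin[length(fin)] + 1)
  if (length(fin) >= 2) cand <- c(cand, (fin[-1] + fin[-length(fin)]) / 2)
  best <- -Inf
  for (t in unique(cand)) {
    pos <- !is.nan(lr) & lr < t
    j <- mean(pos[outcome == 1]) + mean(!pos[outcome == 0]) - 1
    if (j > best) best <- j
  }
  best
}

# A small custom amplicon with controlled hotspot context (contains an AAA
# run inside the hotspot for left-normalization tests).
tiny_ref <- function() {
  set.seed(404)
  left <- rand_dna(60)
  core <- "GTCAAAGCTTGACCAGTGCATCGGATCCTG"   # AAA run at offset 3..5
  right <- rand_dna(60)
  AmpliconReference("tiny", paste0(left, core, right),
                    hotspot = c(60, 90), coding_offset = 100)
}
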