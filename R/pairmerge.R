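## Paired-end self-assembly: each read pair is collapsed into one
## full-length amplicon consensus with quality-aware base selection in the
## overlap. Amplicon fragments always overlap by design, so unmergeable
## pairs are suspect and are excluded from calling (counted in QC).

#' Merge read pairs into amplicon consensus reads
#'
#' Read 2 is reverse-complemented and every candidate overlap of at least
#' `min_overlap` bases is scored as matches minus mismatches; the best
#' overlap wins, ties broken toward the longer overlap. Within the
#' overlap, agreeing bases take quality `min(q1 + q2, 41)`; disagreeing
#' bases take the higher-quality base with quality `higher - lower` (an
#' exact tie keeps the read-1 base). Pairs whose best overlap is shorter
#' than `min_overlap` or whose overlap mismatch fraction exceeds
#' `max_mismatch_frac` are rejected, not errored. Deterministic: no
#' randomness is involved.
#'
#' Identical (seq1, qual1, seq2, qual2) tuples are merged once and the
#' result is fanned back out, which makes ultradeep amplicon inputs cheap
#' without changing any output.
#'
#' @param reads a [PairedReads-class].
#' @param min_overlap minimum acceptable overlap length (default 20).
#' @param max_mismatch_frac maximum mismatch fraction in the overlap
#'   (default 0.25).
#' @return A [MergedReads-class].
#' @examples
#' cfg <- SimConfig("s", 1, 50, sub_error_rate = 0, indel_error_rate = 0)
#' sim <- simulateSample(cfg, npm1Amplicon())
#' mr <- mergePairs(sim$reads)
#' mergeRate(mr)  # 1
#' @export
mergePairs <- function(reads, min_overlap = 20L, max_mismatch_frac = 0.25) {
  n <- length(reads@id)
  if (n == 0L)
    return(new("MergedReads", id = character(0), sequence = character(0),
               quality = character(0), overlap_len = integer(0),
               n_overlap_mismatches = integer(0), merged = logical(0)))
  key <- paste(match(reads@seq1, unique(reads@seq1)),
               match(reads@seq2, unique(reads@seq2)),
               match(reads@qual1, unique(reads@qual1)),
               match(reads@qual2, unique(reads@qual2)))
  first <- which(!duplicated(key))
  map <- match(key, key[first])
  res <- merge_pairs_cpp(reads@seq1[first], reads@qual1[first],
                         reads@seq2[first], reads@qual2[first],
                         as.integer(min_overlap), max_mismatch_frac)
  new("MergedReads", id = reads@id,
      sequence = res$sequence[map], quality = res$quality[map],
      overlap_len = res$overlap_len[map],
      n_overlap_mismatches = res$n_mismatch[map],
      merged = res$merged[map])
}

#' Fraction of pairs successfully merged
#'
#' @param x a [MergedReads-class].
#' @return merge rate in `[0, 1]`.
#' @export
mergeRate <- function(x) {
  if (length(x@merged) == 0L) return(NA_real_)
  mean(x@merged)
}

setMethod("length", "MergedReads", function(x) length(x@id))

setMethod("show", "MergedReads", function(object) {
  cat("MergedReads:", length(object@id), "pairs,",
      sum(object@merged), "merged (rate",
      sprintf("%.4f", mergeRate(object)), ")\n")
})

#' Write merged reads as FASTQ
#'
#' Rejected pairs are omitted from the output.
#'
#' @param x a [MergedReads-class].
#' @param path output FASTQ path (gzip-compressed when ending in `.gz`).
#' @export
writeMergedFastq <- function(x, path) {
  keep <- which(x@merged)
  s <- Biostrings::DNAStringSet(x@sequence[keep])
  names(s) <- x@id[keep]
  Biostrings::writeXStringSet(s, path, format = "fastq",
                              qualities = Biostrings::BStringSet(x@quality[keep]),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
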