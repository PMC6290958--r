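## Dual-index demultiplexing. A read is assigned to a sample only when BOTH
## its 10-nt i7 and i5 indices match that sample within max_mismatch; reads
## whose two indices point at different samples are index-hopping conflicts
## and are quarantined from every sample.

# Hamming distance between equal-length short strings; any non-matching
# character (including N) counts as a mismatch.
.hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Read and validate a sample sheet
#'
#' @param path TSV with columns `sample_id`, `i7`, `i5`.
#' @return validated data.frame.
#' @export
readSampleSheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateSampleSheet(sheet)
  sheet
}

#' @rdname readSampleSheet
#' @param sheet sample sheet data.frame.
#' @export
validateSampleSheet <- function(sheet) {
  if (!all(c("sample_id", "i7", "i5") %in% names(sheet)))
    stop("sample sheet must have columns sample_id, i7, i5")
  if (anyDuplicated(sheet$sample_id)) stop("sample_ids must be unique")
  if (anyDuplicated(paste(sheet$i7, sheet$i5))) stop("(i7, i5) pairs must be unique")
  if (any(nchar(sheet$i7) != 10L) || any(nchar(sheet$i5) != 10L))
    stop("every index must be exactly 10 nt")
  invisible(TRUE)
}

# minimum pairwise Hamming distance within one index role
.minPairwiseDist <- function(idx) {
  u <- unique(idx)
  if (length(u) < 2L) return(Inf)
  m <- Inf
  for (i in seq_len(length(u) - 1L))
    for (j in (i + 1L):length(u))
      m <- min(m, .hamming(u[i], u[j]))
  m
}

#' Demultiplex a multiplexed read set by dual indices
#'
#' Index pairs are parsed from the `i7+i5` comment in each read header.
#' A read is assigned to sample S iff both indices match S within
#' `max_mismatch`; if i7 matches one sample and i5 another, the read is a
#' conflict (index hopping) and is excluded from every sample; otherwise it
#' is unassigned. The partition is exhaustive and disjoint:
#' `sum(assigned) + unassigned + conflict == total`.
#'
#' Before any read is processed the sheet is checked for the
#' unambiguity precondition: all pairwise index distances within a role
#' must be `>= 2 * max_mismatch + 1`.
#'
#' @param reads a [PairedReads-class] (multiplexed, index comments in `id`),
#'   or the path of an R1 FASTQ when `r2_path` is given.
#' @param sheet sample sheet data.frame (`sample_id`, `i7`, `i5`).
#' @param max_mismatch per-index mismatch tolerance (default 1).
#' @param r2_path optional R2 FASTQ path (file-based input).
#' @return list with `samples` (named list of [PairedReads-class]),
#'   `report` ([DemuxReport-class]), and `conflicts` ([PairedReads-class],
#'   the quarantined index-hopping reads).
#' @export
demultiplex <- function(reads, sheet, max_mismatch = 1L, r2_path = NULL) {
  if (is.character(reads)) reads <- readPairedFastq(reads, r2_path)
  validateSampleSheet(sheet)
  need <- 2L * max_mismatch + 1L
  if (.minPairwiseDist(sheet$i7) < need || .minPairwiseDist(sheet$i5) < need)
    stop("sample sheet indices closer than 2*max_mismatch+1 = ", need,
         "; assignment would be ambiguous")
  tok <- sub(".*[ ]", "", reads@id)
  obs_i7 <- substr(tok, 1L, 10L)
  obs_i5 <- substr(tok, 12L, 21L)
  matchRole <- function(obs, ref_idx) {
    u <- unique(obs)
    hit <- vapply(u, function(o) {
      if (nchar(o) != 10L) return(NA_integer_)
      d <- vapply(ref_idx, .hamming, integer(1), a = o)
      w <- which(d <= max_mismatch)
      if (length(w) == 1L) w else NA_integer_
    }, integer(1))
    hit[match(obs, u)]
  }
  m7 <- matchRole(obs_i7, sheet$i7)
  m5 <- matchRole(obs_i5, sheet$i5)
  assigned_to <- ifelse(!is.na(m7) & !is.na(m5) & m7 == m5, m7, NA_integer_)
  conflict <- !is.na(m7) & !is.na(m5) & m7 != m5
  samples <- lapply(seq_len(nrow(sheet)), function(s)
    .subsetPairs(reads, which(!is.na(assigned_to) & assigned_to == s)))
  names(samples) <- sheet$sample_id
  counts <- vapply(samples, length, integer(1))
  report <- new("DemuxReport", assigned = counts,
                unassigned = sum(is.na(assigned_to) & !conflict),
                conflict = sum(conflict), total = length(reads@id))
  list(samples = samples, report = report,
       conflicts = .subsetPairs(reads, which(conflict)))
}

setMethod("show", "DemuxReport", function(object) {
  cat("DemuxReport:", object@total, "reads;",
      sum(object@assigned), "assigned,",
      object@unassigned, "unassigned,",
      object@conflict, "index conflicts\n")
  print(object@assigned)
})

#' Write a demultiplexing report as TSV
#'
#' @param report a [DemuxReport-class].
#' @param path output TSV path.
#' @export
writeDemuxReport <- function(report, path) {
  df <- data.frame(
    category = c(names(report@assigned), "unassigned", "conflict", "total"),
    reads = c(unname(report@assigned), report@unassigned, report@conflict,
              report@total))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
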