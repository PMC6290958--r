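## Seeded synthetic-data generator: multiplexed paired-end amplicon reads
## with known truth (mutant spike-ins, substitution/indel errors, index
## hopping, blanks, dilution series, the 20-nt bioinformatics control).

.ALPHABET <- c("A", "C", "G", "T")

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 quality character consistent with a per-base error rate, capped at 41
.qualChar <- function(rate) {
  q <- if (rate <= 0) 41L else min(41L, as.integer(round(-10 * log10(rate))))
  rawToChar(as.raw(q + 33L))
}

#' Built-in well-separated dual index pairs
#'
#' Returns `n` dual 10-nt index pairs (pairwise Hamming distance >= 5
#' within each role), suitable for `max_mismatch = 1` demultiplexing.
#' Pair 17 is reserved for the bioinformatics control
#' ([controlIndexPair()]) and is never handed out here.
#'
#' @param n number of pairs (1-16).
#' @return data.frame with columns `i7`, `i5`.
#' @export
indexPairs <- function(n) {
  i7 <- c("AAAACTCCAT", "GTGTAACTCC", "GGAAGTAGAA", "TCTTGCACTC", "GGCCTTTCCA",
          "TATCTCGTGA", "ACCCCCTGCA", "CGCCCTAAAG", "TACAATTAGG", "ATATTCATCC",
          "CTACACTGTA", "TATGCCGAAC", "GTTCTAATAA", "ACGACTTAGC", "CTAGAAAGGT",
          "TCATGACCCT")
  i5 <- c("AAAGCCTCAA", "GCCGGAGTCT", "AGGCTTTGAA", "ACAGCTGAAT", "AAATCGTGTG",
          "TCGTCGGAAA", "ATCTAACGAC", "CCCTGCGCAA", "GGACACACTA", "GTCGCCCTTG",
          "AGAGCACTCC", "AGTCCAGGCG", "GACGATACGA", "CTCGGCTAGC", "AAACGCGCGG",
          "TTTATCTATG")
  if (n < 1L || n > length(i7)) stop("n must be between 1 and ", length(i7))
  data.frame(i7 = i7[seq_len(n)], i5 = i5[seq_len(n)], stringsAsFactors = FALSE)
}

#' @rdname indexPairs
#' @export
controlIndexPair <- function() {
  data.frame(i7 = "CGTGCATCAC", i5 = "CAGCTAATAT", stringsAsFactors = FALSE)
}

#' Construct a SimConfig
#'
#' Defaults mirror the assay setup emulated by the simulator: 150 bp
#' paired-end reads, a 1e-3 per-base substitution error rate and a 1e-6
#' per-base 1-nt indel error rate.
#'
#' @param sample_id sample identifier.
#' @param seed per-sample RNG seed.
#' @param n_fragments number of amplicon fragments.
#' @param mutant_fraction per-fragment mutation probability.
#' @param mutation [InsertionSpec-class] carried by mutant fragments, or `NULL`.
#' @param read_length read length (nt).
#' @param sub_error_rate per-base substitution error rate.
#' @param indel_error_rate per-base 1-nt indel error rate.
#' @param i7,i5 10-nt index barcodes.
#' @return A [SimConfig-class].
#' @export
SimConfig <- function(sample_id, seed, n_fragments, mutant_fraction = 0,
                      mutation = NULL, read_length = 150L,
                      sub_error_rate = 1e-3, indel_error_rate = 1e-6,
                      i7 = indexPairs(1)$i7, i5 = indexPairs(1)$i5) {
  new("SimConfig", sample_id = as.character(sample_id), seed = as.integer(seed),
      n_fragments = as.integer(n_fragments),
      mutant_fraction = as.numeric(mutant_fraction), mutation = mutation,
      read_length = as.integer(read_length),
      sub_error_rate = as.numeric(sub_error_rate),
      indel_error_rate = as.numeric(indel_error_rate),
      i7 = as.character(i7), i5 = as.character(i5))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig '", object@sample_id, "': ", object@n_fragments,
      " fragments, mutant fraction ", signif(object@mutant_fraction, 3),
      if (!is.null(object@mutation)) paste0(" (+", object@mutation@inserted, ")"),
      ", seed ", object@seed, "\n", sep = "")
})

# Vectorized substitution errors: per-read error counts are
# Binomial(read_length, rate); error positions are drawn uniformly
# (independent draws; a repeated position re-randomizes the same base,
# which at the rates used is vanishingly rare). Substituted bases are
# always different from the original.
.addSubErrors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  len <- nchar(reads)
  nerr <- stats::rbinom(length(reads), len, rate)
  mx <- max(nerr)
  r <- 1L
  while (r <= mx) {
    idx <- which(nerr >= r)
    pos <- 1L + floor(stats::runif(length(idx)) * len[idx])
    cur <- substr(reads[idx], pos, pos)
    shift <- 1L + floor(stats::runif(length(idx)) * 3)
    newb <- .ALPHABET[((match(cur, .ALPHABET) - 1L + shift) %% 4L) + 1L]
    tmp <- reads[idx]
    substr(tmp, pos, pos) <- newb
    reads[idx] <- tmp
    r <- r + 1L
  }
  reads
}

# Rare 1-nt indel errors: each read suffers at most one event, with
# probability ~ read_length * rate; 50/50 insertion of a random base at a
# random gap vs deletion of a random base.
.addIndelErrors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  len <- nchar(reads)
  hit <- which(stats::runif(length(reads)) < len * rate)
  for (i in hit) {
    L <- len[i]
    if (stats::runif(1) < 0.5) {
      gap <- floor(stats::runif(1) * (L + 1))
      base <- .ALPHABET[1L + floor(stats::runif(1) * 4)]
      reads[i] <- paste0(substr(reads[i], 1L, gap), base,
                         substr(reads[i], gap + 1L, L))
    } else {
      p <- 1L + floor(stats::runif(1) * L)
      reads[i] <- paste0(substr(reads[i], 1L, p - 1L), substr(reads[i], p + 1L, L))
    }
  }
  reads
}

#' Simulate one amplicon sample
#'
#' Each fragment spans the full amplicon and is mutant with probability
#' `mutant_fraction` (per-fragment Bernoulli, so the mutant count is
#' binomially sampled). Read 1 is the first `read_length` bases of the
#' fragment; read 2 the reverse-complement of the last `read_length`
#' bases. Substitution and 1-nt indel errors are applied per base at the
#' configured rates; quality strings carry the Phred equivalent of the
#' substitution rate (capped at Q41). Fully reproducible from the seed.
#'
#' @param cfg a [SimConfig-class].
#' @param ref an [AmpliconReference-class].
#' @return list with elements `reads` ([PairedReads-class]) and `truth`
#'   (one-row data.frame: `sample_id`, `n_fragments`, `n_mutant`,
#'   `true_fraction`, `mutation`).
#' @examples
#' cfg <- SimConfig("s1", seed = 1, n_fragments = 100, mutant_fraction = 0.5,
#'                  mutation = InsertionSpec(111, "TCTG"), sub_error_rate = 0,
#'                  indel_error_rate = 0)
#' sim <- simulateSample(cfg, npm1Amplicon())
#' sim$truth
#' @export
simulateSample <- function(cfg, ref) {
  stopifnot(validObject(cfg))
  set.seed(cfg@seed)
  n <- cfg@n_fragments
  L <- cfg@read_length
  refseq <- refSequence(ref)
  if (is.null(cfg@mutation)) {
    is_mut <- rep(FALSE, n)
    mutseq <- refseq
  } else {
    is_mut <- stats::runif(n) < cfg@mutant_fraction
    mutseq <- applyInsertion(ref, cfg@mutation)
  }
  tmpl <- function(s) {
    nl <- nchar(s)
    c(r1 = substr(s, 1L, min(L, nl)),
      r2 = .revcomp(substr(s, max(1L, nl - L + 1L), nl)))
  }
  wt <- tmpl(refseq); mu <- tmpl(mutseq)
  r1 <- ifelse(is_mut, mu["r1"], wt["r1"])
  r2 <- ifelse(is_mut, mu["r2"], wt["r2"])
  r1 <- .addIndelErrors(.addSubErrors(r1, cfg@sub_error_rate), cfg@indel_error_rate)
  r2 <- .addIndelErrors(.addSubErrors(r2, cfg@sub_error_rate), cfg@indel_error_rate)
  qc <- .qualChar(cfg@sub_error_rate)
  reads <- new("PairedReads",
               id = sprintf("%s:%d", cfg@sample_id, seq_len(n)),
               seq1 = unname(r1), qual1 = strrep(qc, nchar(r1)),
               seq2 = unname(r2), qual2 = strrep(qc, nchar(r2)))
  truth <- data.frame(
    sample_id = cfg@sample_id, n_fragments = n, n_mutant = sum(is_mut),
    true_fraction = if (n > 0) sum(is_mut) / n else 0,
    mutation = if (is.null(cfg@mutation)) NA_character_ else hgvs(cfg@mutation, ref),
    stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate a multiplexed sequencing run
#'
#' Concatenates per-sample reads, attaches the `i7+i5` index comment to
#' every read header, optionally adds the reserved-index bioinformatics
#' control (2000 fragments at 50% mutant fraction carrying the fixed 20-nt
#' insertion), applies index hopping (each hopped read has one of its two
#' indices replaced by the corresponding index of another sample), and
#' shuffles read order.
#'
#' @param configs list of [SimConfig-class] with unique `(i7, i5)` pairs.
#' @param ref an [AmpliconReference-class].
#' @param include_bioinf_control add the 20-nt-insertion control sample?
#' @param hop_rate per-read index hopping probability.
#' @param seed run-level seed (hopping, shuffling, control sample seed).
#' @param dir if non-NULL, write `R1.fastq.gz`, `R2.fastq.gz`,
#'   `sample_sheet.tsv` and `truth.tsv` there.
#' @return list with `reads` ([PairedReads-class], multiplexed), `sheet`
#'   (sample sheet data.frame), `truth` (per-sample truth table),
#'   `n_hopped`, and `files` (paths, when `dir` is given).
#' @export
simulateRun <- function(configs, ref, include_bioinf_control = TRUE,
                        hop_rate = 0, seed = 1L, dir = NULL) {
  set.seed(seed)
  if (include_bioinf_control) {
    cip <- controlIndexPair()
    ctl <- SimConfig("BIOINF_CONTROL", seed = sample.int(2^31 - 2, 1),
                     n_fragments = 2000L, mutant_fraction = 0.5,
                     mutation = bioinfControlInsertion(),
                     sub_error_rate = 0, indel_error_rate = 0,
                     i7 = cip$i7, i5 = cip$i5)
    configs <- c(configs, list(ctl))
  }
  i7s <- vapply(configs, function(c) c@i7, character(1))
  i5s <- vapply(configs, function(c) c@i5, character(1))
  if (anyDuplicated(paste(i7s, i5s)))
    stop("duplicate (i7, i5) index pair across samples")
  sims <- lapply(configs, simulateSample, ref = ref)
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  counts <- vapply(sims, function(s) length(s$reads@id), integer(1))
  sample_of <- rep.int(seq_along(configs), counts)
  cat1 <- function(fld) unlist(lapply(sims, function(s) methods::slot(s$reads, fld)),
                               use.names = FALSE)
  id <- cat1("id"); s1 <- cat1("seq1"); q1 <- cat1("qual1")
  s2 <- cat1("seq2"); q2 <- cat1("qual2")
  ri7 <- i7s[sample_of]; ri5 <- i5s[sample_of]
  n_hopped <- 0L
  if (hop_rate > 0 && length(configs) > 1L) {
    hop <- which(stats::runif(length(id)) < hop_rate)
    n_hopped <- length(hop)
    if (n_hopped) {
      other <- (sample_of[hop] - 1L +
                  sample.int(length(configs) - 1L, n_hopped, replace = TRUE)) %%
        length(configs) + 1L
      swap_i7 <- stats::runif(n_hopped) < 0.5
      ri7[hop[swap_i7]] <- i7s[other[swap_i7]]
      ri5[hop[!swap_i7]] <- i5s[other[!swap_i7]]
    }
  }
  perm <- sample.int(length(id))
  reads <- new("PairedReads",
               id = paste0(id, " ", ri7, "+", ri5)[perm],
               seq1 = s1[perm], qual1 = q1[perm],
               seq2 = s2[perm], qual2 = q2[perm])
  sheet <- data.frame(sample_id = vapply(configs, function(c) c@sample_id, character(1)),
                      i7 = i7s, i5 = i5s, stringsAsFactors = FALSE)
  truth$n_hopped_run <- n_hopped
  out <- list(reads = reads, sheet = sheet, truth = truth, n_hopped = n_hopped)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(r1 = file.path(dir, "R1.fastq.gz"),
                  r2 = file.path(dir, "R2.fastq.gz"),
                  sheet = file.path(dir, "sample_sheet.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    writePairedFastq(reads, files$r1, files$r2)
    utils::write.table(sheet, files$sheet, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, files$truth, sep = "\t", quote = FALSE, row.names = FALSE)
    out$files <- files
  }
  out
}

#' Simulate a limit-of-blank cohort
#'
#' `n_samples` mutation-free samples differing only in their derived
#' seeds (drawn deterministically from `seed`).
#'
#' @param n_samples number of blank samples (the validation design uses 30).
#' @param template a [SimConfig-class] with `mutant_fraction = 0`.
#' @param ref an [AmpliconReference-class].
#' @param seed master seed for the cohort.
#' @return list with `samples` (list of per-sample `simulateSample` results)
#'   and `truth` (combined truth table).
#' @export
simulateBlankCohort <- function(n_samples = 30L, template, ref, seed = 1L) {
  if (template@mutant_fraction != 0)
    stop("blank template must have mutant_fraction = 0")
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_samples)
  samples <- lapply(seq_len(n_samples), function(i) {
    cfg <- template
    cfg@sample_id <- sprintf("blank%02d", i)
    cfg@seed <- seeds[i]
    simulateSample(cfg, ref)
  })
  list(samples = samples,
       truth = do.call(rbind, lapply(samples, `[[`, "truth")))
}

#' Simulate a dilution series
#'
#' One sample per mutant fraction, identical depth and error settings,
#' seeds derived deterministically from the master seed.
#'
#' @param fractions descending non-negative mutant fractions.
#' @param depth fragments per level.
#' @param mutation the spiked [InsertionSpec-class].
#' @param ref an [AmpliconReference-class].
#' @param seed master seed.
#' @param sub_error_rate,indel_error_rate error rates for every level.
#' @return list with `configs` (list of [SimConfig-class], one per level,
#'   index pairs assigned from [indexPairs()]), `fractions`, and `truth`
#'   after simulation via [simulateRun()] is up to the caller.
#' @export
simulateDilutionSeries <- function(fractions, depth, mutation, ref, seed = 1L,
                                   sub_error_rate = 1e-3, indel_error_rate = 0) {
  if (is.unsorted(rev(fractions)) || any(fractions < 0))
    stop("fractions must be descending and non-negative")
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, length(fractions))
  idx <- indexPairs(length(fractions))
  configs <- lapply(seq_along(fractions), function(i) {
    SimConfig(sprintf("dil_%g", fractions[i]), seed = seeds[i],
              n_fragments = depth, mutant_fraction = fractions[i],
              mutation = if (fractions[i] > 0) mutation else NULL,
              sub_error_rate = sub_error_rate,
              indel_error_rate = indel_error_rate,
              i7 = idx$i7[i], i5 = idx$i5[i])
  })
  list(configs = configs, fractions = fractions)
}

#' Write / read paired FASTQ
#'
#' Standard 4-line FASTQ records, Phred+33 qualities, gzip-compressed when
#' the path ends in `.gz`. Read identifiers (including any `i7+i5` index
#' comment) live in the description line.
#'
#' @param reads a [PairedReads-class].
#' @param r1_path,r2_path output (input) FASTQ paths.
#' @return `readPairedFastq` returns a [PairedReads-class];
#'   `writePairedFastq` returns the paths invisibly.
#' @export
writePairedFastq <- function(reads, r1_path, r2_path) {
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = grepl("\\.gz$", path))
  }
  wr(reads@seq1, reads@qual1, reads@id, r1_path)
  wr(reads@seq2, reads@qual2, reads@id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' @rdname writePairedFastq
#' @export
readPairedFastq <- function(r1_path, r2_path) {
  rd <- function(path) Biostrings::readDNAStringSet(path, format = "fastq",
                                                    with.qualities = TRUE)
  x1 <- rd(r1_path); x2 <- rd(r2_path)
  if (length(x1) != length(x2)) stop("R1 and R2 have different read counts")
  new("PairedReads", id = names(x1),
      seq1 = unname(as.character(x1)),
      qual1 = unname(as.character(S4Vectors::mcols(x1)$qualities)),
      seq2 = unname(as.character(x2)),
      qual2 = unname(as.character(S4Vectors::mcols(x2)$qualities)))
}

setMethod("length", "PairedReads", function(x) length(x@id))

setMethod("show", "PairedReads", function(object) {
  cat("PairedReads with", length(object@id), "pairs\n")
})

# subset helper used by demultiplexing
.subsetPairs <- function(reads, i) {
  new("PairedReads", id = reads@id[i], seq1 = reads@seq1[i],
      qual1 = reads@qual1[i], seq2 = reads@seq2[i], qual2 = reads@qual2[i])
}
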