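## Targeted insertion caller: merged reads are aligned directly to the
## single amplicon (banded global alignment with affine gaps), hotspot
## insertions are grouped by their left-normalized representation, and a
## call passes when at least min_mutant_reads support it. VAF =
## supporting reads / hotspot-spanning depth.

.MISMATCH_FLOOR <- 0.20  # reads with > 20% of reference positions mismatched are unalignable

#' Align one merged read to the amplicon
#'
#' Banded global alignment with affine gaps (match +1, mismatch -2, gap
#' open -6, gap extend -1, band half-width >= 32 around the length-
#' difference diagonal). Insertions are reported left-normalized. Reads
#' with more than 20% of reference positions mismatched are flagged
#' unalignable and excluded from depth.
#'
#' @param read a DNA string (merged read).
#' @param ref an [AmpliconReference-class].
#' @param band band half-width (default 32).
#' @param hamming_shortcut use the provably equivalent ungapped shortcut
#'   for equal-length, near-identical reads (default TRUE; the slow path
#'   gives bit-identical results).
#' @return list with `aligned` (logical), `score`, `n_mismatches`, and
#'   `insertions` (data.frame `position0`, `inserted`, left-normalized).
#' @examples
#' ref <- npm1Amplicon()
#' alignRead(refSequence(ref), ref)$n_mismatches  # 0
#' @export
alignRead <- function(read, ref, band = 32L, hamming_shortcut = TRUE) {
  stopifnot(length(read) == 1L)
  m <- nchar(refSequence(ref))
  if (nchar(read) < 0.5 * m || nchar(read) > 1.5 * m)
    stop("read length must be within +/-50% of the amplicon length")
  res <- align_reads_cpp(read, refSequence(ref), band = as.integer(band),
                         hamming_shortcut = hamming_shortcut)
  ins <- data.frame(position0 = integer(0), inserted = character(0),
                    stringsAsFactors = FALSE)
  if (length(res$ins_pos)) {
    specs <- lapply(seq_along(res$ins_pos), function(k)
      leftNormalize(InsertionSpec(res$ins_pos[k], res$ins_seq[k]), ref))
    ins <- data.frame(position0 = vapply(specs, insPosition, integer(1)),
                      inserted = vapply(specs, insSequence, character(1)),
                      stringsAsFactors = FALSE)
    ins <- ins[order(ins$position0), , drop = FALSE]
  }
  unalignable <- !res$aligned[1] || res$n_mismatch[1] > .MISMATCH_FLOOR * m
  list(aligned = !unalignable,
       score = res$score[1],
       n_mismatches = res$n_mismatch[1],
       insertions = ins)
}

# Classify unique merged sequences against the reference.
# Fast path: sequences exactly equal to the reference or to a known mutant
# haplotype (catalog entries, the bioinformatics control, or any haplotype
# already aligned) skip alignment via hash lookup; results are
# bit-identical to the alignment path (property-tested).
.classifyUniqueSeqs <- function(useq, ref, catalog, band, use_fast_path) {
  m <- nchar(refSequence(ref))
  n <- length(useq)
  aligned <- logical(n)
  ins_of <- vector("list", n)   # per-unique-seq data.frame of normalized insertions
  todo <- rep(TRUE, n)
  if (use_fast_path) {
    ent <- catalogEntries(catalog)
    known_specs <- c(
      lapply(seq_len(nrow(ent)), function(i)
        InsertionSpec(ent$position0[i], ent$inserted[i])),
      list(bioinfControlInsertion()))
    hap <- vapply(known_specs, function(s) applyInsertion(ref, s), character(1))
    known_seq <- c(refSequence(ref), hap)
    known_ins <- c(list(data.frame(position0 = integer(0), inserted = character(0),
                                   stringsAsFactors = FALSE)),
                   lapply(known_specs, function(s) {
                     s <- leftNormalize(s, ref)
                     data.frame(position0 = insPosition(s),
                                inserted = insSequence(s),
                                stringsAsFactors = FALSE)
                   }))
    hit <- match(useq, known_seq)
    take <- which(!is.na(hit))
    aligned[take] <- TRUE
    ins_of[take] <- known_ins[hit[take]]
    todo[take] <- FALSE
  }
  idx <- which(todo)
  if (length(idx)) {
    len <- nchar(useq[idx])
    bad_len <- len < 0.5 * m | len > 1.5 * m
    aln_idx <- idx[!bad_len]
    if (length(aln_idx)) {
      res <- align_reads_cpp(useq[aln_idx], refSequence(ref),
                             band = as.integer(band))
      ok <- res$aligned & res$n_mismatch <= .MISMATCH_FLOOR * m
      aligned[aln_idx] <- ok
      empty <- data.frame(position0 = integer(0), inserted = character(0),
                          stringsAsFactors = FALSE)
      ins_of[aln_idx] <- list(empty)
      if (length(res$ins_pos)) {
        keepi <- ok[res$ins_read]
        if (any(keepi)) {
          specs <- lapply(which(keepi), function(k)
            leftNormalize(InsertionSpec(res$ins_pos[k], res$ins_seq[k]), ref))
          df <- data.frame(
            u = aln_idx[res$ins_read[keepi]],
            position0 = vapply(specs, insPosition, integer(1)),
            inserted = vapply(specs, insSequence, character(1)),
            stringsAsFactors = FALSE)
          for (u in unique(df$u))
            ins_of[[u]] <- df[df$u == u, c("position0", "inserted"), drop = FALSE]
        }
      }
    }
  }
  list(aligned = aligned, ins_of = ins_of)
}

#' Call exon-12 insertions in one sample
#'
#' Groups identical left-normalized insertions across reads, computes the
#' hotspot-spanning depth (alignable full-length reads with at least
#' `flank` aligned nt on each side of the hotspot), VAF =
#' supporting / depth, and applies the pass rule: a call passes iff it is
#' supported by at least `min_mutant_reads` reads (assay default 2). Only
#' insertions whose normalized position falls inside the hotspot window
#' are reported as calls; alignable reads without hotspot insertions count
#' in depth as wild-type. Calls are sorted by VAF descending.
#'
#' @param merged a [MergedReads-class] (rejected pairs are ignored), or a
#'   character vector of merged sequences.
#' @param ref an [AmpliconReference-class].
#' @param catalog a [MutationCatalog-class] used for labeling.
#' @param min_mutant_reads minimum supporting reads for a pass call.
#' @param flank required aligned flank around the hotspot (nt).
#' @param sample_id identifier stored in the result.
#' @param band alignment band half-width.
#' @param use_fast_path hash-lookup shortcut for reads identical to the
#'   reference or a known haplotype (bit-identical to the slow path).
#' @return A [SampleCallResult-class].
#' @examples
#' ref <- npm1Amplicon(); cat12 <- npm1Catalog(ref)
#' cfg <- SimConfig("s", 1, 1000, 0.02, parseHgvs("c.863_864insTCTG", ref),
#'                  sub_error_rate = 0, indel_error_rate = 0)
#' mr <- mergePairs(simulateSample(cfg, ref)$reads)
#' sampleCalls(callSample(mr, ref, cat12, sample_id = "s"))
#' @export
callSample <- function(merged, ref, catalog, min_mutant_reads = 2L,
                       flank = 10L, sample_id = "", band = 32L,
                       use_fast_path = TRUE) {
  seqs <- if (is(merged, "MergedReads")) merged@sequence[merged@merged] else merged
  n_reads <- length(seqs)
  empty_calls <- data.frame(position0 = integer(0), inserted = character(0),
                            hgvs = character(0), label = character(0),
                            supporting_reads = integer(0), depth = integer(0),
                            vaf = numeric(0), pass = logical(0),
                            stringsAsFactors = FALSE)
  if (n_reads == 0L)
    return(new("SampleCallResult", sample_id = sample_id, calls = empty_calls,
               depth = 0L, n_reads = 0L, n_unalignable = 0L, n_wildtype = 0L,
               status = "no coverage"))
  hs <- hotspot(ref)
  m <- nchar(refSequence(ref))
  # the flank requirement: global alignments span [0, m); they satisfy the
  # flank rule whenever the hotspot sits >= flank nt inside the amplicon
  if (hs[1] < flank || m - hs[2] < flank)
    warning("hotspot closer than 'flank' nt to the amplicon edge")
  useq <- unique(seqs)
  cnt <- tabulate(match(seqs, useq), nbins = length(useq))
  cls <- .classifyUniqueSeqs(useq, ref, catalog, band, use_fast_path)
  depth <- sum(cnt[cls$aligned])
  n_unalignable <- n_reads - depth
  if (depth == 0L)
    return(new("SampleCallResult", sample_id = sample_id, calls = empty_calls,
               depth = 0L, n_reads = as.integer(n_reads),
               n_unalignable = as.integer(n_unalignable), n_wildtype = 0L,
               status = "no coverage"))
  # gather insertion support over unique sequences
  has_hotspot_ins <- logical(length(useq))
  sup <- list()
  for (u in which(cls$aligned)) {
    df <- cls$ins_of[[u]]
    if (is.null(df) || nrow(df) == 0L) next
    in_hs <- df$position0 >= hs[1] & df$position0 < hs[2]
    if (!any(in_hs)) next
    has_hotspot_ins[u] <- TRUE
    for (k in which(in_hs)) {
      key <- paste0(df$position0[k], ":", df$inserted[k])
      sup[[key]] <- (if (is.null(sup[[key]])) 0L else sup[[key]]) + cnt[u]
    }
  }
  n_wildtype <- sum(cnt[cls$aligned & !has_hotspot_ins])
  if (length(sup) == 0L) {
    calls <- empty_calls
  } else {
    keys <- names(sup)
    pos0 <- as.integer(sub(":.*", "", keys))
    insb <- sub(".*:", "", keys)
    supporting <- as.integer(unlist(sup))
    specs <- lapply(seq_along(keys), function(k) InsertionSpec(pos0[k], insb[k]))
    calls <- data.frame(
      position0 = pos0, inserted = insb,
      hgvs = vapply(specs, hgvs, character(1), ref = ref),
      label = vapply(specs, classifyInsertion, character(1),
                     catalog = catalog, ref = ref),
      supporting_reads = supporting, depth = as.integer(depth),
      vaf = supporting / depth,
      pass = supporting >= min_mutant_reads,
      stringsAsFactors = FALSE)
    calls <- calls[order(-calls$vaf, calls$position0, calls$inserted), ,
                   drop = FALSE]
    rownames(calls) <- NULL
  }
  new("SampleCallResult", sample_id = sample_id, calls = calls,
      depth = as.integer(depth), n_reads = as.integer(n_reads),
      n_unalignable = as.integer(n_unalignable),
      n_wildtype = as.integer(n_wildtype), status = "ok")
}

#' @rdname accessors
#' @export
setGeneric("sampleCalls", function(x) standardGeneric("sampleCalls"))
#' @rdname accessors
#' @export
setMethod("sampleCalls", "SampleCallResult", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("sampleDepth", function(x) standardGeneric("sampleDepth"))
#' @rdname accessors
#' @export
setMethod("sampleDepth", "SampleCallResult", function(x) x@depth)

setMethod("show", "SampleCallResult", function(object) {
  cat("SampleCallResult '", object@sample_id, "' [", object@status, "]: ",
      object@n_reads, " reads, depth ", object@depth, ", ",
      nrow(object@calls), " insertion call(s)\n", sep = "")
  if (nrow(object@calls)) print(object@calls)
})

#' Maximum hotspot-insertion VAF of a sample
#'
#' Background signal measure used by the limit-of-blank experiment:
#' the largest VAF among the sample's hotspot insertion calls, 0 when the
#' sample has none.
#'
#' @param result a [SampleCallResult-class].
#' @return numeric VAF.
#' @export
backgroundVaf <- function(result) {
  calls <- sampleCalls(result)
  if (nrow(calls) == 0L) 0 else max(calls$vaf)
}

#' VAF of a specific insertion in a sample
#'
#' @param result a [SampleCallResult-class].
#' @param spec the [InsertionSpec-class] looked for (normalized internally).
#' @param ref an [AmpliconReference-class].
#' @param require_pass only consider pass calls (default TRUE).
#' @return list with `detected` (logical) and `vaf` (0 when absent).
#' @export
mutationVaf <- function(result, spec, ref, require_pass = TRUE) {
  spec <- leftNormalize(spec, ref)
  calls <- sampleCalls(result)
  i <- which(calls$position0 == insPosition(spec) &
               calls$inserted == insSequence(spec) &
               (calls$pass | !require_pass))
  if (length(i)) list(detected = TRUE, vaf = calls$vaf[i[1]])
  else list(detected = FALSE, vaf = 0)
}

#' Verify the run-level bioinformatics control
#'
#' The control sample (reserved index pair, see [controlIndexPair()]) must
#' yield a pass call whose inserted sequence is the expected 20-nt control
#' insertion; any other outcome fails the run and downstream MRD reporting
#' must not proceed.
#'
#' @param results named list of [SampleCallResult-class] (or a single one).
#' @param ref an [AmpliconReference-class].
#' @param control_id sample id of the control (default `"BIOINF_CONTROL"`).
#' @param expected expected control [InsertionSpec-class].
#' @return list with `pass` (logical) and `detail` (character).
#' @export
verifyBioinfControl <- function(results, ref, control_id = "BIOINF_CONTROL",
                                expected = bioinfControlInsertion()) {
  if (is(results, "SampleCallResult")) {
    ctl <- results
  } else {
    ids <- vapply(results, function(r) r@sample_id, character(1))
    i <- match(control_id, ids)
    if (is.na(i)) return(list(pass = FALSE, detail = "control missing"))
    ctl <- results[[i]]
  }
  hit <- mutationVaf(ctl, expected, ref, require_pass = TRUE)
  if (!hit$detected)
    return(list(pass = FALSE,
                detail = "expected 20-nt control insertion not called"))
  list(pass = TRUE,
       detail = sprintf("control insertion recovered (VAF %.4f, insert %d nt)",
                        hit$vaf, nchar(insSequence(expected))))
}

#' Write sample calls as TSV
#'
#' @param result a [SampleCallResult-class].
#' @param path output path.
#' @export
writeCallsTsv <- function(result, path) {
  utils::write.table(cbind(sample_id = result@sample_id, sampleCalls(result)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample calls as a minimal single-sample VCF 4.2
#'
#' Amplicon-local coordinates (CHROM = amplicon name, 1-based POS of the
#' base left of the insertion gap, anchored REF/ALT). INFO carries
#' supporting reads (SR), depth (DP), VAF and catalog label.
#'
#' @param result a [SampleCallResult-class].
#' @param ref an [AmpliconReference-class].
#' @param path output path.
#' @export
writeCallsVcf <- function(result, ref, path) {
  calls <- sampleCalls(result)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", ref@name, nchar(refSequence(ref))),
           "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Supporting reads\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Hotspot-spanning depth\">",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
           "##INFO=<ID=LABEL,Number=1,Type=String,Description=\"Catalog label\">",
           "##FILTER=<ID=min_reads,Description=\"Fewer supporting reads than the pass threshold\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  rows <- character(0)
  if (nrow(calls)) {
    s <- refSequence(ref)
    rows <- vapply(seq_len(nrow(calls)), function(k) {
      p <- calls$position0[k]          # 0-based gap: anchor base at p (1-based)
      anchor <- substr(s, p, p)
      paste(ref@name, p, calls$hgvs[k], anchor,
            paste0(anchor, calls$inserted[k]), ".",
            if (calls$pass[k]) "PASS" else "min_reads",
            sprintf("SR=%d;DP=%d;VAF=%.6g;LABEL=%s",
                    calls$supporting_reads[k], calls$depth[k], calls$vaf[k],
                    gsub("[ ;=]", "_", calls$label[k])),
            sep = "\t")
    }, character(1))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
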