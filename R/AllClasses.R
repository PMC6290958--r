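#' @import methods
NULL

#' Amplicon reference model
#'
#' Holds the target amplicon sequence together with the exon-12 insertion
#' hotspot window and the coordinate convention that maps amplicon positions
#' to cDNA (c.) numbering. All coordinates inside the package are 0-based,
#' half-open; HGVS c.-coordinates appear only at the parse/format boundary.
#'
#' @slot name single character, reference name.
#' @slot sequence uppercase DNA string (A/C/G/T only), 150-400 nt.
#' @slot hotspot integer vector `c(start, end)`: half-open interval in
#'   0-based amplicon coordinates where exon-12 insertions are expected.
#' @slot codingOffset integer; cDNA coordinate of amplicon position `p`
#'   (0-based) is `p + codingOffset`.
#'
#' @seealso [AmpliconReference()], [npm1Amplicon()]
#' @export
setClass("AmpliconReference",
  representation(name = "character", sequence = "character",
                 hotspot = "integer", codingOffset = "integer"))

setValidity("AmpliconReference", function(object) {
  msg <- character(0)
  if (length(object@sequence) != 1L) msg <- c(msg, "sequence must be a single string")
  s <- object@sequence
  if (grepl("[^ACGT]", s)) msg <- c(msg, "sequence may contain only A/C/G/T")
  n <- nchar(s)
  if (n < 150L || n > 400L) msg <- c(msg, "sequence length must be in [150, 400]")
  h <- object@hotspot
  if (length(h) != 2L || anyNA(h)) msg <- c(msg, "hotspot must be c(start, end)")
  else {
    if (!(h[1] >= 0L && h[1] < h[2] && h[2] <= n))
      msg <- c(msg, "hotspot must satisfy 0 <= start < end <= length(sequence)")
    if (h[2] - h[1] < 12L) msg <- c(msg, "hotspot width must be >= 12 nt")
  }
  if (length(object@codingOffset) != 1L) msg <- c(msg, "codingOffset must be a single integer")
  if (length(msg)) msg else TRUE
})

#' One exon-12 insertion
#'
#' An insertion of `inserted` between amplicon positions `position0 - 1`
#' and `position0` (0-based gap coordinate). HGVS representation is derived
#' on demand via [hgvs()].
#'
#' @slot position0 integer, 0-based gap position in amplicon coordinates.
#' @slot inserted DNA string of the inserted bases (length >= 1).
#'
#' @seealso [InsertionSpec()], [parseHgvs()], [leftNormalize()]
#' @export
setClass("InsertionSpec",
  representation(position0 = "integer", inserted = "character"))

setValidity("InsertionSpec", function(object) {
  msg <- character(0)
  if (length(object@position0) != 1L || is.na(object@position0) || object@position0 < 0L)
    msg <- c(msg, "position0 must be a single non-negative integer")
  if (length(object@inserted) != 1L || is.na(object@inserted) ||
      nchar(object@inserted) < 1L || grepl("[^ACGT]", object@inserted))
    msg <- c(msg, "inserted must be a non-empty A/C/G/T string")
  if (length(msg)) msg else TRUE
})

setClassUnion("InsertionSpecOrNULL", c("InsertionSpec", "NULL"))

#' Catalog of known NPM1 exon-12 insertion types
#'
#' @slot entries data.frame with columns `label`, `hgvs`, `position0`,
#'   `inserted`; one row per distinct left-normalized insertion.
#'
#' @seealso [MutationCatalog()], [npm1Catalog()], [classifyInsertion()]
#' @export
setClass("MutationCatalog", representation(entries = "data.frame"))

setValidity("MutationCatalog", function(object) {
  e <- object@entries
  msg <- character(0)
  need <- c("label", "hgvs", "position0", "inserted")
  if (!all(need %in% names(e))) return("entries must have columns label, hgvs, position0, inserted")
  if (anyDuplicated(e$label)) msg <- c(msg, "labels must be unique")
  if (anyDuplicated(paste(e$position0, e$inserted)))
    msg <- c(msg, "normalized (position0, inserted) pairs must be unique")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for one amplicon sample
#'
#' @slot sample_id sample identifier.
#' @slot seed RNG seed for this sample.
#' @slot n_fragments number of amplicon fragments to simulate.
#' @slot mutant_fraction probability that a fragment carries the mutation.
#' @slot mutation [InsertionSpec-class] or `NULL`.
#' @slot read_length read length in nt (default 150, paired 150 bp chemistry).
#' @slot sub_error_rate per-base substitution error rate.
#' @slot indel_error_rate per-base 1-nt indel error rate.
#' @slot i7,i5 10-nt sample index barcodes.
#'
#' @seealso [SimConfig()], [simulateSample()]
#' @export
setClass("SimConfig",
  representation(sample_id = "character", seed = "integer",
                 n_fragments = "integer", mutant_fraction = "numeric",
                 mutation = "InsertionSpecOrNULL", read_length = "integer",
                 sub_error_rate = "numeric", indel_error_rate = "numeric",
                 i7 = "character", i5 = "character"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  rate_ok <- function(x) length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
  if (!rate_ok(object@mutant_fraction)) msg <- c(msg, "mutant_fraction must be in [0,1]")
  if (!rate_ok(object@sub_error_rate)) msg <- c(msg, "sub_error_rate must be in [0,1]")
  if (!rate_ok(object@indel_error_rate)) msg <- c(msg, "indel_error_rate must be in [0,1]")
  if (object@read_length < 50L) msg <- c(msg, "read_length must be >= 50")
  if (object@n_fragments < 0L) msg <- c(msg, "n_fragments must be >= 0")
  if (nchar(object@i7) != 10L || nchar(object@i5) != 10L)
    msg <- c(msg, "index barcodes must be exactly 10 nt")
  if (object@mutant_fraction > 0 && is.null(object@mutation))
    msg <- c(msg, "mutant_fraction > 0 requires a mutation")
  if (length(msg)) msg else TRUE
})

#' Paired sequencing reads held in memory
#'
#' Parallel character vectors; read 2 is stored in sequencing orientation
#' (reverse-complement of the fragment end). `id` carries the FASTQ
#' description line including the `i7+i5` index comment when multiplexed.
#'
#' @slot id,seq1,qual1,seq2,qual2 parallel character vectors.
#' @export
setClass("PairedReads",
  representation(id = "character", seq1 = "character", qual1 = "character",
                 seq2 = "character", qual2 = "character"))

setValidity("PairedReads", function(object) {
  n <- length(object@id)
  if (length(object@seq1) != n || length(object@qual1) != n ||
      length(object@seq2) != n || length(object@qual2) != n)
    return("all slots must have equal length")
  TRUE
})

#' Self-assembled (merged) amplicon reads
#'
#' @slot id read identifiers.
#' @slot sequence,quality merged consensus sequence and Phred+33 quality
#'   (`NA` where the pair was rejected).
#' @slot overlap_len,n_overlap_mismatches per-pair overlap statistics.
#' @slot merged logical; `FALSE` for rejected pairs.
#' @export
setClass("MergedReads",
  representation(id = "character", sequence = "character", quality = "character",
                 overlap_len = "integer", n_overlap_mismatches = "integer",
                 merged = "logical"))

#' Demultiplexing tally
#'
#' @slot assigned named integer vector of per-sample read counts.
#' @slot unassigned reads matching no sample on at least one index.
#' @slot conflict reads whose i7 and i5 point at different samples
#'   (index hopping); quarantined from every sample.
#' @slot total input read count; `sum(assigned) + unassigned + conflict == total`.
#' @export
setClass("DemuxReport",
  representation(assigned = "integer", unassigned = "integer",
                 conflict = "integer", total = "integer"))

setValidity("DemuxReport", function(object) {
  if (sum(object@assigned) + object@unassigned + object@conflict != object@total)
    return("assigned + unassigned + conflict must equal total")
  TRUE
})

#' Per-sample insertion-calling result
#'
#' @slot sample_id sample identifier.
#' @slot calls data.frame of detected hotspot insertions (columns
#'   `position0`, `inserted`, `hgvs`, `label`, `supporting_reads`, `depth`,
#'   `vaf`, `pass`), sorted by VAF descending.
#' @slot depth hotspot-spanning read count (the VAF denominator).
#' @slot n_reads merged reads given to the caller.
#' @slot n_unalignable reads failing the alignment mismatch floor.
#' @slot n_wildtype reads supporting no hotspot insertion.
#' @slot status `"ok"` or `"no coverage"`.
#' @export
setClass("SampleCallResult",
  representation(sample_id = "character", calls = "data.frame",
                 depth = "integer", n_reads = "integer",
                 n_unalignable = "integer", n_wildtype = "integer",
                 status = "character"))

#' Validation experiment summary
#'
#' @slot lob_vaf limit of blank in VAF units.
#' @slot lod_fraction limit of detection (mutant fraction), `NA` if not reached.
#' @slot blank_vafs per-blank background VAFs.
#' @slot detection per-dilution detection table.
#' @slot lod_reached logical.
#' @export
setClass("ValidationReport",
  representation(lob_vaf = "numeric", lod_fraction = "numeric",
                 blank_vafs = "numeric", detection = "data.frame",
                 lod_reached = "logical"))

#' Run-level QC state
#'
#' @slot demux [DemuxReport-class] for the run.
#' @slot control_pass did the 20-nt bioinformatics control verify?
#' @slot control_detail human-readable control verdict.
#' @slot merge_rates named numeric vector, per-sample merge rates.
#' @export
setClass("RunQC",
  representation(demux = "DemuxReport", control_pass = "logical",
                 control_detail = "character", merge_rates = "numeric"))
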