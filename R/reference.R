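#' Construct an AmpliconReference
#'
#' @param name reference name.
#' @param sequence uppercase DNA string (A/C/G/T).
#' @param hotspot integer `c(start, end)`, half-open 0-based window where
#'   exon-12 insertions are expected.
#' @param coding_offset integer; cDNA coordinate of amplicon position `p`
#'   (0-based) is `p + coding_offset`.
#' @return An [AmpliconReference-class] object.
#' @examples
#' ref <- npm1Amplicon()
#' hotspot(ref)
#' @export
AmpliconReference <- function(name, sequence, hotspot, coding_offset) {
  new("AmpliconReference", name = as.character(name),
      sequence = toupper(as.character(sequence)),
      hotspot = as.integer(hotspot), codingOffset = as.integer(coding_offset))
}

#' Read an amplicon reference from FASTA plus sidecar TSV
#'
#' The FASTA must contain a single record; the sidecar is a two-column
#' key/value TSV with keys `hotspot_start`, `hotspot_end`, `coding_offset`.
#'
#' @param fasta path to a single-record FASTA file.
#' @param sidecar path to the sidecar TSV.
#' @return An [AmpliconReference-class].
#' @export
readAmpliconReference <- function(fasta, sidecar) {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1L) stop("reference FASTA must contain exactly one record")
  kv <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
  val <- function(k) {
    i <- match(k, kv$key)
    if (is.na(i)) stop("sidecar is missing key '", k, "'")
    as.integer(kv$value[i])
  }
  AmpliconReference(name = sub("\\s.*", "", names(ss)[1]),
                    sequence = as.character(ss[[1]]),
                    hotspot = c(val("hotspot_start"), val("hotspot_end")),
                    coding_offset = val("coding_offset"))
}

#' The packaged synthetic NPM1 exon-12 amplicon
#'
#' A 250-nt synthetic stand-in for the NPM1 exon-12 amplicon (the assay is
#' parameterized by [AmpliconReference-class], so a real amplicon can be
#' dropped in). Hotspot window `[105, 135)`, coding offset 753, so the
#' common insertion gap c.863_864 sits at amplicon gap position 111.
#'
#' @return An [AmpliconReference-class].
#' @export
npm1Amplicon <- function() {
  readAmpliconReference(
    system.file("extdata", "npm1_amplicon_synthetic.fasta", package = "npm1mrd"),
    system.file("extdata", "npm1_amplicon_synthetic.tsv", package = "npm1mrd"))
}

#' @rdname accessors
#' @param x an object.
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))
#' Accessors for package classes
#'
#' `refSequence`, `hotspot` and `codingOffset` expose the
#' [AmpliconReference-class] slots; `insPosition` and `insSequence` the
#' [InsertionSpec-class] slots; `catalogEntries` and `catalogLabels` the
#' [MutationCatalog-class] contents; `sampleCalls` the call table of a
#' [SampleCallResult-class].
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("refSequence", "AmpliconReference", function(x) x@sequence)

#' @rdname accessors
#' @export
setGeneric("hotspot", function(x) standardGeneric("hotspot"))
#' @rdname accessors
#' @export
setMethod("hotspot", "AmpliconReference", function(x) x@hotspot)

#' @rdname accessors
#' @export
setGeneric("codingOffset", function(x) standardGeneric("codingOffset"))
#' @rdname accessors
#' @export
setMethod("codingOffset", "AmpliconReference", function(x) x@codingOffset)

setMethod("show", "AmpliconReference", function(object) {
  cat("AmpliconReference '", object@name, "': ", nchar(object@sequence),
      " nt, hotspot [", object@hotspot[1], ", ", object@hotspot[2],
      "), coding offset ", object@codingOffset, "\n", sep = "")
})

#' Construct an InsertionSpec
#'
#' @param position0 0-based gap position in amplicon coordinates: the
#'   insertion falls between positions `position0 - 1` and `position0`.
#' @param inserted DNA string of inserted bases.
#' @return An [InsertionSpec-class].
#' @examples
#' InsertionSpec(111, "TCTG")
#' @export
InsertionSpec <- function(position0, inserted) {
  new("InsertionSpec", position0 = as.integer(position0),
      inserted = toupper(as.character(inserted)))
}

#' @rdname accessors
#' @export
setGeneric("insPosition", function(x) standardGeneric("insPosition"))
#' @rdname accessors
#' @export
setMethod("insPosition", "InsertionSpec", function(x) x@position0)

#' @rdname accessors
#' @export
setGeneric("insSequence", function(x) standardGeneric("insSequence"))
#' @rdname accessors
#' @export
setMethod("insSequence", "InsertionSpec", function(x) x@inserted)

setMethod("show", "InsertionSpec", function(object) {
  cat("InsertionSpec: +", object@inserted, " at gap ", object@position0,
      " (0-based)\n", sep = "")
})

#' Apply an insertion to the reference sequence
#'
#' Returns the mutant haplotype: the reference with `inserted` spliced in
#' at the spec's gap position. Left-normalized and non-normalized
#' representations of the same event yield identical strings.
#'
#' @param ref an [AmpliconReference-class].
#' @param spec an [InsertionSpec-class].
#' @return A character string.
#' @export
applyInsertion <- function(ref, spec) {
  s <- refSequence(ref)
  p <- insPosition(spec)
  if (p < 0L || p > nchar(s)) stop("insertion position outside the amplicon")
  paste0(substr(s, 1L, p), insSequence(spec), substr(s, p + 1L, nchar(s)))
}

#' Parse an HGVS-style insertion
#'
#' Accepts `c.<a>_<b>ins<BASES>` where `b == a + 1`; the amplicon gap
#' position is recovered through the reference's coding offset.
#'
#' @param x HGVS string, e.g. `"c.873_874insGCCA"`.
#' @param ref an [AmpliconReference-class].
#' @return An [InsertionSpec-class].
#' @examples
#' spec <- parseHgvs("c.873_874insGCCA", npm1Amplicon())
#' insSequence(spec)  # "GCCA"
#' @export
parseHgvs <- function(x, ref) {
  stopifnot(length(x) == 1L)
  m <- regmatches(x, regexec("^c\\.([0-9]+)_([0-9]+)ins([ACGTacgt]+)$", x))[[1]]
  if (length(m) == 0L)
    stop("malformed HGVS insertion '", x,
         "': expected c.<int>_<int>ins<DNA>")
  a <- as.integer(m[2]); b <- as.integer(m[3])
  if (b != a + 1L)
    stop("malformed HGVS insertion '", x, "': coordinates ", a, " and ", b,
         " are not consecutive")
  pos0 <- a - codingOffset(ref) + 1L
  if (pos0 < 0L || pos0 > nchar(refSequence(ref)))
    stop("HGVS coordinates of '", x, "' fall outside the amplicon")
  InsertionSpec(pos0, toupper(m[4]))
}

#' Format an InsertionSpec as HGVS
#'
#' Inverse of [parseHgvs()]: `parseHgvs(hgvs(spec, ref), ref)` recovers
#' `spec`.
#'
#' @param spec an [InsertionSpec-class].
#' @param ref an [AmpliconReference-class].
#' @return HGVS string `c.<a>_<a+1>ins<BASES>`.
#' @export
hgvs <- function(spec, ref) {
  a <- insPosition(spec) - 1L + codingOffset(ref)
  sprintf("c.%d_%dins%s", a, a + 1L, insSequence(spec))
}

#' Left-normalize an insertion (VCF-style left alignment)
#'
#' Shifts the insertion maximally left: while the last inserted base equals
#' the reference base immediately left of the gap, the inserted string is
#' rotated right and the gap moves one base left. Equivalent indel
#' representations therefore collapse to a single canonical spec;
#' `applyInsertion` is invariant under normalization.
#'
#' @param spec an [InsertionSpec-class].
#' @param ref an [AmpliconReference-class].
#' @return The normalized [InsertionSpec-class].
#' @export
leftNormalize <- function(spec, ref) {
  s <- refSequence(ref)
  if (insPosition(spec) > nchar(s)) stop("insertion position outside the amplicon")
  pos <- insPosition(spec)
  ins <- insSequence(spec)
  k <- nchar(ins)
  while (pos > 0L && substr(s, pos, pos) == substr(ins, k, k)) {
    ins <- paste0(substr(s, pos, pos), substr(ins, 1L, k - 1L))
    pos <- pos - 1L
  }
  InsertionSpec(pos, ins)
}

#' Construct a MutationCatalog
#'
#' Entries are left-normalized on construction; labels and normalized
#' (position, bases) pairs must be unique.
#'
#' @param labels character vector of entry labels.
#' @param hgvs_strings HGVS insertion strings, parallel to `labels`.
#' @param ref an [AmpliconReference-class].
#' @return A [MutationCatalog-class].
#' @export
MutationCatalog <- function(labels, hgvs_strings, ref) {
  stopifnot(length(labels) == length(hgvs_strings))
  specs <- lapply(hgvs_strings, function(h) leftNormalize(parseHgvs(h, ref), ref))
  entries <- data.frame(
    label = as.character(labels),
    hgvs = as.character(hgvs_strings),
    position0 = vapply(specs, insPosition, integer(1)),
    inserted = vapply(specs, insSequence, character(1)),
    stringsAsFactors = FALSE)
  new("MutationCatalog", entries = entries)
}

#' Read a mutation catalog from TSV
#'
#' @param path TSV with columns `label` and `hgvs`.
#' @param ref an [AmpliconReference-class].
#' @return A [MutationCatalog-class].
#' @export
readMutationCatalog <- function(path, ref) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "hgvs") %in% names(tab)))
    stop("catalog TSV must have columns 'label' and 'hgvs'")
  MutationCatalog(tab$label, tab$hgvs, ref)
}

#' The packaged NPM1 insertion-type catalog
#'
#' Twelve 4-nt exon-12 insertion types: type A/B/D (insTCTG, insCATG,
#' insCCTG by literature convention), the c.873_874insGCCA insertion, and
#' eight synthetic fixture entries. Positions refer to the packaged
#' synthetic amplicon.
#'
#' @param ref an [AmpliconReference-class]; defaults to [npm1Amplicon()].
#' @return A [MutationCatalog-class] with 12 entries.
#' @export
npm1Catalog <- function(ref = npm1Amplicon()) {
  readMutationCatalog(
    system.file("extdata", "npm1_catalog.tsv", package = "npm1mrd"), ref)
}

#' @rdname accessors
#' @export
setGeneric("catalogEntries", function(x) standardGeneric("catalogEntries"))
#' @rdname accessors
#' @export
setMethod("catalogEntries", "MutationCatalog", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("catalogLabels", function(x) standardGeneric("catalogLabels"))
#' @rdname accessors
#' @export
setMethod("catalogLabels", "MutationCatalog", function(x) x@entries$label)

setMethod("show", "MutationCatalog", function(object) {
  cat("MutationCatalog with", nrow(object@entries), "entries\n")
  print(utils::head(object@entries, 12L))
})

setMethod("length", "MutationCatalog", function(x) nrow(x@entries))

#' Classify a (left-normalized) insertion against the catalog
#'
#' Pure lookup on the normalized `(position0, inserted)` pair; anything
#' absent from the catalog is `"novel"`. The spec is normalized internally
#' so callers may pass unnormalized representations.
#'
#' @param spec an [InsertionSpec-class].
#' @param catalog a [MutationCatalog-class].
#' @param ref an [AmpliconReference-class] (used to normalize `spec`).
#' @return The catalog label, or `"novel"`.
#' @export
classifyInsertion <- function(spec, catalog, ref) {
  spec <- leftNormalize(spec, ref)
  e <- catalogEntries(catalog)
  i <- which(e$position0 == insPosition(spec) & e$inserted == insSequence(spec))
  if (length(i)) e$label[i[1]] else "novel"
}

#' The run-level bioinformatics control insertion
#'
#' A fixed 20-nt insertion at the hotspot gap, spiked into every simulated
#' run on a reserved index pair; recovering it end-to-end verifies that
#' demultiplexing, merging and calling work.
#'
#' @return An [InsertionSpec-class] with a 20-nt insert.
#' @export
bioinfControlInsertion <- function() {
  InsertionSpec(111L, "ACTGGTCAAGCTTGACCAGA")
}
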