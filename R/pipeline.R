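## End-to-end orchestration: demultiplex -> merge -> call per sample, plus
## run-level QC (demux tallies, bioinformatics-control verdict).

#' Process a multiplexed sequencing run end to end
#'
#' Demultiplexes by dual indices, self-assembles each sample's read pairs,
#' calls hotspot insertions per sample, and verifies the bioinformatics
#' control when present. A failed control aborts downstream MRD reporting:
#' the per-sample results are still returned for audit, but
#' `qc@control_pass` is `FALSE`.
#'
#' @param reads a multiplexed [PairedReads-class], or an R1 FASTQ path
#'   (then give `r2_path`).
#' @param sheet sample sheet data.frame (`sample_id`, `i7`, `i5`).
#' @param ref an [AmpliconReference-class].
#' @param catalog a [MutationCatalog-class].
#' @param max_mismatch demultiplexing per-index mismatch tolerance.
#' @param min_mutant_reads pass-call support threshold (default 2).
#' @param control_id sample id of the bioinformatics control; set to
#'   `NA` to skip control verification.
#' @param r2_path optional R2 FASTQ path.
#' @param ... passed on to [callSample()].
#' @return list with `results` (named list of [SampleCallResult-class])
#'   and `qc` ([RunQC-class]).
#' @export
processRun <- function(reads, sheet, ref, catalog, max_mismatch = 1L,
                       min_mutant_reads = 2L, control_id = "BIOINF_CONTROL",
                       r2_path = NULL, ...) {
  dm <- demultiplex(reads, sheet, max_mismatch = max_mismatch,
                    r2_path = r2_path)
  merge_rates <- numeric(0)
  results <- list()
  for (sid in names(dm$samples)) {
    mr <- mergePairs(dm$samples[[sid]])
    merge_rates[sid] <- mergeRate(mr)
    results[[sid]] <- callSample(mr, ref, catalog,
                                 min_mutant_reads = min_mutant_reads,
                                 sample_id = sid, ...)
  }
  ctl <- if (is.na(control_id)) list(pass = NA, detail = "control not requested")
         else verifyBioinfControl(results, ref, control_id = control_id)
  qc <- new("RunQC", demux = dm$report,
            control_pass = as.logical(ctl$pass), control_detail = ctl$detail,
            merge_rates = merge_rates)
  list(results = results, qc = qc)
}

setMethod("show", "RunQC", function(object) {
  cat("RunQC: control",
      if (isTRUE(object@control_pass)) "PASS"
      else if (isFALSE(object@control_pass)) "FAIL" else "not checked",
      paste0("(", object@control_detail, ")"), "\n")
  show(object@demux)
})
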