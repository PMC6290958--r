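## Patient-level MRD determination: log reduction between post-induction
## (PI) and post-consolidation (PC) VAFs, positive/negative classification
## against a cutoff (assay default: 1 log), and ROC/Youden re-derivation
## of the cutoff on cohorts with outcome labels.

#' Log reduction between PI and PC VAFs
#'
#' `log10(vaf_pi / vaf_pc)` when both are positive. Sentinels: PC = 0
#' with PI > 0 is maximal clearance (+Inf); PI = 0 with PC > 0 is -Inf;
#' both zero yields NaN, which downstream classification always treats as
#' MRD-negative (the assay's both-zero rule). Scale-invariant:
#' `logReduction(a*k, b*k) == logReduction(a, b)` for `k > 0`.
#'
#' @param vaf_pi,vaf_pc non-negative VAFs (vectorized).
#' @return numeric vector of log reductions (may contain `Inf`, `-Inf`,
#'   `NaN`).
#' @examples
#' logReduction(0.05, 0.005)  # 1
#' logReduction(0, 0)         # NaN -> classified negative
#' @export
logReduction <- function(vaf_pi, vaf_pc) {
  if (any(vaf_pi < 0, na.rm = TRUE) || any(vaf_pc < 0, na.rm = TRUE))
    stop("VAFs must be non-negative")
  out <- suppressWarnings(log10(vaf_pi / vaf_pc))
  out[vaf_pi > 0 & vaf_pc == 0] <- Inf
  out[vaf_pi == 0 & vaf_pc > 0] <- -Inf
  out[vaf_pi == 0 & vaf_pc == 0] <- NaN
  out
}

#' Classify patients as MRD positive or negative
#'
#' A patient is NGS-MRD positive iff the PI-to-PC log reduction is below
#' the cutoff (assay default 1 log). `+Inf` (full clearance) is negative;
#' both-zero patients (NaN) are negative by the assay rule. Raising the
#' cutoff can only move patients from negative to positive (monotone).
#'
#' @param patients data.frame with columns `patient_id`, `vaf_pi`,
#'   `vaf_pc` (VAF units, `[0, 1]`).
#' @param cutoff log-reduction cutoff (> 0; default 1).
#' @return data.frame: `patient_id`, `vaf_pi`, `vaf_pc`, `log_reduction`,
#'   `classification` (`"positive"`/`"negative"`).
#' @examples
#' pts <- data.frame(patient_id = c("p1", "p2", "p3"),
#'                   vaf_pi = c(0.05, 0.04, 0), vaf_pc = c(0.02, 0.0004, 0))
#' classifyMRD(pts)
#' @export
classifyMRD <- function(patients, cutoff = 1) {
  stopifnot(cutoff > 0)
  need <- c("patient_id", "vaf_pi", "vaf_pc")
  if (!all(need %in% names(patients)))
    stop("patients table needs columns patient_id, vaf_pi, vaf_pc")
  if (any(patients$vaf_pi > 1 | patients$vaf_pc > 1, na.rm = TRUE))
    stop("VAFs must lie in [0, 1]")
  lr <- logReduction(patients$vaf_pi, patients$vaf_pc)
  pos <- !is.nan(lr) & lr < cutoff
  data.frame(patient_id = patients$patient_id,
             vaf_pi = patients$vaf_pi, vaf_pc = patients$vaf_pc,
             log_reduction = lr,
             classification = ifelse(pos, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' ROC / Youden-index cutoff selection
#'
#' Re-derives a log-reduction cutoff on a cohort with binary outcome
#' labels (1 = event, e.g. death or relapse; low log reduction predicts
#' the event). Candidate thresholds are the midpoints between consecutive
#' distinct finite log reductions plus `-Inf`/`+Inf` sentinels; at each
#' threshold t a patient is test-positive iff their log reduction is
#' `< t` (NaN, the both-zero case, is never positive). The returned
#' threshold maximizes Youden's J = sensitivity + specificity - 1, ties
#' broken toward higher sensitivity and then toward the lower threshold.
#'
#' @param log_reduction numeric vector (may contain `Inf`, `-Inf`, `NaN`).
#' @param outcome binary vector (1 = event) parallel to `log_reduction`.
#' @return list with `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`, and the full `roc` table for audit.
#' @export
youdenCutoff <- function(log_reduction, outcome) {
  stopifnot(length(log_reduction) == length(outcome))
  outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L))) stop("outcome must be binary 0/1")
  if (sum(outcome == 1L) == 0L || sum(outcome == 0L) == 0L)
    stop("need at least one event and one non-event")
  fin <- sort(unique(log_reduction[is.finite(log_reduction)]))
  # midpoints between consecutive distinct finite values, plus sentinels
  # just outside the finite range (so "-Inf patients only" and "all finite
  # patients" are both achievable) and the +/-Inf extremes
  thr <- c(-Inf,
           if (length(fin) >= 1L) fin[1] - 1,
           if (length(fin) >= 2L) (fin[-1] + fin[-length(fin)]) / 2,
           if (length(fin) >= 1L) fin[length(fin)] + 1,
           Inf)
  thr <- unique(thr)
  roc <- do.call(rbind, lapply(thr, function(t) {
    pos <- !is.nan(log_reduction) & log_reduction < t
    data.frame(threshold = t,
               sensitivity = mean(pos[outcome == 1L]),
               specificity = mean(!pos[outcome == 0L]))
  }))
  roc$youden_j <- roc$sensitivity + roc$specificity - 1
  ord <- order(-roc$youden_j, -roc$sensitivity, roc$threshold)
  best <- roc[ord[1], ]
  list(threshold = best$threshold, sensitivity = best$sensitivity,
       specificity = best$specificity, youden_j = best$youden_j, roc = roc)
}

#' Read a patient table
#'
#' @param path TSV with columns `patient_id`, `vaf_pi`, `vaf_pc` and
#'   optionally `outcome` (binary, for cutoff training).
#' @return data.frame.
#' @export
readPatientTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "vaf_pi", "vaf_pc")
  if (!all(need %in% names(tab)))
    stop("patient table needs columns patient_id, vaf_pi, vaf_pc")
  tab
}
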