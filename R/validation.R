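## Assay validation statistics: nonparametric limit of blank over a blank
## cohort, hit-rate limit of detection over a dilution series, and
## Levey-Jennings monitoring of the run precision controls.

#' Limit of blank (nonparametric)
#'
#' The empirical `1 - alpha` quantile of the blank background VAFs,
#' computed by the rank-position convention used for clinical assays:
#' rank `r = 0.5 + n * (1 - alpha)` with linear interpolation between
#' order statistics (clamped to `[1, n]`). When every blank is zero the
#' LOB is 0; with `alpha = 0` it is the maximum blank value.
#'
#' @param blank_vafs numeric vector of per-blank background VAFs (>= 2).
#' @param alpha type-I error level (default 0.05, i.e. the 95th percentile).
#' @return LOB in VAF units.
#' @examples
#' limitOfBlank(rep(0, 30))          # 0
#' limitOfBlank(c(rep(0, 29), 2e-5)) # order-statistic 95th percentile
#' @export
limitOfBlank <- function(blank_vafs, alpha = 0.05) {
  n <- length(blank_vafs)
  if (n < 2L) stop("limit of blank requires at least 2 blanks")
  if (any(blank_vafs < 0)) stop("blank VAFs must be non-negative")
  if (all(blank_vafs == 0)) return(0)
  x <- sort(blank_vafs)
  r <- 0.5 + n * (1 - alpha)
  r <- min(max(r, 1), n)
  lo <- floor(r); hi <- ceiling(r)
  x[lo] + (r - lo) * (x[hi] - x[lo])
}

#' Limit of detection from a dilution series
#'
#' The smallest mutant fraction whose detection proportion is at least
#' `required_hit_rate` and whose detected replicates' measured VAFs all
#' exceed the LOB. Detection means a pass call of the spiked mutation.
#' A decreasing detection proportion at higher fractions is not assumed
#' (sampling noise) but is flagged with a warning when observed.
#'
#' @param detection data.frame with columns `fraction`, `detected`
#'   (logical) and `vaf` (measured VAF, 0 when undetected); one row per
#'   replicate.
#' @param lob limit of blank in VAF units (default 0).
#' @param required_hit_rate minimum detection proportion (default 0.95).
#' @return list with `lod_fraction` (`NA` when not reached), `reached`,
#'   and `table` (per-fraction summary: replicates, detected, hit_rate,
#'   qualifies).
#' @export
limitOfDetection <- function(detection, lob = 0, required_hit_rate = 0.95) {
  need <- c("fraction", "detected", "vaf")
  if (!all(need %in% names(detection)))
    stop("detection table needs columns fraction, detected, vaf")
  fr <- sort(unique(detection$fraction), decreasing = TRUE)
  if (length(fr) < 2L) stop("need at least 2 dilution levels")
  tab <- do.call(rbind, lapply(fr, function(f) {
    d <- detection[detection$fraction == f, , drop = FALSE]
    data.frame(fraction = f, replicates = nrow(d), detected = sum(d$detected),
               hit_rate = mean(d$detected),
               qualifies = mean(d$detected) >= required_hit_rate &&
                 all(d$vaf[d$detected] > lob))
  }))
  if (is.unsorted(rev(tab$hit_rate)))
    warning("detection proportion is not non-increasing with dilution; ",
            "inspect the series (sampling noise or assay failure)")
  ok <- tab$fraction[tab$qualifies]
  list(lod_fraction = if (length(ok)) min(ok) else NA_real_,
       reached = length(ok) > 0L, table = tab)
}

#' Packaged run precision-control configurations
#'
#' The high and low precision controls emulate a type A mutant cell line
#' diluted in normal DNA at 0.2% and 0.02% VAF respectively, assayed in
#' every run to monitor systemic drift. 50,000 error-free fragments by
#' default.
#'
#' @param level `"high"` (0.2% VAF) or `"low"` (0.02% VAF).
#' @param seed RNG seed for the control sample.
#' @param n_fragments fragments to simulate (default 50000).
#' @param ref an [AmpliconReference-class] (for the type A insertion spec).
#' @return A [SimConfig-class].
#' @export
controlConfig <- function(level = c("high", "low"), seed = 1L,
                          n_fragments = 50000L, ref = npm1Amplicon()) {
  level <- match.arg(level)
  frac <- if (level == "high") 0.002 else 0.0002
  SimConfig(paste0("precision_", level), seed = seed,
            n_fragments = n_fragments, mutant_fraction = frac,
            mutation = parseHgvs("c.863_864insTCTG", ref),
            sub_error_rate = 0, indel_error_rate = 0)
}

#' Levey-Jennings monitoring of one precision-control series
#'
#' The first `baseline_n` runs establish the control limits (their mean
#' and SD) and are in-control by definition; each later run is judged
#' against those limits: beyond +/-2 SD is a warning, beyond +/-3 SD or
#' the second of two consecutive same-side warnings is a failure. A
#' missing measurement (NA) fails that run. With zero baseline SD (all
#' baseline values identical), a value equal to the mean is in-control
#' and anything else fails.
#'
#' @param vafs run-indexed control VAF measurements.
#' @param baseline_n baseline run count (default 5).
#' @return character vector of verdicts in
#'   `c("in-control", "warn", "fail")`, one per run.
#' @export
monitorPrecision <- function(vafs, baseline_n = 5L) {
  n <- length(vafs)
  verdict <- rep("in-control", n)
  verdict[is.na(vafs)] <- "fail"
  if (n <= baseline_n) return(verdict)
  side <- rep(0L, n)  # -1 below / +1 above, for consecutive-warn tracking
  base <- vafs[seq_len(baseline_n)]
  base <- base[!is.na(base)]
  mu <- mean(base); sdv <- stats::sd(base)
  for (i in (baseline_n + 1L):n) {
    if (is.na(vafs[i])) { verdict[i] <- "fail"; next }
    if (is.na(sdv) || sdv == 0) {
      if (vafs[i] != mu) verdict[i] <- "fail"
      next
    }
    z <- (vafs[i] - mu) / sdv
    if (abs(z) > 3) {
      verdict[i] <- "fail"
    } else if (abs(z) > 2) {
      verdict[i] <- "warn"
      side[i] <- sign(z)
      if (i > 1L && side[i - 1L] == side[i]) verdict[i] <- "fail"
    }
  }
  verdict
}

#' Monitor both precision controls of a run series
#'
#' @param series data.frame with columns `run`, `level` (`"high"`/`"low"`)
#'   and `vaf`; every run must supply both levels (a missing level fails
#'   that run).
#' @param baseline_n baseline run count per level.
#' @return data.frame `run`, `high`, `low`, `run_verdict` (worst of the two).
#' @export
monitorControls <- function(series, baseline_n = 5L) {
  runs <- sort(unique(series$run))
  get <- function(lv) {
    v <- rep(NA_real_, length(runs))
    d <- series[series$level == lv, , drop = FALSE]
    v[match(d$run, runs)] <- d$vaf
    v
  }
  high <- monitorPrecision(get("high"), baseline_n)
  low <- monitorPrecision(get("low"), baseline_n)
  rank <- c(`in-control` = 1L, warn = 2L, fail = 3L)
  worst <- ifelse(rank[high] >= rank[low], high, low)
  data.frame(run = runs, high = high, low = low, run_verdict = worst,
             stringsAsFactors = FALSE)
}

#' Build a ValidationReport
#'
#' Convenience wrapper combining [limitOfBlank()] and [limitOfDetection()].
#'
#' @param blank_vafs per-blank background VAFs.
#' @param detection dilution-series detection table (see
#'   [limitOfDetection()]).
#' @param alpha LOB level.
#' @param required_hit_rate LOD hit-rate requirement.
#' @return A [ValidationReport-class].
#' @export
validationReport <- function(blank_vafs, detection, alpha = 0.05,
                             required_hit_rate = 0.95) {
  lob <- limitOfBlank(blank_vafs, alpha)
  lod <- limitOfDetection(detection, lob, required_hit_rate)
  new("ValidationReport", lob_vaf = lob,
      lod_fraction = lod$lod_fraction, blank_vafs = as.numeric(blank_vafs),
      detection = lod$table, lod_reached = lod$reached)
}

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport: LOB =", signif(object@lob_vaf, 4), "VAF;",
      "LOD =", if (object@lod_reached) signif(object@lod_fraction, 4)
               else "not reached", "\n")
  print(object@detection)
})
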