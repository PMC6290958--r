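ref <- npm1Amplicon()
cat12 <- npm1Catalog(ref)
typeA <- parseHgvs("c.863_864insTCTG", ref)

test_that("limit of blank follows the order-statistic convention", {
  expect_identical(limitOfBlank(rep(0, 30)), 0)
  # one nonzero of 30 at the default alpha: rank 0.5 + 30*0.95 = 29 -> x(29) = 0
  x <- c(rep(0, 29), 2e-5)
  expect_identical(limitOfBlank(x), 0)
  # alpha = 0.01: rank 30.2 clamps to 30 -> the nonzero maximum
  expect_identical(limitOfBlank(x, alpha = 0.01), 2e-5)
  # interpolation between order statistics: rank 0.5 + 10*0.9 = 9.5
  y <- c(rep(0, 8), 1e-5, 3e-5)
  expect_equal(limitOfBlank(y, alpha = 0.1), 2e-5)
  # alpha = 0 -> maximum blank value
  expect_identical(limitOfBlank(x, alpha = 0), 2e-5)
  expect_error(limitOfBlank(1e-5), "at least 2")
})

test_that("LOB is monotone: adding a larger blank never lowers it", {
  set.seed(31)
  for (k in 1:20) {
    x <- stats::rexp(sample(5:40, 1), rate = 1e5)
    base <- limitOfBlank(x)
    expect_gte(limitOfBlank(c(x, max(x) * 2)), base)
  }
})

test_that("a noise-free blank cohort yields zero background and LOB 0", {
  tmpl <- SimConfig("blank", 1, 2000, 0, NULL, sub_error_rate = 1e-3,
                    indel_error_rate = 0)
  ch <- simulateBlankCohort(8, tmpl, ref, seed = 12)
  vafs <- vapply(ch$samples, function(s)
    backgroundVaf(callSample(mergePairs(s$reads), ref, cat12)), numeric(1))
  expect_true(all(vafs == 0))  # no indel error process, no insertion calls
  expect_identical(limitOfBlank(vafs), 0)
})

test_that("blank background stays within the error-process expectation", {
  # with a 1e-4 indel error rate the per-sample background VAF is bounded
  # by a few times the per-read hotspot indel rate
  tmpl <- SimConfig("blank", 1, 5000, 0, NULL, sub_error_rate = 0,
                    indel_error_rate = 1e-4)
  ch <- simulateBlankCohort(6, tmpl, ref, seed = 29)
  vafs <- vapply(ch$samples, function(s)
    backgroundVaf(callSample(mergePairs(s$reads), ref, cat12)), numeric(1))
  # ~300 sequenced nt per merged read, hotspot ~30/250 of the amplicon:
  # background insertion VAF per sample far below 3 * 300 * 1e-4
  expect_true(all(vafs <= 3 * 300 * 1e-4))
})

test_that("limit of detection is the smallest qualifying fraction", {
  det <- data.frame(
    fraction = rep(c(1e-3, 1e-4, 1e-5), each = 3),
    detected = c(rep(TRUE, 6), TRUE, FALSE, FALSE),
    vaf = c(rep(1e-3, 3), rep(1e-4, 3), 1e-5, 0, 0))
  lod <- limitOfDetection(det, lob = 0)
  expect_true(lod$reached)
  expect_identical(lod$lod_fraction, 1e-4)
  # a single fully detected level qualifies on its own
  det2 <- data.frame(fraction = rep(c(1e-3, 1e-4), each = 2),
                     detected = c(TRUE, TRUE, FALSE, FALSE),
                     vaf = c(1e-3, 1e-3, 0, 0))
  expect_identical(limitOfDetection(det2, lob = 0)$lod_fraction, 1e-3)
  # nothing qualifies -> not reached, table attached
  det3 <- data.frame(fraction = c(1e-3, 1e-4), detected = c(FALSE, FALSE),
                     vaf = c(0, 0))
  lod3 <- limitOfDetection(det3, lob = 0)
  expect_false(lod3$reached)
  expect_true(is.na(lod3$lod_fraction))
  expect_identical(nrow(lod3$table), 2L)
  # VAFs at or below LOB disqualify a level
  det4 <- data.frame(fraction = rep(c(1e-3, 1e-4), each = 1),
                     detected = c(TRUE, TRUE), vaf = c(1e-3, 1e-4))
  expect_identical(limitOfDetection(det4, lob = 5e-4)$lod_fraction, 1e-3)
  expect_error(limitOfDetection(det4[1, ], lob = 0), "2 dilution levels")
})

test_that("with no indel errors LOD lands where Poisson sampling predicts", {
  # depth 1e5: expected mutant reads are 100 / 10 / 1 at 1e-3 / 1e-4 / 1e-5.
  # P(X >= 2) is ~1 at 1e-3 and 1e-4 but only 0.26 at 1e-5, so the
  # detected limit should be 1e-4 (full pipeline, fixed seed).
  ds <- simulateDilutionSeries(c(1e-3, 1e-4, 1e-5), depth = 1e5,
                               mutation = typeA, ref = ref, seed = 21,
                               sub_error_rate = 0, indel_error_rate = 0)
  det <- do.call(rbind, lapply(ds$configs, function(cfg) {
    res <- callSample(mergePairs(simulateSample(cfg, ref)$reads), ref, cat12,
                      sample_id = cfg@sample_id)
    hit <- mutationVaf(res, typeA, ref)
    data.frame(fraction = cfg@mutant_fraction, detected = hit$detected,
               vaf = hit$vaf)
  }))
  lod <- suppressWarnings(limitOfDetection(det, lob = 0))
  expect_identical(lod$lod_fraction, 1e-4)
})

test_that("Levey-Jennings verdicts follow the 2SD/3SD and repeat-warn rules", {
  # all runs exactly at nominal: in-control throughout (zero-SD branch)
  expect_true(all(monitorPrecision(rep(0.002, 10)) == "in-control"))
  # a single extreme excursion fails
  base <- c(0.0019, 0.0021, 0.002, 0.0018, 0.0022)
  mu <- mean(base); s <- stats::sd(base)
  v <- monitorPrecision(c(base, mu + 3.5 * s))
  expect_identical(v[6], "fail")
  # a 2-3 SD excursion warns; the second consecutive same-side warn fails
  v2 <- monitorPrecision(c(base, mu + 2.5 * s))
  expect_identical(v2[6], "warn")
  v3 <- monitorPrecision(c(base, mu + 2.5 * s, mu + 2.5 * s))
  expect_identical(v3[7], "fail")
  # a missing measurement fails that run
  expect_identical(monitorPrecision(c(base, NA))[6], "fail")
})

test_that("binomial sampling noise alone keeps most runs in control", {
  # precision controls at depth 50,000: per-run VAF = Binomial draw / depth
  in_control <- vapply(1:5, function(s) {
    set.seed(s)
    vafs <- stats::rbinom(12, 50000, 0.002) / 50000
    mean(monitorPrecision(vafs) == "in-control")
  }, numeric(1))
  expect_gte(mean(in_control), 0.9)
})

test_that("both precision-control levels must be present in every run", {
  series <- data.frame(run = rep(1:6, each = 2),
                       level = rep(c("high", "low"), 6),
                       vaf = rep(c(0.002, 0.0002), 6))
  series <- series[-12, ]  # drop the low control of run 6
  out <- monitorControls(series)
  expect_identical(out$run_verdict[6], "fail")
  expect_true(all(out$run_verdict[1:5] == "in-control"))
})

test_that("validationReport combines LOB and LOD", {
  det <- data.frame(fraction = rep(c(1e-3, 1e-4), each = 2),
                    detected = TRUE, vaf = rep(c(1e-3, 1e-4), each = 2))
  rep_ <- validationReport(rep(0, 30), det)
  expect_s4_class(rep_, "ValidationReport")
  expect_identical(rep_@lob_vaf, 0)
  expect_identical(rep_@lod_fraction, 1e-4)
  expect_true(rep_@lod_reached)
})
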