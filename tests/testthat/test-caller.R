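ref <- npm1Amplicon()
cat12 <- npm1Catalog(ref)
typeA <- parseHgvs("c.863_864insTCTG", ref)

test_that("a read identical to the reference aligns with no insertions", {
  a <- alignRead(refSequence(ref), ref)
  expect_true(a$aligned)
  expect_identical(a$n_mismatches, 0L)
  expect_identical(nrow(a$insertions), 0L)
  expect_identical(a$score, nchar(refSequence(ref)))
})

test_that("the GCCA insertion is recovered exactly from its mutant haplotype", {
  gcca <- parseHgvs("c.873_874insGCCA", ref)
  a <- alignRead(applyInsertion(ref, gcca), ref)
  expect_identical(nrow(a$insertions), 1L)
  expect_identical(a$insertions$inserted, "GCCA")
  expect_identical(a$insertions$position0, insPosition(leftNormalize(gcca, ref)))
})

test_that("random hotspot insertions are recovered as their normalized specs", {
  set.seed(202)
  hs <- hotspot(ref)
  n_ok <- 0L
  for (k in 1:200) {
    spec <- InsertionSpec(sample(hs[1]:(hs[2] - 1), 1), rand_dna(sample(1:12, 1)))
    truth <- leftNormalize(spec, ref)
    a <- alignRead(applyInsertion(ref, spec), ref)
    if (nrow(a$insertions) == 1L &&
        a$insertions$position0 == insPosition(truth) &&
        a$insertions$inserted == insSequence(truth)) n_ok <- n_ok + 1L
  }
  expect_identical(n_ok, 200L)  # 100% recovery on error-free mutants
})

test_that("banded alignment equals the unbanded full-DP oracle on short amplicons", {
  set.seed(7)
  for (k in 1:40) {
    x <- rand_dna(sample(40:60, 1))
    y <- x
    # random edits: substitutions and/or a small indel
    for (e in seq_len(sample(0:3, 1))) {
      p <- sample(nchar(y), 1)
      substr(y, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (runif(1) < 0.5) {
      p <- sample(nchar(y) - 1, 1)
      y <- paste0(substr(y, 1, p), rand_dna(sample(1:6, 1)),
                  substr(y, p + 1, nchar(y)))
    }
    got <- npm1mrd:::align_reads_cpp(y, x, band = 32L, hamming_shortcut = FALSE)
    expect_identical(got$score[1], as.integer(brute_align_score(x, y)))
  }
})

test_that("the hash fast path and Hamming shortcut are bit-identical to full DP", {
  cfg <- SimConfig("fp", 55, 4000, 0.05, typeA, sub_error_rate = 2e-3,
                   indel_error_rate = 1e-4)
  mr <- mergePairs(simulateSample(cfg, ref)$reads)
  fast <- callSample(mr, ref, cat12, sample_id = "fp", use_fast_path = TRUE)
  slow <- callSample(mr, ref, cat12, sample_id = "fp", use_fast_path = FALSE)
  expect_identical(sampleCalls(fast), sampleCalls(slow))
  expect_identical(fast@depth, slow@depth)
  expect_identical(fast@n_wildtype, slow@n_wildtype)
  # Hamming shortcut off at the aligner level
  useq <- unique(mr@sequence[mr@merged])
  a1 <- npm1mrd:::align_reads_cpp(useq, refSequence(ref), hamming_shortcut = TRUE)
  a2 <- npm1mrd:::align_reads_cpp(useq, refSequence(ref), hamming_shortcut = FALSE)
  expect_identical(a1, a2)
})

test_that("the pass rule requires at least min_mutant_reads supporting reads", {
  wt <- refSequence(ref)
  mut <- applyInsertion(ref, typeA)
  for (k in 0:3) {
    seqs <- c(rep(wt, 10000 - k), rep(mut, k))
    res <- callSample(seqs, ref, cat12, sample_id = paste0("t", k))
    calls <- sampleCalls(res)
    if (k == 0) {
      expect_identical(nrow(calls), 0L)
    } else {
      expect_identical(calls$supporting_reads, k)
      expect_identical(calls$pass, k >= 2L)
    }
  }
  # the threshold itself is configurable
  res3 <- callSample(c(rep(wt, 100), rep(mut, 2)), ref, cat12,
                     min_mutant_reads = 3L)
  expect_false(sampleCalls(res3)$pass)
})

test_that("VAF is exact counting on error-free input", {
  seqs <- c(rep(refSequence(ref), 9800), rep(applyInsertion(ref, typeA), 200))
  res <- callSample(seqs, ref, cat12, sample_id = "v")
  calls <- sampleCalls(res)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$vaf, 0.02)
  expect_identical(calls$label, "type A")
  expect_identical(res@depth, 10000L)
})

test_that("read accounting is conserved: supporting + wildtype + unalignable = input", {
  cfg <- SimConfig("acc", 91, 5000, 0.03, typeA, sub_error_rate = 5e-3,
                   indel_error_rate = 1e-4)
  mr <- mergePairs(simulateSample(cfg, ref)$reads)
  res <- callSample(mr, ref, cat12, sample_id = "acc")
  calls <- sampleCalls(res)
  # reads with >= 1 hotspot insertion; a read can support two distinct
  # insertions only via an extra indel error, absent among pass calls here
  expect_identical(res@depth + res@n_unalignable, res@n_reads)
  expect_gte(res@n_wildtype + sum(calls$supporting_reads), res@depth)
  expect_lte(res@n_wildtype, res@depth)
})

test_that("empty input and unalignable reads yield a no-coverage result", {
  res <- callSample(character(0), ref, cat12)
  expect_identical(res@status, "no coverage")
  expect_identical(nrow(sampleCalls(res)), 0L)
  # garbage reads: unalignable, excluded from depth
  set.seed(1)
  garbage <- vapply(1:5, function(i) rand_dna(250), character(1))
  res2 <- callSample(garbage, ref, cat12)
  expect_identical(res2@status, "no coverage")
  expect_identical(res2@n_unalignable, 5L)
})

test_that("multiple distinct insertions in one sample are all reported", {
  specB <- parseHgvs("c.863_864insCATG", ref)
  seqs <- c(rep(refSequence(ref), 900),
            rep(applyInsertion(ref, typeA), 60),
            rep(applyInsertion(ref, specB), 40))
  calls <- sampleCalls(callSample(seqs, ref, cat12))
  expect_identical(nrow(calls), 2L)
  expect_identical(calls$label, c("type A", "type B"))  # sorted by VAF desc
  expect_true(all(calls$pass))
})

test_that("the bioinformatics control verdict gates the run", {
  cfg <- SimConfig("s1", 61, 500, 0, NULL, sub_error_rate = 0,
                   indel_error_rate = 0)
  run <- simulateRun(list(cfg), ref, include_bioinf_control = TRUE, seed = 6)
  pr <- processRun(run$reads, run$sheet, ref, cat12)
  expect_true(pr$qc@control_pass)
  ctl_calls <- sampleCalls(pr$results$BIOINF_CONTROL)
  expect_identical(nchar(ctl_calls$inserted[ctl_calls$pass][1]), 20L)
  # control absent -> fail with "control missing"
  v <- verifyBioinfControl(pr$results["s1"], ref)
  expect_false(v$pass)
  expect_match(v$detail, "missing")
  # control corrupted below the support threshold -> fail
  wt <- refSequence(ref)
  ctl1 <- callSample(c(rep(wt, 500), applyInsertion(ref, bioinfControlInsertion())),
                     ref, cat12, sample_id = "BIOINF_CONTROL")
  expect_false(verifyBioinfControl(list(ctl1), ref)$pass)
})

test_that("call tables export to TSV and minimal VCF", {
  seqs <- c(rep(refSequence(ref), 500), rep(applyInsertion(ref, typeA), 25))
  res <- callSample(seqs, ref, cat12, sample_id = "ex")
  d <- withr::local_tempdir()
  tsv <- writeCallsTsv(res, file.path(d, "calls.tsv"))
  back <- utils::read.delim(tsv)
  expect_identical(back$supporting_reads, 25L)
  vcf <- writeCallsVcf(res, ref, file.path(d, "calls.vcf"))
  lines <- readLines(vcf)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_identical(length(body), 1L)
  f <- strsplit(body, "\t")[[1]]
  expect_identical(f[7], "PASS")
  expect_match(f[8], "SR=25;DP=525")
  # ALT = anchor + inserted bases
  expect_identical(substr(f[5], 2, 5), "TCTG")
})
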