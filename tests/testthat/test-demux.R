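ref <- npm1Amplicon()

mk_read <- function(i7, i5, id = "r1") {
  s <- substr(refSequence(ref), 1, 150)
  new("PairedReads", id = paste0(id, " ", i7, "+", i5),
      seq1 = s, qual1 = strrep("I", 150),
      seq2 = rc(s), qual2 = strrep("I", 150))
}

sheet2 <- data.frame(sample_id = c("s1", "s2"),
                     i7 = indexPairs(2)$i7, i5 = indexPairs(2)$i5,
                     stringsAsFactors = FALSE)

test_that("exact dual-index matches are assigned to their sample", {
  dm <- demultiplex(mk_read(sheet2$i7[1], sheet2$i5[1]), sheet2)
  expect_identical(unname(dm$report@assigned), c(1L, 0L))
  expect_identical(dm$report@conflict, 0L)
})

test_that("discordant dual indices are quarantined as conflicts", {
  # i7 of sample 1 with i5 of sample 2: the contamination case dual
  # indexing exists to stop
  dm <- demultiplex(mk_read(sheet2$i7[1], sheet2$i5[2]), sheet2)
  expect_identical(sum(dm$report@assigned), 0L)
  expect_identical(dm$report@conflict, 1L)
  expect_identical(length(dm$conflicts@id), 1L)
})

test_that("one index mismatch is tolerated at max_mismatch 1 but not 0", {
  i7mut <- sheet2$i7[1]
  substr(i7mut, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                 substr(i7mut, 3, 3))[1]
  rd <- mk_read(i7mut, sheet2$i5[1])
  expect_identical(sum(demultiplex(rd, sheet2, max_mismatch = 1)$report@assigned), 1L)
  expect_identical(sum(demultiplex(rd, sheet2, max_mismatch = 0)$report@assigned), 0L)
  # N in an index counts as a mismatch
  i7n <- sheet2$i7[1]; substr(i7n, 5, 5) <- "N"
  expect_identical(sum(demultiplex(mk_read(i7n, sheet2$i5[1]), sheet2,
                                   max_mismatch = 1)$report@assigned), 1L)
})

test_that("demultiplexing conserves reads and matches the simulator's hop truth", {
  idx <- indexPairs(4)
  cfgs <- lapply(1:4, function(i)
    SimConfig(paste0("s", i), 300 + i, 25000, 0, NULL, sub_error_rate = 0,
              indel_error_rate = 0, i7 = idx$i7[i], i5 = idx$i5[i]))
  run <- simulateRun(cfgs, ref, include_bioinf_control = FALSE,
                     hop_rate = 0.01, seed = 8)
  dm <- demultiplex(run$reads, run$sheet)
  r <- dm$report
  # exact conservation: every read lands in exactly one bucket
  expect_identical(sum(r@assigned) + r@unassigned + r@conflict, r@total)
  expect_identical(r@total, 100000L)
  # all hopped reads (and only they) carry discordant valid indices
  expect_identical(r@conflict, run$n_hopped)
  # conflict count is near its binomial expectation (simulator truth oracle)
  expect_lt(abs(r@conflict - 1000), 3 * sqrt(1e5 * 0.01 * 0.99))
})

test_that("with no hopping and exact matching, demultiplexing inverts the run", {
  idx <- indexPairs(2)
  cfgs <- lapply(1:2, function(i)
    SimConfig(paste0("s", i), 50 + i, 1000, 0, NULL, sub_error_rate = 0,
              indel_error_rate = 0, i7 = idx$i7[i], i5 = idx$i5[i]))
  run <- simulateRun(cfgs, ref, include_bioinf_control = FALSE,
                     hop_rate = 0, seed = 4)
  dm <- demultiplex(run$reads, run$sheet, max_mismatch = 0)
  expect_identical(unname(dm$report@assigned), c(1000L, 1000L))
  expect_identical(dm$report@unassigned + dm$report@conflict, 0L)
  # per-sample ids recovered exactly (order aside)
  got <- sort(sub(" .*", "", dm$samples$s1@id))
  expect_identical(got, sort(paste0("s1:", 1:1000)))
})

test_that("raising max_mismatch never decreases any sample's assigned count", {
  set.seed(99)
  idx <- indexPairs(3)
  sheet <- data.frame(sample_id = c("a", "b", "c"), i7 = idx$i7, i5 = idx$i5)
  # reads with randomly perturbed indices
  perturb <- function(x, k) {
    for (p in sample(10, k)) substr(x, p, p) <- sample(c("A", "C", "G", "T"), 1)
    x
  }
  reads <- do.call(c, lapply(1:60, function(i) {
    s <- sample(3, 1)
    mk_read(perturb(idx$i7[s], sample(0:2, 1)),
            perturb(idx$i5[s], sample(0:2, 1)), id = paste0("r", i))@id
  }))
  pr <- new("PairedReads", id = reads,
            seq1 = rep(substr(refSequence(ref), 1, 150), 60),
            qual1 = rep(strrep("I", 150), 60),
            seq2 = rep(rc(substr(refSequence(ref), 1, 150)), 60),
            qual2 = rep(strrep("I", 150), 60))
  a0 <- demultiplex(pr, sheet, max_mismatch = 0)$report@assigned
  a1 <- demultiplex(pr, sheet, max_mismatch = 1)$report@assigned
  a2 <- demultiplex(pr, sheet, max_mismatch = 2)$report@assigned
  expect_true(all(a1 >= a0))
  expect_true(all(a2 >= a1))
})

test_that("ambiguous sheets are rejected before any read is processed", {
  bad <- data.frame(sample_id = c("a", "b"),
                    i7 = c("AAAAAAAAAA", "AAAAAAAAAT"),  # distance 1
                    i5 = indexPairs(2)$i5)
  expect_error(demultiplex(mk_read(bad$i7[1], bad$i5[1]), bad, max_mismatch = 1),
               "ambiguous")
  dup <- data.frame(sample_id = c("a", "b"),
                    i7 = rep(indexPairs(1)$i7, 2), i5 = rep(indexPairs(1)$i5, 2))
  expect_error(validateSampleSheet(dup), "unique")
  short <- data.frame(sample_id = "a", i7 = "ACGT", i5 = indexPairs(1)$i5)
  expect_error(validateSampleSheet(short), "10 nt")
})
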