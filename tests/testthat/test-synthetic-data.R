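test_that("make_reference honours its contract and is deterministic", {
  ref <- make_reference(1, 1000, gc = 0.5, homopolymer_spikes = 0, seed = 7)
  expect_length(ref$loci, 1)
  expect_equal(nchar(ref$loci[[1]]), 1000)
  expect_false(grepl("[^ACGT]", ref$loci[[1]]))
  expect_match(names(ref$loci), "^locus_1_\\d+_\\d+$")

  ref2 <- make_reference(1, 1000, gc = 0.5, homopolymer_spikes = 0, seed = 7)
  expect_identical(ref, ref2)

  refh <- make_reference(1, 1000, gc = 0.5, homopolymer_spikes = 2, seed = 7)
  expect_equal(nrow(refh$homopolymers), 2)
  for (i in 1:2) {
    run <- refh$homopolymers[i, ]
    seg <- substr(refh$loci[[1]], run$start + 1, run$end)
    expect_gte(nchar(seg), 8)
    expect_equal(seg, strrep(run$base, nchar(seg)))
  }

  expect_error(make_reference(0, 1000), "n_loci")
  expect_error(make_reference(1, 100), "locus_length")
  expect_error(make_reference(1, 1000, gc = 1.5), "gc")
})

test_that("design_tiling spans the locus with in-range overlaps", {
  ref <- make_reference(1, 23000, seed = 3)
  des <- design_tiling(ref, 6, amp_len = c(3500, 4500),
                       overlap = c(200, 400), seed = 3)
  expect_equal(nrow(des), 6)
  expect_equal(des$start[1], 0)
  expect_equal(des$end[6], 23000)
  expect_true(all(diff(des$start) > 0))
  ov <- des$end[-6] - des$start[-1]
  expect_true(all(ov >= 200 & ov <= 400))
  lens <- des$end - des$start
  expect_true(all(lens >= 3500 & lens <= 4500))
  # contiguity of the union
  expect_true(all(des$start[-1] < des$end[-6]))

  # single amplicon: no overlap constraint
  ref1 <- make_reference(1, 800, seed = 5)
  d1 <- design_tiling(ref1, 1, amp_len = c(700, 900), overlap = c(50, 60),
                      seed = 5)
  expect_equal(nrow(d1), 1)
  expect_equal(c(d1$start, d1$end), c(0, 800))

  expect_error(
    design_tiling(ref1, 6, amp_len = c(3500, 4500), overlap = c(200, 400)),
    "design error")
})

test_that("primers are amplicon prefix/suffix for every design across seeds", {
  ref <- make_reference(1, 2300, seed = 11)
  for (s in 1:100) {
    des <- design_tiling(ref, 4, amp_len = c(550, 750), overlap = c(20, 60),
                         primer_len = 18, seed = s)
    amp <- substring(ref$loci[[1]], des$start + 1, des$end)
    expect_identical(substring(amp, 1, 18), des$fwd_primer)
    expect_identical(revcomp(substring(amp, nchar(amp) - 17, nchar(amp))),
                     des$rev_primer)
  }
})

test_that("barcode_panel crosses samples with amplicons", {
  ref <- make_reference(1, 3300, seed = 2)
  des <- design_tiling(ref, 6, amp_len = c(550, 700), overlap = c(30, 60),
                       seed = 2)
  samples <- make_sample_barcodes(6, seed = 9)
  expect_equal(samples$padding, rep("GTTAG", 6))
  panel <- barcode_panel(des, samples)
  expect_equal(nrow(panel), 36)
  expect_equal(anyDuplicated(panel[c("sample_id", "amplicon_id")]), 0)

  nobc <- barcode_panel(des, NULL)
  expect_equal(nrow(nobc), 6)
  expect_true(all(is.na(nobc$sample_id)))
  expect_true(all(nobc$barcode == ""))

  dup <- samples; dup$barcode[2] <- dup$barcode[1]
  expect_error(barcode_panel(des, dup), "duplicate barcodes")
})

test_that("zero-error raw reads alternate orientation exactly", {
  tmpl <- rand_seq(400, seed = 1)
  rr <- simulate_raw_read(tmpl, 3, error_profile(0, 0, 0), "mov/1")
  expect_equal(rr$subreads$sequence,
               c(tmpl, revcomp(tmpl), tmpl))
  expect_equal(rr$subreads$orientation, c("sense", "antisense", "sense"))
  expect_equal(rr$subreads$subread_id, paste0("mov/1/", 1:3))
  expect_error(simulate_raw_read("", 3, error_profile(0, 0, 0), "m/1"),
               "template")
  expect_error(simulate_raw_read(tmpl, 0, error_profile(0, 0, 0), "m/1"),
               "n_passes")
})

test_that("realized subread error rate tracks the configured profile", {
  tmpl <- rand_seq(500, seed = 2)
  prof <- profile_10pct()  # 2% sub + 5% ins + 3% del = 10%
  withr::with_seed(20, {
    d <- replicate(200, {
      rr <- simulate_raw_read(tmpl, 9, prof, "m/1")
      mean(vapply(rr$subreads$sequence, function(s)
        min(edit_dist(tmpl, s), edit_dist(tmpl, revcomp(s))),
        numeric(1))) / nchar(tmpl)
    })
  })
  expect_gt(mean(d), 0.05)
  expect_lt(mean(d), 0.2)

  # binomial check on event counts over >= 1e5 bases, via the truth log
  withr::with_seed(21, {
    n_events <- 0; n_bases <- 0
    for (i in 1:30) {
      rr <- simulate_raw_read(tmpl, 9, prof, "m/1", track_errors = TRUE)
      n_events <- n_events + nrow(rr$errors)
      n_bases <- n_bases + 9 * nchar(tmpl)
    }
  })
  expect_gte(n_bases, 1e5)
  p <- 0.10
  se <- sqrt(p * (1 - p) / n_bases)
  expect_lt(abs(n_events / n_bases - p), 3 * se)
})

test_that("homopolymer insertions concentrate inside planted runs", {
  tmpl <- paste0(rand_seq(200, seed = 3), strrep("A", 10), rand_seq(200, seed = 4))
  prof <- error_profile(0, 0.01, 0, homopolymer_ins_rate = 0.5, run_min = 8)
  run_pos <- 201:210
  withr::with_seed(31, {
    ins_in_run <- 0; ins_total <- 0
    for (i in 1:40) {
      rr <- simulate_raw_read(tmpl, 1, prof, "m/1", track_errors = TRUE)
      ins <- rr$errors[rr$errors$type == "ins", ]
      ins_total <- ins_total + nrow(ins)
      ins_in_run <- ins_in_run + sum(ins$pos %in% run_pos)
    }
  })
  expect_gt(ins_total, 0)
  # 10 of 410 positions carry >= 50x the background insertion rate
  expect_gt(ins_in_run / ins_total, 0.5)
})

test_that("simulate_library bookkeeping, determinism and file round trip", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  b1 <- make_test_library(2, 3, depth = 2, out_dir = dir1)
  b2 <- make_test_library(2, 3, depth = 2, out_dir = dir2)

  expect_equal(nrow(b1$truth), 2 * 3 * 2)
  expect_setequal(names(b1$reads), b1$truth$molecule_id)

  # byte-identical artifacts under the same seed
  for (f in c("subreads.fastq", "truth.tsv", "panel.tsv", "reference.fasta"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))

  # every molecule in the FASTQ appears exactly once in the truth table
  reads_back <- read_subreads_fastq(file.path(dir1, "subreads.fastq"))
  expect_setequal(names(reads_back), b1$truth$molecule_id)
  expect_equal(vapply(reads_back, function(r) nrow(r$subreads), integer(1))[
    b1$truth$molecule_id], setNames(b1$truth$n_passes, b1$truth$molecule_id))

  # zero-error profile: subreads normalise back to the template md5
  rr <- b1$reads[[b1$truth$molecule_id[1]]]
  tmpl <- bundle_template(b1, b1$truth$sample_id[1], b1$truth$amplicon_id[1])
  expect_equal(ccscluster:::md5_string(tmpl), b1$truth$template_md5[1])
  norm <- ifelse(seq_len(nrow(rr$subreads)) %% 2 == 0,
                 revcomp(rr$subreads$sequence), rr$subreads$sequence)
  expect_true(all(norm == tmpl))

  expect_error(make_test_library(1, 2, depth = 0), "depth")
})

test_that("pass-count distribution has the configured mean", {
  b <- make_test_library(2, 2, depth = 40, mean_passes = 9, seed = 77)
  m <- mean(b$truth$n_passes)
  expect_gt(m, 8); expect_lt(m, 10)
  expect_true(all(b$truth$n_passes >= 1))
})

test_that("error_profile validates its rates", {
  expect_error(error_profile(0.3, 0.2, 0.1), "0.5")
  expect_error(error_profile(-0.1, 0, 0), "sub_rate")
  expect_s3_class(error_profile(0.1, 0.1, 0.1), "error_profile")
})
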