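test_that("match_primer_pair window semantics", {
  fwd <- "ACGTTGCAACGGTACC"
  rev <- "TTGACCGTAGGATCCA"   # primer oligo, opposite strand
  core <- rand_seq(150, seed = 1)
  seq_sense <- paste0(fwd, core, revcomp(rev))
  expect_equal(match_primer_pair(seq_sense, fwd, rev, 21), "sense")
  expect_equal(match_primer_pair(revcomp(seq_sense), fwd, rev, 21),
               "antisense")

  # primer placed past the window is not found
  shifted <- paste0(strrep("T", 25), fwd, core, revcomp(rev))
  expect_equal(match_primer_pair(shifted, fwd, rev, 21), NA_character_)
  # ... but a window that reaches it does
  expect_equal(match_primer_pair(shifted, fwd, rev, 41), "sense")

  expect_error(match_primer_pair(seq_sense, fwd, rev, 10), "search_space")
})

test_that("match_primer_pair equals the brute-force scanner on random cases", {
  withr::with_seed(99, {
    for (i in 1:10000) {
      ss <- sample(15:40, 1)
      fwd <- rand_seq(sample(8:12, 1))
      rev <- rand_seq(sample(8:12, 1))
      n <- sample(60:120, 1)
      seq <- rand_seq(n)
      # half the time, plant the primers somewhere near the ends
      if (i %% 2 == 0) {
        off1 <- sample(0:20, 1); off2 <- sample(0:20, 1)
        seq <- paste0(substr(seq, 1, off1), fwd,
                      substr(seq, off1 + 1, n - off2 - nchar(rev)),
                      revcomp(rev), substr(seq, n - off2 + 1, n))
        if (i %% 4 == 0) seq <- revcomp(seq)
      }
      expect_identical(match_primer_pair(seq, fwd, rev, ss),
                       oracle_match_primer_pair(seq, fwd, rev, ss))
    }
  })
})

test_that("error-free library clusters perfectly at both levels", {
  b <- make_test_library(2, 3, depth = 3)
  ccs <- build_ccs_all(b$reads)
  cmap <- cluster_ccs(ccs, b$panel, two_level = TRUE)
  expect_equal(nrow(cmap$unassigned), 0)
  m <- merge(cmap$assignments, b$truth, by = "molecule_id")
  expect_true(all(m$sample_id.x == m$sample_id.y))
  expect_true(all(m$amplicon_id.x == m$amplicon_id.y))

  # partition: every molecule exactly once
  ids <- c(cmap$assignments$molecule_id, cmap$unassigned$molecule_id)
  expect_setequal(ids, ccs$molecule_id)
  expect_equal(anyDuplicated(ids), 0)

  # one-level mode: bare primers in a 21 bp window, on an unbarcoded library
  b0 <- make_test_library(0, 3, depth = 3, seed = 43)
  ccs0 <- build_ccs_all(b0$reads)
  cmap1 <- cluster_ccs(ccs0, b0$panel, two_level = FALSE)
  expect_equal(nrow(cmap1$unassigned), 0)
  m1 <- merge(cmap1$assignments, b0$truth, by = "molecule_id")
  expect_true(all(m1$amplicon_id.x == m1$amplicon_id.y))
  expect_true(all(is.na(m1$sample_id.x)))
})

test_that("assignment is invariant to reverse-complementing CCS reads", {
  b <- make_test_library(2, 2, depth = 2)
  ccs <- build_ccs_all(b$reads)
  cmap <- cluster_ccs(ccs, b$panel, two_level = TRUE)
  flip <- seq(1, nrow(ccs), by = 2)
  ccs2 <- ccs
  ccs2$sequence[flip] <- revcomp(ccs2$sequence[flip])
  cmap2 <- cluster_ccs(ccs2, b$panel, two_level = TRUE)
  a1 <- cmap$assignments[order(cmap$assignments$molecule_id), ]
  a2 <- cmap2$assignments[order(cmap2$assignments$molecule_id), ]
  expect_equal(a1[c("molecule_id", "sample_id", "amplicon_id")],
               a2[c("molecule_id", "sample_id", "amplicon_id")])
  flipped_ids <- ccs$molecule_id[flip]
  expect_true(all(a1$orientation[a1$molecule_id %in% flipped_ids] !=
                    a2$orientation[a2$molecule_id %in% flipped_ids]))
})

test_that("corrupted end windows and duplicate panels produce reasons", {
  b <- make_test_library(1, 2, depth = 2)
  ccs <- build_ccs_all(b$reads)
  # corrupt one read inside the forward primer region
  ccs$sequence[1] <- paste0("AAAAAAAA", substr(ccs$sequence[1], 9,
                                               nchar(ccs$sequence[1])))
  cmap <- cluster_ccs(ccs, b$panel, two_level = TRUE)
  expect_true(ccs$molecule_id[1] %in% cmap$unassigned$molecule_id)
  expect_equal(cmap$unassigned$reason[
    cmap$unassigned$molecule_id == ccs$molecule_id[1]], "no_match")

  # a CCS rejected upstream is carried as 'filtered'
  ccs2 <- build_ccs_all(b$reads)
  ccs2$emitted[2] <- FALSE
  cmap2 <- cluster_ccs(ccs2, b$panel, two_level = TRUE)
  expect_equal(cmap2$unassigned$reason[
    cmap2$unassigned$molecule_id == ccs2$molecule_id[2]], "filtered")

  # two panel entries with identical primers make every match ambiguous
  pan_dup <- rbind(b$panel, b$panel[1, ])
  pan_dup$sample_id[nrow(pan_dup)] <- "sampleXX"
  pan_dup$barcode[nrow(pan_dup)] <- pan_dup$barcode[1]
  ccs3 <- build_ccs_all(b$reads)
  cmap3 <- cluster_ccs(ccs3, pan_dup, two_level = TRUE)
  amb <- cmap3$unassigned$reason[cmap3$unassigned$molecule_id %in%
    b$truth$molecule_id[b$truth$amplicon_id == b$panel$amplicon_id[1]]]
  expect_true(all(amb == "ambiguous"))
  expect_gt(length(amb), 0)

  expect_error(cluster_ccs(ccs, b$panel[0, ]), "empty")
  pan_nobc <- b$panel; pan_nobc$barcode <- ""
  expect_error(cluster_ccs(ccs, pan_nobc, two_level = TRUE), "barcode")
})

test_that("whitelists conserve molecules and summarise subread counts", {
  b <- make_test_library(2, 2, depth = 3)
  ccs <- build_ccs_all(b$reads)
  cmap <- cluster_ccs(ccs, b$panel, two_level = TRUE)
  out <- withr::local_tempdir()
  nsub <- vapply(b$reads, function(r) nrow(r$subreads), integer(1))
  smry <- write_whitelists(cmap, out, n_subreads = nsub)

  files <- list.files(out, pattern = "whitelist\\.txt$")
  expect_equal(length(files), 4)  # 2 samples x 2 amplicons, all non-empty
  total <- sum(vapply(file.path(out, files),
                      function(f) length(readLines(f)), integer(1)))
  expect_equal(total + nrow(cmap$unassigned), nrow(ccs))
  expect_equal(sum(smry$n_subreads), sum(b$truth$n_passes))
  expect_equal(sum(smry$n_molecules), nrow(cmap$assignments))

  wl <- read_whitelists(out)
  expect_setequal(names(wl), smry$cluster)
})
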