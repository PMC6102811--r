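test_that("trim_ends arithmetic and bounds", {
  s <- rand_seq(100, seed = 1)
  expect_equal(trim_ends(s, 0), s)
  expect_equal(nchar(trim_ends(s, 21)), 58)
  expect_equal(trim_ends(s, 10), substr(s, 11, 90))
  expect_error(trim_ends(s, 50), "trim_bp")
})

test_that("find_overlaps detects engineered dovetails and nothing else", {
  O <- rand_seq(300, seed = 2)
  A <- paste0(rand_seq(500, seed = 3), O)
  B <- paste0(O, rand_seq(500, seed = 4))
  e <- find_overlaps(c(a = A, b = B), min_overlap = 40, min_identity = 0.94)
  expect_equal(nrow(e), 1)
  expect_equal(e$identity, 1.0)
  expect_equal(e$overlap_len, 300L)
  expect_equal(e$offset, 500L)
  expect_equal(e$rel, "same")

  # same pair with b reverse-complemented: flip edge, same placement
  e2 <- find_overlaps(c(a = A, b = revcomp(B)))
  expect_equal(e2$rel, "flip")
  expect_equal(e2$offset, 500L)

  disjoint <- c(x = rand_seq(400, seed = 5), y = rand_seq(400, seed = 6))
  expect_equal(nrow(find_overlaps(disjoint)), 0)
})

test_that("dovetail detection agrees with the all-offsets oracle", {
  withr::with_seed(30, {
    for (i in 1:25) {
      olen <- sample(40:120, 1)
      O <- rand_seq(olen)
      A <- paste0(rand_seq(sample(30:80, 1)), O)
      B <- paste0(O, rand_seq(sample(30:80, 1)))
      # sprinkle substitutions into the overlap copy in B (stay above 94%)
      n_mut <- sample(0:floor(olen * 0.04), 1)
      if (n_mut > 0) {
        pos <- sample(olen, n_mut)
        for (p in pos) {
          old <- substr(B, p, p)
          substr(B, p, p) <- setdiff(c("A", "C", "G", "T"), old)[sample(3, 1)]
        }
      }
      e <- find_overlaps(c(a = A, b = B), min_overlap = 40,
                         min_identity = 0.90)
      o <- oracle_best_dovetail(A, B)
      expect_equal(nrow(e), 1)
      expect_equal(e$offset, o$offset)
      expect_equal(e$overlap_len, o$overlap_len)
      expect_equal(e$identity, o$identity)
    }
  })
})

test_that("two-member conflicts become Ns; three-member columns take the plurality", {
  O <- rand_seq(200, seed = 7)
  A <- paste0(rand_seq(300, seed = 8), O)
  B <- paste0(O, rand_seq(300, seed = 9))
  e <- find_overlaps(c(a = A, b = B))
  asm <- layout_consensus(c(a = A, b = B), e, sample_id = "s1")
  expect_equal(nrow(asm$contigs), 1)
  expect_equal(asm$contigs$sequence, paste0(A, substr(B, 201, 500)))
  expect_false(grepl("N", asm$contigs$sequence))

  # engineer exactly one disagreement inside the overlap
  p <- 100L
  B2 <- B
  old <- substr(B2, p, p)
  substr(B2, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  e2 <- find_overlaps(c(a = A, b = B2))
  asm2 <- layout_consensus(c(a = A, b = B2), e2, sample_id = "s1")
  cs <- asm2$contigs$sequence
  expect_equal(substr(cs, 300 + p, 300 + p), "N")
  expect_equal(sum(strsplit(cs, "")[[1]] == "N"), 1)
  expect_equal(asm2$n_positions$start, 300 + p - 1L)  # 0-based BED
  expect_equal(asm2$n_positions$end, 300 + p)

  # three voters A,A,G at one column -> plurality base, no N
  core <- rand_seq(400, seed = 10)
  m1 <- core
  m2 <- substr(core, 101, 400)
  m3 <- substr(core, 201, 400)
  p2 <- 250L
  stopifnot(substr(core, p2, p2) != "G" || TRUE)
  old2 <- substr(m3, p2 - 200L, p2 - 200L)
  alt <- setdiff(c("A", "C", "G", "T"), old2)[1]
  substr(m3, p2 - 200L, p2 - 200L) <- alt
  seqs <- c(m1 = m1, m2 = m2, m3 = m3)
  e3 <- find_overlaps(seqs, min_overlap = 40, min_identity = 0.90)
  asm3 <- layout_consensus(seqs, e3, sample_id = "s1")
  expect_equal(nrow(asm3$contigs), 1)
  expect_equal(asm3$contigs$sequence, core)  # 2-vs-1 plurality wins everywhere

  # a 2-2 tie among >= 3 voters is conservative: N
  m4 <- substr(core, 201, 400)
  substr(m4, p2 - 200L, p2 - 200L) <- alt
  seqs4 <- c(m1 = m1, m2 = m2, m3 = m3, m4 = m4)
  e4 <- find_overlaps(seqs4, min_overlap = 40, min_identity = 0.90)
  asm4 <- layout_consensus(seqs4, e4, sample_id = "s1")
  expect_equal(substr(asm4$contigs$sequence, p2, p2), "N")
})

test_that("an error-free tiling path reassembles the reference exactly", {
  b <- make_test_library(1, 4, depth = 2, mean_passes = 3)
  ccs <- build_ccs_all(b$reads)
  cmap <- cluster_ccs(ccs, b$panel, two_level = TRUE)
  rec <- consensus_all(cmap, b$reads, b$panel, min_subreads = 0,
                       two_level = TRUE)
  trim <- nchar(b$panel$padding[1]) + nchar(b$panel$barcode[1])
  asm <- assemble_sample(rec, trim_bp = trim)
  expect_equal(nrow(asm$contigs), 1)
  expect_equal(length(asm$singletons), 0)
  expect_equal(asm$contigs$sequence, unname(b$reference$loci[1]))

  # single consensus: singleton passthrough
  asm1 <- assemble_sample(rec[1, ], trim_bp = trim)
  expect_equal(nrow(asm1$contigs), 0)
  expect_equal(asm1$singletons, rec$cluster[1])
})

test_that("assembly is per sample and orientation-invariant", {
  b <- make_test_library(2, 3, depth = 2, mean_passes = 3)
  ccs <- build_ccs_all(b$reads)
  cmap <- cluster_ccs(ccs, b$panel, two_level = TRUE)
  rec <- consensus_all(cmap, b$reads, b$panel, min_subreads = 0,
                       two_level = TRUE)
  trim <- nchar(b$panel$padding[1]) + nchar(b$panel$barcode[1])
  by_sample <- split(rec, rec$sample_id)
  expect_equal(length(by_sample), 2)
  asms <- lapply(by_sample, assemble_sample, trim_bp = trim)
  for (a in asms) expect_equal(a$contigs$sequence,
                               unname(b$reference$loci[1]))

  # reverse-complement a non-root member (the layout root is the longest
  # sequence and sets the contig strand): same contig comes back
  rec2 <- by_sample[[1]]
  short_i <- which.min(nchar(rec2$sequence))
  rec2$sequence[short_i] <- revcomp(rec2$sequence[short_i])
  asm2 <- assemble_sample(rec2, trim_bp = trim)
  expect_equal(asm2$contigs$sequence, unname(b$reference$loci[1]))
})

test_that("every N in a contig maps to a disagreeing or tied column", {
  O <- rand_seq(150, seed = 20)
  A <- paste0(rand_seq(250, seed = 21), O)
  B <- paste0(O, rand_seq(250, seed = 22))
  B_mut <- B
  for (p in c(30L, 90L)) {
    old <- substr(B_mut, p, p)
    substr(B_mut, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  seqs <- c(a = A, b = B_mut)
  asm <- layout_consensus(seqs, find_overlaps(seqs), sample_id = "s")
  lay <- asm$layout
  chars <- strsplit(asm$contigs$sequence, "")[[1]]
  n_cols <- which(chars == "N")
  expect_equal(length(n_cols), 2)
  for (col in n_cols) {
    voters <- character(0)
    for (r in seq_len(nrow(lay))) {
      s <- seqs[[lay$member[r]]]
      if (lay$orientation[r] == "-") s <- revcomp(s)
      idx <- col - lay$offset[r]
      if (idx >= 1 && idx <= nchar(s))
        voters <- c(voters, substr(s, idx, idx))
    }
    tab <- table(voters)
    expect_true(length(voters) >= 2 &&
                  sum(tab == max(tab)) > 1)  # disagreement or tie
  }
})

test_that("assembly artifacts are written when requested", {
  O <- rand_seq(120, seed = 23)
  seqs_rec <- tibble::tibble(
    cluster = c("s1__amp1", "s1__amp2"),
    sample_id = "s1",
    sequence = c(paste0(rand_seq(200, seed = 24), O),
                 paste0(O, rand_seq(200, seed = 25))),
    status = "emitted")
  out <- withr::local_tempdir()
  asm <- assemble_sample(seqs_rec, trim_bp = 0, out_dir = out)
  expect_true(file.exists(file.path(out, "s1_preassembly.fasta")))
  expect_true(file.exists(file.path(out, "s1_assembly.fasta")))
  expect_true(file.exists(file.path(out, "s1_layout.tsv")))
  fa <- read_fasta(file.path(out, "s1_assembly.fasta"))
  expect_equal(unname(fa[1]), asm$contigs$sequence[1])
})
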