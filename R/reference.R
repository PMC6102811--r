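# Synthetic reference loci, amplicon tiling designs and barcode panels.
# Everything downstream of the simulator is exercised against these objects,
# so all generation is deterministic for a fixed seed.

#' Generate a synthetic reference
#'
#' Draws `n_loci` random loci and optionally plants homopolymer runs
#' (length 8-12 of a single base) at recorded positions, the classic site
#' of systematic insertion errors in SMRT data.
#'
#' @param n_loci number of loci (>= 1).
#' @param locus_length length of every locus in bp (>= 200).
#' @param gc GC fraction in `[0, 1]`.
#' @param homopolymer_spikes number of homopolymer runs planted per locus.
#' @param seed RNG seed; output is byte-identical for a fixed seed.
#' @return object of class `reference_set`: a list with `loci` (named
#'   character vector, ids `locus_<chrom>_<start>_<end>`, 1-based inclusive
#'   in the id) and `homopolymers` (tibble of planted runs, 0-based
#'   half-open coordinates).
#' @export
#' @examples
#' ref <- make_reference(1, 1000, gc = 0.5, homopolymer_spikes = 2, seed = 7)
#' nchar(ref$loci)
#' ref$homopolymers
make_reference <- function(n_loci, locus_length, gc = 0.5,
                           homopolymer_spikes = 0, seed = 1) {
  assert_scalar_number(n_loci, "n_loci", lo = 1, integer = TRUE)
  assert_scalar_number(locus_length, "locus_length", lo = 200, integer = TRUE)
  assert_scalar_number(gc, "gc", lo = 0, hi = 1)
  assert_scalar_number(homopolymer_spikes, "homopolymer_spikes", lo = 0,
                       integer = TRUE)
  with_seed(seed, {
    loci <- character(n_loci)
    ids <- character(n_loci)
    hp <- vector("list", n_loci)
    for (i in seq_len(n_loci)) {
      seq_i <- random_dna(locus_length, gc)
      runs <- NULL
      if (homopolymer_spikes > 0) {
        # plant one run per equal-width segment so runs never overlap
        seg <- floor(locus_length / homopolymer_spikes)
        if (seg < 20)
          stop("locus too short for the requested homopolymer spikes",
               call. = FALSE)
        starts <- integer(homopolymer_spikes)
        lens <- integer(homopolymer_spikes)
        bases <- character(homopolymer_spikes)
        for (k in seq_len(homopolymer_spikes)) {
          lens[k] <- sample(8:12, 1)
          starts[k] <- (k - 1) * seg + sample.int(seg - lens[k], 1)
          bases[k] <- sample(DNA_BASES, 1)
          substr(seq_i, starts[k] + 1, starts[k] + lens[k]) <-
            strrep(bases[k], lens[k])
        }
        runs <- tibble(start = starts, end = starts + lens, base = bases)
      }
      g_start <- sample.int(1e8L, 1)
      ids[i] <- sprintf("locus_%d_%d_%d", i, g_start,
                        g_start + locus_length - 1L)
      loci[i] <- seq_i
      if (!is.null(runs)) runs$locus_id <- ids[i]
      hp[[i]] <- runs
    }
    hp_tbl <- if (all(vapply(hp, is.null, logical(1)))) {
      tibble(locus_id = character(), start = integer(), end = integer(),
             base = character())
    } else {
      do.call(rbind, hp)[, c("locus_id", "start", "end", "base")]
    }
    structure(list(loci = setNames(loci, ids), homopolymers = hp_tbl),
              class = "reference_set")
  })
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d locus/loci, lengths %s bp, %d homopolymer run(s)\n",
              length(x$loci), paste(unique(nchar(x$loci)), collapse = "/"),
              nrow(x$homopolymers)))
  invisible(x)
}

#' Design a tiling path of overlapping amplicons over each locus
#'
#' Amplicons span each locus end-to-end; adjacent amplicons overlap by an
#' amount drawn from `overlap`. Primers are taken verbatim from the amplicon
#' ends: the forward primer is the amplicon prefix and the reverse primer is
#' the reverse complement of the amplicon suffix (i.e. the primer oligo as
#' synthesized).
#'
#' @param ref a `reference_set`.
#' @param n_amplicons amplicons per locus.
#' @param amp_len length-2 vector: allowed amplicon length range (bp).
#' @param overlap length-2 vector: allowed overlap range between adjacent
#'   amplicons (bp).
#' @param primer_len primer length (bp).
#' @param seed RNG seed.
#' @return tibble of amplicon designs: amplicon_id, locus_id, start, end
#'   (0-based half-open on the locus), fwd_primer, rev_primer.
#' @export
design_tiling <- function(ref, n_amplicons, amp_len = c(3500, 4500),
                          overlap = c(200, 400), primer_len = 24, seed = 1) {
  stopifnot(inherits(ref, "reference_set"))
  assert_scalar_number(n_amplicons, "n_amplicons", lo = 1, integer = TRUE)
  stopifnot(length(amp_len) == 2, amp_len[1] <= amp_len[2],
            length(overlap) == 2, overlap[1] <= overlap[2])
  assert_scalar_number(primer_len, "primer_len", lo = 8, integer = TRUE)
  if (primer_len >= amp_len[1])
    stop("design error: primer_len must be shorter than the smallest amplicon",
         call. = FALSE)
  with_seed(seed, {
    out <- lapply(names(ref$loci), function(lid) {
      L <- nchar(ref$loci[[lid]])
      n <- n_amplicons
      if (n == 1) {
        if (L < amp_len[1] || L > amp_len[2])
          stop(sprintf(
            "design error: locus length %d outside amp_len [%d, %d] for a single amplicon",
            L, amp_len[1], amp_len[2]), call. = FALSE)
        lens <- L
        ov <- integer(0)
      } else {
        lo_span <- n * amp_len[1] - (n - 1) * overlap[2]
        hi_span <- n * amp_len[2] - (n - 1) * overlap[1]
        if (L < lo_span || L > hi_span)
          stop(sprintf(
            "design error: locus length %d cannot be tiled by %d amplicons of %d-%d bp overlapping %d-%d bp (feasible span %d-%d)",
            L, n, amp_len[1], amp_len[2], overlap[1], overlap[2],
            lo_span, hi_span), call. = FALSE)
        ov <- sample(overlap[1]:overlap[2], n - 1, replace = TRUE)
        lens <- sample(amp_len[1]:amp_len[2], n, replace = TRUE)
        target <- L + sum(ov)
        guard <- 0L
        while (sum(lens) != target) {
          diff <- target - sum(lens)
          moved <- FALSE
          for (i in seq_len(n)) {
            if (diff > 0 && lens[i] < amp_len[2]) {
              lens[i] <- lens[i] + 1L; diff <- diff - 1L; moved <- TRUE
            } else if (diff < 0 && lens[i] > amp_len[1]) {
              lens[i] <- lens[i] - 1L; diff <- diff + 1L; moved <- TRUE
            }
            if (diff == 0) break
          }
          if (!moved) {
            # lengths pinned at a bound: absorb the remainder in the overlaps
            for (i in seq_len(n - 1)) {
              if (diff < 0 && ov[i] < overlap[2]) {
                ov[i] <- ov[i] + 1L; diff <- diff + 1L; moved <- TRUE
              } else if (diff > 0 && ov[i] > overlap[1]) {
                ov[i] <- ov[i] - 1L; diff <- diff - 1L; moved <- TRUE
              }
              if (diff == 0) break
            }
            target <- L + sum(ov)
          }
          if (!moved || (guard <- guard + 1L) > 10L * (L + n))
            stop("design error: could not satisfy tiling geometry", call. = FALSE)
        }
      }
      starts <- integer(n)
      for (i in seq_len(n)[-1]) starts[i] <- starts[i - 1] + lens[i - 1] - ov[i - 1]
      ends <- starts + lens
      amp_seq <- substring(ref$loci[[lid]], starts + 1, ends)
      tibble(
        amplicon_id = sprintf("%s_amp%02d", lid, seq_len(n)),
        locus_id = lid,
        start = starts, end = ends,
        fwd_primer = substring(amp_seq, 1, primer_len),
        rev_primer = revcomp(substring(amp_seq, lens - primer_len + 1, lens)))
    })
    do.call(rbind, out)
  })
}

#' Generate per-sample symmetric barcodes
#'
#' @param n_samples number of samples.
#' @param barcode_len barcode length (default 16 bp, the standard symmetric
#'   barcode length).
#' @param padding shared 5' padding sequence placed outside the barcode on
#'   the synthesis oligo (default `"GTTAG"`).
#' @param seed RNG seed.
#' @return tibble: sample_id, barcode, padding.
#' @export
make_sample_barcodes <- function(n_samples, barcode_len = 16,
                                 padding = "GTTAG", seed = 1) {
  assert_scalar_number(n_samples, "n_samples", lo = 1, integer = TRUE)
  with_seed(seed, {
    repeat {
      bc <- vapply(seq_len(n_samples), function(i) random_dna(barcode_len),
                   character(1))
      if (!anyDuplicated(bc)) break
    }
    tibble(sample_id = sprintf("sample%02d", seq_len(n_samples)),
           barcode = bc, padding = padding)
  })
}

#' Combine amplicon designs and sample barcodes into a primer panel
#'
#' One panel row per (sample, amplicon). With an empty `samples` the panel is
#' unbarcoded (one-level clustering mode): sample ids are `NA` and barcode /
#' padding are empty strings.
#'
#' @param designs tibble from [design_tiling()].
#' @param samples tibble from [make_sample_barcodes()], or `NULL`.
#' @return panel tibble: sample_id, amplicon_id, barcode, padding,
#'   fwd_primer, rev_primer.
#' @export
barcode_panel <- function(designs, samples = NULL) {
  if (is.null(samples) || nrow(samples) == 0) {
    samples <- tibble(sample_id = NA_character_, barcode = "", padding = "")
  }
  if (anyDuplicated(samples$barcode[samples$barcode != ""]))
    stop("panel error: duplicate barcodes", call. = FALSE)
  grid <- expand.grid(si = seq_len(nrow(samples)), ai = seq_len(nrow(designs)))
  grid <- grid[order(grid$si, grid$ai), ]
  tibble(
    sample_id = samples$sample_id[grid$si],
    amplicon_id = designs$amplicon_id[grid$ai],
    barcode = samples$barcode[grid$si],
    padding = samples$padding[grid$si],
    fwd_primer = designs$fwd_primer[grid$ai],
    rev_primer = designs$rev_primer[grid$ai])
}
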