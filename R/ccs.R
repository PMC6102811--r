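# Per-molecule circular consensus (CCS): orient subreads against the longest
# subread, star-align them to it in a diagonal band, and call a per-column
# majority consensus. This is a deliberately simple, deterministic stand-in
# for vendor "reads of insert" consensus callers; its predicted accuracy is
# the mean per-column agreement fraction, not a likelihood-based estimate.

#' Orient subreads against the seed subread
#'
#' The seed is the longest subread (ties: first in order). Every subread is
#' returned in the orientation (as-is or reverse complement) minimising its
#' edit distance to the seed; ties keep the original orientation. Order is
#' preserved.
#'
#' @param raw a `raw_read`.
#' @return character vector of oriented subread sequences.
#' @export
orient_subreads <- function(raw) {
  stopifnot(inherits(raw, "raw_read"))
  seqs <- raw$subreads$sequence
  if (length(seqs) == 0) stop("input error: raw read has no subreads",
                              call. = FALSE)
  seed_i <- which.max(nchar(seqs))
  seed <- seqs[seed_i]
  vapply(seqs, function(s) {
    rc <- revcomp(s)
    if (.cpp_edit_distance(seed, rc) < .cpp_edit_distance(seed, s)) rc else s
  }, character(1), USE.NAMES = FALSE)
}

#' Build a circular consensus sequence for one molecule
#'
#' Oriented subreads are aligned to the seed subread inside a diagonal band
#' and a per-column majority consensus is called; gap-majority columns are
#' dropped and base ties break deterministically (template base first, then
#' A<C<G<T). The predicted
#' accuracy is the mean over consensus columns of the fraction of subreads
#' agreeing with the called base. A molecule is rejected (not emitted) when
#' its pass count or predicted accuracy falls below the thresholds; the
#' defaults (1 pass, 0.90) reproduce the permissive reads-of-insert settings
#' used for clustering. A single-pass molecule scores 1.0 by the column
#' definition and is therefore never rejected on accuracy.
#'
#' @param raw a `raw_read`.
#' @param min_passes minimum subread count to emit.
#' @param min_predicted_accuracy minimum predicted accuracy to emit.
#' @param band_frac alignment band half-width as a fraction of the seed
#'   length (default 0.15, generous for up to ~20% per-base error).
#' @param min_band minimum band half-width in bp.
#' @param max_rounds consensus refinement rounds: the column majority is
#'   recomputed against the previous round's consensus until it stops
#'   changing (at most `max_rounds` times), which removes the residual bias
#'   of a single error-laden seed subread.
#' @return one-row tibble: molecule_id, sequence, n_passes,
#'   predicted_accuracy, emitted, reason (`NA` when emitted).
#' @export
build_ccs <- function(raw, min_passes = 1, min_predicted_accuracy = 0.90,
                      band_frac = 0.15, min_band = 32, max_rounds = 3) {
  stopifnot(inherits(raw, "raw_read"))
  n <- nrow(raw$subreads)
  if (n == 0) stop("input error: raw read has no subreads", call. = FALSE)
  oriented <- orient_subreads(raw)
  template <- oriented[which.max(nchar(oriented))]
  tab <- table(oriented)
  uniq <- names(tab)
  band <- max(min_band, ceiling(band_frac * max(nchar(oriented))))
  for (round in seq_len(max_rounds)) {
    res <- .cpp_column_consensus(template, uniq, as.numeric(tab),
                                 as.integer(band), 0L)
    if (res$edits == 0 || nchar(res$consensus) == 0) break
    template <- res$consensus
  }
  acc <- res$accuracy
  emitted <- TRUE
  reason <- NA_character_
  if (n < min_passes) {
    emitted <- FALSE
    reason <- sprintf("n_passes %d < min_passes %d", n, min_passes)
  } else if (acc < min_predicted_accuracy) {
    emitted <- FALSE
    reason <- sprintf("predicted_accuracy %.4f < %.2f", acc,
                      min_predicted_accuracy)
  }
  tibble(molecule_id = raw$molecule_id,
         sequence = res$consensus,
         n_passes = as.integer(n),
         predicted_accuracy = acc,
         emitted = emitted,
         reason = reason)
}

#' Build CCS reads for a collection of molecules
#'
#' @param reads named list of `raw_read` objects (e.g. a simulated bundle's
#'   `reads`, or [read_subreads_fastq()] output).
#' @param ... passed to [build_ccs()].
#' @param out_prefix if non-`NULL`, write `<out_prefix>.fastq` (emitted CCS
#'   reads, ids `<molecule>/ccs`) and `<out_prefix>_report.tsv` (one row per
#'   molecule: molecule_id, n_passes, predicted_accuracy, status, reason).
#' @return CCS tibble with one row per molecule.
#' @export
build_ccs_all <- function(reads, ..., out_prefix = NULL) {
  ccs <- do.call(rbind, lapply(reads, build_ccs, ...))
  if (!is.null(out_prefix)) {
    write_ccs_fastq(ccs, paste0(out_prefix, ".fastq"))
    rep_tbl <- data.frame(
      molecule_id = ccs$molecule_id, n_passes = ccs$n_passes,
      predicted_accuracy = sprintf("%.6f", ccs$predicted_accuracy),
      status = ifelse(ccs$emitted, "emitted", "rejected"),
      reason = ifelse(is.na(ccs$reason), "", ccs$reason))
    write.table(rep_tbl, paste0(out_prefix, "_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  ccs
}
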