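# Cluster consensus polishing. Each cluster's whitelisted raw subreads are
# polished into one consensus by deterministic iterative majority voting:
# orient all subreads against the current template, banded-align each to it,
# take the per-column majority (including insertions and deletions), and
# repeat until a fixpoint or max_iters. This replaces likelihood-based
# polishers with a dependency-free, reproducible procedure; the clustering
# upstream decides *what* gets polished, which is where accuracy is won.

orient_to_template <- function(seqs, template) {
  vapply(seqs, function(s) {
    rc <- revcomp(s)
    if (.cpp_edit_distance(template, rc) < .cpp_edit_distance(template, s)) rc
    else s
  }, character(1), USE.NAMES = FALSE)
}

#' Polish a cluster of subreads into a consensus sequence
#'
#' @param subreads character vector of raw subread sequences (>= 1); either
#'   orientation, duplicates allowed (they vote with multiplicity).
#' @param max_iters maximum polishing iterations (default 5; a fixpoint,
#'   i.e. zero edits between successive templates, usually lands in 2-3).
#' @param band_frac alignment band half-width as a fraction of template
#'   length (default 0.10).
#' @param min_band minimum band half-width in bp.
#' @return list with `sequence` (the consensus) and `iterations` used.
#' @export
polish_cluster <- function(subreads, max_iters = 5, band_frac = 0.10,
                           min_band = 32) {
  if (length(subreads) == 0)
    stop("input error: no subreads to polish", call. = FALSE)
  template <- subreads[which.max(nchar(subreads))]
  iters <- 0L
  for (it in seq_len(max_iters)) {
    iters <- it
    oriented <- orient_to_template(subreads, template)
    tab <- table(oriented)
    band <- max(min_band, ceiling(band_frac * nchar(template)))
    res <- .cpp_column_consensus(template, names(tab), as.numeric(tab),
                                 as.integer(band), 1L)
    if (res$edits == 0) break
    template <- res$consensus
    if (nchar(template) == 0)
      stop("polishing collapsed to an empty consensus", call. = FALSE)
  }
  list(sequence = template, iterations = iters)
}

#' Polish every cluster of a cluster map
#'
#' Clusters with fewer than `min_subreads` whitelisted subreads are reported
#' with status `filtered_low_support` and carry no sequence (the default
#' threshold of 100 removes weakly supported consensus sequences in routine
#' runs; set it to 0 to keep everything, as done for accuracy evaluation).
#' Emitted consensus sequences are oriented to the panel's forward-primer
#' sense.
#'
#' @param cmap a `cluster_map`.
#' @param reads named list of `raw_read` objects resolving every whitelisted
#'   molecule; a missing molecule is a hard error (it signals a
#'   whitelist/subread mismatch upstream).
#' @param panel panel tibble (used to orient consensus sequences).
#' @param min_subreads support threshold (default 100).
#' @param min_subread_length drop subreads shorter than this before counting
#'   and polishing (default 0 = keep all).
#' @param two_level,include_padding how the panel was matched (affects the
#'   composite used for orientation).
#' @param max_iters,band_frac passed to [polish_cluster()].
#' @return tibble of consensus records: cluster, sample_id, amplicon_id,
#'   sequence, n_molecules, n_subreads, status, iterations.
#' @export
consensus_all <- function(cmap, reads, panel, min_subreads = 100,
                          min_subread_length = 0, two_level = FALSE,
                          include_padding = TRUE, max_iters = 5,
                          band_frac = 0.10) {
  stopifnot(inherits(cmap, "cluster_map"))
  a <- cmap$assignments
  missing <- setdiff(a$molecule_id, names(reads))
  if (length(missing) > 0)
    stop(sprintf("whitelisted molecule(s) missing from subread source: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  a$cluster <- cluster_label(a$sample_id, a$amplicon_id)
  comp <- composite_primers(panel, two_level, include_padding)
  out <- list()
  for (cl in unique(a$cluster)) {
    sel <- a[a$cluster == cl, ]
    subs <- unlist(lapply(reads[sel$molecule_id],
                          function(r) r$subreads$sequence), use.names = FALSE)
    if (min_subread_length > 0) subs <- subs[nchar(subs) >= min_subread_length]
    n_sub <- length(subs)
    n_mol <- nrow(sel)
    if (n_sub < min_subreads) {
      out[[cl]] <- tibble(
        cluster = cl, sample_id = sel$sample_id[1],
        amplicon_id = sel$amplicon_id[1], sequence = NA_character_,
        n_molecules = n_mol, n_subreads = n_sub,
        status = "filtered_low_support", iterations = NA_integer_)
      next
    }
    pol <- polish_cluster(subs, max_iters = max_iters, band_frac = band_frac)
    seq_out <- pol$sequence
    # orient to the panel's fwd sense for this cluster
    pj <- which(panel$amplicon_id == sel$amplicon_id[1] &
                (is.na(sel$sample_id[1]) | is.na(panel$sample_id) |
                 panel$sample_id == sel$sample_id[1]))[1]
    if (!is.na(pj)) {
      ss <- max(nchar(comp$fwd[pj]), nchar(comp$rev[pj])) + 30L
      ori <- match_primer_pair(seq_out, comp$fwd[pj], comp$rev[pj],
                               search_space = min(ss, nchar(seq_out)))
      if (identical(ori, "antisense")) seq_out <- revcomp(seq_out)
    }
    out[[cl]] <- tibble(
      cluster = cl, sample_id = sel$sample_id[1],
      amplicon_id = sel$amplicon_id[1], sequence = seq_out,
      n_molecules = n_mol, n_subreads = n_sub,
      status = "emitted", iterations = pol$iterations)
  }
  do.call(rbind, out)
}

#' Write emitted consensus records to FASTA plus a run report
#'
#' FASTA ids follow `<sample|nobc>__<amplicon>__nsub<count>`.
#'
#' @param records tibble from [consensus_all()].
#' @param path output FASTA.
#' @param report_path optional TSV run report (cluster, n_molecules,
#'   n_subreads, status, iterations).
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(records, path, report_path = NULL) {
  em <- records[records$status == "emitted", , drop = FALSE]
  seqs <- setNames(em$sequence, sprintf("%s__nsub%d", em$cluster, em$n_subreads))
  write_fasta(seqs, path)
  if (!is.null(report_path)) {
    write.table(
      records[c("cluster", "n_molecules", "n_subreads", "status", "iterations")],
      report_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
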