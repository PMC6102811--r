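# Core clustering step: assign each CCS read to a (sample, amplicon) panel
# entry by locating the expected primer (one-level) or barcode+primer
# composite (two-level) in the end windows of the read, considering both
# orientations. Matching is an exact substring test by default; the match
# is intentionally simple so that cluster membership is unambiguous and
# auditable.

# does `window` contain `pat` (allowing up to max_mismatch Hamming mismatches
# at some offset)?
window_contains <- function(window, pat, max_mismatch = 0) {
  if (max_mismatch == 0) return(grepl(pat, window, fixed = TRUE))
  np <- nchar(pat); nw <- nchar(window)
  if (np > nw) return(FALSE)
  pch <- strsplit(pat, "", fixed = TRUE)[[1]]
  wch <- strsplit(window, "", fixed = TRUE)[[1]]
  for (off in 0:(nw - np)) {
    if (sum(wch[(off + 1):(off + np)] != pch) <= max_mismatch) return(TRUE)
  }
  FALSE
}

#' Match a primer pair against the end windows of a CCS read
#'
#' A read is `"sense"` when the forward primer occurs within its first
#' `search_space` bases and the reverse complement of the reverse primer
#' occurs within its last `search_space` bases; it is `"antisense"` when the
#' reverse-complemented read satisfies the same test. Sense is tested first,
#' so a read matching both ways (palindromic pathologies) counts as sense.
#' Occurrences must lie fully inside the window.
#'
#' @param ccs_seq CCS read sequence.
#' @param fwd forward primer (5'->3' as synthesized; may include barcode /
#'   padding for two-level clustering).
#' @param rev reverse primer (5'->3' as synthesized, i.e. on the opposite
#'   strand).
#' @param search_space window length at each end; must be at least as long
#'   as the longer primer.
#' @param max_mismatch maximum Hamming mismatches tolerated inside a primer
#'   occurrence (default 0 = exact matching).
#' @return `"sense"`, `"antisense"`, or `NA` when neither matches.
#' @export
#' @examples
#' match_primer_pair("ACGTACGTAAAATTTTCCCCGGGG", "ACGTA", "CCCCG", 10)
match_primer_pair <- function(ccs_seq, fwd, rev, search_space,
                              max_mismatch = 0) {
  if (search_space < max(nchar(fwd), nchar(rev)))
    stop("parameter error: search_space shorter than a primer", call. = FALSE)
  rev_rc <- revcomp(rev)
  n <- nchar(ccs_seq)
  ss <- min(search_space, n)
  head_w <- substr(ccs_seq, 1L, ss)
  tail_w <- substr(ccs_seq, n - ss + 1L, n)
  if (window_contains(head_w, fwd, max_mismatch) &&
      window_contains(tail_w, rev_rc, max_mismatch)) return("sense")
  # the antisense test on the flipped read reuses the same two windows:
  # revcomp(read) head window = revcomp(tail window)
  if (window_contains(revcomp(tail_w), fwd, max_mismatch) &&
      window_contains(revcomp(head_w), rev_rc, max_mismatch))
    return("antisense")
  NA_character_
}

composite_primers <- function(panel, two_level, include_padding) {
  if (two_level) {
    pad <- if (include_padding) panel$padding else ""
    list(fwd = paste0(pad, panel$barcode, panel$fwd_primer),
         rev = paste0(pad, panel$barcode, panel$rev_primer))
  } else {
    list(fwd = panel$fwd_primer, rev = panel$rev_primer)
  }
}

#' Cluster CCS reads by barcode/primer matching
#'
#' One-level clustering matches each amplicon's primer pair in a short end
#' window (default 21 bp); two-level clustering matches
#' barcode(+padding)+primer composites in a wider window (default 121 bp,
#' room for padding + barcode + primer plus slack). A read matching exactly
#' one panel entry is assigned; reads matching none or more than one are set
#' aside with reasons `no_match` / `ambiguous`, and CCS rows that were not
#' emitted upstream are set aside as `filtered`.
#'
#' @param ccs CCS tibble ([build_ccs_all()] or [read_ccs_fastq()]).
#' @param panel panel tibble; barcodes are required iff `two_level`.
#' @param search_space end-window length; default 21 (one-level) or 121
#'   (two-level).
#' @param two_level match barcode+primer composites instead of bare primers.
#' @param include_padding prepend the shared padding to the composite
#'   (two-level only; the padding sits outermost on the synthesis oligo).
#' @param max_mismatch Hamming tolerance inside a primer occurrence
#'   (default 0 = exact).
#' @return object of class `cluster_map`: list with `assignments`
#'   (molecule_id, sample_id, amplicon_id, orientation) and `unassigned`
#'   (molecule_id, reason).
#' @export
cluster_ccs <- function(ccs, panel, search_space = NULL, two_level = FALSE,
                        include_padding = TRUE, max_mismatch = 0) {
  if (is.null(panel) || nrow(panel) == 0)
    stop("input error: empty primer panel", call. = FALSE)
  if (two_level && any(is.na(panel$barcode) | panel$barcode == ""))
    stop("input error: two-level clustering requires barcodes in the panel",
         call. = FALSE)
  if (!two_level) {
    panel <- panel[!duplicated(panel$amplicon_id), , drop = FALSE]
    panel$sample_id <- NA_character_
  }
  if (is.null(search_space)) search_space <- if (two_level) 121L else 21L
  comp <- composite_primers(panel, two_level, include_padding)
  if (search_space < max(nchar(comp$fwd), nchar(comp$rev)))
    stop("parameter error: search_space shorter than a composite primer",
         call. = FALSE)

  assigned <- vector("list", nrow(ccs))
  unassigned <- vector("list", nrow(ccs))
  for (i in seq_len(nrow(ccs))) {
    mol <- ccs$molecule_id[i]
    if (!isTRUE(ccs$emitted[i])) {
      unassigned[[i]] <- tibble(molecule_id = mol, reason = "filtered")
      next
    }
    hits <- integer(0)
    ori <- character(0)
    for (j in seq_len(nrow(panel))) {
      o <- match_primer_pair(ccs$sequence[i], comp$fwd[j], comp$rev[j],
                             search_space, max_mismatch)
      if (!is.na(o)) { hits <- c(hits, j); ori <- c(ori, o) }
    }
    if (length(hits) == 1L) {
      assigned[[i]] <- tibble(
        molecule_id = mol, sample_id = panel$sample_id[hits],
        amplicon_id = panel$amplicon_id[hits], orientation = ori)
    } else {
      unassigned[[i]] <- tibble(
        molecule_id = mol,
        reason = if (length(hits) == 0L) "no_match" else "ambiguous")
    }
  }
  empty_a <- tibble(molecule_id = character(), sample_id = character(),
                    amplicon_id = character(), orientation = character())
  empty_u <- tibble(molecule_id = character(), reason = character())
  structure(list(
    assignments = rbind(empty_a, do.call(rbind, assigned[!vapply(assigned, is.null, TRUE)])),
    unassigned = rbind(empty_u, do.call(rbind, unassigned[!vapply(unassigned, is.null, TRUE)]))),
    class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  k <- nrow(unique(x$assignments[c("sample_id", "amplicon_id")]))
  cat(sprintf("<cluster_map> %d molecule(s) in %d cluster(s); %d unassigned\n",
              nrow(x$assignments), k, nrow(x$unassigned)))
  if (nrow(x$unassigned) > 0) print(table(x$unassigned$reason))
  invisible(x)
}

cluster_label <- function(sample_id, amplicon_id) {
  paste0(ifelse(is.na(sample_id), "nobc", sample_id), "__", amplicon_id)
}

#' Write per-cluster raw-read whitelists
#'
#' One plain-text file per non-empty cluster
#' (`<sample|nobc>__<amplicon>.whitelist.txt`, one molecule id per line),
#' for use as a whitelist restricting downstream polishing to that cluster's
#' raw reads, plus `cluster_summary.tsv` (per-cluster molecule and subread
#' counts) and `unassigned.tsv` (molecule, reason).
#'
#' @param cmap a `cluster_map`.
#' @param out_dir output directory (created if needed).
#' @param n_subreads optional named integer vector (molecule id -> subread
#'   count) used for the summary's subread totals.
#' @return the summary tibble, invisibly.
#' @export
write_whitelists <- function(cmap, out_dir, n_subreads = NULL) {
  stopifnot(inherits(cmap, "cluster_map"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("I/O error: cannot create directory '%s'", out_dir),
         call. = FALSE)
  a <- cmap$assignments
  a$cluster <- cluster_label(a$sample_id, a$amplicon_id)
  summaries <- list()
  for (cl in unique(a$cluster)) {
    mols <- a$molecule_id[a$cluster == cl]
    writeLines(mols, file.path(out_dir, paste0(cl, ".whitelist.txt")))
    nsub <- if (is.null(n_subreads)) NA_integer_
            else sum(n_subreads[mols], na.rm = TRUE)
    summaries[[cl]] <- tibble(
      cluster = cl,
      sample_id = a$sample_id[a$cluster == cl][1],
      amplicon_id = a$amplicon_id[a$cluster == cl][1],
      n_molecules = length(mols), n_subreads = nsub)
  }
  summary_tbl <- if (length(summaries)) do.call(rbind, summaries)
    else tibble(cluster = character(), sample_id = character(),
                amplicon_id = character(), n_molecules = integer(),
                n_subreads = integer())
  write.table(summary_tbl, file.path(out_dir, "cluster_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cmap$unassigned, file.path(out_dir, "unassigned.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary_tbl)
}

#' Read whitelist files from a directory
#'
#' @param dir directory holding `*.whitelist.txt` files.
#' @return named list (cluster label -> character vector of molecule ids).
#' @export
read_whitelists <- function(dir) {
  files <- list.files(dir, pattern = "\\.whitelist\\.txt$", full.names = TRUE)
  out <- lapply(files, readLines)
  names(out) <- sub("\\.whitelist\\.txt$", "", basename(files))
  out
}
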