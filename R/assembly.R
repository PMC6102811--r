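# Overlap-layout-consensus assembly of trimmed amplicon consensus sequences,
# per sample. Overlaps are dovetail (suffix-prefix) or containment alignments
# in either orientation; members are laid out at fixed offsets from the
# overlap edges and a per-column vote is taken with explicit conflict rules:
# two disagreeing voters write an N, three or more voters write the most
# frequent base, and a >=3-voter tie also writes an N (the conservative
# extension of the two-voter rule).

#' Trim a fixed number of bases from each end of a sequence
#'
#' Used to remove extraneous ends (padding, barcodes) from consensus
#' sequences before assembly.
#'
#' @param seq DNA string.
#' @param trim_bp bases to remove from each end; must satisfy
#'   `2 * trim_bp < nchar(seq)`.
#' @return the trimmed sequence.
#' @export
trim_ends <- function(seq, trim_bp) {
  assert_scalar_number(trim_bp, "trim_bp", lo = 0, integer = TRUE)
  n <- nchar(seq)
  if (2 * trim_bp >= n)
    stop(sprintf("parameter error: trim_bp %d would remove the whole %d bp sequence",
                 trim_bp, n), call. = FALSE)
  substr(seq, trim_bp + 1L, n - trim_bp)
}

overlap_configs <- function(a, b) {
  rb <- revcomp(b)
  la <- nchar(a); lb <- nchar(b)
  cfg <- list()
  add <- function(r, rel, kind, offset) {
    cfg[[length(cfg) + 1L]] <<- list(
      score = r$score, matches = r$matches, columns = r$columns,
      rel = rel, kind = kind, offset = offset)
  }
  r <- .cpp_overlap_align(a, b, 0L);  add(r, "same", "dovetail", r$a_start)
  r <- .cpp_overlap_align(b, a, 0L);  add(r, "same", "dovetail", -r$a_start)
  r <- .cpp_overlap_align(a, rb, 0L); add(r, "flip", "dovetail", r$a_start)
  r <- .cpp_overlap_align(rb, a, 0L); add(r, "flip", "dovetail", -r$a_start)
  r <- .cpp_overlap_align(a, b, 1L);  add(r, "same", "containment", r$a_start)
  r <- .cpp_overlap_align(b, a, 1L);  add(r, "same", "containment", -r$a_start)
  r <- .cpp_overlap_align(a, rb, 1L); add(r, "flip", "containment", r$a_start)
  r <- .cpp_overlap_align(rb, a, 1L); add(r, "flip", "containment", -r$a_start)
  cfg
}

#' Find pairwise overlaps among consensus sequences
#'
#' Every pair is tested for dovetail (suffix-prefix) and containment
#' alignments in both relative orientations; the best-scoring configuration
#' passing the length and identity thresholds becomes the pair's edge, so
#' the overlap graph is simple.
#'
#' @param seqs named character vector of (trimmed) consensus sequences.
#' @param min_overlap minimum overlap alignment length in bp (default 40).
#' @param min_identity minimum overlap identity, matches / alignment columns
#'   (default 0.94).
#' @return tibble of edges: from, to, rel (`same`/`flip`), kind
#'   (`dovetail`/`containment`), offset (of `to` relative to `from`, in
#'   `from`'s orientation frame, with `to` flipped when rel = `flip`),
#'   overlap_len, identity, score.
#' @export
find_overlaps <- function(seqs, min_overlap = 40, min_identity = 0.94) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  ids <- names(seqs)
  edges <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        cfg <- overlap_configs(seqs[[i]], seqs[[j]])
        ok <- Filter(function(c)
          c$columns >= min_overlap &&
          c$matches / c$columns >= min_identity, cfg)
        if (length(ok) == 0) next
        best <- ok[[which.max(vapply(ok, function(c) c$score, numeric(1)))]]
        edges[[length(edges) + 1L]] <- tibble(
          from = ids[i], to = ids[j], rel = best$rel, kind = best$kind,
          offset = as.integer(best$offset),
          overlap_len = as.integer(best$columns),
          identity = best$matches / best$columns, score = best$score)
      }
    }
  }
  if (length(edges) == 0)
    return(tibble(from = character(), to = character(), rel = character(),
                  kind = character(), offset = integer(),
                  overlap_len = integer(), identity = numeric(),
                  score = numeric()))
  do.call(rbind, edges)
}

# place `v` given `u`'s placement and an edge expressed in u's "+" frame
place_neighbor <- function(p_u, o_u, len_u, len_v, offset, rel) {
  if (o_u == "+") {
    list(p = p_u + offset, o = if (rel == "same") "+" else "-")
  } else {
    list(p = p_u + len_u - offset - len_v,
         o = if (rel == "same") "-" else "+")
  }
}

#' Lay out overlapping sequences and call the assembly consensus
#'
#' Members are placed at offsets implied by the overlap edges (greedy
#' breadth-first from the longest sequence of each connected component;
#' contradictory placements raise an assembly error). Per column: one voter
#' writes its base; two agreeing voters write the base; two disagreeing
#' voters write an N; three or more voters write the most frequent base,
#' with ties written as N.
#'
#' @param seqs named character vector (same set passed to
#'   [find_overlaps()]).
#' @param edges overlap edge tibble from [find_overlaps()].
#' @param sample_id sample label carried onto the result (optional).
#' @return object of class `tiled_assembly`: list with `sample_id`,
#'   `contigs` (tibble: contig_id, sequence, n_members, length),
#'   `layout` (tibble: member, contig, offset, orientation),
#'   `n_positions` (tibble: contig_id, start, end; 0-based half-open runs of
#'   N), and `singletons` (ids of members in no overlap).
#' @export
layout_consensus <- function(seqs, edges, sample_id = NA_character_) {
  ids <- names(seqs)
  lens <- nchar(seqs)
  adj <- setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(edges))) {
    e <- edges[k, ]
    lf <- lens[[e$from]]; lt <- lens[[e$to]]
    adj[[e$from]] <- c(adj[[e$from]],
                       list(list(v = e$to, rel = e$rel, offset = e$offset)))
    # reverse edge, re-expressed in `to`'s own "+" frame
    off_r <- if (e$rel == "same") -e$offset else e$offset + lt - lf
    adj[[e$to]] <- c(adj[[e$to]],
                     list(list(v = e$from, rel = e$rel, offset = off_r)))
  }
  placed <- list()
  comp_of <- setNames(rep(NA_integer_, length(ids)), ids)
  n_comp <- 0L
  for (start in ids[order(-lens)]) {
    if (!is.na(comp_of[[start]])) next
    n_comp <- n_comp + 1L
    placed[[start]] <- list(p = 0L, o = "+")
    comp_of[[start]] <- n_comp
    queue <- start
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (e in adj[[u]]) {
        pl <- place_neighbor(placed[[u]]$p, placed[[u]]$o,
                             lens[[u]], lens[[e$v]], e$offset, e$rel)
        if (is.na(comp_of[[e$v]])) {
          placed[[e$v]] <- pl
          comp_of[[e$v]] <- n_comp
          queue <- c(queue, e$v)
        } else if (placed[[e$v]]$p != pl$p || placed[[e$v]]$o != pl$o) {
          stop("assembly error: inconsistent layout offsets (contradictory overlap edges)",
               call. = FALSE)
        }
      }
    }
  }
  comp_sizes <- table(comp_of)
  singletons <- names(comp_of)[comp_of %in% as.integer(names(comp_sizes)[comp_sizes == 1])]
  contigs <- list(); layout <- list(); npos <- list()
  ci <- 0L
  for (comp in sort(unique(comp_of[!(ids %in% singletons)]))) {
    ci <- ci + 1L
    members <- ids[comp_of == comp]
    offs <- vapply(members, function(m) placed[[m]]$p, numeric(1))
    offs <- offs - min(offs)
    oris <- vapply(members, function(m) placed[[m]]$o, character(1))
    width <- max(offs + lens[members])
    cid <- sprintf("%s__contig%d",
                   ifelse(is.na(sample_id), "nobc", sample_id), ci)
    mat <- matrix(NA_character_, nrow = length(members), ncol = width)
    for (mi in seq_along(members)) {
      s <- seqs[[members[mi]]]
      if (oris[mi] == "-") s <- revcomp(s)
      mat[mi, (offs[mi] + 1):(offs[mi] + nchar(s))] <-
        strsplit(s, "", fixed = TRUE)[[1]]
    }
    counts <- vapply(DNA_BASES, function(b) colSums(mat == b, na.rm = TRUE),
                     numeric(width))
    if (width == 1) counts <- matrix(counts, nrow = 1)
    mx <- apply(counts, 1, max)
    nwin <- rowSums(counts == mx)
    winner <- DNA_BASES[max.col(counts, ties.method = "first")]
    cons <- ifelse(nwin == 1L, winner, "N")
    contig_seq <- paste(cons, collapse = "")
    contigs[[ci]] <- tibble(contig_id = cid, sequence = contig_seq,
                            n_members = length(members),
                            length = nchar(contig_seq))
    layout[[ci]] <- tibble(member = members, contig = cid,
                           offset = as.integer(offs), orientation = oris)
    is_n <- cons == "N"
    if (any(is_n)) {
      r <- rle(is_n)
      endc <- cumsum(r$lengths)
      startc <- endc - r$lengths
      npos[[ci]] <- tibble(contig_id = cid,
                           start = startc[r$values], end = endc[r$values])
    }
  }
  structure(list(
    sample_id = sample_id,
    contigs = if (length(contigs)) do.call(rbind, contigs)
      else tibble(contig_id = character(), sequence = character(),
                  n_members = integer(), length = integer()),
    layout = if (length(layout)) do.call(rbind, layout)
      else tibble(member = character(), contig = character(),
                  offset = integer(), orientation = character()),
    n_positions = if (length(npos)) do.call(rbind, npos)
      else tibble(contig_id = character(), start = integer(), end = integer()),
    singletons = singletons),
    class = "tiled_assembly")
}

#' @export
print.tiled_assembly <- function(x, ...) {
  cat(sprintf("<tiled_assembly> sample %s: %d contig(s), %d singleton(s)\n",
              ifelse(is.na(x$sample_id), "nobc", x$sample_id),
              nrow(x$contigs), length(x$singletons)))
  invisible(x)
}

#' Assemble one sample's consensus sequences
#'
#' Trims `trim_bp` bases from each end of every emitted consensus, finds
#' overlaps, and lays out the assembly. Optionally writes the merged
#' pre-assembly multi-FASTA, the assembly FASTA, a layout TSV and a BED of
#' N positions (0-based half-open).
#'
#' @param records consensus records for one sample ([consensus_all()]
#'   output, or any tibble with cluster/sequence/status columns).
#' @param trim_bp bases trimmed from each consensus end before assembly.
#' @param min_overlap,min_identity overlap thresholds ([find_overlaps()]).
#' @param out_dir optional output directory for the FASTA/TSV/BED artifacts.
#' @param sample_id sample label (defaults to the records' sample).
#' @return a `tiled_assembly`.
#' @export
assemble_sample <- function(records, trim_bp = 0, min_overlap = 40,
                            min_identity = 0.94, out_dir = NULL,
                            sample_id = NULL) {
  em <- records[records$status == "emitted", , drop = FALSE]
  if (is.null(sample_id))
    sample_id <- if (nrow(em)) em$sample_id[1] else NA_character_
  seqs <- setNames(vapply(em$sequence, trim_ends, character(1),
                          trim_bp = trim_bp, USE.NAMES = FALSE),
                   em$cluster)
  edges <- find_overlaps(seqs, min_overlap = min_overlap,
                         min_identity = min_identity)
  asm <- layout_consensus(seqs, edges, sample_id = sample_id)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    tag <- ifelse(is.na(sample_id), "nobc", sample_id)
    write_fasta(seqs, file.path(out_dir, paste0(tag, "_preassembly.fasta")))
    if (nrow(asm$contigs) > 0)
      write_fasta(setNames(asm$contigs$sequence, asm$contigs$contig_id),
                  file.path(out_dir, paste0(tag, "_assembly.fasta")))
    write.table(asm$layout, file.path(out_dir, paste0(tag, "_layout.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    bed <- asm$n_positions
    write.table(bed, file.path(out_dir, paste0(tag, "_Npositions.bed")),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  asm
}
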