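# Accuracy evaluation: local alignment of consensus/assembly sequences to a
# reference with per-alignment error accounting, an error-type decomposition,
# and a bootstrap experiment relating CCS sampling depth to consensus and
# assembly accuracy.

#' Align a query to a reference and report identity and error counts
#'
#' Best local alignment (match +1, mismatch -2, gap open -5, gap extend -2,
#' approximating standard nucleotide-BLAST scoring at these match/mismatch
#' scores) against every locus; the best-scoring locus wins. Percent
#' identity is `100 * matches / alignment_columns` where columns include
#' gap positions. Classification: `complete` = 100% identity with the whole
#' query aligned; `truncated` = 100% identity over a partial span;
#' `partial` = identity below 100; `unmapped` = no alignment with positive
#' score.
#'
#' @param query DNA string.
#' @param reference a `reference_set` or named character vector of loci.
#' @param query_id label carried into the report.
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' Both strands of the query are tried and the better-scoring one is
#' reported (`strand`); query coordinates refer to the aligned strand.
#'
#' @return one-row tibble: query_id, locus_id, strand, target_start,
#'   target_end (0-based half-open), percent_identity, n_match, n_mismatch,
#'   n_insertion_bases, n_deletion_bases, n_insertion_events,
#'   n_deletion_events, alignment_columns, query_from, query_to,
#'   classification.
#' @export
align_and_report <- function(query, reference, query_id = "query",
                             gap_open = 5, gap_extend = 2) {
  if (!is.character(query) || length(query) != 1L || nchar(query) == 0)
    stop("input error: query must be a non-empty DNA string", call. = FALSE)
  loci <- if (inherits(reference, "reference_set")) reference$loci else reference
  stopifnot(length(loci) >= 1, !is.null(names(loci)))
  # ACGTN alphabet; an N (assembly conflict) never matches anything
  alpha <- c("A", "C", "G", "T", "N")
  submat <- matrix(-2, 5, 5, dimnames = list(alpha, alpha))
  diag(submat) <- 1
  submat["N", ] <- -2
  submat[, "N"] <- -2
  best <- NULL; best_score <- -Inf; best_locus <- NA_character_
  best_strand <- "+"
  for (strand in c("+", "-")) {
    qd <- Biostrings::DNAString(if (strand == "+") query else revcomp(query))
    for (lid in names(loci)) {
      pa <- Biostrings::pairwiseAlignment(
        qd, Biostrings::DNAString(loci[[lid]]), type = "local",
        substitutionMatrix = submat, gapOpening = gap_open,
        gapExtension = gap_extend)
      if (Biostrings::score(pa) > best_score) {
        best <- pa; best_score <- Biostrings::score(pa); best_locus <- lid
        best_strand <- strand
      }
    }
  }
  unmapped <- function() tibble(
    query_id = query_id, locus_id = NA_character_, strand = NA_character_,
    target_start = NA_integer_, target_end = NA_integer_,
    percent_identity = 0, n_match = 0L, n_mismatch = 0L,
    n_insertion_bases = 0L, n_deletion_bases = 0L,
    n_insertion_events = 0L, n_deletion_events = 0L,
    alignment_columns = 0L, query_from = NA_integer_,
    query_to = NA_integer_, classification = "unmapped")
  if (best_score <= 0) return(unmapped())
  ni <- Biostrings::nindel(best)
  ins <- Biostrings::insertion(ni)   # extra bases in the query
  del <- Biostrings::deletion(ni)    # bases missing from the query
  n_match <- Biostrings::nmatch(best)
  n_mism <- Biostrings::nmismatch(best)
  cols <- as.integer(n_match + n_mism + ins[1, "WidthSum"] + del[1, "WidthSum"])
  pid <- unname(100 * n_match / cols)
  q_from <- Biostrings::start(Biostrings::pattern(best))
  q_to <- Biostrings::end(Biostrings::pattern(best))
  full_query <- (q_from == 1L && q_to == nchar(query))
  classification <- if (pid == 100 && full_query) "complete"
    else if (pid == 100) "truncated" else "partial"
  tibble(
    query_id = query_id, locus_id = best_locus, strand = best_strand,
    target_start = Biostrings::start(Biostrings::subject(best)) - 1L,
    target_end = Biostrings::end(Biostrings::subject(best)),
    percent_identity = pid, n_match = as.integer(n_match),
    n_mismatch = as.integer(n_mism),
    n_insertion_bases = as.integer(ins[1, "WidthSum"]),
    n_deletion_bases = as.integer(del[1, "WidthSum"]),
    n_insertion_events = as.integer(ins[1, "Length"]),
    n_deletion_events = as.integer(del[1, "Length"]),
    alignment_columns = as.integer(cols),
    query_from = q_from, query_to = q_to,
    classification = classification)
}

#' Decompose alignment errors by type
#'
#' Totals and fractions of insertion, deletion and substitution
#' (single-nucleotide) errors across a set of alignment reports. Indels are
#' counted in bases by default; `mode = "events"` counts gap runs instead.
#'
#' @param reports tibble with columns n_mismatch, n_insertion_bases,
#'   n_deletion_bases (and `_events` variants), e.g. rows from
#'   [align_and_report()] or [bootstrap_experiment()].
#' @param mode `"bases"` or `"events"`.
#' @return list with `totals` and `fractions` (named: insertion, deletion,
#'   substitution), `total_errors`, `mode` and `all_perfect` (fractions are
#'   reported as 0 with `all_perfect = TRUE` when there are no errors).
#' @export
classify_errors <- function(reports, mode = c("bases", "events")) {
  mode <- match.arg(mode)
  stopifnot(nrow(reports) >= 1)
  ins <- sum(reports[[if (mode == "bases") "n_insertion_bases"
                      else "n_insertion_events"]])
  del <- sum(reports[[if (mode == "bases") "n_deletion_bases"
                      else "n_deletion_events"]])
  sub <- sum(reports$n_mismatch)
  tot <- ins + del + sub
  fr <- if (tot > 0) c(insertion = ins / tot, deletion = del / tot,
                       substitution = sub / tot)
        else c(insertion = 0, deletion = 0, substitution = 0)
  list(totals = c(insertion = ins, deletion = del, substitution = sub),
       fractions = fr, total_errors = tot, mode = mode,
       all_perfect = tot == 0)
}

#' Bootstrap the relationship between CCS sampling depth and accuracy
#'
#' For every amplicon cluster, sampling depth `d` and replicate: draw `d`
#' CCS read ids with replacement, gather the corresponding raw subreads
#' (a CCS id drawn twice contributes its subreads twice), polish them into
#' a consensus (no support filter), and align it to the reference. Each
#' replicate's consensus set is then assembled per sample and contigs are
#' aligned too; an assembly's subread depth is the minimum subread count
#' over its member clusters.
#'
#' @param bundle a simulated library bundle ([simulate_library()]).
#' @param depths integer vector of CCS sample sizes (default 1:40).
#' @param replicates replicates per depth (default 25).
#' @param seed RNG seed; results are deterministic for a fixed seed.
#' @param amplicons optional amplicon id subset.
#' @param assemble also assemble each replicate's consensus set
#'   (default TRUE).
#' @param trim_bp,min_overlap,min_identity assembly parameters.
#' @param min_predicted_accuracy,band_frac,max_iters CCS/polish parameters.
#' @return tibble with one row per (sample, amplicon, depth, replicate):
#'   consensus alignment columns (percent_identity, n_mismatch,
#'   n_insertion_bases, ...), n_subreads, and assembly columns
#'   (assembly_contig, assembly_identity, assembly_n_subreads; `NA` when the
#'   amplicon's consensus joined no contig).
#' @export
bootstrap_experiment <- function(bundle, depths = 1:40, replicates = 25,
                                 seed = 1, amplicons = NULL, assemble = TRUE,
                                 trim_bp = 0, min_overlap = 40,
                                 min_identity = 0.94,
                                 min_predicted_accuracy = 0.90,
                                 band_frac = 0.10, max_iters = 5) {
  stopifnot(!is.null(bundle$reads), !is.null(bundle$panel))
  two_level <- any(!is.na(bundle$panel$sample_id))
  ccs <- build_ccs_all(bundle$reads,
                       min_predicted_accuracy = min_predicted_accuracy)
  cmap <- cluster_ccs(ccs, bundle$panel, two_level = two_level)
  a <- cmap$assignments
  if (!is.null(amplicons)) a <- a[a$amplicon_id %in% amplicons, , drop = FALSE]
  if (nrow(a) == 0) stop("no clustered CCS reads to bootstrap", call. = FALSE)
  a$cluster <- cluster_label(a$sample_id, a$amplicon_id)
  clusters <- split(a$molecule_id, a$cluster)
  meta <- a[!duplicated(a$cluster), c("cluster", "sample_id", "amplicon_id")]
  subread_seqs <- lapply(bundle$reads, function(r) r$subreads$sequence)
  loci <- bundle$reference$loci

  with_seed(seed, {
    rows <- list()
    for (ci in seq_len(nrow(meta))) {
      cl <- meta$cluster[ci]
      ids <- clusters[[cl]]
      if (length(ids) == 0) {
        warning(sprintf("cluster %s has no CCS reads; skipped", cl))
        next
      }
      for (d in depths) {
        for (r in seq_len(replicates)) {
          picked <- sample(ids, d, replace = TRUE)
          subs <- unlist(subread_seqs[picked], use.names = FALSE)
          pol <- polish_cluster(subs, max_iters = max_iters,
                                band_frac = band_frac)
          rep_row <- align_and_report(pol$sequence, loci, query_id = cl)
          rows[[length(rows) + 1L]] <- cbind(
            tibble(sample_id = meta$sample_id[ci],
                   amplicon_id = meta$amplicon_id[ci],
                   ccs_sample_size = d, replicate = r,
                   n_subreads = length(subs),
                   consensus = pol$sequence),
            rep_row[, setdiff(names(rep_row), "query_id")])
        }
      }
    }
    res <- do.call(rbind, rows)
    res$assembly_contig <- NA_character_
    res$assembly_identity <- NA_real_
    res$assembly_n_subreads <- NA_integer_
    if (assemble) {
      key <- paste(ifelse(is.na(res$sample_id), "nobc", res$sample_id),
                   res$ccs_sample_size, res$replicate)
      for (k in unique(key)) {
        sel <- which(key == k)
        if (length(sel) < 2) next
        recs <- tibble(cluster = res$amplicon_id[sel],
                       sample_id = res$sample_id[sel],
                       sequence = res$consensus[sel], status = "emitted")
        asm <- assemble_sample(recs, trim_bp = trim_bp,
                               min_overlap = min_overlap,
                               min_identity = min_identity)
        if (nrow(asm$contigs) == 0) next
        for (g in seq_len(nrow(asm$contigs))) {
          cid <- asm$contigs$contig_id[g]
          members <- asm$layout$member[asm$layout$contig == cid]
          arep <- align_and_report(asm$contigs$sequence[g], loci,
                                   query_id = cid)
          midx <- sel[res$amplicon_id[sel] %in% members]
          res$assembly_contig[midx] <- cid
          res$assembly_identity[midx] <- arep$percent_identity
          res$assembly_n_subreads[midx] <- min(res$n_subreads[midx])
        }
      }
    }
    res$consensus <- NULL
    res
  })
}

#' Write a results table to TSV with a '#' column-header comment
#'
#' Shared writer for alignment reports, bootstrap results and depth
#' summaries: the first line is a `#`-prefixed tab-separated column list,
#' followed by the rows.
#'
#' @param tbl a tibble/data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(tbl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(tbl), collapse = "\t")), con)
  write.table(tbl, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Summarise bootstrap results per sampling depth
#'
#' Pools amplicons and reports, per depth, the mean/min/max consensus
#' identity, the mean/min/max assembly identity, and the number of distinct
#' assemblies that were 100% identical to the reference.
#'
#' @param results tibble from [bootstrap_experiment()].
#' @return tibble with one row per depth.
#' @export
summarize_depth_accuracy <- function(results) {
  stopifnot(nrow(results) >= 1)
  out <- lapply(sort(unique(results$ccs_sample_size)), function(d) {
    sel <- results[results$ccs_sample_size == d, , drop = FALSE]
    asm <- unique(sel[!is.na(sel$assembly_contig),
                      c("sample_id", "replicate", "assembly_contig",
                        "assembly_identity")])
    tibble(
      ccs_sample_size = d,
      n_consensus = nrow(sel),
      mean_consensus_identity = mean(sel$percent_identity),
      min_consensus_identity = min(sel$percent_identity),
      max_consensus_identity = max(sel$percent_identity),
      n_assemblies = nrow(asm),
      mean_assembly_identity = if (nrow(asm)) mean(asm$assembly_identity)
        else NA_real_,
      min_assembly_identity = if (nrow(asm)) min(asm$assembly_identity)
        else NA_real_,
      max_assembly_identity = if (nrow(asm)) max(asm$assembly_identity)
        else NA_real_,
      n_perfect_assemblies = sum(asm$assembly_identity == 100))
  })
  do.call(rbind, out)
}
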