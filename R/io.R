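# Readers/writers for the plain-text formats the pipeline exchanges:
# FASTA/FASTQ (via Biostrings), the primer/barcode panel TSV, the simulator
# truth table, and per-cluster whitelists.

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' Qualities are discarded; no stage of the pipeline consumes them.
#'
#' @param path FASTQ file.
#' @return named character vector of sequences.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write sequences to FASTQ with a constant placeholder quality
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param qual_char single quality character applied to every base
#'   (default `"5"`, i.e. Q20).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, qual_char = "5") {
  ids <- names(seqs)
  stopifnot(!is.null(ids))
  qual <- vapply(nchar(seqs), function(n) strrep(qual_char, n), character(1))
  lines <- as.vector(rbind(paste0("@", ids), unname(seqs), "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write a primer/barcode panel to TSV
#'
#' Columns: sample_id, amplicon_id, barcode, padding, fwd_primer, rev_primer.
#' Unbarcoded (one-level) panels carry `NA` sample ids and empty barcodes.
#'
#' @param panel panel tibble (see [barcode_panel()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  cols <- c("sample_id", "amplicon_id", "barcode", "padding",
            "fwd_primer", "rev_primer")
  stopifnot(all(cols %in% names(panel)))
  write.table(panel[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a primer/barcode panel from TSV
#'
#' @param path panel TSV written by [write_panel()].
#' @return panel tibble.
#' @export
read_panel <- function(path) {
  df <- read.delim(path, colClasses = "character", na.strings = "NA")
  df$barcode[is.na(df$barcode)] <- ""
  df$padding[is.na(df$padding)] <- ""
  as_tibble(df)
}

write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_truth <- function(path) {
  as_tibble(read.delim(path, colClasses = c(
    molecule_id = "character", sample_id = "character",
    amplicon_id = "character", n_passes = "integer",
    template_md5 = "character")))
}

#' Read a subreads FASTQ into raw-read objects
#'
#' Subread ids must share a `"<movie>/<zmw>/"` prefix per molecule; records
#' are grouped on that prefix and ordered by their pass index.
#'
#' @param path subreads FASTQ.
#' @return named list of raw-read objects keyed by molecule id.
#' @export
read_subreads_fastq <- function(path) {
  seqs <- read_fastq(path)
  ids <- names(seqs)
  mol <- sub("/[^/]*$", "", ids)
  k <- suppressWarnings(as.integer(sub("^.*/", "", ids)))
  ord <- order(match(mol, unique(mol)), k)
  seqs <- seqs[ord]; ids <- ids[ord]; mol <- mol[ord]
  split_idx <- split(seq_along(ids), factor(mol, levels = unique(mol)))
  reads <- lapply(split_idx, function(ix) {
    structure(list(
      molecule_id = mol[ix[1]],
      true_sample_id = NA_character_,
      true_amplicon_id = NA_character_,
      subreads = tibble(
        subread_id = ids[ix],
        sequence = unname(seqs[ix]),
        orientation = NA_character_)),
      class = "raw_read")
  })
  names(reads) <- unique(mol)
  reads
}

#' Write CCS reads to FASTQ
#'
#' Emitted reads only; ids follow the `"<movie>/<zmw>/ccs"` convention.
#'
#' @param ccs CCS tibble from [build_ccs_all()].
#' @param path output FASTQ.
#' @return `path`, invisibly.
#' @export
write_ccs_fastq <- function(ccs, path) {
  keep <- ccs[ccs$emitted, , drop = FALSE]
  seqs <- setNames(keep$sequence, paste0(keep$molecule_id, "/ccs"))
  write_fastq(seqs, path, qual_char = "I")
  invisible(path)
}

#' Read a CCS FASTQ into a CCS tibble
#'
#' Pass counts and predicted accuracies are unknown for externally produced
#' CCS files and are set to `NA`; every read is treated as emitted.
#'
#' @param path CCS FASTQ with ids `"<movie>/<zmw>/ccs"`.
#' @return CCS tibble.
#' @export
read_ccs_fastq <- function(path) {
  seqs <- read_fastq(path)
  tibble(
    molecule_id = sub("/ccs$", "", names(seqs)),
    sequence = unname(seqs),
    n_passes = NA_integer_,
    predicted_accuracy = NA_real_,
    emitted = TRUE,
    reason = NA_character_)
}
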