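# SMRT amplicon library simulator: multi-pass raw reads with alternating
# subread orientation and a per-base substitution/insertion/deletion error
# model, plus an extra insertion rate inside homopolymer runs (where the
# inserted base repeats the run base, emulating the systematic duplication
# errors long-read chemistry shows in such tracts).

#' Construct an error profile for the read simulator
#'
#' Per-base event probabilities. Substitution and deletion are mutually
#' exclusive per base; an insertion is placed after a base independently.
#' Inside homopolymer runs of length >= `run_min`, the insertion probability
#' is raised by `homopolymer_ins_rate` and the inserted base repeats the run
#' base.
#'
#' @param sub_rate substitution probability per base.
#' @param ins_rate insertion probability per base.
#' @param del_rate deletion probability per base.
#' @param homopolymer_ins_rate extra insertion probability inside runs.
#' @param run_min minimum run length for the homopolymer surcharge.
#' @return object of class `error_profile`.
#' @export
#' @examples
#' error_profile(0.02, 0.05, 0.03)
error_profile <- function(sub_rate = 0.03, ins_rate = 0.08, del_rate = 0.04,
                          homopolymer_ins_rate = 0, run_min = 4) {
  for (nm in c("sub_rate", "ins_rate", "del_rate", "homopolymer_ins_rate"))
    assert_scalar_number(get(nm), nm, lo = 0, hi = 1)
  assert_scalar_number(run_min, "run_min", lo = 1, integer = TRUE)
  if (sub_rate + ins_rate + del_rate > 0.5)
    stop("parameter error: sub_rate + ins_rate + del_rate must be <= 0.5",
         call. = FALSE)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate,
                 homopolymer_ins_rate = homopolymer_ins_rate,
                 run_min = run_min),
            class = "error_profile")
}

# Corrupt one template copy. protect_ends leaves the first/last `protect`
# template bases untouched (no events there, including insertions).
# Returns list(sequence, errors = tibble(pos, type) | NULL).
mutate_sequence <- function(template, profile, protect = 0, track = FALSE) {
  ch <- strsplit(template, "", fixed = TRUE)[[1]]
  n <- length(ch)
  prot <- rep(FALSE, n)
  if (protect > 0) {
    p <- min(protect, n)
    prot[seq_len(p)] <- TRUE
    prot[seq.int(n - p + 1L, n)] <- TRUE
  }
  r <- rle(ch)
  in_run <- rep(r$lengths >= profile$run_min, r$lengths)

  u <- runif(n)
  is_sub <- u < profile$sub_rate & !prot
  is_del <- u >= profile$sub_rate &
    u < profile$sub_rate + profile$del_rate & !prot
  ins_p <- profile$ins_rate + profile$homopolymer_ins_rate * in_run
  is_ins <- runif(n) < ins_p & !prot

  out <- ch
  if (any(is_sub)) {
    idx <- match(ch[is_sub], DNA_BASES)
    shift <- sample.int(3L, sum(is_sub), replace = TRUE)
    out[is_sub] <- DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
  }
  out[is_del] <- ""
  if (any(is_ins)) {
    ins_base <- character(sum(is_ins))
    run_ins <- in_run[is_ins]
    ins_base[run_ins] <- ch[is_ins][run_ins]  # duplicate the run base
    if (any(!run_ins))
      ins_base[!run_ins] <- sample(DNA_BASES, sum(!run_ins), replace = TRUE)
    out[is_ins] <- paste0(out[is_ins], ins_base)
  }
  errors <- NULL
  if (track) {
    errors <- tibble(
      pos = c(which(is_sub), which(is_del), which(is_ins)),
      type = rep(c("sub", "del", "ins"),
                 c(sum(is_sub), sum(is_del), sum(is_ins))))
    errors <- errors[order(errors$pos), ]
  }
  list(sequence = paste(out, collapse = ""), errors = errors)
}

#' Simulate one multi-pass raw read
#'
#' Subread `k` is an independently corrupted copy of the template,
#' reverse-complemented for even `k` so that orientations alternate along
#' the molecule, as successive passes over a circularised insert do.
#' Subreads are emitted already adapter-split; the SMRTbell adapter itself
#' is not modelled.
#'
#' @param template amplicon template (sense strand, including any barcode /
#'   padding ends).
#' @param n_passes number of subreads (>= 1).
#' @param profile an [error_profile()].
#' @param molecule_id molecule identifier, conventionally `"<movie>/<zmw>"`.
#' @param protect_ends leave this many template bases error-free at each end
#'   (0 disables; used to study clustering in isolation from end errors).
#' @param track_errors record per-subread error positions in an `errors`
#'   tibble (subread, pos, type) on the returned object.
#' @return object of class `raw_read`.
#' @export
simulate_raw_read <- function(template, n_passes, profile, molecule_id,
                              protect_ends = 0, track_errors = FALSE) {
  if (!is.character(template) || length(template) != 1L || nchar(template) == 0)
    stop("parameter error: template must be a non-empty DNA string",
         call. = FALSE)
  assert_scalar_number(n_passes, "n_passes", lo = 1, integer = TRUE)
  stopifnot(inherits(profile, "error_profile"))
  seqs <- character(n_passes)
  errs <- if (track_errors) vector("list", n_passes) else NULL
  for (k in seq_len(n_passes)) {
    m <- mutate_sequence(template, profile, protect = protect_ends,
                         track = track_errors)
    seqs[k] <- if (k %% 2L == 0L) revcomp(m$sequence) else m$sequence
    if (track_errors) {
      e <- m$errors
      e$subread <- k
      errs[[k]] <- e
    }
  }
  structure(list(
    molecule_id = molecule_id,
    true_sample_id = NA_character_,
    true_amplicon_id = NA_character_,
    subreads = tibble(
      subread_id = paste0(molecule_id, "/", seq_len(n_passes)),
      sequence = seqs,
      orientation = ifelse(seq_len(n_passes) %% 2L == 1L, "sense", "antisense")),
    errors = if (track_errors) do.call(rbind, errs) else NULL),
    class = "raw_read")
}

#' @export
print.raw_read <- function(x, ...) {
  cat(sprintf("<raw_read> %s: %d subread(s), lengths %d-%d\n", x$molecule_id,
              nrow(x$subreads), min(nchar(x$subreads$sequence)),
              max(nchar(x$subreads$sequence))))
  invisible(x)
}

# Sense-strand template for one panel row: padding+barcode+amplicon+
# revcomp(padding+barcode). The locus-specific primers are the amplicon ends
# themselves, so they are not concatenated again.
panel_template <- function(panel_row, ref, designs) {
  d <- designs[designs$amplicon_id == panel_row$amplicon_id, ]
  if (nrow(d) != 1L)
    stop(sprintf("amplicon '%s' not found in designs", panel_row$amplicon_id),
         call. = FALSE)
  amp <- substring(ref$loci[[d$locus_id]], d$start + 1, d$end)
  ext <- paste0(panel_row$padding, panel_row$barcode)
  paste0(ext, amp, revcomp(ext))
}

#' Simulate a SMRT amplicon library
#'
#' Generates `depth_per_amplicon` molecules for every panel row. Pass counts
#' are drawn from a shifted Poisson, `1 + Poisson(mean_passes - 1)`, so every
#' molecule has at least one subread and the mean equals `mean_passes`.
#'
#' @param ref a `reference_set`.
#' @param designs tibble from [design_tiling()].
#' @param panel tibble from [barcode_panel()].
#' @param depth_per_amplicon molecules per (sample, amplicon) (>= 1).
#' @param profile an [error_profile()].
#' @param mean_passes mean subreads per molecule (default 9, typical for
#'   3-5 kb amplicons in a long movie).
#' @param protect_ends per-template error-free end length (see
#'   [simulate_raw_read()]).
#' @param out_dir if non-`NULL`, write `subreads.fastq`, `truth.tsv`,
#'   `panel.tsv` and `reference.fasta` there.
#' @param movie movie name used in molecule ids `"<movie>/<zmw>"`.
#' @param seed RNG seed; the library (including files) is byte-identical for
#'   a fixed seed.
#' @return a library bundle: list with `reads` (named list of `raw_read`),
#'   `truth` (tibble: molecule_id, sample_id, amplicon_id, n_passes,
#'   template_md5), `panel`, `designs`, `reference`, and `paths`.
#' @export
simulate_library <- function(ref, designs, panel, depth_per_amplicon, profile,
                             mean_passes = 9, protect_ends = 0,
                             out_dir = NULL, movie = "sim_movie", seed = 1) {
  if (!is.numeric(depth_per_amplicon) || depth_per_amplicon < 1)
    stop("design error: depth_per_amplicon must be >= 1", call. = FALSE)
  assert_scalar_number(mean_passes, "mean_passes", lo = 1)
  stopifnot(inherits(profile, "error_profile"))
  with_seed(seed, {
    templates <- vapply(seq_len(nrow(panel)), function(i)
      panel_template(panel[i, ], ref, designs), character(1))
    md5s <- vapply(templates, md5_string, character(1), USE.NAMES = FALSE)
    zmw <- 0L
    reads <- list()
    rows <- vector("list", nrow(panel) * depth_per_amplicon)
    ri <- 0L
    for (i in seq_len(nrow(panel))) {
      for (d in seq_len(depth_per_amplicon)) {
        zmw <- zmw + 1L
        mol <- sprintf("%s/%d", movie, zmw)
        np <- 1L + rpois(1, mean_passes - 1)
        rr <- simulate_raw_read(templates[i], np, profile, mol,
                                protect_ends = protect_ends)
        rr$true_sample_id <- panel$sample_id[i]
        rr$true_amplicon_id <- panel$amplicon_id[i]
        reads[[mol]] <- rr
        ri <- ri + 1L
        rows[[ri]] <- tibble(
          molecule_id = mol, sample_id = panel$sample_id[i],
          amplicon_id = panel$amplicon_id[i], n_passes = np,
          template_md5 = md5s[i])
      }
    }
    truth <- do.call(rbind, rows)
    paths <- NULL
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir) &&
          !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
        stop(sprintf("I/O error: cannot create output directory '%s'", out_dir),
             call. = FALSE)
      paths <- list(
        subreads = file.path(out_dir, "subreads.fastq"),
        truth = file.path(out_dir, "truth.tsv"),
        panel = file.path(out_dir, "panel.tsv"),
        reference = file.path(out_dir, "reference.fasta"))
      all_sub <- do.call(rbind, lapply(reads, function(r) r$subreads))
      write_fastq(setNames(all_sub$sequence, all_sub$subread_id),
                  paths$subreads)
      write_truth(truth, paths$truth)
      write_panel(panel, paths$panel)
      write_fasta(ref$loci, paths$reference)
    }
    list(reads = reads, truth = truth, panel = panel, designs = designs,
         reference = ref, paths = paths)
  })
}
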