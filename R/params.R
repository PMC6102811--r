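# Single run-parameters file shared by every pipeline stage, plus the
# end-to-end orchestrator: ccs -> cluster -> consensus -> assemble
# (-> evaluate when a reference is given). Each stage logs what it did and
# writes a manifest (inputs, parameter hash, outputs) so any artifact can be
# traced to the exact effective parameters.

PARAM_DEFAULTS <- list(
  # paths
  subreads = NULL, ccs = NULL, panel = NULL, reference = NULL,
  out_dir = "ccscluster_out",
  # clustering
  search_space = NULL, two_level = FALSE, include_padding = TRUE,
  max_mismatch = 0,
  # ccs
  min_passes = 1, min_predicted_accuracy = 0.90,
  # consensus
  min_subreads = 100, min_subread_length = 0, max_iters = 5, band_frac = 0.10,
  # assembly
  trim_bp = NULL, min_overlap = 40, min_identity = 0.94,
  # evaluate
  depths = NULL, replicates = 25, seed = 1
)

validate_params <- function(p) {
  chk <- function(name, lo, hi = Inf, integer = FALSE) {
    if (!is.null(p[[name]]))
      tryCatch(assert_scalar_number(p[[name]], name, lo, hi, integer),
               error = function(e)
                 stop(sprintf("config error: %s", conditionMessage(e)),
                      call. = FALSE))
  }
  chk("search_space", 1, integer = TRUE)
  chk("max_mismatch", 0, integer = TRUE)
  chk("min_passes", 1, integer = TRUE)
  chk("min_predicted_accuracy", 0, 1)
  chk("min_subreads", 0, integer = TRUE)
  chk("min_subread_length", 0, integer = TRUE)
  chk("max_iters", 1, integer = TRUE)
  chk("band_frac", 0.01, 1)
  chk("trim_bp", 0, integer = TRUE)
  chk("min_overlap", 1, integer = TRUE)
  chk("min_identity", 0, 1)
  chk("replicates", 1, integer = TRUE)
  chk("seed", -2^31, 2^31, integer = TRUE)
  for (flag in c("two_level", "include_padding"))
    if (!is.logical(p[[flag]]) || length(p[[flag]]) != 1L)
      stop(sprintf("config error: '%s' must be true/false", flag),
           call. = FALSE)
  if (!is.null(p$depths) &&
      (!is.numeric(p$depths) || any(p$depths < 1)))
    stop("config error: 'depths' must be positive integers", call. = FALSE)
  invisible(p)
}

#' Default run parameters
#'
#' @return named list of every run parameter with its default.
#' @export
default_params <- function() PARAM_DEFAULTS

#' Load run parameters from a YAML/key-value file
#'
#' Flat keys; unknown keys are rejected, missing keys take their defaults
#' (search window 21/121 by clustering mode, CCS accuracy threshold 0.90,
#' consensus support threshold 100, ...). If a panel path is present the
#' two-level flag is cross-checked against the panel's barcodes. The
#' effective parameters are echoed via `message()`.
#'
#' @param path parameter file; an empty file yields all defaults.
#' @return validated parameter list (class `run_params`).
#' @export
load_params <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config error: parameter file '%s' not found", path),
         call. = FALSE)
  vals <- tryCatch(yaml::read_yaml(path),
                   error = function(e)
                     stop(sprintf("config error: malformed parameter file: %s",
                                  conditionMessage(e)), call. = FALSE))
  if (is.null(vals)) vals <- list()
  if (!is.list(vals))
    stop("config error: parameter file must hold key: value pairs",
         call. = FALSE)
  unknown <- setdiff(names(vals), names(PARAM_DEFAULTS))
  if (length(unknown) > 0)
    stop(sprintf("config error: unknown parameter key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  p <- PARAM_DEFAULTS
  p[names(vals)] <- vals
  validate_params(p)
  if (isTRUE(p$two_level) && !is.null(p$panel)) {
    if (file.exists(p$panel)) {
      pan <- read_panel(p$panel)
      if (any(is.na(pan$barcode) | pan$barcode == ""))
        stop("config error: two_level = true but the panel has entries without barcodes",
             call. = FALSE)
    }
  }
  shown <- p[!vapply(p, is.null, logical(1))]
  message("effective parameters: ",
          paste(sprintf("%s=%s", names(shown),
                        vapply(shown, function(v) paste(v, collapse = ","),
                               character(1))),
                collapse = " "))
  structure(p, class = "run_params")
}

params_hash <- function(p) {
  md5_string(paste(deparse(p[order(names(p))]), collapse = "\n"))
}

stage_manifest <- function(out_dir, stage, inputs, outputs, p, extra = list()) {
  manifest <- c(list(stage = stage, inputs = inputs,
                     params_hash = unname(params_hash(unclass(p))),
                     outputs = outputs), extra)
  jsonlite::write_json(manifest,
                       file.path(out_dir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Run the full pipeline
#'
#' Executes ccs -> cluster -> consensus -> assemble, and evaluate when a
#' reference is configured, logging each stage to stderr and
#' `<out_dir>/run.log` and writing a JSON manifest per stage. A stage
#' failure stops the run with the failing stage named.
#'
#' @param params a `run_params` list from [load_params()] (or an equivalent
#'   list; it is validated again here).
#' @return invisibly, a list of per-stage artifact paths and summaries.
#' @export
run_all <- function(params) {
  p <- validate_params(as.list(params))
  if (is.null(p$subreads))
    stop("config error: 'subreads' path is required", call. = FALSE)
  for (key in c("subreads", "ccs", "panel", "reference")) {
    if (!is.null(p[[key]]) && !file.exists(p[[key]]))
      stop(sprintf("config error: '%s' path '%s' does not exist", key,
                   p[[key]]), call. = FALSE)
  }
  if (is.null(p$panel))
    stop("config error: 'panel' path is required", call. = FALSE)
  if (!dir.exists(p$out_dir) &&
      !dir.create(p$out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("I/O error: cannot create out_dir '%s'", p$out_dir),
         call. = FALSE)
  log_file <- file.path(p$out_dir, "run.log")
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    message(line)
    cat(line, "\n", file = log_file, append = TRUE)
  }
  run_stage <- function(stage, fn) {
    log_msg("stage %s: start", stage)
    out <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    log_msg("stage %s: done", stage)
    out
  }

  panel <- read_panel(p$panel)
  reads <- run_stage("read_subreads",
                     function() read_subreads_fastq(p$subreads))
  n_subreads <- vapply(reads, function(r) nrow(r$subreads), integer(1))

  ccs <- run_stage("ccs", function() {
    if (!is.null(p$ccs)) {
      log_msg("using precomputed CCS reads from %s", p$ccs)
      read_ccs_fastq(p$ccs)
    } else {
      out <- build_ccs_all(reads, min_passes = p$min_passes,
                           min_predicted_accuracy = p$min_predicted_accuracy,
                           out_prefix = file.path(p$out_dir, "ccs"))
      log_msg("ccs: %d/%d molecules emitted", sum(out$emitted), nrow(out))
      out
    }
  })
  stage_manifest(p$out_dir, "ccs", inputs = p$subreads,
                 outputs = file.path(p$out_dir, "ccs.fastq"), p = p,
                 extra = list(n_molecules = nrow(ccs)))

  cmap <- run_stage("cluster", function() {
    out <- cluster_ccs(ccs, panel, search_space = p$search_space,
                       two_level = p$two_level,
                       include_padding = p$include_padding,
                       max_mismatch = p$max_mismatch)
    log_msg("cluster: %d assigned, %d unassigned", nrow(out$assignments),
            nrow(out$unassigned))
    out
  })
  wl_dir <- file.path(p$out_dir, "whitelists")
  write_whitelists(cmap, wl_dir, n_subreads = n_subreads)
  stage_manifest(p$out_dir, "cluster", inputs = p$panel, outputs = wl_dir,
                 p = p, extra = list(n_assigned = nrow(cmap$assignments)))

  records <- run_stage("consensus", function() {
    out <- consensus_all(cmap, reads, panel, min_subreads = p$min_subreads,
                         min_subread_length = p$min_subread_length,
                         two_level = p$two_level,
                         include_padding = p$include_padding,
                         max_iters = p$max_iters, band_frac = p$band_frac)
    log_msg("consensus: %d emitted, %d filtered",
            sum(out$status == "emitted"), sum(out$status != "emitted"))
    out
  })
  cons_fa <- file.path(p$out_dir, "consensus.fasta")
  write_consensus_fasta(records, cons_fa,
                        report_path = file.path(p$out_dir,
                                                "consensus_report.tsv"))
  stage_manifest(p$out_dir, "consensus", inputs = wl_dir, outputs = cons_fa,
                 p = p, extra = list(n_emitted = sum(records$status == "emitted")))

  trim_bp <- p$trim_bp
  if (is.null(trim_bp)) {
    # default: strip the synthesis extension (padding + barcode) if present
    trim_bp <- max(nchar(panel$padding) + nchar(panel$barcode), 0)
  }
  asm_dir <- file.path(p$out_dir, "assembly")
  assemblies <- run_stage("assemble", function() {
    em <- records[records$status == "emitted", , drop = FALSE]
    by_sample <- split(em, ifelse(is.na(em$sample_id), "nobc", em$sample_id))
    lapply(by_sample, function(recs)
      assemble_sample(recs, trim_bp = trim_bp, min_overlap = p$min_overlap,
                      min_identity = p$min_identity, out_dir = asm_dir))
  })
  stage_manifest(p$out_dir, "assemble", inputs = cons_fa, outputs = asm_dir,
                 p = p,
                 extra = list(n_samples = length(assemblies),
                              trim_bp = trim_bp))

  reports <- NULL
  if (!is.null(p$reference)) {
    reports <- run_stage("evaluate", function() {
      loci <- read_fasta(p$reference)
      em <- records[records$status == "emitted", , drop = FALSE]
      reps <- lapply(seq_len(nrow(em)), function(i)
        align_and_report(em$sequence[i], loci, query_id = em$cluster[i]))
      for (asm in assemblies) {
        if (nrow(asm$contigs) == 0) next
        reps <- c(reps, lapply(seq_len(nrow(asm$contigs)), function(g)
          align_and_report(asm$contigs$sequence[g], loci,
                           query_id = asm$contigs$contig_id[g])))
      }
      do.call(rbind, reps)
    })
    rep_path <- file.path(p$out_dir, "alignment_reports.tsv")
    write_report_tsv(reports, rep_path)
    stage_manifest(p$out_dir, "evaluate", inputs = p$reference,
                   outputs = rep_path, p = p,
                   extra = list(n_reports = nrow(reports)))
  }
  log_msg("pipeline complete")
  invisible(list(ccs = ccs, cluster_map = cmap, consensus = records,
                 assemblies = assemblies, reports = reports,
                 out_dir = p$out_dir))
}
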