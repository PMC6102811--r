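# Shared fixtures: small simulated libraries built in code at test time.
# Sizes are scaled down from realistic amplicon libraries (3-8 kb amplicons)
# so the whole suite stays fast; the science being exercised is unchanged.

rand_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# small tiled multiplex library: n_samples x n_amplicons, short amplicons
make_test_library <- function(n_samples = 2, n_amplicons = 3, depth = 4,
                              amp_len = c(550, 650), overlap = c(100, 150),
                              locus_len = NULL, profile = error_profile(0, 0, 0),
                              mean_passes = 3, protect_ends = 0,
                              homopolymer_spikes = 0, seed = 42,
                              out_dir = NULL) {
  if (is.null(locus_len)) {
    # middle of the feasible span for the requested tiling
    locus_len <- round(n_amplicons * mean(amp_len) -
                         (n_amplicons - 1) * mean(overlap))
  }
  ref <- make_reference(1, locus_len, gc = 0.45,
                        homopolymer_spikes = homopolymer_spikes, seed = seed)
  designs <- design_tiling(ref, n_amplicons, amp_len = amp_len,
                           overlap = overlap, primer_len = 20, seed = seed)
  samples <- if (n_samples > 0) make_sample_barcodes(n_samples, seed = seed)
             else NULL
  panel <- barcode_panel(designs, samples)
  bundle <- simulate_library(ref, designs, panel, depth_per_amplicon = depth,
                             profile = profile, mean_passes = mean_passes,
                             protect_ends = protect_ends, out_dir = out_dir,
                             seed = seed + 1)
  bundle
}

# an error profile totalling ~10% per-base error, insertion-leaning as is
# typical for raw SMRT subreads
profile_10pct <- function(hp_ins = 0) {
  error_profile(sub_rate = 0.02, ins_rate = 0.05, del_rate = 0.03,
                homopolymer_ins_rate = hp_ins, run_min = 6)
}

edit_dist <- function(a, b) ccscluster:::.cpp_edit_distance(a, b)

# strand-agnostic identity between two sequences (1 - edit/len)
strand_identity <- function(x, ref) {
  d <- min(edit_dist(ref, x), edit_dist(ref, revcomp(x)))
  1 - d / nchar(ref)
}

# template (with barcode/padding extensions) for one panel row
bundle_template <- function(bundle, sample_id, amplicon_id) {
  pan <- bundle$panel
  sel <- which((is.na(pan$sample_id) & is.na(sample_id) |
                  !is.na(pan$sample_id) & !is.na(sample_id) &
                  pan$sample_id == sample_id) &
                 pan$amplicon_id == amplicon_id)
  ccscluster:::panel_template(pan[sel[1], ], bundle$reference, bundle$designs)
}
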