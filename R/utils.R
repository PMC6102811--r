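DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character vectors (alphabet
#' `A/C/G/T/N`, case preserved).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtN", "TGCAtgcaN", x))
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(sprintf("%s contains characters outside A/C/G/T", what), call. = FALSE)
  invisible(x)
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("parameter '%s' must be a single number", name), call. = FALSE)
  if (integer && x != as.integer(x))
    stop(sprintf("parameter '%s' must be an integer", name), call. = FALSE)
  if (x < lo || x > hi)
    stop(sprintf("parameter '%s' must be in [%s, %s]", name, lo, hi), call. = FALSE)
  invisible(x)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# md5 of a character string (via a temporary file; tools::md5sum is file-based)
md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(charToRaw(x), tf)
  unname(tools::md5sum(tf))
}
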