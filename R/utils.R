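#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state. seed = NULL leaves the global
# stream untouched so callers can manage reproducibility themselves.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Complement / reverse-complement for plain character vectors of A/C/G/T.
# Biostrings handles whole sequences; these cover single alleles without
# round-tripping through XString objects.
comp_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

variant_key <- function(chromosome, position, ref, alt) {
  paste(chromosome, position, ref, alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
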