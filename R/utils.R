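#' @keywords internal
"_PACKAGE"

## Seed handling: every stochastic generator is a pure function of
## (arguments, seed).  The caller's RNG state is left untouched.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; accepts the A/C/G/T/N alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Random uppercase DNA strings, one per entry of len.
random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  vapply(len, function(l) {
    paste(sample(alphabet, l, replace = TRUE), collapse = "")
  }, character(1))
}

## Hamming distance between two equal-length strings; positions where
## either side is 'N' always count as mismatches.
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  nraw <- charToRaw("N")
  sum(ra != rb | ra == nraw | rb == nraw)
}

## As hamming(), but on pre-converted raw vectors (hot path in the aligner).
hamming_raw <- function(ra, rb, nraw = charToRaw("N")) {
  sum(ra != rb | ra == nraw | rb == nraw)
}

## stop() with call. = FALSE everywhere
err <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    err(name, " must be in [0, 1]")
  }
  invisible(x)
}
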