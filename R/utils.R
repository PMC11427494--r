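#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
# All generators go through this so they are pure functions of their
# arguments, seed included.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  chars <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE)
  apply(matrix(chars, nrow = len), 2L, paste, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Truncate (not round) a p-value to three decimals, the convention used when
# quoting p-values in the report layer (e.g. 3/64 = 0.046875 -> 0.046).
truncate_p3 <- function(p) floor(p * 1000) / 1000
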