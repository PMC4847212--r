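# Small shared helpers: DNA string manipulation and seeded evaluation.

DNA_BASES <- c("A", "C", "G", "T")

# let data.table dispatch its own methods inside this namespace
.datatable.aware <- TRUE

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All kmers of a string in order of start position (1-based starts implied).
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(s, starts, starts + k - 1L)
}

# Longest single-base run.
max_homopolymer_run <- function(s) {
  if (!nchar(s)) return(0L)
  max(rle(strsplit(s, "", fixed = TRUE)[[1]])$lengths)
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
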