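#' @useDynLib lpmominer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# The 20 standard amino-acid letters plus X for unknown residues.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

stop_lpmo <- function(class, msg, ...) {
  stop(structure(class = c(class, "lpmominer_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Count occurrences of a residue letter inside a string (optionally a span).
count_residue <- function(s, letter, from = 1L, to = nchar(s)) {
  if (to < from) return(0L)
  sum(seq_chars(substr(s, from, to)) == letter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
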