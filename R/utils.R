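# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG to `seed`, runs `expr`, and restores the caller's RNG state so
#' that seeded generators do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.double(seed) * 48271 + as.double(offset)) %% 2147483587
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# IUPAC nucleotide code expansions (DNA).
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Reverse complement of a plain character string (IUPAC-aware).
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Byte-level complement lookup (ACGTN + IUPAC), ASCII-indexed.
COMP_BYTES <- local({
  m <- as.raw(seq_len(256) - 1L)
  from <- utf8ToInt("ACGTNRYSWKMBDHVacgtnryswkmbdhv")
  to <- utf8ToInt("TGCANYRSWMKVHDBtgcanyrswmkvhdb")
  m[from + 1L] <- as.raw(to)
  m
})

# Reverse complement on raw bytes (fast path for per-read work).
revcomp_raw <- function(b) rev(COMP_BYTES[as.integer(b) + 1L])

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
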