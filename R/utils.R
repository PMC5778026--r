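# Internal helpers: classed errors, seeded RNG scope, small sequence ops.

abort_cid <- function(label, msg, ..., data = NULL) {
  cond <- errorCondition(
    sprintf(msg, ...),
    class = c(paste0("cidscope_error_", label), "cidscope_error"),
    data = data
  )
  stop(cond)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators are pure given (config, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_cid("seed", "seed must be a single number, got %s", deparse(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed deterministically; keeps results < 2^31.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

seq_len_nt <- function(x) nchar(x)

# 1-based inclusive substring, vector-safe for a single sequence.
subseq_chr <- function(x, start, end) substr(x, start, end)

# Replace [start, end] (1-based inclusive) of x with `repl`.
splice_chr <- function(x, start, end, repl) {
  paste0(substr(x, 1L, start - 1L), repl, substr(x, end + 1L, nchar(x)))
}

# Per-base substitution errors at rate `rate`; substitutes to a different base.
mutate_seq <- function(x, rate) {
  if (rate <= 0) return(x)
  n <- nchar(x)
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  chars[hit] <- vapply(chars[hit], function(b) {
    sample(setdiff(DNA_BASES, b), 1L)
  }, character(1))
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x)

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "cidscope")
  if (!nzchar(p)) abort_cid("extdata", "missing packaged data file '%s'", file)
  p
}
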