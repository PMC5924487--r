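# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive an independent per-stage seed from the run seed, kept < 2^31.
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + as.integer(stage) * 1009L) %% 2147483587L
}

# Gene symbols are matched case-insensitively after whitespace stripping.
norm_symbols <- function(x) {
  toupper(gsub("[[:space:]]+", "", as.character(x)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stopf("'%s' must be TRUE or FALSE", name)
  }
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < min) {
    stopf("'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x > max) {
    stopf("'%s' must be a single finite number in [%s, %s]",
          name, format(min), format(max))
  }
  as.numeric(x)
}

dna_alphabet_valid <- function(x) {
  length(x) == 1L && is.character(x) && !is.na(x) &&
    grepl("^[ACGTacgt]*$", x)
}

iupac_valid <- function(x) {
  length(x) == 1L && is.character(x) && !is.na(x) &&
    grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]*$", x)
}

revcomp <- function(x) {
  if (nchar(x) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
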