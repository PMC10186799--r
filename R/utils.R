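#' Derive a reproducible sub-stream seed
#'
#' One top-level seed drives every stochastic stage; each stage draws from its
#' own sub-stream so that adding or reordering stages does not perturb the
#' others. The derivation is a fixed integer hash of the seed and a stage tag.
#'
#' @param seed Integer top-level seed.
#' @param tag Character stage label.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (v in utf8ToInt(tag)) h <- (h * 131 + v) %% 2147483629
  as.integer((abs(seed) * 48271 + h * 9973 + 17) %% 2147483629)
}

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# random DNA strings of the given lengths
random_dna <- function(lengths) {
  vapply(lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
}

# vectorized reverse complement of plain character sequences
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# mutate sequences with i.i.d. substitution errors; substitutions are always
# to a different base
mutate_seqs <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  bases <- c("A", "C", "G", "T")
  n_err <- rbinom(length(seqs), lens, error_rate)
  for (i in which(n_err > 0L)) {
    for (p in sample.int(lens[i], n_err[i])) {
      substr(seqs[i], p, p) <- sample(setdiff(bases, substr(seqs[i], p, p)), 1L)
    }
  }
  seqs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sym <- function(...) stop(..., call. = FALSE)
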