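# mutate an exact fraction of positions (distinct sites, always to a
# different base) — used to derive strain variants and background decoys
diverge_seq <- function(seq, frac) {
  n <- nchar(seq)
  k <- round(frac * n)
  if (k == 0L) return(seq)
  for (p in sample.int(n, k)) {
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(seq, p, p)), 1L)
  }
  seq
}

#' Generate a marker-gene validation scenario with known composition
#'
#' Emulates the free-living-symbiont validation experiment: a sample's reads
#' are screened against four marker databases — symbiont 16S rRNA targets,
#' host mitochondrial CO1 targets, and a background decoy set for each
#' (related bacterial 16S and non-host mollusk CO1 sequences) — and the ratio
#' of 16S to CO1 read percentages separates free-living symbiont populations
#' (fluid samples, high ratio) from host-associated ones (gill samples, ratio
#' of order 1).
#'
#' Databases: a handful of target sequences per marker (strain variants a few
#' percent apart) plus decoys diverged from the targets by
#' `background_divergence`. Reads: fixed known counts per category (the truth
#' composition), the remainder drawn from an unrelated community decoy
#' sequence.
#'
#' @param scenario `"gill"` (truth 16S:CO1 read ratio 2.5, order 1-10) or
#'   `"fluid"` (truth ratio 100, order 10-300).
#' @param seed Integer seed.
#' @param total_reads Total reads in the sample.
#' @param background_divergence Fraction of diverged positions in decoys;
#'   must be > 0 (decoys identical to targets are useless).
#' @param error_rate Per-base substitution error on reads.
#' @param read_length Read length (bp).
#' @param counts Optional named list overriding per-category read counts
#'   (`target_16S`, `target_CO1`, `background_16S`, `background_CO1`).
#' @return List: `databases` (4 named character vectors), `reads` (named
#'   character vector), `truth` (data.table read_id, category), `truth_ratio`,
#'   `total_reads`, `scenario`.
#' @export
generate_marker_read_sets <- function(scenario = c("gill", "fluid"), seed = 1,
                                      total_reads = 20000,
                                      background_divergence = 0.10,
                                      error_rate = 0.002, read_length = 150,
                                      counts = NULL) {
  scenario <- match.arg(scenario)
  if (background_divergence <= 0)
    stop_sym("background_divergence must be > 0: ",
             "decoys would be indistinguishable from targets")
  default_counts <- if (scenario == "gill") {
    list(target_16S = 200L, target_CO1 = 80L,
         background_16S = 100L, background_CO1 = 100L)
  } else {
    list(target_16S = 600L, target_CO1 = 6L,
         background_16S = 100L, background_CO1 = 100L)
  }
  if (!is.null(counts)) default_counts <- modifyList(default_counts, counts)
  cts <- default_counts
  n_other <- total_reads - sum(unlist(cts))
  if (n_other < 0) stop_sym("category counts exceed total_reads")

  with_seed(seed, {
    base_16s <- random_dna(1200)
    base_co1 <- random_dna(650)
    db <- list(
      target_16S = setNames(c(base_16s,
                              vapply(1:2, function(i) diverge_seq(base_16s, 0.02),
                                     character(1))),
                            sprintf("sym16S_%d", 1:3)),
      target_CO1 = setNames(c(base_co1,
                              vapply(1:2, function(i) diverge_seq(base_co1, 0.02),
                                     character(1))),
                            sprintf("hostCO1_%d", 1:3)))
    db$background_16S <- setNames(
      vapply(db$target_16S, diverge_seq, character(1),
             frac = background_divergence),
      sprintf("bact16S_%d", 1:3))
    db$background_CO1 <- setNames(
      vapply(db$target_CO1, diverge_seq, character(1),
             frac = background_divergence),
      sprintf("molluskCO1_%d", 1:3))
    community <- random_dna(30000)

    draw_reads <- function(seqs, n) {
      if (n == 0L) return(character(0))
      src <- seqs[sample.int(length(seqs), n, replace = TRUE)]
      w <- nchar(src) - read_length + 1L
      start <- as.integer(floor(runif(n) * w))
      out <- substr(src, start + 1L, start + read_length)
      rc <- runif(n) < 0.5
      if (any(rc)) out[rc] <- revcomp(out[rc])
      mutate_seqs(out, error_rate)
    }

    cat_names <- c("target_16S", "target_CO1", "background_16S",
                   "background_CO1")
    pieces <- lapply(cat_names, function(cn) draw_reads(db[[cn]], cts[[cn]]))
    other <- draw_reads(community, n_other)
    reads <- c(unlist(pieces), other)
    categories <- c(rep(cat_names, times = vapply(pieces, length, integer(1))),
                    rep("other", n_other))
    ids <- sprintf("%s_m%06d", scenario, seq_along(reads))
    names(reads) <- ids

    truth_ratio <- if (cts$target_CO1 > 0)
      cts$target_16S / cts$target_CO1 else NA_real_
    list(databases = db, reads = reads,
         truth = data.table::data.table(read_id = ids, category = categories),
         truth_ratio = truth_ratio, total_reads = length(reads),
         scenario = scenario)
  })
}
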