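MARKER_CATEGORIES <- c("target_16S", "target_CO1", "background_16S",
                       "background_CO1")

# data.table(seq_idx, kmer) of canonical k-mers (lexicographic min of k-mer
# and reverse complement) for a character vector of sequences
canonical_kmers <- function(seqs, k) {
  lens <- nchar(seqs)
  keep <- which(lens >= k)
  out <- data.table::rbindlist(lapply(split(keep, lens[keep]), function(idx) {
    L <- lens[idx[1]]
    n_k <- L - k + 1L
    km <- vapply(seq_len(n_k), function(o)
      substring(seqs[idx], o, o + k - 1L), character(length(idx)))
    data.table::data.table(seq_idx = rep(idx, times = n_k),
                           kmer = as.vector(km))
  }))
  if (!nrow(out)) return(data.table::data.table(seq_idx = integer(),
                                                kmer = character()))
  rc <- revcomp(out$kmer)
  out[, kmer := ifelse(kmer <= rc, kmer, rc)]
  out
}

#' Build a k-mer marker database with mandatory background decoys
#'
#' Indexes canonical `k_marker`-mers of all sequences in the four marker
#' categories (symbiont 16S targets, host CO1 targets, and a background
#' decoy set for each). All four categories are mandatory: without decoys,
#' reads from related non-target organisms would be miscounted as targets.
#'
#' @param fastas Named list over `target_16S`, `target_CO1`,
#'   `background_16S`, `background_CO1`; each a named character vector of
#'   sequences or a FASTA path.
#' @param k_marker k-mer size (<= shortest sequence).
#' @return A `marker_db`: `$index` (data.table kmer -> category, keyed),
#'   `$k`, `$categories`, `$n_kmers` per category.
#' @export
build_marker_index <- function(fastas, k_marker = 31) {
  missing_cat <- setdiff(MARKER_CATEGORIES, names(fastas))
  if (length(missing_cat))
    stop_sym("missing marker categor(ies): ",
             paste(missing_cat, collapse = ", "),
             " (background decoys are mandatory)")
  seqs <- lapply(fastas[MARKER_CATEGORIES], function(x) {
    if (length(x) == 1L && is.null(names(x)) && file.exists(x)) read_fasta(x)
    else x
  })
  if (any(vapply(seqs, length, integer(1)) == 0L))
    stop_sym("every marker category needs >= 1 sequence")
  if (k_marker > min(vapply(seqs, function(s) min(nchar(s)), numeric(1))))
    stop_sym("k_marker exceeds the shortest database sequence")
  idx <- data.table::rbindlist(lapply(MARKER_CATEGORIES, function(cn) {
    km <- canonical_kmers(unname(seqs[[cn]]), k_marker)
    unique(data.table::data.table(kmer = km$kmer, category = cn))
  }))
  data.table::setkey(idx, kmer)
  structure(list(index = idx, k = as.integer(k_marker),
                 categories = MARKER_CATEGORIES,
                 n_kmers = table(idx$category)),
            class = "marker_db")
}

#' @export
print.marker_db <- function(x, ...) {
  cat("marker_db: k =", x$k, "|",
      paste(names(x$n_kmers), as.integer(x$n_kmers), collapse = ", "), "\n")
  invisible(x)
}

#' Classify reads against the marker database (unambiguous assignment)
#'
#' Per read, matching canonical k-mers are counted per category. A read is
#' assigned to category `c` iff its hits reach `min_hit_frac` of the read's
#' k-mer count **and** exceed every other category's hits by the factor
#' `margin`; otherwise it stays ambiguous/unassigned. This is the precise
#' reading of "unambiguous" used throughout: decoy categories absorb reads
#' from related non-target sequences.
#'
#' @param reads Named character vector of reads, or a FASTQ path.
#' @param db A `marker_db` from [build_marker_index()].
#' @param min_hit_frac Minimum fraction of a read's k-mers that must hit.
#' @param margin Required fold-advantage over every other category.
#' @return A `marker_classification`: `$counts` (named integer vector over
#'   the four categories plus `ambiguous` and `unassigned`), `$assignments`
#'   (data.table read_id, category), `$n_total`, `$n_short` (reads shorter
#'   than k, tallied unassigned with a warning).
#' @export
classify_reads <- function(reads, db, min_hit_frac = 0.5, margin = 2.0) {
  if (is.character(reads) && length(reads) == 1L && is.null(names(reads)) &&
      file.exists(reads))
    reads <- read_fastq(reads)
  n_total <- length(reads)
  ids <- names(reads) %||% as.character(seq_len(n_total))
  lens <- nchar(reads)
  short <- lens < db$k
  if (any(short))
    warning(sum(short), " read(s) shorter than k_marker counted unassigned",
            call. = FALSE)

  hits <- matrix(0L, n_total, length(db$categories),
                 dimnames = list(NULL, db$categories))
  if (any(!short)) {
    km <- canonical_kmers(unname(reads), db$k)  # skips short reads itself
    matched <- db$index[km, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(matched)) {
      agg <- matched[, .N, by = .(seq_idx, category)]
      hits[cbind(agg$seq_idx, match(agg$category, db$categories))] <- agg$N
    }
  }
  n_k <- pmax(lens - db$k + 1L, 0L)
  qualifies <- matrix(FALSE, n_total, length(db$categories))
  for (c in seq_along(db$categories)) {
    others_max <- do.call(pmax, as.data.frame(hits[, -c, drop = FALSE]))
    qualifies[, c] <- hits[, c] >= min_hit_frac * n_k &
      hits[, c] >= margin * others_max & hits[, c] > 0
  }
  n_qual <- rowSums(qualifies)
  assigned_cat <- rep(NA_character_, n_total)
  one <- n_qual == 1L & !short
  assigned_cat[one] <- db$categories[max.col(qualifies[one, , drop = FALSE])]
  status <- ifelse(!is.na(assigned_cat), assigned_cat,
                   ifelse(!short & rowSums(hits) > 0 & n_qual != 1L,
                          "ambiguous", "unassigned"))

  counts <- setNames(integer(length(db$categories) + 2L),
                     c(db$categories, "ambiguous", "unassigned"))
  tab <- table(status)
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts,
                 assignments = data.table::data.table(read_id = ids,
                                                      category = status),
                 n_total = n_total, n_short = sum(short)),
            class = "marker_classification")
}

#' @export
print.marker_classification <- function(x, ...) {
  cat("marker_classification:", x$n_total, "reads |",
      paste(names(x$counts), x$counts, collapse = ", "), "\n")
  invisible(x)
}

#' 16S:CO1 marker-read ratio for one sample
#'
#' Percentages are computed against **all** reads in the sample (not only
#' assigned ones). The ratio can equivalently be computed directly from
#' already-printed percentages via `pct_16s` / `pct_co1`. A zero CO1
#' percentage yields an infinite ratio with `ratio_defined = FALSE` rather
#' than an error.
#'
#' @param counts Named counts from [classify_reads()] (uses `target_16S`
#'   and `target_CO1`); or `NULL` when giving percentages directly.
#' @param total_reads Total reads in the sample (counts mode).
#' @param pct_16s,pct_co1 Percentages of unambiguous 16S / CO1 reads
#'   (percentage mode).
#' @param sample_id Optional label.
#' @return One-row data.frame: sample_id, total_reads, n_16s, n_co1,
#'   pct_16s, pct_co1, ratio, ratio_defined.
#' @export
marker_ratio <- function(counts = NULL, total_reads = NULL, pct_16s = NULL,
                         pct_co1 = NULL, sample_id = NA_character_) {
  if (!is.null(counts)) {
    if (is.null(total_reads) || total_reads <= 0)
      stop_sym("total_reads must be > 0")
    n_16s <- as.integer(counts[["target_16S"]])
    n_co1 <- as.integer(counts[["target_CO1"]])
    pct_16s <- 100 * n_16s / total_reads
    pct_co1 <- 100 * n_co1 / total_reads
  } else {
    if (is.null(pct_16s) || is.null(pct_co1))
      stop_sym("either counts+total_reads or pct_16s+pct_co1 required")
    n_16s <- NA_integer_; n_co1 <- NA_integer_
    total_reads <- total_reads %||% NA_integer_
  }
  defined <- pct_co1 > 0
  ratio <- if (defined) pct_16s / pct_co1 else Inf
  data.frame(sample_id = sample_id, total_reads = total_reads,
             n_16s = n_16s, n_co1 = n_co1, pct_16s = pct_16s,
             pct_co1 = pct_co1, ratio = ratio, ratio_defined = defined,
             stringsAsFactors = FALSE)
}

#' Flag samples whose marker ratio indicates a free-living population
#'
#' Relative mode (default): a sample is flagged iff its ratio is at least
#' `fold_threshold` times the median ratio of the host-associated reference
#' rows — a conservative lower bound on "orders of magnitude higher".
#' Absolute mode: flagged iff the ratio reaches `absolute_threshold`.
#'
#' @param ratios Numeric vector of per-sample 16S:CO1 ratios.
#' @param is_host Logical vector: which samples are host-associated
#'   references (required in relative mode).
#' @param fold_threshold Fold over the host median required to flag.
#' @param absolute_threshold If non-NULL, use absolute mode instead.
#' @return Logical vector (`TRUE` = free-living signal).
#' @export
flag_lifestyle <- function(ratios, is_host = NULL, fold_threshold = 10,
                           absolute_threshold = NULL) {
  if (!is.null(absolute_threshold)) return(ratios >= absolute_threshold)
  if (is.null(is_host) || !any(is_host))
    stop_sym("relative mode needs >= 1 host-associated reference row")
  ratios >= fold_threshold * median(ratios[is_host])
}

#' Published Mariana Back-Arc marker-read percentages
#'
#' The reported percentages of unambiguous reads mapping to the
#' *Alviniconcha hessleri* symbiont 16S rRNA and host mitochondrial CO1
#' marker databases for the nine Mariana Back-Arc samples (six gill, three
#' diffuse-fluid), with the published ratio for comparison. For some rows
#' the published ratio is not reproducible from the rounded printed
#' percentages (`consistent = FALSE`).
#'
#' @return data.frame: sample_id, vent_field, lifestyle, origin, pct_16s,
#'   pct_co1, published_ratio, consistent.
#' @export
mariana_marker_table <- function() {
  path <- system.file("extdata", "mariana_marker_percentages.tsv",
                      package = "symbiopop")
  x <- read_tsv_prov(path)
  x$consistent <- abs(round(x$pct_16s / x$pct_co1, 2) - x$published_ratio) <
    0.005
  x
}
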