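NUCS <- c("A", "C", "G", "T")

#' Pile up nucleotide counts over the pangenome
#'
#' For every retained site, counts each nucleotide observed in aligned reads
#' covering it, per sample. Coverage statistics (mean depth and breadth over
#' all pangenome positions) are computed along the way and feed sample QC.
#'
#' @param alignments A single `alignment_set` or a named list of them (one
#'   per sample). Unnamed entries take their `sample_id` attribute.
#' @param pg The [pangenome()].
#' @param site_list Optional data.frame (gene_id, pos) restricting the count
#'   matrix to given sites; default: all positions with any coverage.
#' @return List with `counts` (a `nuc_counts` object: `$sites`, `$samples`,
#'   `$counts` array site x sample x nucleotide) and `coverage` (data.frame
#'   sample_id, mean_depth, breadth).
#' @export
pileup_counts <- function(alignments, pg, site_list = NULL) {
  if (inherits(alignments, "alignment_set"))
    alignments <- setNames(list(alignments),
                           attr(alignments, "sample_id") %||% "sample1")
  if (is.null(names(alignments)))
    names(alignments) <- vapply(alignments, function(a)
      attr(a, "sample_id"), character(1))
  samples <- names(alignments)

  glen <- pg$genes$length
  offsets <- c(0L, cumsum(glen))[seq_along(glen)]
  total_len <- sum(glen)

  per_sample <- lapply(alignments, function(aln) {
    bad <- setdiff(unique(aln$gene_id), pg$genes$gene_id)
    if (length(bad))
      stop_sym("alignments reference unknown gene(s): ",
               paste(bad, collapse = ", "))
    gi <- match(aln$gene_id, pg$genes$gene_id)
    cpp_pileup(gi, aln$start, aln$seq, offsets, total_len)
  })

  depth <- vapply(per_sample, rowSums, numeric(total_len))
  if (is.null(dim(depth))) depth <- matrix(depth, ncol = length(samples))
  coverage <- data.frame(
    sample_id = samples,
    mean_depth = colMeans(depth),
    breadth = colMeans(depth >= 1),
    stringsAsFactors = FALSE, row.names = NULL)

  gene_of_flat <- rep.int(seq_along(glen), glen)
  pos_of_flat <- sequence(glen) - 1L
  if (is.null(site_list)) {
    flat_idx <- which(rowSums(depth) > 0)
  } else {
    gi <- match(site_list$gene_id, pg$genes$gene_id)
    if (anyNA(gi)) stop_sym("site_list references unknown gene(s)")
    flat_idx <- offsets[gi] + site_list$pos + 1L
  }
  sites <- data.frame(gene_id = pg$genes$gene_id[gene_of_flat[flat_idx]],
                      pos = pos_of_flat[flat_idx], stringsAsFactors = FALSE)
  counts <- array(0L, dim = c(length(flat_idx), length(samples), 4L),
                  dimnames = list(NULL, samples, NUCS))
  for (j in seq_along(samples))
    counts[, j, ] <- per_sample[[j]][flat_idx, , drop = FALSE]

  nc <- structure(list(sites = sites, samples = samples, counts = counts),
                  class = "nuc_counts")
  list(counts = nc, coverage = coverage)
}

#' @export
print.nuc_counts <- function(x, ...) {
  cat("nuc_counts:", nrow(x$sites), "sites x", length(x$samples),
      "samples\n")
  invisible(x)
}

#' Partition samples by mean coverage
#'
#' Samples at or above the threshold are retained for the primary analysis;
#' the rest are flagged `low_coverage` and can be folded into a secondary run
#' restricted to the sites covered in them.
#'
#' @param cov Coverage data.frame from [pileup_counts()].
#' @param min_mean_depth Retention threshold (inclusive), default 10x.
#' @return List with `retained` and `low_coverage` character vectors.
#' @export
sample_qc <- function(cov, min_mean_depth = 10) {
  if (!nrow(cov)) stop_sym("empty coverage summary")
  keep <- cov$mean_depth >= min_mean_depth
  if (!any(keep))
    stop_sym("no sample meets the coverage threshold (",
             min_mean_depth, "x); review min_mean_depth")
  list(retained = cov$sample_id[keep],
       low_coverage = cov$sample_id[!keep])
}

#' Call and filter biallelic variants
#'
#' A site is retained iff (a) its per-sample depth is at least
#' `min_site_depth` in every retained sample (complete-case, so all pairwise
#' comparisons use one site set); (b) exactly two alleles reach a pooled
#' count of `min_allele_count` and any further allele stays at or below
#' `noise_allele_max` (sequencing-error tolerance); and (c) the pooled
#' minor-allele frequency is at least `min_maf`. The reference allele is the
#' pooled majority allele, ties broken alphabetically.
#'
#' @param nc A `nuc_counts` object from [pileup_counts()].
#' @param samples Retained sample ids (>= 2); default all samples.
#' @param min_site_depth Per-sample depth floor.
#' @param min_allele_count Pooled count both alleles must reach.
#' @param noise_allele_max Pooled ceiling for any third/fourth allele.
#' @param min_maf Pooled minor-allele frequency floor.
#' @return A `variant_table`: `$sites` (gene_id, pos, ref, alt, maf),
#'   `$ref_counts` / `$alt_counts` (site x sample matrices), `$samples`.
#'   Empty (with a warning) when no site survives.
#' @export
call_variants <- function(nc, samples = NULL, min_site_depth = 10,
                          min_allele_count = 4, noise_allele_max = 2,
                          min_maf = 0.02) {
  samples <- samples %||% nc$samples
  if (length(samples) < 2L) stop_sym("need >= 2 retained samples")
  missing_s <- setdiff(samples, nc$samples)
  if (length(missing_s))
    stop_sym("unknown sample(s): ", paste(missing_s, collapse = ", "))
  cts <- nc$counts[, samples, , drop = FALSE]
  n_sites <- dim(cts)[1]

  per_sample <- lapply(seq_along(samples), function(j)
    matrix(cts[, j, ], nrow = n_sites))
  depth <- vapply(per_sample, rowSums, numeric(n_sites))
  if (is.null(dim(depth))) depth <- matrix(depth, nrow = n_sites)
  ok_depth <- rowSums(depth >= min_site_depth) == length(samples)

  pooled <- Reduce(`+`, per_sample)  # site x 4
  # count-desc / alphabetical tie-break ordering via weighted scores
  score <- sweep(pooled * 4, 2, c(3, 2, 1, 0), "+")
  o1 <- max.col(score, ties.method = "first")
  s2 <- score; s2[cbind(seq_len(n_sites), o1)] <- -1L
  o2 <- max.col(s2, ties.method = "first")
  s3 <- s2; s3[cbind(seq_len(n_sites), o2)] <- -1L
  o3 <- max.col(s3, ties.method = "first")
  c1 <- pooled[cbind(seq_len(n_sites), o1)]
  c2 <- pooled[cbind(seq_len(n_sites), o2)]
  c3 <- pooled[cbind(seq_len(n_sites), o3)]

  n_major <- rowSums(pooled >= min_allele_count)
  maf <- ifelse(c1 + c2 > 0, c2 / (c1 + c2), 0)
  ok_biallelic <- ok_depth & n_major == 2L & c3 <= noise_allele_max
  keep <- ok_biallelic & maf >= min_maf
  ledger <- c(candidate_sites = n_sites, after_depth = sum(ok_depth),
              after_biallelic = sum(ok_biallelic), after_maf = sum(keep))

  if (!any(keep)) {
    warning("no site survived variant filtering", call. = FALSE)
    keep <- logical(n_sites)
  }
  idx <- which(keep)
  ref <- NUCS[o1[idx]]
  alt <- NUCS[o2[idx]]
  ref_counts <- matrix(0L, length(idx), length(samples),
                       dimnames = list(NULL, samples))
  alt_counts <- ref_counts
  for (j in seq_along(samples)) {
    m <- per_sample[[j]]
    ref_counts[, j] <- m[cbind(idx, o1[idx])]
    alt_counts[, j] <- m[cbind(idx, o2[idx])]
  }
  structure(list(
    sites = data.frame(gene_id = nc$sites$gene_id[idx],
                       pos = nc$sites$pos[idx], ref = ref, alt = alt,
                       maf = maf[idx], stringsAsFactors = FALSE),
    ref_counts = ref_counts, alt_counts = alt_counts, samples = samples,
    filter_ledger = ledger),
    class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "biallelic sites x",
      length(x$samples), "samples\n")
  invisible(x)
}
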