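#' Mean per-base depth of every pangenome gene, per sample
#'
#' Mean depth of a gene is the total number of aligned bases on it divided by
#' its length — the coverage profile from which presence/absence is called.
#'
#' @param alignments A single `alignment_set` or named list of them.
#' @param pg The [pangenome()].
#' @return A `gene_depth_matrix`: gene x sample numeric matrix with the
#'   pangenome gene table in `attr(, "genes")`.
#' @export
gene_depths <- function(alignments, pg) {
  if (inherits(alignments, "alignment_set"))
    alignments <- setNames(list(alignments),
                           attr(alignments, "sample_id") %||% "sample1")
  if (is.null(names(alignments)))
    names(alignments) <- vapply(alignments, function(a)
      attr(a, "sample_id"), character(1))
  m <- matrix(0, nrow(pg$genes), length(alignments),
              dimnames = list(pg$genes$gene_id, names(alignments)))
  for (s in names(alignments)) {
    aln <- alignments[[s]]
    if (nrow(aln)) {
      bases <- tapply(nchar(aln$seq), aln$gene_id, sum)
      m[names(bases), s] <- as.numeric(bases)
    }
  }
  m <- m / pg$genes$length
  structure(m, genes = pg$genes,
            class = c("gene_depth_matrix", "matrix"))
}

#' Call gene presence/absence from normalized coverage
#'
#' Depths are normalized per sample by the median depth over genes with any
#' coverage (robust to a few high-coverage genes). A gene is present when
#' its normalized depth reaches `theta_present`, absent at or below
#' `theta_absent`, and "uncertain" (`NA`) in between — uncertain calls count
#' as absent in Jaccard distances but disqualify genes from group-unique
#' calls.
#'
#' @param depths A `gene_depth_matrix` from [gene_depths()].
#' @param theta_present Normalized-depth presence threshold.
#' @param theta_absent Normalized-depth absence ceiling.
#' @return A `presence_matrix`: gene x sample integer matrix of 1 (present),
#'   0 (absent), `NA` (uncertain).
#' @export
call_presence <- function(depths, theta_present = 0.25, theta_absent = 0.05) {
  if (theta_absent >= theta_present)
    stop_sym("theta_absent must be < theta_present")
  m <- unclass(depths)
  med <- apply(m, 2, function(col) median(col[col > 0]))
  if (any(!is.finite(med) | med <= 0))
    stop_sym("sample(s) without positive median gene depth: ",
             paste(colnames(m)[!is.finite(med) | med <= 0], collapse = ", "))
  norm <- sweep(m, 2, med, "/")
  out <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  out[norm >= theta_present] <- 1L
  out[norm <= theta_absent] <- 0L
  structure(out, thresholds = c(present = theta_present,
                                absent = theta_absent),
            class = c("presence_matrix", "matrix"))
}

#' Jaccard distances between samples' present-gene sets
#'
#' `1 - |A intersect B| / |A union B|` over the sets of genes called
#' present; uncertain (`NA`) calls are treated as absent. Two empty sets
#' have distance 0 by convention.
#'
#' @param p A `presence_matrix` (gene x sample; 1/0/NA) or logical matrix.
#' @return A [dist_matrix()] with metric `"jaccard"`.
#' @export
jaccard_matrix <- function(p) {
  m <- unclass(p)
  m[is.na(m)] <- 0L
  m <- m == 1L | m == TRUE
  if (ncol(m) < 2L) stop_sym("need >= 2 samples")
  s <- colnames(m) %||% paste0("sample", seq_len(ncol(m)))
  out <- matrix(0, ncol(m), ncol(m), dimnames = list(s, s))
  for (i in seq_len(ncol(m))) for (j in seq_len(i - 1L)) {
    un <- sum(m[, i] | m[, j])
    out[i, j] <- out[j, i] <- if (un == 0) 0 else 1 - sum(m[, i] & m[, j]) / un
  }
  dist_matrix(out, "jaccard")
}

#' Genes uniquely associated with one group
#'
#' Strict rule: a gene is unique to group G iff it is called present in
#' every sample of G and absent in every sample of every other group. Any
#' uncertain call disqualifies the gene — borderline coverage must not
#' fabricate group-unique genes. When a gene -> functional-category table is
#' supplied, per-category counts are aggregated per group.
#'
#' @param p A `presence_matrix`.
#' @param grouping Named character vector: sample id -> group label (or a
#'   metadata data.frame with `sample_id` and a `group` column).
#' @param categories Optional data.frame (gene_id, category) of functional
#'   annotations.
#' @return A `unique_gene_report`: `$genes` (data.frame gene_id, group,
#'   category), `$per_group` (list of gene_id vectors),
#'   `$category_counts` (group x category table or NULL).
#' @export
unique_genes <- function(p, grouping, categories = NULL) {
  m <- unclass(p)
  if (is.data.frame(grouping))
    grouping <- setNames(as.character(grouping$group), grouping$sample_id)
  grouping <- grouping[colnames(m)]
  if (anyNA(grouping)) stop_sym("grouping must label every sample")
  if (length(unique(grouping)) < 2L)
    stop_sym("grouping must define >= 2 groups")
  groups <- unique(grouping)
  res <- lapply(groups, function(g) {
    ing <- m[, grouping == g, drop = FALSE]
    outg <- m[, grouping != g, drop = FALSE]
    ok <- rowSums(is.na(ing)) == 0L & rowSums(is.na(outg)) == 0L &
      rowSums(ing == 1L) == ncol(ing) & rowSums(outg == 0L) == ncol(outg)
    rownames(m)[ok]
  })
  names(res) <- groups
  genes <- data.frame(
    gene_id = unlist(res, use.names = FALSE),
    group = rep(groups, times = vapply(res, length, integer(1))),
    stringsAsFactors = FALSE)
  genes$category <- if (!is.null(categories))
    categories$category[match(genes$gene_id, categories$gene_id)]
  else rep(NA_character_, nrow(genes))
  cat_counts <- if (!is.null(categories) && nrow(genes))
    table(genes$group, genes$category, useNA = "no")
  else NULL
  structure(list(genes = genes, per_group = res,
                 category_counts = cat_counts, grouping = grouping),
            class = "unique_gene_report")
}

#' @export
print.unique_gene_report <- function(x, ...) {
  cat("unique_gene_report:\n")
  for (g in names(x$per_group))
    cat("  ", g, ": ", length(x$per_group[[g]]), " unique gene(s)\n",
        sep = "")
  invisible(x)
}
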