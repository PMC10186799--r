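#' Pool allele counts over a set of samples
#'
#' @param v A `variant_table`.
#' @param population Character vector of sample ids to pool (counts are
#'   summed per site across members).
#' @return List with `ref` and `alt` pooled count vectors (one per site).
#' @export
allele_count_pair <- function(v, population) {
  bad <- setdiff(population, v$samples)
  if (length(bad)) stop_sym("unknown sample(s): ", paste(bad, collapse = ", "))
  if (!length(population)) stop_sym("population must be non-empty")
  list(ref = rowSums(v$ref_counts[, population, drop = FALSE]),
       alt = rowSums(v$alt_counts[, population, drop = FALSE]))
}

#' Per-site alternate-allele frequencies of a (pooled) population
#'
#' Pooling sums ref/alt counts across member samples; frequency is
#' `alt / (ref + alt)`, `NA` where the pooled depth is zero.
#'
#' @inheritParams allele_count_pair
#' @return Numeric vector of per-site frequencies (NA = missing).
#' @export
allele_frequencies <- function(v, population) {
  p <- allele_count_pair(v, population)
  n <- p$ref + p$alt
  ifelse(n > 0, p$alt / n, NA_real_)
}

#' Hudson's fixation index between two allele-count populations
#'
#' Hudson-type estimator with finite-sample correction, combined across
#' sites as a ratio of averages. Per site with allele frequencies `p1, p2`
#' and total allele counts `n1, n2` (reads treated as independent allele
#' draws):
#' \deqn{num = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}}
#' \deqn{den = p_1(1-p_2) + p_2(1-p_1)}
#' Genome-wide \eqn{F_{ST} = \sum num_i / \sum den_i} over sites with
#' `den > 0`; sites with `n < 2` in either population are excluded.
#'
#' @param pop1,pop2 Lists with `ref` and `alt` count vectors over the same
#'   sites (see [allele_count_pair()]).
#' @return List: `fst`, and `per_site` data.frame (num, den, used) kept for
#'   audit.
#' @export
hudson_fst <- function(pop1, pop2) {
  n1 <- pop1$ref + pop1$alt
  n2 <- pop2$ref + pop2$alt
  if (length(n1) != length(n2)) stop_sym("populations cover different sites")
  p1 <- ifelse(n1 > 0, pop1$alt / n1, NA_real_)
  p2 <- ifelse(n2 > 0, pop2$alt / n2, NA_real_)
  usable <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  used <- usable & !is.na(den) & den > 0
  if (!any(used)) stop_sym("no usable site for F_ST (all depths < 2 or den = 0)")
  list(fst = sum(num[used]) / sum(den[used]),
       per_site = data.frame(num = num, den = den, used = used))
}

#' Pairwise fixation indices under a grouping
#'
#' Applies [hudson_fst()] to every unordered pair of populations, where a
#' population is a single sample (`grouping = "sample"`) or the depth-summed
#' pool of samples sharing a metadata label (`vent_field`, `lifestyle`,
#' `deme`). Negative genome-wide values are reported as computed; a
#' zero-clamped matrix is provided alongside for display.
#'
#' @param v A `variant_table`.
#' @param metadata data.frame with sample_id plus grouping columns
#'   (see [sample_metadata()]).
#' @param grouping One of `"sample"`, `"vent_field"`, `"lifestyle"`,
#'   `"deme"`.
#' @return An `fst_result`: `$fst` (symmetric matrix, zero diagonal),
#'   `$fst_clamped`, `$pairs` (long data.frame with num/den sums),
#'   `$grouping`, `$groups` (member samples per population).
#' @export
pairwise_fst <- function(v, metadata,
                         grouping = c("sample", "vent_field", "lifestyle",
                                      "deme")) {
  grouping <- match.arg(grouping)
  metadata <- metadata[metadata$sample_id %in% v$samples, , drop = FALSE]
  lab <- if (grouping == "sample") metadata$sample_id
         else as.character(metadata[[grouping]])
  groups <- split(metadata$sample_id, lab)
  if (length(groups) < 2L)
    stop_sym("grouping '", grouping, "' yields fewer than 2 populations")
  pools <- lapply(groups, function(s) allele_count_pair(v, s))
  g <- names(groups)
  m <- matrix(0, length(g), length(g), dimnames = list(g, g))
  pairs <- list()
  for (i in seq_along(g)) for (j in seq_len(i - 1L)) {
    h <- hudson_fst(pools[[i]], pools[[j]])
    m[i, j] <- m[j, i] <- h$fst
    pairs[[length(pairs) + 1L]] <- data.frame(
      pop1 = g[j], pop2 = g[i], fst = h$fst,
      fst_clamped = max(0, h$fst),
      num_sum = sum(h$per_site$num[h$per_site$used]),
      den_sum = sum(h$per_site$den[h$per_site$used]),
      n_sites_used = sum(h$per_site$used), stringsAsFactors = FALSE)
  }
  structure(list(fst = m, fst_clamped = pmax(m, 0),
                 pairs = do.call(rbind, pairs), grouping = grouping,
                 groups = groups),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("fst_result (grouping:", x$grouping, ")\n")
  print(round(x$fst, 4))
  invisible(x)
}

#' Classify a fixation index into differentiation bands
#'
#' Bands follow the population-genetic convention used for these symbiont
#' comparisons: weak below 0.2, moderate 0.2-0.5, strong above 0.5.
#'
#' @param fst Numeric vector of fixation indices (finite).
#' @return Character vector: `"weak"`, `"moderate"`, or `"strong"`.
#' @export
classify_differentiation <- function(fst) {
  if (any(!is.finite(fst)))
    stop_sym("fst must be finite")
  ifelse(fst < 0.2, "weak", ifelse(fst <= 0.5, "moderate", "strong"))
}
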