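#' Construct a labelled distance matrix
#'
#' @param m Square numeric matrix (symmetric, zero diagonal, non-negative).
#' @param metric_name Metric label, e.g. `"bray_curtis"` or `"jaccard"`.
#' @return A `dist_matrix` (classed matrix with a `metric_name` attribute).
#' @export
dist_matrix <- function(m, metric_name) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop_sym("m must be square")
  if (max(abs(m - t(m))) > 1e-12) stop_sym("distance matrix not symmetric")
  if (any(diag(m) != 0)) stop_sym("distance matrix diagonal must be zero")
  if (any(m < 0)) stop_sym("distances must be non-negative")
  structure(m, metric_name = metric_name, class = c("dist_matrix", "matrix"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix (", attr(x, "metric_name"), "), ", nrow(x),
      " observations\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

# sample x feature profile matrix from nucleotide counts: per-site base
# proportions (depth artifacts removed) or raw counts
count_profiles <- function(nc, normalization = c("per_site_freq",
                                                 "raw_counts")) {
  normalization <- match.arg(normalization)
  cts <- nc$counts
  n_sites <- dim(cts)[1]; n_samp <- dim(cts)[2]
  prof <- matrix(0, n_samp, n_sites * 4L,
                 dimnames = list(nc$samples, NULL))
  for (j in seq_len(n_samp)) {
    m <- matrix(cts[, j, ], nrow = n_sites)
    if (normalization == "per_site_freq") {
      d <- rowSums(m)
      m <- m / ifelse(d > 0, d, 1)
    }
    prof[j, ] <- as.vector(t(m))
  }
  prof
}

#' Bray-Curtis dissimilarities between samples' nucleotide-count profiles
#'
#' Each sample's profile concatenates, over variant sites, its per-site
#' nucleotide proportions (default; removes depth artifacts between
#' samples), or the raw counts (`normalization = "raw_counts"`). Then
#' \eqn{BC(u, v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)}.
#'
#' @param x A `nuc_counts` object, or a plain numeric matrix of non-negative
#'   abundances with samples as rows.
#' @param normalization Profile mode (ignored for plain matrices).
#' @return A [dist_matrix()] with metric `"bray_curtis"`.
#' @export
bray_curtis_matrix <- function(x, normalization = c("per_site_freq",
                                                    "raw_counts")) {
  prof <- if (inherits(x, "nuc_counts")) count_profiles(x, normalization)
          else as.matrix(x)
  if (nrow(prof) < 2L) stop_sym("need >= 2 samples")
  zero <- rowSums(prof) == 0
  if (any(zero))
    stop_sym("all-zero profile for sample(s): ",
             paste(rownames(prof)[zero] %||% which(zero), collapse = ", "))
  n <- nrow(prof)
  m <- matrix(0, n, n, dimnames = list(rownames(prof), rownames(prof)))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <-
      sum(abs(prof[i, ] - prof[j, ])) / sum(prof[i, ] + prof[j, ])
  }
  dist_matrix(m, "bray_curtis")
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centers the squared distance matrix (`B = -J D^2 J / 2`),
#' eigendecomposes `B`, and scales eigenvectors by the square roots of
#' positive eigenvalues. Negative eigenvalues (non-Euclidean input) are
#' reported, contribute zero coordinates, and enter the
#' proportion-explained denominator by absolute value; no Cailliez/Lingoes
#' correction is applied.
#'
#' @param d A [dist_matrix()], `dist`, or symmetric matrix.
#' @param n_axes Number of axes to return (`<= n - 1`).
#' @return A `pcoa_result`: `$coordinates` (n x n_axes), `$eigenvalues`
#'   (all n), `$proportion_explained` (per returned axis).
#' @export
pcoa <- function(d, n_axes = 2) {
  m <- if (inherits(d, "dist")) as.matrix(d) else unclass(as.matrix(d))
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop_sym("pcoa input must be a symmetric distance matrix")
  n <- nrow(m)
  if (n_axes > n - 1L) stop_sym("n_axes must be <= n - 1")
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (m^2) %*% J
  ee <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- ee$values
  tol <- max(abs(ev)) * 1e-9
  coords <- matrix(0, n, n_axes,
                   dimnames = list(rownames(m),
                                   paste0("Axis", seq_len(n_axes))))
  for (a in seq_len(n_axes)) {
    if (ev[a] > tol) coords[, a] <- ee$vectors[, a] * sqrt(ev[a])
  }
  prop <- pmax(ev, 0) / sum(abs(ev))
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion_explained = prop[seq_len(n_axes)]),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("pcoa_result:", nrow(x$coordinates), "points,",
      ncol(x$coordinates), "axes; proportion explained:",
      paste(sprintf("%.1f%%", 100 * x$proportion_explained),
            collapse = ", "), "\n")
  invisible(x)
}
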