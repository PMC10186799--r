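#' Specify one simulated metagenomic sample
#'
#' A sample is a strain mixture from one deme (one vent field's symbiont
#' population), labelled with a lifestyle, sequenced to a target mean depth,
#' and optionally contaminated with host-derived reads (gill tissue samples
#' are dominated by host DNA; diffuse-fluid samples are nearly host-free).
#'
#' @param sample_id Unique sample label.
#' @param vent_field Vent field label (the geographic grouping).
#' @param lifestyle `"host_associated"` or `"free_living"`.
#' @param deme 1-based index of the deme the sample draws strains from.
#' @param strain_proportions Numeric simplex vector over the deme's strains
#'   (must sum to 1 within 1e-9), or `NULL` for an equal mixture of the
#'   deme's strains. Equal proportions are the neutral default: with a
#'   finite founder pool of S strains, uneven weights inflate the realized
#'   between-deme differentiation above the island-model F by roughly
#'   `(sum of squared weights) x (1 - F)`, and the equal mixture attains
#'   the 1/S floor of that founder effect. Use [dirichlet_proportions()]
#'   for deliberately uneven mixtures.
#' @param mean_depth Target mean symbiont coverage (x-fold).
#' @param host_read_fraction Fraction of the sample's reads that originate
#'   from the host genome, in `[0, 1)`.
#' @return A `sample_spec` list.
#' @export
sample_spec <- function(sample_id, vent_field, lifestyle, deme,
                        strain_proportions = NULL, mean_depth = 20,
                        host_read_fraction = 0) {
  lifestyle <- match.arg(lifestyle, c("host_associated", "free_living"))
  if (!is.null(strain_proportions)) {
    if (abs(sum(strain_proportions) - 1) > 1e-9)
      stop_sym("strain_proportions of '", sample_id, "' must sum to 1")
    if (any(strain_proportions < 0))
      stop_sym("strain_proportions must be non-negative")
  }
  if (mean_depth <= 0) stop_sym("mean_depth must be > 0")
  if (host_read_fraction < 0 || host_read_fraction >= 1)
    stop_sym("host_read_fraction must be in [0, 1)")
  structure(list(sample_id = sample_id, vent_field = vent_field,
                 lifestyle = lifestyle, deme = as.integer(deme),
                 strain_proportions = strain_proportions,
                 mean_depth = mean_depth,
                 host_read_fraction = host_read_fraction),
            class = "sample_spec")
}

#' Build the default sample layout
#'
#' The study design this emulates: per vent field (deme), a few host-associated
#' gill samples plus one free-living fluid sample, all drawing strains from the
#' same deme pool. Host-associated samples carry substantial host read
#' contamination; fluid samples almost none.
#'
#' @param n_demes Number of demes / vent fields.
#' @param host_per_deme Host-associated samples per deme.
#' @param free_per_deme Free-living samples per deme.
#' @param mean_depth Target symbiont coverage for every sample.
#' @param host_frac_gill,host_frac_fluid Host read fractions by lifestyle.
#' @return List of [sample_spec()] objects.
#' @export
default_samples <- function(n_demes = 2, host_per_deme = 2, free_per_deme = 1,
                            mean_depth = 20, host_frac_gill = 0.2,
                            host_frac_fluid = 0.01) {
  out <- list()
  for (d in seq_len(n_demes)) {
    field <- paste0("field", d)
    for (i in seq_len(host_per_deme))
      out[[length(out) + 1L]] <- sample_spec(
        sprintf("%s_gill%d", field, i), field, "host_associated", d,
        mean_depth = mean_depth, host_read_fraction = host_frac_gill)
    for (i in seq_len(free_per_deme))
      out[[length(out) + 1L]] <- sample_spec(
        sprintf("%s_fluid%d", field, i), field, "free_living", d,
        mean_depth = mean_depth, host_read_fraction = host_frac_fluid)
  }
  out
}

#' Draw an uneven strain mixture from a symmetric Dirichlet
#'
#' @param n Number of strains.
#' @param alpha Dirichlet concentration (smaller = more uneven).
#' @param seed Integer seed.
#' @return Simplex vector of length `n`.
#' @export
dirichlet_proportions <- function(n, alpha = 1, seed = 1) {
  with_seed(seed, {
    x <- stats::rgamma(n, shape = alpha)
    x / sum(x)
  })
}

#' Configure the geography-versus-lifestyle scenario
#'
#' Emulates the study contrast: demes map one-to-one onto vent fields, and
#' the host-associated and free-living samples of a field share the field's
#' strain pool with only a mild lifestyle-specific tilt of the mixture
#' weights. Under this design the pooled-by-field fixation index reflects
#' the island-model `fst_target` while the pooled-by-lifestyle index stays
#' near zero — geography, not lifestyle, structures the populations.
#'
#' Mixture construction per field: a field-level Dirichlet base weight
#' vector; per lifestyle a log-normal tilt (`sd = lifestyle_tilt_sd`)
#' applied to the base; per sample a smaller log-normal jitter
#' (`sd = sample_jitter_sd`), renormalized.
#'
#' @param seed Integer seed.
#' @param fst_target Between-field island-model F.
#' @param n_fields Number of vent fields (= demes).
#' @param hosts_per_field,free_per_field Samples per field by lifestyle.
#' @param lifestyle_tilt_sd,sample_jitter_sd Log-scale s.d. of the
#'   lifestyle tilt / per-sample jitter of mixture weights.
#' @param ... Passed on to [sim_config()] (e.g. `n_variant_sites`,
#'   `error_rate`).
#' @return A [sim_config()] with explicit per-sample strain proportions.
#' @export
geography_lifestyle_config <- function(seed = 1, fst_target = 0.4,
                                       n_fields = 2, hosts_per_field = 2,
                                       free_per_field = 1,
                                       lifestyle_tilt_sd = 0.5,
                                       sample_jitter_sd = 0.2, ...) {
  base_cfg <- sim_config(n_demes = n_fields, fst_target = fst_target,
                         seed = seed, ...)
  S <- base_cfg$strains_per_deme
  samples <- list()
  with_seed(derive_seed(seed, "mixtures"), {
    for (d in seq_len(n_fields)) {
      field <- paste0("field", d)
      base_w <- stats::rgamma(S, shape = 5)
      tilt <- list(host_associated = exp(stats::rnorm(S, 0, lifestyle_tilt_sd)),
                   free_living = exp(stats::rnorm(S, 0, lifestyle_tilt_sd)))
      layout <- c(rep("host_associated", hosts_per_field),
                  rep("free_living", free_per_field))
      for (i in seq_along(layout)) {
        lf <- layout[i]
        w <- base_w * tilt[[lf]] * exp(stats::rnorm(S, 0, sample_jitter_sd))
        w <- w / sum(w)
        nm <- sprintf("%s_%s%d", field,
                      if (lf == "host_associated") "gill" else "fluid",
                      sum(layout[seq_len(i)] == lf))
        samples[[length(samples) + 1L]] <- sample_spec(
          nm, field, lf, d, strain_proportions = w,
          host_read_fraction = if (lf == "host_associated") 0.2 else 0.01)
      }
    }
  })
  base_cfg$samples <- samples
  validate_sim_config(base_cfg)
  base_cfg
}

#' Configure a synthetic symbiont metagenome study
#'
#' Defaults encode the emulated study conditions: two vent-field demes over a
#' shared pangenome (80 core genes of roughly 1 kb, so planted variants sit
#' about one per 40 bp), 2000 biallelic variant sites confined to core genes,
#' 20 strains per deme, 3 samples per deme at 20x coverage, 150-bp reads with
#' a 0.5% substitution error rate.
#'
#' @param n_demes Number of demes (island-model populations).
#' @param fst_target Island-model differentiation parameter F in `[0, 1)`;
#'   the expected Hudson fixation index between demes.
#' @param n_core_genes Core genes shared by every strain.
#' @param n_accessory_per_deme Accessory genes private to each deme.
#' @param gene_length_range `(min, max)` gene length in bp.
#' @param n_variant_sites Number of biallelic sites planted in core genes.
#' @param strains_per_deme Haplotypes drawn per deme.
#' @param samples List of [sample_spec()]; default [default_samples()].
#' @param read_length Read length in bp (Illumina-style short reads).
#' @param error_rate Per-base substitution error probability, `[0, 0.5)`.
#' @param host_genome_length Length of the host decoy sequence (bp).
#' @param seed Integer seed; all stages derive sub-streams from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_demes = 2, fst_target = 0.2, n_core_genes = 80,
                       n_accessory_per_deme = 2,
                       gene_length_range = c(800, 1200),
                       n_variant_sites = 2000, strains_per_deme = 20,
                       samples = default_samples(n_demes),
                       read_length = 150, error_rate = 0.005,
                       host_genome_length = 50000L, seed = 1) {
  cfg <- structure(list(
    n_demes = as.integer(n_demes), fst_target = fst_target,
    n_core_genes = as.integer(n_core_genes),
    n_accessory_per_deme = as.integer(n_accessory_per_deme),
    gene_length_range = as.integer(gene_length_range),
    n_variant_sites = as.integer(n_variant_sites),
    strains_per_deme = as.integer(strains_per_deme),
    samples = samples, read_length = as.integer(read_length),
    error_rate = error_rate,
    host_genome_length = as.integer(host_genome_length),
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(gene_length_range) != 2L || gene_length_range[1] > gene_length_range[2])
      stop_sym("invalid gene_length_range: min > max")
    if (fst_target < 0 || fst_target >= 1)
      stop_sym("fst_target must be in [0, 1)")
    if (error_rate < 0 || error_rate >= 0.5)
      stop_sym("error_rate must be in [0, 0.5)")
    if (read_length > gene_length_range[1])
      stop_sym("read_length must not exceed the minimum gene length")
    if (any(c(n_demes, n_core_genes, n_variant_sites, strains_per_deme) < 1))
      stop_sym("all counts must be >= 1")
    if (n_accessory_per_deme < 0)
      stop_sym("n_accessory_per_deme must be >= 0")
    ids <- vapply(samples, `[[`, character(1), "sample_id")
    if (anyDuplicated(ids)) stop_sym("duplicate sample_id in samples")
    demes <- vapply(samples, `[[`, integer(1), "deme")
    if (any(demes < 1L | demes > n_demes))
      stop_sym("sample deme index outside 1..n_demes")
  })
  invisible(cfg)
}
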