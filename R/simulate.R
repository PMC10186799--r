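#' Simulate deme allele frequencies under the Balding-Nichols island model
#'
#' Each site gets an ancestral frequency `p ~ Uniform(0.05, 0.95)` (bounded
#' away from fixation, where estimator variance explodes). Each deme's
#' frequency is then drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose mean is
#' `p` and whose variance is `F p (1-p)` — so the expected Hudson fixation
#' index between demes equals the single parameter `F`. At `F = 0` deme
#' frequencies equal the ancestral frequencies exactly.
#'
#' @param fst_target Island-model `F` in `[0, 1)`.
#' @param n_sites Number of variant sites.
#' @param n_demes Number of demes.
#' @param seed Integer seed.
#' @return List with `ancestral_freqs` (length `n_sites`) and `deme_freqs`
#'   (`n_demes x n_sites` matrix, values in `[0, 1]`).
#' @export
simulate_deme_frequencies <- function(fst_target, n_sites, n_demes = 2,
                                      seed = 1) {
  if (fst_target < 0 || fst_target >= 1)
    stop_sym("fst_target must be in [0, 1)")
  with_seed(seed, {
    p <- runif(n_sites, 0.05, 0.95)
    if (fst_target == 0) {
      dm <- matrix(rep(p, each = n_demes), nrow = n_demes)
    } else {
      f <- (1 - fst_target) / fst_target
      dm <- matrix(rbeta(n_demes * n_sites, rep(p, each = n_demes) * f,
                         rep(1 - p, each = n_demes) * f),
                   nrow = n_demes)
    }
    list(ancestral_freqs = p, deme_freqs = dm)
  })
}

# choose n_sites distinct (gene, offset) positions in core genes
place_variant_sites <- function(pg, n_sites) {
  core <- pg$genes[pg$genes$category == "core", ]
  total <- sum(core$length)
  if (n_sites > total)
    stop_sym("n_variant_sites exceeds total core gene length")
  flat <- sort(sample.int(total, n_sites))
  ends <- cumsum(core$length)
  gidx <- findInterval(flat - 1L, c(0L, ends), rightmost.closed = TRUE)
  pos <- flat - c(0L, ends)[gidx] - 1L  # 0-based offset within gene
  sites <- data.frame(gene_id = core$gene_id[gidx], pos = pos,
                      stringsAsFactors = FALSE)
  if (anyDuplicated(sites[c("gene_id", "pos")]))
    stop_sym("variant site collision: two sites at the same position")
  sites$ref <- substr(pg$seq[sites$gene_id], sites$pos + 1L, sites$pos + 1L)
  sites$alt <- vapply(sites$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
    USE.NAMES = FALSE)
  sites
}

#' Simulate strain haplotypes and per-sample read sets
#'
#' Variant sites are planted at distinct positions in core genes only, so
#' sequence differentiation (fixation index) and gene content (accessory
#' genes) stay orthogonal axes of ground truth. Each deme's strains draw
#' their allele at every site as `Bernoulli(deme frequency)`; a strain
#' carries all core genes plus its deme's accessory genes. Reads are sampled
#' uniformly along the genes a strain carries (strain picked per the sample's
#' mixture proportions), on either strand, with i.i.d. substitution errors.
#' Host contamination is drawn from a single random host decoy sequence.
#'
#' @param config A [sim_config()].
#' @param pg A [pangenome()] from [generate_pangenome()].
#' @param freqs Output of [simulate_deme_frequencies()].
#' @return A `symbiont_sim` object: `$reads` (per-sample named character
#'   vectors), `$truth` (completed truth set with `read_origins`),
#'   `$pangenome`, `$config`.
#' @export
simulate_strains_and_samples <- function(config, pg, freqs) {
  validate_sim_config(config)
  n_sites <- config$n_variant_sites
  sites <- with_seed(derive_seed(config$seed, "sites"),
                     place_variant_sites(pg, n_sites))

  # strain haplotypes: rows d<d>_s<s>, 0 = ref, 1 = alt
  n_strain <- config$n_demes * config$strains_per_deme
  strain_meta <- data.frame(
    strain_id = sprintf("d%d_s%02d",
                        rep(seq_len(config$n_demes), each = config$strains_per_deme),
                        rep(seq_len(config$strains_per_deme), config$n_demes)),
    deme = rep(seq_len(config$n_demes), each = config$strains_per_deme),
    stringsAsFactors = FALSE)
  hap <- with_seed(derive_seed(config$seed, "haplotypes"), {
    h <- matrix(0L, n_strain, n_sites)
    for (i in seq_len(n_strain)) {
      h[i, ] <- rbinom(n_sites, 1L, freqs$deme_freqs[strain_meta$deme[i], ])
    }
    h
  })
  rownames(hap) <- strain_meta$strain_id

  # gene content truth: core genes for all, accessory genes of the own deme
  gc_truth <- matrix(FALSE, n_strain, nrow(pg$genes),
                     dimnames = list(strain_meta$strain_id, pg$genes$gene_id))
  gc_truth[, pg$genes$category == "core"] <- TRUE
  for (i in seq_len(n_strain)) {
    own <- !is.na(pg$genes$deme) & pg$genes$deme == strain_meta$deme[i]
    gc_truth[i, own] <- TRUE
  }

  # realized strain gene sequences (core genes with alleles substituted)
  strain_seq <- matrix(NA_character_, n_strain, nrow(pg$genes),
                       dimnames = list(strain_meta$strain_id, pg$genes$gene_id))
  for (g in pg$genes$gene_id) {
    in_g <- which(sites$gene_id == g)
    base_seq <- pg$seq[[g]]
    for (i in seq_len(n_strain)) {
      if (!gc_truth[i, g]) next
      s <- base_seq
      if (length(in_g)) {
        is_alt <- hap[i, in_g] == 1L
        for (j in in_g[is_alt])
          substr(s, sites$pos[j] + 1L, sites$pos[j] + 1L) <- sites$alt[j]
      }
      strain_seq[i, g] <- s
    }
  }

  host_seq <- with_seed(derive_seed(config$seed, "host"),
                        random_dna(config$host_genome_length))

  rl <- config$read_length
  reads <- list()
  origins <- list()
  for (sp in config$samples) {
    sid <- sp$sample_id
    deme_rows <- which(strain_meta$deme == sp$deme)
    props <- sp$strain_proportions %||%
      rep(1 / length(deme_rows), length(deme_rows))
    if (length(props) != length(deme_rows))
      stop_sym("strain_proportions of '", sid, "' must have length ",
               length(deme_rows))

    res <- with_seed(derive_seed(config$seed, paste0("reads_", sid)), {
      present <- which(gc_truth[deme_rows[1], ])  # same content within deme
      glen <- pg$genes$length[present]
      w <- glen - rl + 1L
      n_sym <- rpois(1, sp$mean_depth * sum(glen) / rl)
      n_host <- if (sp$host_read_fraction > 0)
        round(n_sym * sp$host_read_fraction / (1 - sp$host_read_fraction)) else 0L

      strain_i <- deme_rows[sample.int(length(deme_rows), n_sym, TRUE, prob = props)]
      gene_i <- present[sample.int(length(present), n_sym, TRUE, prob = w)]
      start <- as.integer(floor(runif(n_sym) * (pg$genes$length[gene_i] - rl + 1L)))
      full <- strain_seq[cbind(strain_i, gene_i)]
      sq <- substr(full, start + 1L, start + rl)

      h_start <- if (n_host > 0)
        as.integer(floor(runif(n_host) * (config$host_genome_length - rl + 1L)))
      else integer(0)
      h_sq <- substr(rep(host_seq, n_host), h_start + 1L, h_start + rl)

      all_sq <- c(sq, h_sq)
      rcflag <- runif(n_sym + n_host) < 0.5
      if (any(rcflag)) all_sq[rcflag] <- revcomp(all_sq[rcflag])
      all_sq <- mutate_seqs(all_sq, config$error_rate)
      ids <- sprintf("%s_r%07d", sid, seq_len(n_sym + n_host))

      org <- data.table::data.table(
        sample_id = sid, read_id = ids,
        origin = c(rep("symbiont", n_sym), rep("host", n_host)),
        strain_id = c(strain_meta$strain_id[strain_i], rep(NA_character_, n_host)),
        gene_id = c(pg$genes$gene_id[gene_i], rep(NA_character_, n_host)),
        gene_category = c(pg$genes$category[gene_i], rep(NA_character_, n_host)),
        start = c(start, h_start),
        strand = ifelse(rcflag, "-", "+"))
      list(reads = setNames(all_sq, ids), origins = org)
    })
    reads[[sid]] <- res$reads
    origins[[sid]] <- res$origins
  }

  truth <- list(ancestral_freqs = freqs$ancestral_freqs,
                deme_freqs = freqs$deme_freqs, sites = sites,
                strain_haplotypes = hap, strain_meta = strain_meta,
                strain_gene_content = gc_truth,
                read_origins = data.table::rbindlist(origins))
  structure(list(reads = reads, truth = truth, pangenome = pg,
                 config = config),
            class = "symbiont_sim")
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: pangenome, deme frequencies, strains and reads.
#'
#' @param config A [sim_config()].
#' @return A `symbiont_sim` object (see [simulate_strains_and_samples()]).
#' @export
simulate_metagenomes <- function(config) {
  pg <- generate_pangenome(config)
  freqs <- simulate_deme_frequencies(config$fst_target, config$n_variant_sites,
                                     config$n_demes,
                                     derive_seed(config$seed, "freqs"))
  simulate_strains_and_samples(config, pg, freqs)
}

#' @export
print.symbiont_sim <- function(x, ...) {
  cat("symbiont_sim:", length(x$reads), "samples,",
      sum(vapply(x$reads, length, integer(1))), "reads,",
      nrow(x$truth$sites), "planted variant sites, fst_target =",
      x$config$fst_target, "\n")
  invisible(x)
}

#' Sample metadata table of a simulation
#'
#' @param sim A `symbiont_sim` object (or a `sim_config`).
#' @return data.frame with sample_id, vent_field, lifestyle, deme.
#' @export
sample_metadata <- function(sim) {
  cfg <- if (inherits(sim, "sim_config")) sim else sim$config
  do.call(rbind, lapply(cfg$samples, function(sp)
    data.frame(sample_id = sp$sample_id, vent_field = sp$vent_field,
               lifestyle = sp$lifestyle, deme = sp$deme,
               stringsAsFactors = FALSE)))
}

#' Write simulated reads to per-sample FASTQ files
#'
#' @param sim A `symbiont_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of FASTQ paths.
#' @export
write_sample_fastq <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(sim$reads), function(sid) {
    p <- file.path(dir, paste0(sid, ".fastq"))
    write_fastq(sim$reads[[sid]], p)
    p
  }, character(1))
  paths
}
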