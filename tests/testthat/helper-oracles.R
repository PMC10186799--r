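# Independent oracles and shared fixtures. Oracles are deliberately naive
# (full enumeration / per-site loops) and never call the code paths they
# check.

# brute-force all-positions Hamming-distance read placement
brute_force_map <- function(read, genes, max_mismatch_frac) {
  L <- nchar(read)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(read)))
  best_nm <- L + 1L
  best <- list()
  for (g in seq_along(genes)) {
    glen <- nchar(genes[[g]])
    if (glen < L) next
    for (start in 0:(glen - L)) {
      piece <- substr(genes[[g]], start + 1L, start + L)
      for (orient in c("+", "-")) {
        q <- if (orient == "+") read else rc
        nm <- sum(utf8ToInt(q) != utf8ToInt(piece))
        if (nm < best_nm) {
          best_nm <- nm
          best <- list(list(gene = g, start = start, orient = orient))
        } else if (nm == best_nm) {
          best[[length(best) + 1L]] <- list(gene = g, start = start,
                                            orient = orient)
        }
      }
    }
  }
  if (!length(best) || best_nm > max_mismatch_frac * L)
    return(list(status = "unmapped"))
  genes_hit <- unique(vapply(best, `[[`, numeric(1), "gene"))
  if (length(genes_hit) > 1L) return(list(status = "ambiguous"))
  # lowest start, forward orientation first, matching the mapper's tie rule
  ord <- order(vapply(best, `[[`, numeric(1), "start"),
               vapply(best, function(b) b$orient == "-", logical(1)))
  b <- best[[ord[1]]]
  list(status = "mapped", gene = b$gene, start = b$start, orient = b$orient,
       nm = best_nm)
}

# per-site loop evaluation of the Hudson estimator
brute_force_hudson <- function(ref1, alt1, ref2, alt2) {
  num_sum <- 0; den_sum <- 0
  for (i in seq_along(ref1)) {
    n1 <- ref1[i] + alt1[i]; n2 <- ref2[i] + alt2[i]
    if (n1 < 2 || n2 < 2) next
    p1 <- alt1[i] / n1; p2 <- alt2[i] / n2
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    if (den > 0) {
      num_sum <- num_sum + num
      den_sum <- den_sum + den
    }
  }
  num_sum / den_sum
}

# reconstruct a strain's realized gene sequence from the truth set alone
truth_strain_seq <- function(sim, strain_id, gene_id) {
  s <- sim$pangenome$seq[[gene_id]]
  sites <- sim$truth$sites
  in_g <- which(sites$gene_id == gene_id)
  for (j in in_g) {
    if (sim$truth$strain_haplotypes[strain_id, j] == 1L)
      substr(s, sites$pos[j] + 1L, sites$pos[j] + 1L) <- sites$alt[j]
  }
  s
}

# build a nuc_counts object by hand (site x sample x ACGT)
make_nuc_counts <- function(counts, gene_id = "g1") {
  n_sites <- dim(counts)[1]
  samples <- dimnames(counts)[[2]]
  structure(list(sites = data.frame(gene_id = rep(gene_id, n_sites),
                                    pos = seq_len(n_sites) - 1L,
                                    stringsAsFactors = FALSE),
                 samples = samples, counts = counts),
            class = "nuc_counts")
}

# ---- cached fixtures (built once per test run) ----
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# noisy simulation at the default study conditions, mapped end to end
noisy_pipeline_fixture <- function() fixture("noisy", function() {
  cfg <- sim_config(seed = 42, fst_target = 0.3)
  sim <- simulate_metagenomes(cfg)
  aln <- lapply(names(sim$reads), function(s)
    map_reads(sim$reads[[s]], sim$pangenome, sample_id = s))
  names(aln) <- names(sim$reads)
  pc <- pileup_counts(aln, sim$pangenome)
  list(sim = sim, aln = aln, counts = pc$counts, coverage = pc$coverage)
})

# error-free simulation for exact-recovery checks
clean_sim_fixture <- function() fixture("clean", function() {
  cfg <- sim_config(seed = 11, n_core_genes = 20, n_variant_sites = 200,
                    error_rate = 0)
  sim <- simulate_metagenomes(cfg)
  aln <- lapply(names(sim$reads), function(s)
    map_reads(sim$reads[[s]], sim$pangenome, sample_id = s))
  names(aln) <- names(sim$reads)
  list(sim = sim, aln = aln)
})

marker_scenarios_fixture <- function() fixture("markers", function() {
  lapply(setNames(c("gill", "fluid"), c("gill", "fluid")), function(sc) {
    ms <- generate_marker_read_sets(sc, seed = 19, total_reads = 8000)
    db <- build_marker_index(ms$databases)
    cl <- classify_reads(ms$reads, db)
    list(ms = ms, db = db, cl = cl)
  })
})
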