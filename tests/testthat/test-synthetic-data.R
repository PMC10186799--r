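test_that("pangenome generation: gene counts, determinism, degenerate ranges", {
  cfg <- sim_config(n_demes = 2, n_core_genes = 5, n_accessory_per_deme = 2,
                    n_variant_sites = 10, gene_length_range = c(500, 700),
                    read_length = 100, seed = 1)
  pg <- generate_pangenome(cfg)
  expect_equal(nrow(pg$genes), 5 + 2 * 2)
  expect_equal(sum(pg$genes$category == "core"), 5)
  expect_equal(pg$genes$deme[pg$genes$category == "accessory"],
               rep(1:2, each = 2))

  pg2 <- generate_pangenome(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(pg$seq, f1); write_fasta(pg2$seq, f2)
  expect_identical(readLines(f1), readLines(f2))

  cfg_deg <- sim_config(n_core_genes = 5, gene_length_range = c(500, 500),
                        n_variant_sites = 10, read_length = 100, seed = 2)
  expect_true(all(nchar(generate_pangenome(cfg_deg)$seq) == 500))

  expect_error(sim_config(gene_length_range = c(900, 800)), "min > max")
})

test_that("island-model deme frequencies: limits, support, mean reversion", {
  f0 <- simulate_deme_frequencies(0, 50, n_demes = 3, seed = 1)
  expect_equal(f0$deme_freqs, matrix(rep(f0$ancestral_freqs, each = 3), nrow = 3))

  f99 <- simulate_deme_frequencies(0.99, 500, seed = 2)
  expect_true(all(f99$deme_freqs >= 0 & f99$deme_freqs <= 1))

  expect_error(simulate_deme_frequencies(1, 10), "fst_target")

  # frequency conservation: with many demes the across-deme mean reverts to
  # the ancestral frequency, and the across-deme variance matches F p(1-p)
  fr <- simulate_deme_frequencies(0.4, 200, n_demes = 400, seed = 9)
  dev <- colMeans(fr$deme_freqs) - fr$ancestral_freqs
  expect_lt(max(abs(dev)), 4.5 * sqrt(0.4 * 0.25 / 400))
  v_obs <- apply(fr$deme_freqs, 2, var)
  v_exp <- 0.4 * fr$ancestral_freqs * (1 - fr$ancestral_freqs)
  expect_equal(mean(v_obs / v_exp), 1, tolerance = 0.1)
})

test_that("read simulation: exact substrings at zero error, counts, host spike-ins", {
  cs <- clean_sim_fixture()
  sim <- cs$sim

  org <- sim$truth$read_origins[sample_id == names(sim$reads)[1]]
  org <- org[origin == "symbiont"]
  reads <- sim$reads[[1]]
  pick <- org[seq(1, min(nrow(org), 200))]
  for (i in seq_len(nrow(pick))) {
    full <- truth_strain_seq(sim, pick$strain_id[i], pick$gene_id[i])
    expected <- substr(full, pick$start[i] + 1L,
                       pick$start[i] + sim$config$read_length)
    if (pick$strand[i] == "-")
      expected <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(expected)))
    expect_identical(unname(reads[pick$read_id[i]]), expected)
  }

  # read counts Poisson-consistent with target depth
  cfg <- sim_config(seed = 5, n_core_genes = 10, n_accessory_per_deme = 0,
                    gene_length_range = c(1000, 1000), n_variant_sites = 50,
                    samples = list(sample_spec("s1", "f1", "host_associated",
                                               1, mean_depth = 20)))
  s <- simulate_metagenomes(cfg)
  lambda <- 20 * 10 * 1000 / 150
  expect_lt(abs(length(s$reads$s1) - lambda), 4 * sqrt(lambda))

  # zero host fraction => no host-origin reads
  expect_equal(nrow(s$truth$read_origins[origin == "host"]), 0L)

  # positive host fraction => about that share of reads
  cfg_h <- sim_config(seed = 6, n_core_genes = 10, n_accessory_per_deme = 0,
                      gene_length_range = c(1000, 1000), n_variant_sites = 50,
                      samples = list(sample_spec("s1", "f1", "host_associated",
                                                 1, mean_depth = 20,
                                                 host_read_fraction = 0.3)))
  s_h <- simulate_metagenomes(cfg_h)
  frac <- mean(s_h$truth$read_origins$origin == "host")
  expect_equal(frac, 0.3, tolerance = 0.05)
})

test_that("simulation is deterministic and keeps variants in core genes", {
  cfg <- sim_config(seed = 77, n_core_genes = 8, n_variant_sites = 60,
                    gene_length_range = c(500, 800), read_length = 100)
  s1 <- simulate_metagenomes(cfg)
  s2 <- simulate_metagenomes(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$sites, s2$truth$sites)

  core_ids <- s1$pangenome$genes$gene_id[s1$pangenome$genes$category == "core"]
  expect_true(all(s1$truth$sites$gene_id %in% core_ids))
  expect_false(anyDuplicated(s1$truth$sites[c("gene_id", "pos")]) > 0)
})

test_that("accessory genes of a deme occur only in that deme's samples", {
  cs <- clean_sim_fixture()
  org <- cs$sim$truth$read_origins[gene_category == "accessory"]
  md <- sample_metadata(cs$sim)
  gene_deme <- with(cs$sim$pangenome$genes,
                    setNames(deme, gene_id))
  expect_true(all(gene_deme[org$gene_id] ==
                    md$deme[match(org$sample_id, md$sample_id)]))
})

test_that("marker scenario generator controls composition and refuses blind decoys", {
  expect_error(generate_marker_read_sets("gill", background_divergence = 0),
               "indistinguishable")

  ms <- generate_marker_read_sets("gill", seed = 3, total_reads = 2000,
                                  counts = list(target_16S = 0L,
                                                target_CO1 = 0L,
                                                background_16S = 150L,
                                                background_CO1 = 150L))
  expect_equal(sum(ms$truth$category %in% c("target_16S", "target_CO1")), 0L)

  gill <- generate_marker_read_sets("gill", seed = 4, total_reads = 2000)
  fluid <- generate_marker_read_sets("fluid", seed = 4, total_reads = 2000)
  expect_gt(fluid$truth_ratio, gill$truth_ratio)
  expect_true(gill$truth_ratio >= 1 && gill$truth_ratio <= 10)
  expect_true(fluid$truth_ratio >= 10 && fluid$truth_ratio <= 300)
})
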