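test_that("pileup counts observed bases and conserves depth", {
  set.seed(40)
  g <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  substr(g, 50, 50) <- "C"
  pg <- pangenome("g1", g, "core")
  # ten identical error-free reads covering position 49 (0-based)
  reads <- setNames(rep(substr(g, 21, 100), 10), paste0("r", 1:10))
  aln <- map_reads(reads, pg, sample_id = "s1")
  pc <- pileup_counts(aln, pg)
  i <- which(pc$counts$sites$pos == 49L)
  expect_equal(unname(pc$counts$counts[i, "s1", ]), c(0L, 10L, 0L, 0L))

  # depth at every covered position equals the overlapping alignment count
  depth <- rowSums(pc$counts$counts[, "s1", ])
  overlap <- vapply(pc$counts$sites$pos, function(p)
    sum(aln$start <= p & aln$start + nchar(aln$seq) > p), integer(1))
  expect_equal(unname(depth), overlap)
  expect_equal(pc$coverage$mean_depth, sum(nchar(aln$seq)) / 200)
})

test_that("simulated 20x samples report mean depth within 10% of target", {
  np <- noisy_pipeline_fixture()
  # depth is measured over the whole pangenome incl. the other deme's
  # accessory genes; compare against the per-sample attainable target
  pg <- np$sim$pangenome
  md <- sample_metadata(np$sim)
  own_len <- vapply(md$deme, function(d)
    sum(pg$genes$length[pg$genes$category == "core" |
                          (!is.na(pg$genes$deme) & pg$genes$deme == d)]),
    numeric(1))
  target <- 20 * own_len / sum(pg$genes$length)
  expect_true(all(abs(np$coverage$mean_depth - target) / target < 0.1))
})

test_that("coverage QC partitions at the threshold inclusively and monotonically", {
  cov <- data.frame(sample_id = c("a", "b"), mean_depth = c(10.0, 9.99),
                    breadth = c(1, 1))
  qc <- sample_qc(cov, 10)
  expect_equal(qc$retained, "a")
  expect_equal(qc$low_coverage, "b")

  cov2 <- data.frame(sample_id = c("deep", "burke"),
                     mean_depth = c(12, 5.9), breadth = c(1, 1))
  expect_equal(sample_qc(cov2, 10)$low_coverage, "burke")

  expect_error(sample_qc(data.frame(sample_id = "x", mean_depth = 3,
                                    breadth = 0.5), 10),
               "review min_mean_depth")

  # raising the threshold never adds a sample
  set.seed(41)
  cov3 <- data.frame(sample_id = paste0("s", 1:20),
                     mean_depth = runif(20, 0, 30), breadth = 1)
  prev <- cov3$sample_id
  for (th in c(0, 5, 10, 15, 25)) {
    cur <- tryCatch(sample_qc(cov3, th)$retained, error = function(e) character())
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("variant filters: monomorphic sites drop, ties break alphabetically", {
  counts <- array(0L, dim = c(3, 2, 4),
                  dimnames = list(NULL, c("s1", "s2"), c("A", "C", "G", "T")))
  # site 1: monomorphic C
  counts[1, , "C"] <- c(20L, 20L)
  # site 2: pooled A=50, G=50, T=1 -> biallelic A/G, ref A by tie-break
  counts[2, , "A"] <- c(25L, 25L)
  counts[2, , "G"] <- c(25L, 25L)
  counts[2, 1, "T"] <- 1L
  # site 3: depth below floor in s2
  counts[3, , "A"] <- c(10L, 4L)
  counts[3, , "T"] <- c(10L, 4L)
  nc <- make_nuc_counts(counts)
  v <- call_variants(nc, min_site_depth = 10, min_allele_count = 4,
                     noise_allele_max = 2, min_maf = 0.02)
  expect_equal(nrow(v$sites), 1L)
  expect_equal(v$sites$pos, 1L)
  expect_equal(v$sites$ref, "A")
  expect_equal(v$sites$alt, "G")
  expect_equal(unname(v$ref_counts[1, ]), c(25L, 25L))
  expect_equal(v$sites$maf, 0.5)

  # all sites filtered -> empty table with a warning, not an error
  nc_mono <- make_nuc_counts(counts[1, , , drop = FALSE])
  expect_warning(v0 <- call_variants(nc_mono), "no site survived")
  expect_equal(nrow(v0$sites), 0L)
})

test_that("raising depth or MAF filters never adds a variant site", {
  set.seed(42)
  counts <- array(rpois(50 * 3 * 4, 4), dim = c(50, 3, 4),
                  dimnames = list(NULL, paste0("s", 1:3), c("A", "C", "G", "T")))
  nc <- make_nuc_counts(counts)
  site_key <- function(v) paste(v$sites$gene_id, v$sites$pos)
  suppressWarnings({
    prev <- site_key(call_variants(nc, min_site_depth = 0, min_maf = 0))
    for (d in c(5, 10, 15)) {
      cur <- site_key(call_variants(nc, min_site_depth = d, min_maf = 0))
      expect_true(all(cur %in% prev))
      prev <- cur
    }
    prev <- site_key(call_variants(nc, min_site_depth = 5, min_maf = 0))
    for (m in c(0.05, 0.1, 0.3)) {
      cur <- site_key(call_variants(nc, min_site_depth = 5, min_maf = m))
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  })
})

test_that("planted variants are recovered and spurious calls stay rare", {
  np <- noisy_pipeline_fixture()
  sim <- np$sim
  qc <- sample_qc(np$coverage, 10)
  v <- call_variants(np$counts, qc$retained)

  truth_key <- paste(sim$truth$sites$gene_id, sim$truth$sites$pos)
  called_key <- paste(v$sites$gene_id, v$sites$pos)

  # callable planted sites: still polymorphic in the realized strain pools
  # (finite founder pools fix a fraction of planted sites) and deep enough
  # in every sample
  hap <- sim$truth$strain_haplotypes
  pool_maf <- pmin(colMeans(hap), 1 - colMeans(hap))
  nc_truth <- pileup_counts(np$aln, sim$pangenome, site_list = sim$truth$sites)
  depth_ok <- apply(vapply(seq_along(qc$retained), function(j)
    rowSums(nc_truth$counts$counts[, qc$retained[j], ]) >= 10,
    logical(nrow(sim$truth$sites))), 1, all)
  callable <- pool_maf >= 0.05 & depth_ok

  recall <- mean(truth_key[callable] %in% called_key)
  expect_gt(recall, 0.95)

  # spurious calls are error-floor artifacts: with ~82 kb of candidate
  # positions, pooled depth ~145 and error rate 0.005, about
  # 3 * P(Binom(145, 0.005/3) >= 4) * 82000 ~ 27 sites reach the
  # min_allele_count = 4 boundary (~2% of calls)
  spurious_idx <- which(!(called_key %in% truth_key))
  expect_lt(length(spurious_idx) / length(called_key), 0.03)
  alt_tot <- rowSums(v$alt_counts[spurious_idx, , drop = FALSE])
  expect_true(all(alt_tot <= 6))

  # a stricter pooled-count filter removes the error floor entirely
  v_strict <- call_variants(np$counts, qc$retained, min_allele_count = 8)
  strict_key <- paste(v_strict$sites$gene_id, v_strict$sites$pos)
  expect_lt(mean(!(strict_key %in% truth_key)), 0.001)
  expect_gt(mean(truth_key[callable] %in% strict_key), 0.9)
})
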