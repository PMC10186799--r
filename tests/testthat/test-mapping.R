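make_pg <- function(seqs) {
  pangenome(names(seqs), unname(seqs), rep("core", length(seqs)))
}

test_that("exact substrings map uniquely with zero mismatches; paralogs are ambiguous", {
  set.seed(21)
  g1 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  g2 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  # plant a shared 120-bp segment in both genes (a paralogous region)
  shared <- substr(g1, 101, 220)
  substr(g2, 201, 320) <- shared
  pg <- make_pg(c(g1 = g1, g2 = g2))

  unique_read <- substr(g1, 301, 380)
  aln <- map_reads(c(r1 = unique_read), pg)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$gene_id, "g1")
  expect_equal(aln$start, 300L)
  expect_equal(aln$n_mismatch, 0L)
  expect_equal(aln$strand, "+")

  # a reverse-complement read maps back to the forward strand
  rc_read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(unique_read)))
  aln_rc <- map_reads(c(r1 = rc_read), pg)
  expect_equal(aln_rc$start, 300L)
  expect_equal(aln_rc$strand, "-")
  expect_equal(aln_rc$seq, unique_read)  # stored gene-forward

  amb_read <- substr(shared, 11, 90)
  aln2 <- map_reads(c(r1 = amb_read), pg)
  expect_equal(nrow(aln2), 0L)
  expect_equal(attr(aln2, "stats")$n_ambiguous, 1L)
})

test_that("reads with non-ACGT symbols are skipped with a warning tally", {
  set.seed(22)
  g <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  pg <- make_pg(c(g1 = g))
  reads <- c(ok = substr(g, 1, 80),
             bad = paste0(substr(g, 1, 79), "N"))
  expect_warning(aln <- map_reads(reads, pg), "non-ACGT")
  expect_equal(nrow(aln), 1L)
  expect_equal(attr(aln, "stats")$n_skipped, 1L)
})

test_that("mapper agrees with the brute-force Hamming scan on small instances", {
  for (seed in 1:3) {
    set.seed(seed)
    n_genes <- sample(3:5, 1)
    genes <- setNames(
      vapply(seq_len(n_genes), function(i)
        paste(sample(c("A", "C", "G", "T"), sample(150:300, 1), TRUE),
              collapse = ""), character(1)),
      paste0("g", seq_len(n_genes)))
    pg <- make_pg(genes)

    reads <- character(0)
    for (r in 1:30) {
      g <- sample(n_genes, 1)
      L <- 60
      start <- sample(nchar(genes[g]) - L + 1, 1)
      rd <- substr(genes[g], start, start + L - 1)
      # plant at most one mismatch beyond the first seed window so the
      # seed-and-extend search sees every placement the oracle sees
      if (runif(1) < 0.5) {
        p <- sample((22):L, 1)
        substr(rd, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(rd, p, p)), 1)
      }
      if (runif(1) < 0.5)
        rd <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(rd)))
      reads <- c(reads, rd)
    }
    # plus a few random reads that should map nowhere
    reads <- c(reads, vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
      character(1)))
    names(reads) <- paste0("r", seq_along(reads))

    aln <- map_reads(reads, pg, max_mismatch_frac = 0.05)
    for (i in seq_along(reads)) {
      oracle <- brute_force_map(reads[i], genes, max_mismatch_frac = 0.05)
      hit <- aln[aln$read_id == names(reads)[i]]
      if (oracle$status == "mapped") {
        expect_equal(nrow(hit), 1L)
        expect_equal(hit$gene_id, names(genes)[oracle$gene])
        expect_equal(hit$start, oracle$start)
        expect_equal(hit$n_mismatch, oracle$nm)
      } else {
        expect_equal(nrow(hit), 0L)
      }
    }
  }
})

test_that("SAM round trip preserves the alignment set; coordinates are 1-based on disk", {
  cs <- clean_sim_fixture()
  aln <- cs$aln[[1]]
  pg <- cs$sim$pangenome
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, pg, sam)

  # SAM POS is internal 0-based start + 1
  body <- readLines(sam)
  body <- body[!startsWith(body, "@")]
  pos <- as.integer(vapply(strsplit(body, "\t"), `[[`, character(1), 4))
  expect_equal(pos, aln$start + 1L)

  back <- read_sam(sam, pg, sample_id = attr(aln, "sample_id"))
  for (col in c("read_id", "gene_id", "start", "strand", "seq", "n_mismatch"))
    expect_equal(back[[col]], aln[[col]])
})

test_that("read_sam skips unmapped records and rejects unknown references", {
  set.seed(30)
  g <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  pg <- make_pg(c(geneA = g))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:geneA\tLN:200",
    sprintf("r1\t0\tgeneA\t1\t60\t50M\t*\t0\t0\t%s\t*", substr(g, 1, 50)),
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\t*"), sam)
  aln <- read_sam(sam, pg)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$start, 0L)  # SAM POS=1 -> internal 0
  expect_equal(aln$n_mismatch, 0L)

  sam2 <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:mystery_gene\tLN:200",
    sprintf("r1\t0\tmystery_gene\t1\t60\t50M\t*\t0\t0\t%s\t*",
            substr(g, 1, 50))), sam2)
  expect_error(read_sam(sam2, pg), "mystery_gene")
})

test_that("nearly all symbiont reads map to their true gene at 1% error", {
  cfg <- sim_config(seed = 55, n_core_genes = 10, n_variant_sites = 100,
                    error_rate = 0.01,
                    samples = list(sample_spec("s1", "f1", "host_associated",
                                               1, mean_depth = 15),
                                   sample_spec("s2", "f2", "host_associated",
                                               2, mean_depth = 15)))
  sim <- simulate_metagenomes(cfg)
  aln <- lapply(names(sim$reads), function(s)
    map_reads(sim$reads[[s]], sim$pangenome, max_mismatch_frac = 0.05,
              sample_id = s))
  org <- sim$truth$read_origins[origin == "symbiont"]
  hits <- data.table::rbindlist(lapply(aln, function(a)
    data.table::data.table(read_id = a$read_id, gene_id = a$gene_id)))
  merged <- merge(org, hits, by = "read_id", suffixes = c("_true", "_mapped"))
  # mapped-to-true-gene rate among all symbiont-origin reads
  rate <- sum(merged$gene_id_true == merged$gene_id_mapped) / nrow(org)
  expect_gt(rate, 0.99)
})
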