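test_that("gene depths are aligned bases over gene length", {
  set.seed(70)
  g1 <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  g2 <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
  pg <- pangenome(c("g1", "g2"), c(g1, g2), c("core", "core"))
  starts <- seq(1, by = 150, length.out = 10)
  reads <- setNames(substring(g1, starts, starts + 149), paste0("r", 1:10))
  aln <- map_reads(reads, pg, sample_id = "s1")
  gd <- gene_depths(aln, pg)
  expect_equal(gd["g1", "s1"], 10 * 150 / 1500)
  expect_equal(gd["g2", "s1"], 0)
})

test_that("presence calls honor both thresholds and the uncertain band", {
  depths <- matrix(c(20, 20,
                     20, 20,
                     0, 20,
                     3, 20), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  pm <- call_presence(depths, theta_present = 0.25, theta_absent = 0.05)
  # s1 median over covered genes = 20: normalized 1, 1, 0, 0.15
  expect_equal(unname(pm[, "s1"]), c(1L, 1L, 0L, NA))
  expect_equal(unname(pm[, "s2"]), rep(1L, 4))
  expect_error(call_presence(depths, 0.1, 0.2), "theta_absent")

  # raising theta_present never converts absent to present
  set.seed(71)
  d <- matrix(runif(40, 0, 30), 20, 2,
              dimnames = list(paste0("g", 1:20), c("a", "b")))
  prev <- call_presence(d, 0.1, 0.01)
  for (tp in c(0.25, 0.5, 0.9)) {
    cur <- call_presence(d, tp, 0.01)
    gained <- !is.na(cur) & cur == 1L & !is.na(prev) & prev != 1L
    expect_false(any(gained))
    prev <- cur
  }
})

test_that("Jaccard distances follow the set formula and metric axioms", {
  p <- matrix(c(1, 1, 1, 0,
                0, 1, 1, 1), ncol = 2,
              dimnames = list(paste0("g", 1:4), c("A", "B")))
  jm <- jaccard_matrix(p)
  expect_equal(jm["A", "B"], 1 - 2 / 4)

  same <- matrix(1, 3, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(jaccard_matrix(same)["A", "B"], 0)

  disj <- matrix(c(1, 0, 0, 1), 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(jaccard_matrix(disj)["A", "B"], 1)

  empty <- matrix(0, 3, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(jaccard_matrix(empty)["A", "B"], 0)

  set.seed(72)
  for (i in 1:5) {
    m <- matrix(rbinom(60, 1, 0.5), 12, 5,
                dimnames = list(NULL, paste0("s", 1:5)))
    jm <- unclass(jaccard_matrix(m))
    expect_true(isSymmetric(jm))
    expect_equal(unname(diag(jm)), rep(0, 5))
    for (a in 1:5) for (b in 1:5) for (c in 1:5)
      expect_lte(jm[a, b], jm[a, c] + jm[c, b] + 1e-12)
  }

  skip_if_not_installed("vegan")
  m <- matrix(rbinom(60, 1, 0.5), 12, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  m[, 1] <- pmax(m[, 1], 1L)  # vegan is undefined on empty sets
  got <- unclass(jaccard_matrix(m))
  want <- as.matrix(vegan::vegdist(t(m), method = "jaccard", binary = TRUE))
  expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("group-unique genes need presence in all members and absence elsewhere", {
  p <- matrix(c(1, 1, 0, NA,
                1, 1, 0, 1,
                1, 0, 1, 0,
                1, 0, 1, 0), ncol = 4,
              dimnames = list(c("core", "uniqA", "uniqB", "messy"),
                              c("a1", "a2", "b1", "b2")))
  grp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  ug <- unique_genes(p, grp)
  expect_equal(ug$per_group$A, "uniqA")
  expect_equal(ug$per_group$B, "uniqB")
  # 'core' present everywhere, 'messy' has an uncertain call: neither counts

  # brute-force enumeration over all genes agrees
  brute <- lapply(c(A = "A", B = "B"), function(g) {
    rownames(p)[vapply(seq_len(nrow(p)), function(i) {
      x <- p[i, ]
      !anyNA(x) && all(x[grp == g] == 1) && all(x[grp != g] == 0)
    }, logical(1))]
  })
  expect_equal(ug$per_group[order(names(ug$per_group))],
               brute[order(names(brute))])

  # disjoint across groups, invariant to sample order
  expect_length(intersect(ug$per_group$A, ug$per_group$B), 0)
  perm <- c("b2", "a1", "b1", "a2")
  ug2 <- unique_genes(p[, perm], grp[perm])
  expect_equal(lapply(ug2$per_group, sort)[names(ug$per_group)],
               lapply(ug$per_group, sort))

  expect_error(unique_genes(p, c(a1 = "A", a2 = "A", b1 = "A", b2 = "A")),
               ">= 2 groups")
})

test_that("error-free simulation: presence equals truth and planted genes are unique", {
  cs <- clean_sim_fixture()
  sim <- cs$sim
  gd <- gene_depths(cs$aln, sim$pangenome)
  pm <- call_presence(gd)
  md <- sample_metadata(sim)

  # truth per sample: union of its strains' gene content (same within deme)
  truth_pm <- vapply(md$sample_id, function(s) {
    d <- md$deme[md$sample_id == s]
    strains <- sim$truth$strain_meta$strain_id[sim$truth$strain_meta$deme == d]
    as.integer(colSums(sim$truth$strain_gene_content[strains, , drop = FALSE]) > 0)
  }, integer(nrow(sim$pangenome$genes)))
  rownames(truth_pm) <- sim$pangenome$genes$gene_id
  expect_equal(unclass(pm)[, md$sample_id], truth_pm[, md$sample_id],
               ignore_attr = TRUE)

  ug <- unique_genes(pm, setNames(as.character(md$deme), md$sample_id))
  planted <- split(sim$pangenome$genes$gene_id[!is.na(sim$pangenome$genes$deme)],
                   as.character(sim$pangenome$genes$deme[!is.na(sim$pangenome$genes$deme)]))
  expect_equal(lapply(ug$per_group[names(planted)], sort),
               lapply(planted, sort))

  # Jaccard PCoA axis 1 separates the demes
  jp <- pcoa(jaccard_matrix(pm))
  ax1 <- split(jp$coordinates[, 1],
               md$deme[match(rownames(jp$coordinates), md$sample_id)])
  expect_true(max(ax1[[1]]) < min(ax1[[2]]) || max(ax1[[2]]) < min(ax1[[1]]))
})
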