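test_that("sequence p-distance handles heterozygotes as allele draws", {
  aln <- locus_alignment("toy", c(a = "ACGT", b = "ACGT", c = "ACGA"))
  D <- seq_distance(aln)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.25)
  # AR vs AA: the R site contributes 0.5 over 2 sites
  aln2 <- locus_alignment("toy2", c(x = "AR", y = "AA", z = "AG"))
  D2 <- seq_distance(aln2)
  expect_equal(D2["x", "y"], 0.25)
  expect_equal(D2["x", "z"], 0.25)
  expect_equal(D2["y", "z"], 0.5)
  # missing sites are excluded pairwise
  aln3 <- locus_alignment("toy3", c(x = "ANT", y = "AGT", z = "AGA"))
  expect_equal(seq_distance(aln3)["x", "y"], 0)
  expect_error(seq_distance(locus_alignment("bad", c(x = "NN", y = "NN", z = "AA"))),
               "zero comparable")
})

test_that("SNP allele-sharing distance matches direct evaluation", {
  calls <- rbind(a = c(0L, 2L, 1L, 1L), b = c(2L, 0L, 1L, 1L),
                 c = c(0L, 0L, 0L, 0L), d = c(1L, 1L, 1L, 1L))
  meta <- data.frame(snp_id = paste0("s", 1:4),
                     discovery_panel = "vinifera", genome = "nuclear")
  colnames(calls) <- meta$snp_id
  gm <- genotype_matrix(calls, meta)
  D <- snp_distance(gm)
  expect_equal(D["a", "a"], 0)
  expect_equal(D["a", "b"], (1 + 1 + 0 + 0) / 4)
  expect_equal(D["c", "d"], 0.5)  # all-het vs all-homref
})

test_that("distances satisfy the triangle inequality on fuzzed inputs", {
  set.seed(41)
  for (r in 1:8) {
    h <- random_hap_matrix(5L, 30L)
    rownames(h) <- paste0("s", 1:5)
    D <- seq_distance(locus_alignment("fz", h))
    for (i in 1:5) for (j in 1:5) for (k in 1:5)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("NJ recovers an additive 4-taxon tree exactly", {
  tr <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):0);")
  D <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(D)
  expect_no_topo_diff(nj, tr)
  # recovered path lengths equal the input matrix
  expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
               tolerance = 1e-10)
})

test_that("negative NJ branch estimates are clamped to zero", {
  D <- matrix(c(0, 1.401, 1.923, 4.550,
                1.401, 0, 2.907, 1.088,
                1.923, 2.907, 0, 4.502,
                4.550, 1.088, 4.502, 0), 4L, 4L,
              dimnames = list(letters[1:4], letters[1:4]))
  expect_message(tr <- nj_tree(D), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are deterministic and taxon-order invariant", {
  sim <- small_sim()
  concat <- concatenate_alignments(sim$alignments, "union_fill_N")
  tr1 <- suppressMessages(nj_bootstrap(concat, B = 30L, seed = 5))
  tr2 <- suppressMessages(nj_bootstrap(concat, B = 30L, seed = 5))
  expect_identical(tr1$node.label, tr2$node.label)
  perm <- sample(seq_along(concat$ids))
  concat_p <- locus_alignment(concat$locus, concat$seq[perm, , drop = FALSE])
  tr3 <- suppressMessages(nj_bootstrap(concat_p, B = 30L, seed = 5))
  for (cl in c("EA", "EU", "NA1", "NA2", "CAL")) {
    tips <- sim$accessions$accession_id[sim$accessions$clade_label == cl &
                                          !sim$accessions$known_hybrid]
    tips <- setdiff(intersect(tips, tr1$tip.label), sim$truth$hybrids$name)
    expect_equal(clade_support(tr1, tips), clade_support(tr3, tips))
  }
})

test_that("panel subsampling keeps other classes and is seed-stable", {
  sim <- small_sim()
  gm <- sim$genotypes
  n_vin <- sum(gm$snp_meta$discovery_panel == "vinifera" &
                 gm$snp_meta$genome == "nuclear")
  nuc <- subset_snps(gm, gm$snp_ids[gm$snp_meta$genome == "nuclear"])
  n_vin_nuc <- sum(nuc$snp_meta$discovery_panel == "vinifera")
  full <- subsample_by_panel(nuc, "vinifera", n_vin_nuc, seed = 1)
  expect_identical(full$snp_ids, nuc$snp_ids)  # target = available: identity
  expect_error(subsample_by_panel(nuc, "vinifera", n_vin_nuc + 1L), "exceeds")
  counts <- vapply(1:10, function(s) {
    sub <- subsample_by_panel(nuc, "vinifera", 50L, seed = s)
    c(vin = sum(sub$snp_meta$discovery_panel == "vinifera"),
      oth = sum(sub$snp_meta$discovery_panel != "vinifera"))
  }, numeric(2L))
  expect_true(all(counts["vin", ] == 50L))
  expect_true(all(counts["oth", ] == sum(nuc$snp_meta$discovery_panel != "vinifera")))
  # membership varies across seeds
  s1 <- subsample_by_panel(nuc, "vinifera", 50L, seed = 1)
  s2 <- subsample_by_panel(nuc, "vinifera", 50L, seed = 2)
  expect_false(identical(s1$snp_ids, s2$snp_ids))
})

test_that("clade branch summary is 1 on an ultrametric tree", {
  txt <- "((a1:1,a2:1)EA:2,(b1:1,b2:1)EU:2,(o1:2.5,o2:2.5)OUT:0.5);"
  tr <- ape::read.tree(text = txt)
  acc <- accession_table(c("a1", "a2", "b1", "b2", "o1", "o2"),
                         paste0("sp", 1:6),
                         c("EA", "EA", "EU", "EU", "OUT", "OUT"))
  summ <- clade_branch_summary(tr, acc)
  expect_equal(summ$ratio[summ$clade %in% c("EA", "EU")], c(1, 1),
               tolerance = 1e-10)
  expect_error(clade_branch_summary(tr, accession_table("a1", "s", "EA")),
               "no outgroup")
})
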