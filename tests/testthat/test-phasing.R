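test_that("SNP extraction expands IUPAC codes and drops invariant columns", {
  aln <- locus_alignment("toy", c(a = "AAG", b = "ARG", c = "AGG"))
  snp <- extract_snp_genotypes(aln)
  expect_equal(ncol(snp$geno), 1L)       # column 1 invariant, column 3 invariant
  expect_equal(snp$positions, 1L)        # 0-based offset of column 2
  expect_equal(unname(snp$geno[, 1L]), c(0L, 1L, 2L))  # A<G, counts of G
  expect_true(all(snp$biallelic))
  # N and '-' become missing
  aln2 <- locus_alignment("toy2", c(a = "AT", b = "NT", c = "TT"))
  expect_true(is.na(extract_snp_genotypes(aln2)$geno["b", 1L]))
})

test_that("forced phases get confidence 1", {
  # all homozygous
  g <- rbind(a = c(0L, 2L, 0L), b = c(2L, 0L, 0L))
  hs <- phase_em(g, n_restarts = 2L)
  expect_identical(hs$h1, hs$h2)
  expect_equal(unname(hs$confidence), c(1, 1))
  # exactly one heterozygous site: unique unordered pair
  g2 <- rbind(a = c(1L, 0L), b = c(0L, 0L))
  hs2 <- phase_em(g2, n_restarts = 2L)
  expect_equal(sort(unname(c(hs2$h1["a", 1L], hs2$h2["a", 1L]))), c(0L, 1L))
  expect_equal(unname(hs2$confidence["a"]), 1)
})

test_that("EM resolves a double heterozygote by population linkage", {
  # 8 unambiguous individuals support haplotypes 00 and 11; the double het
  # should be phased cis (00 | 11) with high posterior
  g <- rbind(matrix(0L, 4L, 2L), matrix(2L, 4L, 2L), c(1L, 1L))
  rownames(g) <- paste0("i", 1:9)
  hs <- phase_em(g)
  expect_equal(unname(hs$h1["i9", ]), c(0L, 0L))
  expect_equal(unname(hs$h2["i9", ]), c(1L, 1L))
  expect_gt(hs$confidence["i9"], 0.9)
})

test_that("phasing is consistent with genotypes and preserves missingness", {
  sim <- small_sim()
  aln <- sim$alignments[[1]]
  snp <- extract_snp_genotypes(aln)
  keep <- which(snp$biallelic)
  g <- snp$geno[, keep, drop = FALSE]
  g[2L, 3L] <- NA_integer_  # inject a missing call
  hs <- phase_em(g, seed = 1)
  recon <- hs$h1 + hs$h2
  expect_identical(is.na(recon), is.na(g))
  expect_true(all(recon == g, na.rm = TRUE))
  het <- !is.na(g) & g == 1L
  expect_true(all((hs$h1 != hs$h2)[het]))
})

test_that("phasing is deterministic given the seed", {
  sim <- small_sim()
  snp <- extract_snp_genotypes(sim$alignments[[2]])
  keep <- which(snp$biallelic)
  g <- snp$geno[, keep, drop = FALSE]
  expect_identical(phase_em(g, seed = 3), phase_em(g, seed = 3))
})

test_that("switch-error rate is low on coalescent loci with known truth", {
  # under the coalescent haplotypes are shared between individuals, so
  # population frequencies make the phase statistically identifiable
  set.seed(17)
  n_adj <- 0L; n_switch <- 0L
  for (l in 1:10) {
    h <- coalescent_haplotypes(160, 10) == "T"
    storage.mode(h) <- "integer"
    t1 <- h[seq(1L, 159L, by = 2L), , drop = FALSE]
    t2 <- h[seq(2L, 160L, by = 2L), , drop = FALSE]
    g <- t1 + t2
    rownames(g) <- paste0("i", seq_len(nrow(g)))
    hs <- phase_em(g, seed = l)
    # population singletons are statistically unphaseable and excluded, as
    # in the usual switch-error definition
    ac <- colSums(h)
    informative <- ac > 1L & ac < nrow(h) - 1L
    for (i in seq_len(nrow(g))) {
      het <- which(g[i, ] == 1L & informative)
      if (length(het) < 2L) next
      m <- hs$h1[i, het] == t1[i, het]
      sw <- sum(m[-1L] != m[-length(m)])
      n_adj <- n_adj + length(het) - 1L
      n_switch <- n_switch + sw
    }
  }
  expect_gt(n_adj, 100L)
  expect_lt(n_switch / n_adj, 0.05)
})

test_that("inter-haplotype differences count het sites", {
  h1 <- rbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 0L, 0L))
  h2 <- rbind(c(0L, 1L, 0L, 1L), c(0L, 0L, 0L, 0L))
  hs <- toy_hapset("t", c("x", "hom"), h1, h2)
  d <- interhap_differences(hs)
  expect_equal(unname(d), c(2L, 0L))
})

test_that("over-ambiguous individuals fall back to greedy phasing, flagged", {
  S <- 24L
  g <- rbind(matrix(0L, 5L, S), matrix(2L, 5L, S), rep(1L, S))
  rownames(g) <- paste0("i", 1:11)
  hs <- phase_em(g, max_het_sites = 8L)
  expect_equal(unname(hs$confidence["i11"]), 0)
  # greedy phase against the pool still reconstructs the two pool haplotypes
  expect_true(all(hs$h1["i11", ] == 0L) || all(hs$h1["i11", ] == 1L))
  recon <- hs$h1["i11", ] + hs$h2["i11", ]
  expect_true(all(recon == 1L))
})

test_that("phased haplotypes export to FASTA with /1 /2 suffixes", {
  hs <- toy_hapset("t", c("x", "y"),
                   rbind(c(0L, 1L), c(0L, 0L)), rbind(c(1L, 1L), c(0L, 0L)))
  p <- withr::local_tempfile(fileext = ".fasta")
  write_phased_fasta(hs, p)
  lines <- readLines(p)
  expect_equal(lines[c(1, 3, 5, 7)], c(">x/1", ">x/2", ">y/1", ">y/2"))
})
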