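test_that("site classification follows the variable/PI/singleton definitions", {
  # col1 {A,A,A,T}: variable singleton; col2 {A,A,T,T}: parsimony-informative;
  # col3 monomorphic; col4 het codes only (ignored); col5 missing
  aln <- locus_alignment("toy", c(
    s1 = "AAARN", s2 = "AAAR-", s3 = "ATAGN", s4 = "TTAGN"))
  cl <- classify_sites(aln)
  expect_equal(cl$n_variable, 2L)
  expect_equal(cl$n_parsimony_informative, 1L)
  expect_equal(cl$n_singleton, 1L)
  expect_equal(cl$n_sites_scanned, 5L)
  mono <- locus_alignment("m", c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  expect_equal(classify_sites(mono)$n_variable, 0L)
})

test_that("variable = PI + singletons on fuzzed alignments", {
  set.seed(11)
  for (r in 1:25) {
    h <- random_hap_matrix(sample(4:9, 1L), sample(5:25, 1L))
    rownames(h) <- paste0("s", seq_len(nrow(h)))
    aln <- locus_alignment("fz", h)
    cl <- classify_sites(aln)
    expect_equal(cl$n_variable, cl$n_parsimony_informative + cl$n_singleton)
    expect_lte(cl$n_variable, cl$n_sites_scanned)
  }
})

test_that("hand-evaluated examples: theta_w, He, pi", {
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_equal(watterson_theta(3, 4, 100), 3 / (1 + 1/2 + 1/3) / 100,
               tolerance = 1e-12)
  expect_error(watterson_theta(3, 1, 100), "n >= 2")
  expect_equal(haplotype_diversity(c(4)), 0)
  expect_equal(haplotype_diversity(c(2, 1, 1)), (4/3) * (1 - 0.375),
               tolerance = 1e-12)
  h2 <- rbind(strsplit("AA", "")[[1]], strsplit("AT", "")[[1]],
              strsplit("TT", "")[[1]])
  expect_equal(nucleotide_diversity(h2), mean(c(0.5, 1, 0.5)),
               tolerance = 1e-12)
  # two haplotypes differing at 2 of 100 sites
  expect_equal(nucleotide_diversity(rbind(c("A", "A"), c("T", "T")),
                                    total_length = 100), 0.02)
})

test_that("segregating sites and haplotype tally", {
  h <- rbind(c("A", "A", "A"), c("A", "A", "T"), c("A", "T", "T"))
  expect_equal(segregating_sites(h), 2L)
  expect_equal(length(haplotype_tally(h)), 3L)
  h4 <- matrix("A", 4L, 3L)
  expect_equal(segregating_sites(h4), 0L)
  expect_equal(unname(haplotype_tally(h4)), 4L)
  # missing-tolerant identity: NA sites are excluded per comparison
  hm <- rbind(c("A", "T", "G"), c("A", NA, "G"))
  expect_equal(length(haplotype_tally(hm)), 1L)
})

test_that("Fay & Wu's H matches a hand enumeration and its trivial cases", {
  # two orientable sites, derived counts 3 and 1 among n = 4:
  # theta_pi = 0.5 + 0.5 = 1; theta_H = 1.5 + 1/6; H = 1 - 5/3
  h <- rbind(c("T", "G"), c("T", "C"), c("T", "C"), c("A", "C"))
  og <- rbind(c("A", "C"), c("A", "C"))
  expect_equal(fay_wu_h(h, og), 1 - 5/3, tolerance = 1e-12)
  # no polymorphism -> 0 over orientable sites
  hmono <- matrix("A", 4L, 2L)
  expect_equal(fay_wu_h(hmono, og[, 1:2]), 0)
  # tied outgroup consensus -> site skipped; all sites tied -> undefined
  og_tie <- rbind(c("A", "C"), c("T", "G"))
  expect_true(is.na(fay_wu_h(h, og_tie)))
})

test_that("statistics match the brute-force oracle and ignore row order", {
  set.seed(21)
  for (r in 1:20) {
    h <- random_hap_matrix(sample(4:8, 1L), sample(6:15, 1L))
    expect_equal(watterson_theta(segregating_sites(h), nrow(h), ncol(h)),
                 oracle_theta_w(h), tolerance = 1e-12)
    expect_equal(nucleotide_diversity(h), oracle_pi(h), tolerance = 1e-12)
    expect_equal(haplotype_diversity(haplotype_tally(h)), oracle_he(h),
                 tolerance = 1e-12)
    expect_equal(tajimas_d(h), oracle_tajima_d(h), tolerance = 1e-12)
    perm <- sample(nrow(h))
    expect_equal(tajimas_d(h[perm, , drop = FALSE]), tajimas_d(h),
                 tolerance = 1e-12)
    expect_equal(nucleotide_diversity(h[perm, , drop = FALSE]),
                 nucleotide_diversity(h), tolerance = 1e-12)
  }
})

test_that("Tajima's D centres near zero under the neutral coalescent", {
  set.seed(5)
  d <- replicate(500, {
    h <- coalescent_haplotypes(20, 10)
    if (oracle_S(h) == 0L) NA_real_ else tajimas_d(h)
  })
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.15)
})

test_that("theta_w and pi agree in expectation under the neutral coalescent", {
  set.seed(6)
  reps <- t(replicate(200, {
    h <- coalescent_haplotypes(15, 4)
    c(tw = watterson_theta(segregating_sites(h), nrow(h), ncol(h)) * ncol(h),
      pi = nucleotide_diversity(h) * ncol(h))
  }))
  dif <- reps[, "tw"] - reps[, "pi"]
  se <- stats::sd(dif) / sqrt(nrow(reps))
  expect_lt(abs(mean(dif)), 2 * se + 1e-9)
})

test_that("diversity table has one row per locus and sane invariants", {
  sim <- small_sim()
  hs <- vitnet:::phase_all_loci(sim$alignments, pipeline_config())
  tab <- diversity_table(hs, sim$accessions)
  expect_equal(nrow(tab), length(sim$alignments))
  expect_true(all(tab$theta_w >= 0 & tab$pi >= 0))
  expect_true(all(tab$he >= 0 & tab$he <= 1))
  expect_true(all(tab$n_sequences == 2L * length(hs[[1]]$ids)))
  summ <- attr(tab, "summary")
  expect_equal(summ$mean[summ$statistic == "theta_w"], mean(tab$theta_w))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_diversity_table(tab, p)
  expect_equal(nrow(utils::read.delim(p)), nrow(tab))
})
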