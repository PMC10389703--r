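test_that("dbar averages per-locus inter-haplotype differences", {
  mk <- function(d) {  # one accession with d het sites over 6 columns
    h1 <- matrix(0L, 1L, 6L); h2 <- h1
    if (d > 0) h2[1, seq_len(d)] <- 1L
    toy_hapset("x", "acc", h1, h2)
  }
  sets <- list(mk(2L), mk(4L), mk(6L))
  sets <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]; s$locus <- paste0("l", i); s
  })
  expect_equal(unname(dbar_statistic(sets)), 4)
  expect_equal(unname(dbar_statistic(list(mk(0L)))), 0)
})

test_that("Tukey outlier rule matches hand quartiles and shift invariance", {
  v <- c(a = 1, b = 1, c = 2, d = 2, e = 9)
  fl <- flag_outliers(v, rep("g", 5L))
  expect_identical(unname(fl), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(flag_outliers(rep(3, 6), rep("g", 6L))))
  fl_shift <- flag_outliers(v + 100, rep("g", 5L))
  expect_identical(fl, fl_shift)
  # groups below 4 members use the pooled fence
  expect_message(
    fl2 <- flag_outliers(c(v, f = 1.5), c(rep("g", 5L), "tiny")),
    "pooled")
  expect_false(fl2[["f"]])
})

test_that("a non-hybrid gets a homozygous clade pair", {
  sim <- small_sim()
  hs <- vitnet:::phase_all_loci(sim$alignments, pipeline_config())
  pure <- sim$accessions$accession_id[!grepl("^HYB", sim$accessions$accession_id)][1]
  cl <- sim$accessions$clade_label[sim$accessions$accession_id == pure]
  ap <- assign_parents(pure, hs, sim$accessions,
                       exclude = sim$truth$hybrids$name)
  expect_equal(ap$parental_clades, c(cl, cl))
})

test_that("array heterozygosity is the het fraction of non-missing calls", {
  calls <- rbind(a = c(0L, 1L, 1L, 2L), b = c(0L, 0L, 2L, 2L),
                 c = c(NA, 1L, 0L, NA))
  meta <- data.frame(snp_id = paste0("s", 1:4),
                     discovery_panel = "vinifera", genome = "nuclear")
  colnames(calls) <- meta$snp_id
  gm <- genotype_matrix(calls, meta)
  het <- array_heterozygosity(gm)
  expect_equal(unname(het), c(0.5, 0, 0.5))
})

test_that("chlorotype definition groups identical strings, hets -> missing", {
  calls <- rbind(a = c(0L, 0L, 0L), b = c(0L, 0L, 0L),
                 c = c(0L, 2L, 2L), d = c(2L, 2L, 2L))
  meta <- data.frame(snp_id = paste0("cp", 1:3),
                     discovery_panel = "vinifera", genome = "chloroplast")
  colnames(calls) <- meta$snp_id
  gm <- genotype_matrix(calls, meta)
  ch <- define_chlorotypes(gm)
  expect_equal(length(unique(ch$chlorotype_id)), 3L)
  expect_equal(ch$chlorotype_id[1], ch$chlorotype_id[2])
  # a heterozygous call is treated as missing in the string
  calls2 <- calls; calls2["c", 1L] <- 1L
  gm2 <- genotype_matrix(calls2, meta)
  ch2 <- define_chlorotypes(gm2)
  expect_equal(substr(ch2$snp_string[3], 1, 1), "?")
  # monomorphic loci are not informative
  calls3 <- calls; calls3[, 3L] <- 0L
  expect_equal(nchar(define_chlorotypes(genotype_matrix(calls3, meta))$snp_string[1]), 2L)
})

test_that("single-linkage collapse chains at t=1 and is a no-op at t=0", {
  strings <- c("000", "001", "011", "111")
  asn <- data.frame(accession_id = letters[1:4],
                    chlorotype_id = paste0("C", 1:4),
                    snp_string = strings, stringsAsFactors = FALSE)
  class(asn) <- c("chlorotype_assignment", class(asn))
  col1 <- collapse_chlorotypes(asn, t = 1L)
  expect_equal(length(unique(col1$collapsed_group_id)), 1L)
  expect_equal(unique(col1$collapsed_group_id), "000")  # smallest member
  col0 <- collapse_chlorotypes(asn, t = 0L)
  expect_equal(length(unique(col0$collapsed_group_id)), 4L)
  expect_identical(col0$collapsed_group_id, col0$snp_string)
})

test_that("maternal inference follows the chlorotype sharing contract", {
  acc <- accession_table(
    c("hyb", "eu1", "na1", "ea1"), paste0("sp", 1:4),
    c("UNKNOWN", "EU", "NA1", "EA"), known_hybrid = c(TRUE, FALSE, FALSE, FALSE))
  mk_asn <- function(strings) {
    asn <- data.frame(accession_id = c("hyb", "eu1", "na1", "ea1"),
                      chlorotype_id = paste0("C", seq_along(strings)),
                      snp_string = strings, stringsAsFactors = FALSE)
    class(asn) <- c("chlorotype_assignment", class(asn))
    collapse_chlorotypes(asn, t = 0L)
  }
  # hybrid shares with NA1 only -> NA1 maternal
  m1 <- infer_maternal("hyb", c("EU", "NA1"), mk_asn(c("111", "000", "111", "010")),
                       acc)
  expect_equal(m1$maternal_clade, "NA1")
  # both parental clades share the group -> UNKNOWN
  m2 <- infer_maternal("hyb", c("EU", "NA1"), mk_asn(c("111", "111", "111", "010")),
                       acc)
  expect_equal(m2$maternal_clade, "UNKNOWN")
  # neither shares -> UNKNOWN with nearest clade and distance reported
  m3 <- infer_maternal("hyb", c("EU", "NA1"), mk_asn(c("110", "000", "011", "111")),
                       acc)
  expect_equal(m3$maternal_clade, "UNKNOWN")
  # distances: to 000 = 2, to 011 = 2, to 111 = 1 -> EA is nearest at 1
  expect_equal(m3$nearest_distance, 1)
  expect_equal(m3$nearest_clade, "EA")
})

test_that("the full hybrid report flags the planted hybrids with parentage", {
  sim <- small_sim()
  hs <- vitnet:::phase_all_loci(sim$alignments, pipeline_config())
  rep <- suppressMessages(hybrid_report(hs, sim$accessions, gm = sim$genotypes))
  hybs <- sim$truth$hybrids
  for (k in seq_len(nrow(hybs))) {
    row <- rep[rep$accession_id == hybs$name[k], ]
    expect_true(row$outlier)
    expect_setequal(c(row$parent1, row$parent2), c(hybs$p1[k], hybs$p2[k]))
    expect_equal(row$maternal_clade, hybs$maternal[k])
  }
  # chlorotype collapse at t=0 after definition is a no-op partition-wise
  ch <- define_chlorotypes(sim$genotypes)
  c0 <- collapse_chlorotypes(ch, t = 0L)
  ok <- !is.na(c0$chlorotype_id)
  expect_equal(tapply(c0$collapsed_group_id[ok], c0$chlorotype_id[ok],
                      function(x) length(unique(x))) |> unname() |> max(), 1L)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_hybrid_report(rep, p1, p2)
  expect_equal(nrow(utils::read.delim(p1)), nrow(rep))
  expect_true(jsonlite::validate(paste(readLines(p2), collapse = "")))
})
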