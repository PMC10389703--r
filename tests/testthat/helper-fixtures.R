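# Shared fixtures, built once per test run.

# a small, fast simulated dataset for structural tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, species_per_clade = 2L,
                        accessions_per_species = 2L, n_loci = 4L,
                        locus_length = 450L, n_array_snps = 300L,
                        n_leaf_traits = 10L, n_oiv_traits = 6L)
      cache <<- simulate_vitis(cfg)
    }
    cache
  }
})

# a default-condition simulated dataset (the study conditions)
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_vitis(sim_config(seed = 7))
    cache
  }
})

# tiny hand-built haplotype_set
toy_hapset <- function(locus, ids, h1, h2, locus_length = ncol(h1)) {
  rownames(h1) <- ids; rownames(h2) <- ids
  structure(list(locus = locus, ids = ids, h1 = h1, h2 = h2,
                 alleles = matrix(c("A", "T"), 2L, ncol(h1)),
                 snp_positions = seq_len(ncol(h1)) - 1L,
                 locus_length = locus_length,
                 confidence = stats::setNames(rep(1, length(ids)), ids)),
            class = "haplotype_set")
}

expect_no_topo_diff <- function(t1, t2) {
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))), 0)
}
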