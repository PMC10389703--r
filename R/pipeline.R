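# End-to-end orchestration: diversity -> phasing -> hybrid detection ->
# haplotype networks -> chlorotypes/maternal inference -> hybrid-free trees
# -> ascertainment experiment -> morphometrics & phylogenetic signal.

#' Pipeline configuration
#'
#' @param stages named logical toggles; any of `diversity`, `networks`,
#'   `trees`, `ascertainment`, `morpho` may be disabled (phasing and hybrid
#'   detection always run, downstream stages depend on them).
#' @param B bootstrap replicates for trees (default 100).
#' @param n_perm permutations for the Abouheif test (default 999).
#' @param epsilon median-joining network relaxation (default 0).
#' @param collapse_t chlorotype collapse threshold (default 1).
#' @param subsample_fractions fractions of the vinifera-panel SNPs retained
#'   in the ascertainment experiment, relative to the full panel (defaults
#'   mirror the 12,971 / 7,197 / 3,197 / 2,697-SNP series: 10,774 -> 5,000 ->
#'   1,000 -> 500 vinifera SNPs).
#' @param max_het_sites,n_restarts phasing controls (see [phase_em]).
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c(diversity = TRUE, networks = FALSE,
                                       trees = TRUE, ascertainment = TRUE,
                                       morpho = TRUE),
                            B = 100L, n_perm = 999L, epsilon = 0,
                            collapse_t = 1L,
                            subsample_fractions = c(1, 5000 / 10774,
                                                    1000 / 10774, 500 / 10774),
                            max_het_sites = 16L, n_restarts = 10L,
                            seed = 1L) {
  defaults <- c(diversity = TRUE, networks = FALSE, trees = TRUE,
                ascertainment = TRUE, morpho = TRUE)
  defaults[names(stages)] <- stages
  structure(list(stages = defaults, B = B, n_perm = n_perm, epsilon = epsilon,
                 collapse_t = collapse_t,
                 subsample_fractions = subsample_fractions,
                 max_het_sites = max_het_sites, n_restarts = n_restarts,
                 seed = seed),
            class = "pipeline_config")
}

#' Load a dataset from a manifest of file paths
#'
#' The manifest maps roles to paths rather than assuming file names:
#' `loci` (character vector of FASTA paths), `genotypes`, `snp_meta`,
#' `accessions`, and optionally `leaf_traits`, `oiv_traits`, `tree`.
#'
#' @param manifest named list of paths.
#' @return list with the same data slots as a `vitis_sim`.
#' @export
load_manifest <- function(manifest) {
  stopifnot(all(c("loci", "accessions") %in% names(manifest)))
  accessions <- read_accessions(manifest$accessions)
  out <- list(
    alignments = lapply(manifest$loci, read_fasta_alignment),
    accessions = accessions,
    genotypes = if (!is.null(manifest$genotypes))
      read_genotypes(manifest$genotypes, manifest$snp_meta) else NULL,
    leaf_traits = if (!is.null(manifest$leaf_traits))
      read_traits(manifest$leaf_traits, accessions = accessions) else NULL,
    oiv_traits = if (!is.null(manifest$oiv_traits))
      read_traits(manifest$oiv_traits, accessions = accessions) else NULL,
    tree = if (!is.null(manifest$tree)) read_newick(manifest$tree) else NULL
  )
  out
}

# Phase every locus, keeping only biallelic SNP columns.
phase_all_loci <- function(alignments, config) {
  lapply(alignments, function(aln) {
    snp <- extract_snp_genotypes(aln)
    if (!all(snp$biallelic)) {
      keep <- which(snp$biallelic)
      snp <- list(geno = snp$geno[, keep, drop = FALSE],
                  alleles = snp$alleles[, keep, drop = FALSE],
                  positions = snp$positions[keep],
                  biallelic = rep(TRUE, length(keep)), ids = snp$ids)
    }
    phase_em(snp, locus = aln$locus, locus_length = aln$length_bp,
             max_het_sites = config$max_het_sites, seed = config$seed,
             n_restarts = config$n_restarts)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on a simulated or loaded dataset
#' and returns a report bundle. Hybrid-free tree stages automatically exclude
#' the known hybrids plus the newly flagged outliers whose parental pair was
#' resolved. Deterministic given the data and `config$seed`.
#'
#' @param data a `vitis_sim` or the result of [load_manifest].
#' @param config a [pipeline_config].
#' @return list of class `pipeline_bundle` with elements per stage
#'   (`site_classes`, `diversity`, `hap_sets`, `hybrids`, `networks`,
#'   `tree_seq`, `tree_snp`, `clade_supports`, `ascertainment`, `morpho`),
#'   plus `params` (seeds and settings) and `status`.
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  st <- config$stages
  bundle <- list(params = list(config = unclass(config),
                               r_version = as.character(getRversion())),
                 status = "complete")
  concat <- concatenate_alignments(data$alignments, id_policy = "union_fill_N")
  bundle$site_classes <- classify_sites(concat)

  hap_sets <- phase_all_loci(data$alignments, config)
  bundle$hap_sets <- hap_sets

  if (st[["diversity"]])
    bundle$diversity <- diversity_table(hap_sets, data$accessions)

  bundle$hybrids <- hybrid_report(hap_sets, data$accessions,
                                  gm = data$genotypes,
                                  collapse_t = config$collapse_t)
  excluded <- hybrid_exclusion_list(bundle$hybrids, data$accessions)
  bundle$excluded_hybrids <- excluded

  if (st[["networks"]]) {
    bundle$networks <- lapply(hap_sets, function(hs) {
      h <- hap_char_matrix(hs)
      ok_cols <- colSums(is.na(h)) == 0L
      h <- h[, ok_cols, drop = FALSE]
      if (ncol(h) == 0L || nrow(unique(h)) < 2L) return(NULL)
      cl <- data$accessions$clade_label[
        match(sub("/[12]$", "", rownames(h)), data$accessions$accession_id)]
      build_mj_network(h, clades = cl, epsilon = config$epsilon)
    })
  }

  if (st[["trees"]]) {
    keep <- setdiff(concat$ids, excluded)
    sub <- locus_alignment(concat$locus, concat$seq[keep, , drop = FALSE])
    bundle$tree_seq <- nj_bootstrap(sub, B = config$B, seed = config$seed,
                                    unit = "alignment_site")
    clades <- setdiff(unique(data$accessions$clade_label), c("OUT", "UNKNOWN"))
    bundle$clade_supports <- vapply(clades, function(cl) {
      tips <- intersect(
        data$accessions$accession_id[data$accessions$clade_label == cl],
        bundle$tree_seq$tip.label)
      if (length(tips) < 2L) return(NA_real_)
      clade_support(bundle$tree_seq, tips)
    }, numeric(1L))
    if (!is.null(data$genotypes)) {
      gm <- data$genotypes
      keepg <- setdiff(gm$ids, excluded)
      gm_sub <- genotype_matrix(gm$calls[keepg, , drop = FALSE], gm$snp_meta)
      bundle$tree_snp <- nj_bootstrap(gm_sub, B = config$B,
                                      seed = config$seed, unit = "snp")
    }
  }

  if (st[["ascertainment"]] && !is.null(data$genotypes)) {
    bundle$ascertainment <- ascertainment_experiment(
      data$genotypes, data$accessions, exclude = excluded,
      fractions = config$subsample_fractions, seed = config$seed)
  }

  if (st[["morpho"]] && !is.null(data$leaf_traits) &&
      !is.null(bundle$tree_seq)) {
    bundle$morpho <- morpho_stage(data, bundle$tree_seq, excluded, config)
  }
  bundle$params$excluded_hybrids <- excluded
  class(bundle) <- "pipeline_bundle"
  bundle
}

#' Hybrid exclusion list for pure-species reruns
#'
#' Known hybrids plus newly flagged inter-haplotype outliers confirmed as
#' interspecific, i.e. whose parental clade pair resolved to two distinct
#' clades. Outliers with the non-hybrid (clade, clade) signature stay in.
#'
#' @param report a `hybrid_report`.
#' @param accessions an [accession_table].
#' @export
hybrid_exclusion_list <- function(report, accessions) {
  known <- accessions$accession_id[accessions$known_hybrid]
  confirmed <- report$accession_id[report$confirmed_hybrid]
  sort(union(known, confirmed))
}

#' SNP ascertainment-bias subsampling experiment
#'
#' Builds NJ trees from the full array and from reduced sets with the
#' vinifera-panel SNPs thinned to the given fractions, and summarises the
#' per-clade root-to-tip branch lengths of each tree.
#'
#' @param gm a [genotype_matrix].
#' @param accessions an [accession_table].
#' @param exclude accessions (hybrids) dropped before tree building.
#' @param fractions fractions of the vinifera-panel SNPs retained.
#' @param seed RNG seed.
#' @return data frame with one row per (set, clade): `set`, `n_snps`,
#'   `n_vinifera`, `clade`, `mean_depth`, `ratio`.
#' @export
ascertainment_experiment <- function(gm, accessions,
                                     exclude = character(0L),
                                     fractions = c(1, 5000 / 10774,
                                                   1000 / 10774, 500 / 10774),
                                     seed = 1L) {
  keep <- setdiff(gm$ids, exclude)
  gm <- genotype_matrix(gm$calls[keep, , drop = FALSE], gm$snp_meta)
  n_vin <- sum(gm$snp_meta$discovery_panel == "vinifera" &
                 gm$snp_meta$genome == "nuclear")
  nuclear <- subset_snps(gm, gm$snp_ids[gm$snp_meta$genome == "nuclear"])
  out <- NULL
  for (i in seq_along(fractions)) {
    target <- round(fractions[i] * n_vin)
    sub <- subsample_by_panel(nuclear, "vinifera", target, seed = seed + i)
    tr <- nj_tree(snp_distance(sub))
    summ <- clade_branch_summary(tr, accessions)
    summ$set <- i
    summ$n_snps <- length(sub$snp_ids)
    summ$n_vinifera <- target
    out <- rbind(out, summ)
  }
  out[, c("set", "n_snps", "n_vinifera", "clade", "n_tips", "mean_depth",
          "ratio")]
}

# PCA + phylogenetic signal on the non-hybrid accessions with complete data.
morpho_stage <- function(data, tree, excluded, config) {
  keep <- Reduce(intersect, list(
    setdiff(data$accessions$accession_id[data$accessions$clade_label != "OUT"],
            excluded),
    data$leaf_traits$ids, tree$tip.label))
  res <- list(n_accessions = length(keep))
  prox <- abouheif_proximity(tree, tips = keep)
  subset_tt <- function(tt, keep) trait_table(
    tt$values[keep, , drop = FALSE], tt$trait_type)
  leaf <- subset_tt(data$leaf_traits, keep)
  res$leaf_pca <- trait_pca(leaf, scale = TRUE)
  res$leaf_signal <- phylo_signal_table(leaf, prox, n_perm = config$n_perm,
                                        seed = config$seed)
  res$leaf_ppca <- ppca(leaf, prox)
  res$leaf_selected <- select_top_loadings(res$leaf_ppca$loadings)
  if (!is.null(data$oiv_traits)) {
    oiv <- subset_tt(data$oiv_traits, keep)
    res$oiv_pca <- trait_pca(oiv, scale = TRUE)
    res$oiv_signal <- phylo_signal_table(oiv, prox, n_perm = config$n_perm,
                                         seed = config$seed + 1000L)
    res$oiv_ppca <- ppca(oiv, prox)
    res$oiv_selected <- select_top_loadings(res$oiv_ppca$loadings)
  }
  res
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("<pipeline_bundle> status:", x$status, "\n")
  cat("  sites: ", x$site_classes$n_variable, " variable / ",
      x$site_classes$n_sites_scanned, " scanned\n", sep = "")
  if (!is.null(x$hybrids))
    cat("  hybrids flagged:", sum(x$hybrids$outlier), "of",
        nrow(x$hybrids), "accessions\n")
  if (!is.null(x$clade_supports))
    cat("  clade supports:",
        paste(names(x$clade_supports), round(x$clade_supports), sep = "=",
              collapse = " "), "\n")
  invisible(x)
}
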