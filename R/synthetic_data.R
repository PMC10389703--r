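# Synthetic data generator: emits datasets with the statistical structure the
# analysis assumes — a star radiation of 5 ingroup clades plus an outgroup,
# hierarchical sequence divergence (clade / species / haplotype), diploid
# consensus sequences with IUPAC heterozygote codes, F1 hybrids between
# clades carrying the maternal clade's chloroplast haplotype, an SNP array
# with discovery-panel ascertainment, and clade-structured Brownian traits —
# together with the full ground truth for every downstream stage.

#' Simulation configuration
#'
#' Defaults describe the scaled-down study conditions used throughout the
#' package: 5 ingroup clades (EA, EU, NA1, NA2, CAL) plus an outgroup, 3
#' species per clade with 2 accessions each, 12 loci of 600 bp, pairwise
#' between-clade divergence 0.02 substitutions/site with within-species
#' diversity 0.004, three F1 hybrids between clades with stated maternal
#' clades, a 1,200-SNP array ascertained 83/14.5/2.5% in the
#' vinifera/american/muscadinia panels with 2% missing calls, and 23
#' chloroplast SNPs carrying clade-diagnostic chlorotypes.
#'
#' @param seed RNG seed (mandatory).
#' @param species_per_clade,accessions_per_species,n_outgroup_accessions
#'   sample structure.
#' @param n_loci,locus_length sequence data dimensions.
#' @param between_clade_divergence expected pairwise divergence between
#'   ingroup clades (substitutions/site).
#' @param species_divergence expected pairwise divergence between species of
#'   the same clade.
#' @param within_theta expected pairwise diversity within a species.
#' @param outgroup_divergence expected pairwise divergence outgroup vs
#'   ingroup.
#' @param hybrids data frame with columns `name`, `p1`, `p2`, `maternal`,
#'   `known`; parents must be distinct clades.
#' @param n_array_snps nuclear array size.
#' @param panel_fractions named fractions for the discovery panels.
#' @param missing_rate missing-call rate for nuclear array SNPs.
#' @param n_chloro_snps chloroplast SNPs on the array.
#' @param n_leaf_traits,n_oiv_traits trait counts.
#' @param clade_sd,bm_sigma,noise_sd trait model: clade mean-shift SD,
#'   Brownian rate on the unit-depth tree, residual SD.
#' @param leaves_per_accession raw leaves emitted per accession.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       species_per_clade = 3L,
                       accessions_per_species = 2L,
                       n_outgroup_accessions = 3L,
                       n_loci = 12L,
                       locus_length = 600L,
                       between_clade_divergence = 0.02,
                       species_divergence = 0.008,
                       within_theta = 0.004,
                       outgroup_divergence = 0.04,
                       hybrids = data.frame(
                         name = c("HYB1", "HYB2", "HYB3"),
                         p1 = c("EU", "EA", "NA2"),
                         p2 = c("NA1", "EU", "CAL"),
                         maternal = c("NA1", "EA", "NA2"),
                         known = c(TRUE, FALSE, FALSE),
                         stringsAsFactors = FALSE),
                       n_array_snps = 1200L,
                       panel_fractions = c(vinifera = 0.83, american = 0.145,
                                           muscadinia = 0.025),
                       missing_rate = 0.02,
                       n_chloro_snps = 23L,
                       n_leaf_traits = 12L,
                       n_oiv_traits = 10L,
                       clade_sd = 1.5,
                       bm_sigma = 1,
                       noise_sd = 0.5,
                       leaves_per_accession = 8L) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  rates <- c(cfg$between_clade_divergence, cfg$species_divergence,
             cfg$within_theta, cfg$outgroup_divergence)
  if (any(rates < 0)) stop("divergence rates must be >= 0")
  if (cfg$species_divergence > cfg$between_clade_divergence ||
      cfg$within_theta > cfg$species_divergence)
    stop("divergences must nest: within_theta <= species <= between-clade")
  clades <- c("EA", "EU", "NA1", "NA2", "CAL")
  if (nrow(cfg$hybrids)) {
    if (any(cfg$hybrids$p1 == cfg$hybrids$p2))
      stop("hybrid parents must be distinct clades")
    if (!all(c(cfg$hybrids$p1, cfg$hybrids$p2) %in% clades))
      stop("hybrid parents must be ingroup clades")
    if (!all(cfg$hybrids$maternal == cfg$hybrids$p1 |
             cfg$hybrids$maternal == cfg$hybrids$p2))
      stop("maternal clade must be one of the two parents")
  }
  cfg$clades <- clades
  structure(cfg, class = "sim_config")
}

# point mutations at Poisson(rate * L) random sites, to a different base
mutate_seq <- function(seq, rate) {
  L <- length(seq)
  k <- stats::rpois(1L, rate * L)
  if (k == 0L) return(seq)
  sites <- sample.int(L, min(k, L))
  for (s in sites) seq[s] <- sample(setdiff(DNA_BASES, seq[s]), 1L)
  seq
}

consensus_from_pair <- function(h1, h2) {
  out <- h1
  het <- h1 != h2
  if (any(het)) {
    pair <- paste0(pmin(h1[het], h2[het]), pmax(h1[het], h2[het]))
    out[het] <- IUPAC_FROM_PAIR[pair]
  }
  out
}

#' Simulate a complete dataset
#'
#' Produces, in memory, all the inputs the pipeline consumes (per-locus
#' consensus alignments, SNP-array genotypes with metadata, accession table,
#' trait tables, raw per-leaf measurements, species tree) plus the ground
#' truth (true haplotypes, hybrid parentages and maternal clades, clade
#' chlorotypes, trait parameters). Deterministic given `config$seed`.
#'
#' @param config a [sim_config].
#' @return list of class `vitis_sim`.
#' @export
simulate_vitis <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_vitis_impl(config))
}

simulate_vitis_impl <- function(cfg) {
  clades <- cfg$clades
  # lineage rates per site (divergences are pairwise = 2 x lineage depth)
  r_hap <- cfg$within_theta / 2
  r_sp <- (cfg$species_divergence - cfg$within_theta) / 2
  r_cl <- (cfg$between_clade_divergence - cfg$species_divergence) / 2
  r_out <- (cfg$outgroup_divergence - cfg$species_divergence) / 2

  species <- c(
    unlist(lapply(clades, function(cl) paste0(cl, "_sp", seq_len(cfg$species_per_clade)))),
    "OUT_sp1")
  clade_of_species <- c(rep(clades, each = cfg$species_per_clade), "OUT")
  names(clade_of_species) <- species

  acc_species <- c(
    unlist(lapply(species[clade_of_species != "OUT"], function(sp)
      rep(sp, cfg$accessions_per_species))),
    rep("OUT_sp1", cfg$n_outgroup_accessions))
  acc_ids <- unlist(lapply(split(seq_along(acc_species), acc_species)[unique(acc_species)],
                           function(ix) paste0(acc_species[ix[1L]], "_a", seq_along(ix))))
  acc_ids <- unname(acc_ids)
  acc_species <- acc_species[order(match(acc_species, unique(acc_species)))]
  acc_clade <- clade_of_species[acc_species]

  hyb <- cfg$hybrids
  if (nrow(hyb)) {
    hyb$donor1 <- vapply(hyb$p1, function(cl)
      sample(species[clade_of_species == cl], 1L), character(1L))
    hyb$donor2 <- vapply(hyb$p2, function(cl)
      sample(species[clade_of_species == cl], 1L), character(1L))
  }
  all_ids <- c(acc_ids, hyb$name)

  accessions <- accession_table(
    accession_id = all_ids,
    species_label = c(acc_species, if (nrow(hyb)) paste0("hyb_", hyb$name)),
    clade_label = c(unname(acc_clade), hyb$maternal),
    known_hybrid = c(rep(FALSE, length(acc_ids)), hyb$known)
  )

  # ---- per-locus sequences -------------------------------------------------
  alignments <- vector("list", cfg$n_loci)
  hap_truth <- vector("list", cfg$n_loci)
  L <- cfg$locus_length
  for (l in seq_len(cfg$n_loci)) {
    root <- sample(DNA_BASES, L, replace = TRUE)
    clade_anc <- lapply(stats::setNames(clades, clades),
                        function(cl) mutate_seq(root, r_cl))
    clade_anc$OUT <- mutate_seq(root, r_out)
    sp_anc <- lapply(stats::setNames(species, species), function(sp)
      mutate_seq(clade_anc[[clade_of_species[sp]]], r_sp))
    draw_hap <- function(sp) mutate_seq(sp_anc[[sp]], r_hap)
    h1 <- matrix(NA_character_, length(all_ids), L, dimnames = list(all_ids, NULL))
    h2 <- h1
    for (i in seq_along(acc_ids)) {
      h1[acc_ids[i], ] <- draw_hap(acc_species[i])
      h2[acc_ids[i], ] <- draw_hap(acc_species[i])
    }
    if (nrow(hyb)) for (k in seq_len(nrow(hyb))) {
      h1[hyb$name[k], ] <- draw_hap(hyb$donor1[k])
      h2[hyb$name[k], ] <- draw_hap(hyb$donor2[k])
    }
    cons <- t(vapply(all_ids, function(a) consensus_from_pair(h1[a, ], h2[a, ]),
                     character(L)))
    alignments[[l]] <- locus_alignment(sprintf("locus%02d", l), cons)
    hap_truth[[l]] <- list(h1 = h1, h2 = h2)
  }

  # ---- SNP array -----------------------------------------------------------
  # gamete origins: species for both gametes of a pure accession; the two
  # donor species for a hybrid
  gam1 <- stats::setNames(c(acc_species, hyb$donor1), all_ids)
  gam2 <- stats::setNames(c(acc_species, hyb$donor2), all_ids)
  n <- length(all_ids)
  nv <- round(cfg$panel_fractions[["vinifera"]] * cfg$n_array_snps)
  na_ <- round(cfg$panel_fractions[["american"]] * cfg$n_array_snps)
  nm <- cfg$n_array_snps - nv - na_
  panel <- rep(c("vinifera", "american", "muscadinia"), c(nv, na_, nm))
  calls <- matrix(0L, n, cfg$n_array_snps, dimnames = list(all_ids, NULL))
  american_clades <- c("NA1", "NA2", "CAL")
  for (j in seq_len(cfg$n_array_snps)) {
    if (panel[j] == "vinifera") {
      if (stats::runif(1L) < 0.5) {  # species-level polymorphism within EU
        sp <- sample(species[clade_of_species == "EU"], 1L)
        calls[, j] <- (gam1 == sp) + (gam2 == sp)
      } else {                       # accession-level (recent) heterozygosity
        a <- sample(acc_ids[acc_clade == "EU"], 1L)
        calls[a, j] <- 1L
      }
    } else if (panel[j] == "american") {
      u <- stats::runif(1L)
      if (u < 0.3) {                 # clade-level split among American clades
        cl <- sample(american_clades, 1L)
        carrier_sp <- species[clade_of_species == cl]
        calls[, j] <- (gam1 %in% carrier_sp) + (gam2 %in% carrier_sp)
      } else if (u < 0.65) {
        sp <- sample(species[clade_of_species %in% american_clades], 1L)
        calls[, j] <- (gam1 == sp) + (gam2 == sp)
      } else {
        a <- sample(acc_ids[acc_clade %in% american_clades], 1L)
        calls[a, j] <- 1L
      }
    } else {
      if (stats::runif(1L) < 0.5) {  # split between the subgenera
        carrier_sp <- species[clade_of_species != "OUT"]
        calls[, j] <- (gam1 %in% carrier_sp) + (gam2 %in% carrier_sp)
      } else {
        a <- sample(acc_ids[acc_clade == "OUT"], 1L)
        calls[a, j] <- 1L
      }
    }
  }
  storage.mode(calls) <- "integer"
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(calls)) < cfg$missing_rate, n)
    calls[mask] <- NA_integer_
  }

  # chloroplast: clade-diagnostic haplotypes (two dedicated sites per clade,
  # pairwise distance 4 between clades) plus a one-step variant carried by
  # the last accession of each ingroup clade; hybrids inherit the maternal
  # clade's chlorotype. Calls are haploid-homozygous (0/2), no missing.
  cp_clades <- c(clades, "OUT")
  cp_bits <- matrix(0L, length(cp_clades), cfg$n_chloro_snps,
                    dimnames = list(cp_clades, NULL))
  for (k in seq_along(cp_clades)) cp_bits[k, c(2L * k - 1L, 2L * k)] <- 1L
  cp_acc <- matrix(0L, n, cfg$n_chloro_snps, dimnames = list(all_ids, NULL))
  for (i in seq_along(acc_ids)) cp_acc[acc_ids[i], ] <- cp_bits[acc_clade[i], ]
  if (nrow(hyb)) for (k in seq_len(nrow(hyb)))
    cp_acc[hyb$name[k], ] <- cp_bits[hyb$maternal[k], ]
  variant_site_base <- 2L * length(cp_clades)
  for (k in seq_along(clades)) {
    members <- acc_ids[acc_clade == clades[k]]
    site <- variant_site_base + k
    if (length(members) && site <= cfg$n_chloro_snps)
      cp_acc[members[length(members)], site] <- 1L
  }
  cp_calls <- 2L * cp_acc

  full_calls <- cbind(calls, cp_calls)
  snp_ids <- c(sprintf("snp%05d", seq_len(cfg$n_array_snps)),
               sprintf("cp%02d", seq_len(cfg$n_chloro_snps)))
  colnames(full_calls) <- snp_ids
  meta <- data.frame(
    snp_id = snp_ids,
    discovery_panel = c(panel, rep("vinifera", cfg$n_chloro_snps)),
    genome = c(rep("nuclear", cfg$n_array_snps),
               rep("chloroplast", cfg$n_chloro_snps)),
    stringsAsFactors = FALSE)
  genotypes <- genotype_matrix(full_calls, meta)

  # ---- species tree (non-hybrid accessions), unit-depth for traits --------
  sp_strs <- vapply(species, function(sp) {
    tips <- acc_ids[acc_species == sp]
    paste0("(", paste0(tips, ":", r_hap, collapse = ","), ")", sp, ":", r_sp)
  }, character(1L))
  cl_strs <- vapply(c(clades, "OUT"), function(cl) {
    sps <- species[clade_of_species == cl]
    stem <- if (cl == "OUT") r_out else r_cl
    paste0("(", paste(sp_strs[sps], collapse = ","), ")", cl, ":", stem)
  }, character(1L))
  tree <- ape::read.tree(text = paste0("(", paste(cl_strs, collapse = ","), ");"))
  tree <- ape::collapse.singles(tree)

  # ---- traits --------------------------------------------------------------
  unit_tree <- tree
  unit_tree$edge.length <- unit_tree$edge.length /
    max(ape::node.depth.edgelength(unit_tree))
  clade_names <- c(clades, "OUT")
  sim_trait_block <- function(n_traits, prefix) {
    effects <- matrix(stats::rnorm(length(clade_names) * n_traits,
                                   sd = cfg$clade_sd),
                      length(clade_names), n_traits,
                      dimnames = list(clade_names, NULL))
    vals <- matrix(NA_real_, length(all_ids), n_traits,
                   dimnames = list(all_ids,
                                   paste0(prefix, seq_len(n_traits))))
    for (t in seq_len(n_traits)) {
      bm <- ape::rTraitCont(unit_tree, model = "BM", sigma = cfg$bm_sigma)
      base <- bm[acc_ids] + effects[unname(acc_clade), t] +
        stats::rnorm(length(acc_ids), sd = cfg$noise_sd)
      vals[acc_ids, t] <- base
      if (nrow(hyb)) {
        vals[hyb$name, t] <- (effects[hyb$p1, t] + effects[hyb$p2, t]) / 2 +
          stats::rnorm(nrow(hyb), sd = cfg$noise_sd)
      }
    }
    list(vals = vals, effects = effects)
  }
  leaf_block <- sim_trait_block(cfg$n_leaf_traits, "LM")
  leaf_types <- rep(c("length", "angle", "ratio"),
                    length.out = cfg$n_leaf_traits)
  leaf_traits <- trait_table(leaf_block$vals, leaf_types)
  oiv_block <- sim_trait_block(cfg$n_oiv_traits, "OIV")
  oiv_vals <- round(5 + oiv_block$vals)
  oiv_vals[oiv_vals < 1] <- 1
  oiv_vals[oiv_vals > 9] <- 9
  oiv_types <- rep(c("morphology", "color", "pilosity"),
                   length.out = cfg$n_oiv_traits)
  oiv_traits <- trait_table(oiv_vals, oiv_types)

  # raw per-leaf measurements for trait preparation: a vein length, a
  # left/right angle pair, and area/perimeter for circularity
  raw <- do.call(rbind, lapply(all_ids, function(a) {
    nl <- cfg$leaves_per_accession
    vein <- stats::rlnorm(1L, meanlog = 2, sdlog = 0.3)
    ang <- stats::rnorm(1L, 45, 5)
    area <- stats::rlnorm(1L, meanlog = 4, sdlog = 0.3)
    shape <- stats::runif(1L, 1.1, 1.8)  # perimeter^2 / (4 pi area)
    data.frame(
      accession_id = a, leaf = seq_len(nl),
      veinN2 = vein * exp(stats::rnorm(nl, sd = 0.1)),
      angleN1N2_L = ang + stats::rnorm(nl, sd = 2),
      angleN1N2_R = ang + stats::rnorm(nl, sd = 2),
      area = area * exp(stats::rnorm(nl, sd = 0.1)),
      perimeter = sqrt(4 * pi * area * shape) * exp(stats::rnorm(nl, sd = 0.05)),
      stringsAsFactors = FALSE)
  }))

  truth <- list(
    hybrids = hyb,
    clade_of = stats::setNames(c(unname(acc_clade), hyb$maternal), all_ids),
    species_of = stats::setNames(c(acc_species, rep(NA_character_, nrow(hyb))),
                                 all_ids),
    hap_truth = hap_truth,
    clade_chlorotypes = cp_bits,
    trait_effects = list(leaf = leaf_block$effects, oiv = oiv_block$effects),
    rates = c(clade = r_cl, species = r_sp, haplotype = r_hap, outgroup = r_out)
  )
  structure(list(config = cfg, alignments = alignments, genotypes = genotypes,
                 accessions = accessions, leaf_traits = leaf_traits,
                 oiv_traits = oiv_traits, raw_leaves = raw, tree = tree,
                 truth = truth),
            class = "vitis_sim")
}

#' @export
print.vitis_sim <- function(x, ...) {
  cat("<vitis_sim> ", length(x$accessions$accession_id), " accessions (",
      sum(grepl("^HYB", x$accessions$accession_id)), " hybrids), ",
      length(x$alignments), " loci, ",
      length(x$genotypes$snp_ids), " SNPs\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to files
#'
#' Emits the same formats the loaders consume: one FASTA per locus,
#' genotype + SNP metadata TSVs, accession TSV, trait TSVs, raw-leaf TSV,
#' the species tree in newick, and the ground truth as JSON.
#'
#' @param sim a `vitis_sim`.
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (a in sim$alignments)
    write_fasta_alignment(a, file.path(dir, paste0(a$locus, ".fasta")))
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"),
                  file.path(dir, "snp_meta.tsv"))
  write_accessions(sim$accessions, file.path(dir, "accessions.tsv"))
  write_traits(sim$leaf_traits, file.path(dir, "leaf_traits.tsv"))
  write_traits(sim$oiv_traits, file.path(dir, "oiv_traits.tsv"))
  utils::write.table(sim$raw_leaves, file.path(dir, "raw_leaves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  truth <- sim$truth
  truth$hap_truth <- NULL  # bulky; regenerate from the seed when needed
  truth$clade_chlorotypes <- apply(sim$truth$clade_chlorotypes, 1L, paste,
                                   collapse = "")
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(dir)
}
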