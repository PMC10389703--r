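# Distance matrices and neighbour-joining trees with bootstrap support, plus
# the SNP ascertainment-bias subsampling experiment and per-clade
# branch-length summaries.

# Base-dosage encoding of a diploid consensus alignment: for each of A/C/G/T
# a matrix of expected allele dosage in {0, 0.5, 1}; unambiguous base -> 1,
# heterozygote code -> 0.5/0.5, missing -> 0 everywhere.
base_dosage <- function(seqm) {
  al <- iupac_alleles(c(seqm))            # 2 x (n*L)
  lapply(DNA_BASES, function(b) {
    m <- matrix(((al[1L, ] == b) + (al[2L, ] == b)) / 2, nrow = nrow(seqm))
    m[is.na(m)] <- 0
    m
  })
}

#' Pairwise p-distance between diploid consensus sequences
#'
#' Per comparable site (both accessions non-missing) the contribution is the
#' probability that alleles drawn one from each accession differ: identical
#' homozygotes contribute 0, different homozygotes 1, a heterozygote against a
#' homozygote sharing one allele 0.5. The distance is the mean over comparable
#' sites.
#'
#' @param aln a [locus_alignment] (typically the concatenation of all loci).
#' @param cols optional column indices (1-based) for bootstrap resampling.
#' @return symmetric distance matrix with accession dimnames.
#' @export
seq_distance <- function(aln, cols = NULL) {
  m <- aln$seq
  if (nrow(m) < 2L) stop("need >= 2 accessions")
  enc <- list(Fb = base_dosage(m),
              present = matrix(as.numeric(m %in% c(DNA_BASES, names(IUPAC_HET))),
                               nrow = nrow(m)),
              ids = aln$ids)
  seq_distance_enc(enc, cols)
}

# distance from a precomputed dosage encoding (bootstrap hot path)
seq_distance_enc <- function(enc, cols = NULL) {
  Fb <- enc$Fb; present <- enc$present
  if (!is.null(cols)) {
    Fb <- lapply(Fb, function(f) f[, cols, drop = FALSE])
    present <- present[, cols, drop = FALSE]
  }
  match_prob <- Reduce(`+`, lapply(Fb, function(f) tcrossprod(f)))
  comp <- tcrossprod(present)
  if (any(comp[upper.tri(comp)] == 0))
    stop("accession pair with zero comparable sites")
  D <- (comp - match_prob) / comp
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(enc$ids, enc$ids)
  D
}

#' Allele-sharing distance from SNP genotypes
#'
#' `1 - IBS`: per SNP `|g_i - g_j| / 2`, averaged over the SNPs non-missing in
#' both accessions.
#'
#' @param gm a [genotype_matrix].
#' @param cols optional SNP indices for bootstrap resampling.
#' @return symmetric distance matrix.
#' @export
snp_distance <- function(gm, cols = NULL) {
  snp_distance_enc(encode_genotypes(gm), cols)
}

# per-dosage-level indicator encoding (bootstrap hot path)
encode_genotypes <- function(gm) {
  gh <- gm$calls / 2
  lev <- c(0, 0.5, 1)
  list(Ind = lapply(lev, function(v) ((gh == v) & !is.na(gh)) * 1),
       pres = (!is.na(gh)) * 1, lev = lev, ids = gm$ids)
}

snp_distance_enc <- function(enc, cols = NULL) {
  Ind <- enc$Ind; pres <- enc$pres
  if (!is.null(cols)) {
    Ind <- lapply(Ind, function(m) m[, cols, drop = FALSE])
    pres <- pres[, cols, drop = FALSE]
  }
  comp <- tcrossprod(pres)
  if (any(comp[upper.tri(comp)] == 0))
    stop("accession pair sharing zero genotyped SNPs")
  lev <- enc$lev
  S <- matrix(0, nrow(pres), nrow(pres))
  for (a in seq_along(lev)) for (b in seq_along(lev)) {
    dab <- abs(lev[a] - lev[b])
    if (dab > 0) S <- S + dab * tcrossprod(Ind[[a]], Ind[[b]])
  }
  D <- S / comp
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(enc$ids, enc$ids)
  D
}

#' Neighbour-joining tree
#'
#' Saitou-Nei NJ via ape; negative branch-length estimates are clamped to
#' zero (with a message).
#'
#' @param D symmetric distance matrix.
#' @return an `ape::phylo`.
#' @export
nj_tree <- function(D) {
  tr <- ape::nj(stats::as.dist(D))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative NJ branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Neighbour-joining tree with bootstrap support
#'
#' Resamples columns (alignment sites or SNPs) with replacement, rebuilds the
#' NJ tree per replicate, and reports for each internal edge of the full-data
#' tree the percentage of replicates containing the same bipartition, stored
#' as internal node labels (0-100). Deterministic given `seed`; resampling
#' draws only column indices so the result is invariant to taxon order.
#'
#' @param data a [locus_alignment] (`unit = "alignment_site"`) or
#'   [genotype_matrix] (`unit = "snp"`).
#' @param B bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @param unit resampling unit.
#' @return `phylo` with `node.label` percentages; trees with < 4 tips are
#'   returned without supports.
#' @export
nj_bootstrap <- function(data, B = 100L, seed = 1L,
                         unit = c("alignment_site", "snp")) {
  unit <- match.arg(unit)
  dist_fun <- if (unit == "alignment_site") {
    if (!inherits(data, "locus_alignment")) stop("alignment_site unit needs a locus_alignment")
    m <- data$seq
    enc <- list(Fb = base_dosage(m),
                present = matrix(as.numeric(m %in% c(DNA_BASES, names(IUPAC_HET))),
                                 nrow = nrow(m)),
                ids = data$ids)
    function(cols) seq_distance_enc(enc, cols)
  } else {
    if (!inherits(data, "genotype_matrix")) stop("snp unit needs a genotype_matrix")
    enc <- encode_genotypes(data)
    function(cols) snp_distance_enc(enc, cols)
  }
  ncols <- if (unit == "alignment_site") data$length_bp else length(data$snp_ids)
  main <- nj_tree(dist_fun(NULL))
  if (length(main$tip.label) < 4L) return(main)
  boots <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(ncols, ncols, replace = TRUE)
      suppressMessages(nj_tree(dist_fun(cols)))
    })
  })
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- round(100 * counts / B, 1)
  main
}

#' Bootstrap support of a clade
#'
#' Support (in percent) attached to the smallest edge of `tree` that
#' separates exactly `tips` from the rest; `NA` when the clade is not
#' monophyletic in the tree.
#'
#' @param tree a `phylo` with `node.label` supports from [nj_bootstrap].
#' @param tips tip labels of the putative clade.
#' @export
clade_support <- function(tree, tips) {
  if (!ape::is.monophyletic(tree, tips)) return(NA_real_)
  node <- ape::getMRCA(tree, tips)
  if (is.null(node)) return(NA_real_)
  lab <- tree$node.label[node - length(tree$tip.label)]
  suppressWarnings(as.numeric(lab))
}

#' Subsample SNPs of one discovery-panel class
#'
#' Keeps all SNPs of the other classes and a uniform random subset of the
#' named class, preserving SNP order. Models the reduced-ascertainment sets
#' used to study discovery-panel bias.
#'
#' @param gm a [genotype_matrix].
#' @param panel_class class to thin (`vinifera`, `american`, `muscadinia`).
#' @param target_count SNPs of that class to retain.
#' @param seed RNG seed.
#' @export
subsample_by_panel <- function(gm, panel_class, target_count, seed = 1L) {
  in_class <- which(gm$snp_meta$discovery_panel == panel_class)
  if (target_count > length(in_class))
    stop("target_count (", target_count, ") exceeds available ",
         panel_class, " SNPs (", length(in_class), ")")
  keep_class <- with_seed(seed, sort(sample(in_class, target_count)))
  keep <- sort(c(setdiff(seq_along(gm$snp_ids), in_class), keep_class))
  subset_snps(gm, gm$snp_ids[keep])
}

#' Per-clade root-to-tip branch-length summary
#'
#' Roots the tree on the outgroup (clade `OUT`; several outgroup accessions
#' root on their common edge), measures each tip's root-to-tip path length,
#' and summarises per clade the mean and its ratio to the overall ingroup
#' mean. Under ascertainment bias, the discovery-panel clade shows a ratio
#' above 1.
#'
#' @param tree a `phylo` containing the outgroup tips.
#' @param accessions an [accession_table].
#' @return data frame with `clade`, `n_tips`, `mean_depth`, `ratio`.
#' @export
clade_branch_summary <- function(tree, accessions) {
  out_ids <- intersect(accessions$accession_id[accessions$clade_label == "OUT"],
                       tree$tip.label)
  if (!length(out_ids)) stop("no outgroup (clade OUT) tips in tree")
  rooted <- tryCatch(ape::root(tree, outgroup = out_ids, resolve.root = TRUE),
                     error = function(e) ape::root(tree, outgroup = out_ids[1L],
                                                   resolve.root = TRUE))
  depth <- ape::node.depth.edgelength(rooted)[seq_along(rooted$tip.label)]
  names(depth) <- rooted$tip.label
  cl <- accessions$clade_label[match(rooted$tip.label, accessions$accession_id)]
  ingroup <- !is.na(cl) & cl != "OUT"
  overall <- mean(depth[ingroup])
  clades <- sort(unique(cl[ingroup]))
  data.frame(
    clade = clades,
    n_tips = vapply(clades, function(x) sum(cl == x, na.rm = TRUE), integer(1L)),
    mean_depth = vapply(clades, function(x) mean(depth[!is.na(cl) & cl == x]), numeric(1L)),
    ratio = vapply(clades, function(x) mean(depth[!is.na(cl) & cl == x]) / overall, numeric(1L)),
    row.names = NULL
  )
}
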