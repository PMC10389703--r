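# Per-locus diversity statistics on phased haplotypes: segregating sites,
# Watterson's theta, nucleotide diversity, haplotype diversity, Tajima's D and
# Fay & Wu's H, plus site classification on the diploid consensus alignment.
#
# Missing data policy is pairwise deletion throughout: every pairwise
# comparison uses the sites where both haplotypes carry an unambiguous base.

#' Classify alignment columns
#'
#' Scans the diploid consensus alignment column by column. Two-fold IUPAC
#' heterozygote codes, `N` and `-` are treated as missing, so polymorphism
#' carried only by heterozygotes is not counted here (it is recovered after
#' phasing). A column is variable when at least two distinct unambiguous bases
#' are present, parsimony-informative when at least two bases each occur in at
#' least two sequences, and a singleton site otherwise.
#'
#' @param aln a [locus_alignment].
#' @return list with `n_variable`, `n_parsimony_informative`, `n_singleton`,
#'   `n_sites_scanned`.
#' @export
classify_sites <- function(aln) {
  if (aln$length_bp == 0L) stop("zero-length alignment")
  m <- aln$seq
  variable <- 0L; pi_sites <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    tab <- table(col[col %in% DNA_BASES])
    if (length(tab) >= 2L) {
      variable <- variable + 1L
      if (sum(tab >= 2L) >= 2L) pi_sites <- pi_sites + 1L
    }
  }
  list(n_variable = variable,
       n_parsimony_informative = pi_sites,
       n_singleton = variable - pi_sites,
       n_sites_scanned = ncol(m))
}

#' Count segregating sites among haplotypes
#'
#' @param h character matrix, haplotypes x sites; `NA` marks missing states.
#' @return integer count of columns with >= 2 observed states.
#' @export
segregating_sites <- function(h) {
  sum(apply(h, 2L, function(col) length(unique(col[!is.na(col)])) >= 2L))
}

#' Tally distinct haplotypes
#'
#' Haplotypes are grouped by exact match after excluding, per comparison, the
#' sites missing in either haplotype. Grouping is greedy in input order, so it
#' is deterministic.
#'
#' @param h character matrix, haplotypes x sites.
#' @return integer vector of group sizes (named by representative row index).
#' @export
haplotype_tally <- function(h) {
  reps <- integer(0L)   # row indices of group representatives
  counts <- integer(0L)
  for (i in seq_len(nrow(h))) {
    hit <- 0L
    for (g in seq_along(reps)) {
      a <- h[reps[g], ]; b <- h[i, ]
      ok <- !is.na(a) & !is.na(b)
      if (all(a[ok] == b[ok])) { hit <- g; break }
    }
    if (hit) counts[hit] <- counts[hit] + 1L
    else { reps <- c(reps, i); counts <- c(counts, 1L) }
  }
  names(counts) <- as.character(reps)
  counts
}

#' Watterson's theta per site
#'
#' `theta_W = S / (a1 * L)` with `a1` the harmonic number of `n - 1`.
#'
#' @param S segregating sites.
#' @param n number of sequences (phased haplotypes).
#' @param L sites scanned.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2L) stop("watterson_theta needs n >= 2")
  if (L < 1L) stop("watterson_theta needs L >= 1")
  S / (sum(1 / seq_len(n - 1L)) * L)
}

# Pairwise mismatch counts and comparable-site counts over all unordered
# haplotype pairs. Columns outside the matrix (invariant, assumed present)
# can be credited to the comparable length via extra_sites.
pairwise_diffs <- function(h, extra_sites = 0L) {
  n <- nrow(h)
  pairs <- utils::combn(n, 2L)
  diffs <- numeric(ncol(pairs)); comp <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- h[pairs[1L, k], ]; b <- h[pairs[2L, k], ]
    ok <- !is.na(a) & !is.na(b)
    diffs[k] <- sum(a[ok] != b[ok])
    comp[k] <- sum(ok) + extra_sites
  }
  list(diffs = diffs, comparable = comp)
}

#' Nucleotide diversity (pi) per site
#'
#' Mean over all unordered haplotype pairs of the per-site difference rate;
#' each pair is compared over the sites where both haplotypes are unambiguous.
#' Pairs with zero comparable sites are skipped with a warning.
#'
#' @param h character matrix of variable sites, haplotypes x sites, `NA`
#'   missing.
#' @param total_length full locus length; columns not in `h` are assumed
#'   invariant and present. Defaults to `ncol(h)`.
#' @export
nucleotide_diversity <- function(h, total_length = ncol(h)) {
  if (nrow(h) < 2L) stop("nucleotide_diversity needs >= 2 haplotypes")
  pd <- pairwise_diffs(h, extra_sites = total_length - ncol(h))
  usable <- pd$comparable > 0
  if (!all(usable)) warning(sum(!usable), " pair(s) with no comparable sites skipped")
  mean(pd$diffs[usable] / pd$comparable[usable])
}

#' Haplotype diversity (expected heterozygosity of haplotypes)
#'
#' `He = n/(n-1) * (1 - sum(p_k^2))`.
#'
#' @param counts haplotype multiplicities.
#' @export
haplotype_diversity <- function(counts) {
  n <- sum(counts)
  if (n < 2L) stop("haplotype_diversity needs n >= 2")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

# Tajima (1989) constants for sample size n.
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Standard normalized difference between the mean pairwise difference count
#' and `S/a1`. The mean pairwise count uses pairwise deletion, consistent with
#' [nucleotide_diversity]. Undefined (returns `NA`) when `S = 0`.
#'
#' @param h character matrix of variable sites, haplotypes x sites.
#' @export
tajimas_d <- function(h) {
  n <- nrow(h)
  if (n < 4L) stop("tajimas_d needs n >= 4")
  S <- segregating_sites(h)
  if (S == 0L) return(NA_real_)
  pd <- pairwise_diffs(h)
  Pi <- mean(pd$diffs)
  k <- tajima_constants(n)
  (Pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Fay & Wu's H
#'
#' Unnormalized `theta_pi - theta_H` over sites that can be oriented with the
#' outgroup. The ancestral state at a site is the majority base across the
#' outgroup haplotypes; ties, fully missing outgroup, sites not biallelic in
#' the ingroup, and sites whose outgroup state is absent from the ingroup are
#' not orientable and are excluded. Returns `NA` when no site is orientable,
#' `0` when orientable sites exist but none segregate.
#'
#' @param h ingroup haplotypes, character matrix (haplotypes x sites).
#' @param outgroup_h outgroup haplotypes over the same sites.
#' @export
fay_wu_h <- function(h, outgroup_h) {
  stopifnot(ncol(h) == ncol(outgroup_h))
  theta_pi <- 0; theta_h <- 0; orientable <- 0L
  for (j in seq_len(ncol(h))) {
    og <- outgroup_h[, j]; og <- og[!is.na(og)]
    if (!length(og)) next
    tab <- sort(table(og), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) next  # tied consensus
    anc <- names(tab)[1L]
    x <- h[, j]; x <- x[!is.na(x)]
    states <- unique(x)
    if (length(states) > 2L || length(x) < 2L) next
    if (!(anc %in% states) && length(states) == 2L) next
    orientable <- orientable + 1L
    if (length(states) < 2L) next
    n <- length(x)
    i <- sum(x != anc)
    theta_pi <- theta_pi + 2 * i * (n - i) / (n * (n - 1))
    theta_h <- theta_h + 2 * i^2 / (n * (n - 1))
  }
  if (orientable == 0L) return(NA_real_)
  theta_pi - theta_h
}

#' Per-locus diversity table
#'
#' One row per locus with sample size, length, segregating sites, haplotype
#' count, Watterson's theta, nucleotide diversity, haplotype diversity,
#' Tajima's D and Fay & Wu's H (oriented on the outgroup accessions). A
#' `summary` attribute holds means and ranges across loci.
#'
#' @param hap_sets list of [haplotype_set] objects, one per locus.
#' @param accessions an [accession_table]; clade `OUT` marks the outgroup.
#' @return data frame with one row per locus and attribute `summary`.
#' @export
diversity_table <- function(hap_sets, accessions) {
  out_ids <- accessions$accession_id[accessions$clade_label == "OUT"]
  rows <- lapply(hap_sets, function(hs) {
    h <- hap_char_matrix(hs)
    acc_of <- rep(hs$ids, each = 2L)
    is_out <- acc_of %in% out_ids
    n <- nrow(h)
    S <- segregating_sites(h)
    counts <- haplotype_tally(h)
    fw <- if (any(is_out) && any(!is_out))
      fay_wu_h(h[!is_out, , drop = FALSE], h[is_out, , drop = FALSE])
    else NA_real_
    data.frame(
      locus = hs$locus,
      n_sequences = n,
      size_bp = hs$locus_length,
      n_snps = S,
      n_haplotypes = length(counts),
      theta_w = watterson_theta(S, n, hs$locus_length),
      pi = if (S > 0L) nucleotide_diversity(h, hs$locus_length) else 0,
      he = haplotype_diversity(counts),
      tajima_d = if (S > 0L) tajimas_d(h) else NA_real_,
      fay_wu_h = fw,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  num <- c("theta_w", "pi", "he", "tajima_d", "fay_wu_h")
  attr(tab, "summary") <- data.frame(
    statistic = num,
    mean = vapply(num, function(v) mean(tab[[v]], na.rm = TRUE), numeric(1L)),
    min = vapply(num, function(v) suppressWarnings(min(tab[[v]], na.rm = TRUE)), numeric(1L)),
    max = vapply(num, function(v) suppressWarnings(max(tab[[v]], na.rm = TRUE)), numeric(1L))
  )
  tab
}

#' Write the diversity table as TSV
#' @param tab result of [diversity_table].
#' @param path output file.
#' @export
write_diversity_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
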