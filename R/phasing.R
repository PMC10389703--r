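# Haplotype phasing of diploid Sanger consensus sequences.
#
# IUPAC heterozygote codes mark sites where an accession carries two alleles;
# the two underlying haplotypes per accession are inferred with an
# expectation-maximisation algorithm on population haplotype frequencies
# (Excoffier-Slatkin style): the E-step distributes each individual over its
# genotype-compatible haplotype pairs, the M-step re-estimates frequencies.
# Suitable for short non-recombining amplicons.

#' Extract SNP genotypes from a locus alignment
#'
#' Retains columns where the accessions jointly carry at least two distinct
#' unambiguous alleles (heterozygote codes contribute both of their alleles).
#' Per retained column each accession is coded by its alternate-allele count:
#' 0/2 homozygous, 1 heterozygous, `NA` missing (`N` or `-`). Alleles are
#' labelled alphabetically (allele 0 < allele 1); columns with more than two
#' alleles are reported but carry `NA` allele codes beyond the first two and
#' must be dropped before phasing.
#'
#' @param aln a [locus_alignment].
#' @return list with `geno` (accessions x SNPs integer matrix), `alleles`
#'   (2 x SNPs character matrix), `positions` (0-based column offsets into the
#'   alignment), `biallelic` (logical per SNP), `ids`.
#' @export
extract_snp_genotypes <- function(aln) {
  n <- length(aln$ids)
  keep <- integer(0L); allele_list <- list(); geno_cols <- list()
  for (j in seq_len(aln$length_bp)) {
    al <- iupac_alleles(aln$seq[, j])
    states <- sort(unique(al[!is.na(al)]))
    if (length(states) < 2L) next
    keep <- c(keep, j)
    g <- rep(NA_integer_, n)
    if (length(states) == 2L) {
      alt <- states[2L]
      cnt <- colSums(al == alt)
      g[!is.na(cnt)] <- as.integer(cnt[!is.na(cnt)])
      # columns where an accession carries an allele outside {states}: cannot
      # happen for 2 states, all alleles are in states by construction
    }
    geno_cols[[length(geno_cols) + 1L]] <- g
    allele_list[[length(allele_list) + 1L]] <- c(states, rep(NA, 2L))[1:2]
  }
  if (!length(keep)) {
    return(list(geno = matrix(NA_integer_, n, 0L, dimnames = list(aln$ids, NULL)),
                alleles = matrix(character(0L), 2L, 0L),
                positions = integer(0L),
                biallelic = logical(0L), ids = aln$ids))
  }
  geno <- do.call(cbind, geno_cols)
  rownames(geno) <- aln$ids
  alleles <- do.call(cbind, allele_list)
  biallelic <- !is.na(alleles[2L, ]) &
    vapply(seq_along(keep), function(k) {
      al <- iupac_alleles(aln$seq[, keep[k]])
      length(unique(al[!is.na(al)])) == 2L
    }, logical(1L))
  list(geno = geno, alleles = alleles, positions = keep - 1L,
       biallelic = biallelic, ids = aln$ids)
}

# Enumerate the genotype-compatible (unordered) haplotype pairs of one
# individual as two allele matrices (rows = pairs). Missing sites are
# expanded over all completions; swap symmetry is broken at the first
# heterozygous site. Returns NULL when the enumeration exceeds 2^max_bits
# pairs.
enumerate_pairs <- function(g, max_bits) {
  S <- length(g)
  het <- which(!is.na(g) & g == 1L)
  mis <- which(is.na(g))
  n_bits <- if (length(het)) (length(het) - 1L) + 2L * length(mis)
            else 2L * length(mis)
  if (n_bits > max_bits) return(NULL)
  base <- rep(NA_integer_, S)
  hom <- !is.na(g) & g != 1L
  base[hom] <- g[hom] %/% 2L
  hetm <- if (length(het) == 0L) matrix(integer(0L), 1L, 0L)
          else if (length(het) == 1L) matrix(0L, 1L, 1L)
          else cbind(0L, as.matrix(expand.grid(rep(list(0:1), length(het) - 1L))))
  # missing-site completion codes: pairs (h1,h2); unordered when no het site
  # has broken the swap symmetry yet
  codes <- if (length(het)) list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
           else list(c(0L, 0L), c(0L, 1L), c(1L, 1L))
  mism <- if (length(mis) == 0L) matrix(integer(0L), 1L, 0L)
          else as.matrix(expand.grid(rep(list(seq_along(codes)), length(mis))))
  R <- nrow(hetm) * nrow(mism)
  hi <- rep(seq_len(nrow(hetm)), times = nrow(mism))
  mi <- rep(seq_len(nrow(mism)), each = nrow(hetm))
  h1 <- matrix(rep(base, each = R), R, S)
  h2 <- h1
  if (length(het)) {
    h1[, het] <- hetm[hi, , drop = FALSE]
    h2[, het] <- 1L - hetm[hi, , drop = FALSE]
  }
  if (length(mis)) {
    c1 <- vapply(codes, `[`, integer(1L), 1L)
    c2 <- vapply(codes, `[`, integer(1L), 2L)
    h1[, mis] <- matrix(c1[mism[mi, , drop = FALSE]], R)
    h2[, mis] <- matrix(c2[mism[mi, , drop = FALSE]], R)
  }
  list(h1 = h1, h2 = h2)
}

#' EM haplotype phasing
#'
#' Estimates population haplotype frequencies by EM over all
#' genotype-compatible haplotype pairs (missing genotypes are summed over
#' their completions in the E-step), then assigns each individual its
#' maximum-posterior pair. `phase_confidence` is the posterior probability of
#' the chosen pair; ties are broken towards the lexicographically smallest
#' pair. Individuals whose ambiguity exceeds `max_het_sites` bits are phased
#' by a greedy site-by-site pass against the EM haplotype pool and flagged
#' with confidence 0.
#'
#' @param snp result of [extract_snp_genotypes] (all columns must be
#'   biallelic), or a bare genotype matrix.
#' @param locus locus name for the result.
#' @param locus_length full locus length in bp (defaults to the number of SNP
#'   columns when unknown).
#' @param max_het_sites ambiguity cap in bits (default 16).
#' @param seed RNG seed for the EM restarts (default 1).
#' @param n_restarts random restarts (default 10).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return a `haplotype_set`: `locus`, `ids`, `h1`, `h2` (accessions x SNPs
#'   allele matrices over {0,1,NA}), `alleles`, `snp_positions` (0-based),
#'   `locus_length`, `confidence`.
#' @export
phase_em <- function(snp, locus = "locus", locus_length = NULL,
                     max_het_sites = 16L, seed = 1L, n_restarts = 10L,
                     max_iter = 500L, tol = 1e-8) {
  if (is.matrix(snp)) {
    snp <- list(geno = snp, alleles = NULL, positions = seq_len(ncol(snp)) - 1L,
                biallelic = rep(TRUE, ncol(snp)), ids = rownames(snp))
  }
  if (!all(snp$biallelic)) stop("non-biallelic SNP column(s); filter upstream")
  g <- snp$geno
  n <- nrow(g); S <- ncol(g)
  if (is.null(locus_length)) locus_length <- S
  ids <- snp$ids
  if (S == 0L) {
    empty <- matrix(integer(0L), n, 0L, dimnames = list(ids, NULL))
    return(structure(list(locus = locus, ids = ids, h1 = empty, h2 = empty,
                          alleles = snp$alleles, snp_positions = snp$positions,
                          locus_length = locus_length,
                          confidence = stats::setNames(rep(1, n), ids)),
                     class = "haplotype_set"))
  }

  pairs <- lapply(seq_len(n), function(i) enumerate_pairs(g[i, ], max_het_sites))
  fallback <- vapply(pairs, is.null, logical(1L))

  # haplotype dictionary over all enumerated pairs; haplotypes are hashed
  # exactly by 50-bit chunks to avoid per-row string building
  hap_key <- function(m) {
    chunks <- split(seq_len(ncol(m)), (seq_len(ncol(m)) - 1L) %/% 50L)
    nums <- lapply(chunks, function(cc)
      as.vector(m[, cc, drop = FALSE] %*% 2^(seq_along(cc) - 1L)))
    do.call(paste, c(nums, sep = ":"))
  }
  live <- which(!fallback)
  if (length(live)) {
    per_n <- vapply(pairs[live], function(p) nrow(p$h1), integer(1L))
    all_h <- rbind(do.call(rbind, lapply(pairs[live], `[[`, "h1")),
                   do.call(rbind, lapply(pairs[live], `[[`, "h2")))
    P <- sum(per_n)
    keys <- hap_key(all_h)
    dict_keys <- unique(keys)
    K <- length(dict_keys)
    hap_mat <- all_h[match(dict_keys, keys), , drop = FALSE]
    idx <- match(keys, dict_keys)
    HA <- idx[seq_len(P)]
    HB <- idx[P + seq_len(P)]
    IND <- rep(live, per_n)
  } else {
    K <- 0L
    hap_mat <- matrix(integer(0L), 0L, S)
    HA <- HB <- IND <- integer(0L)
  }
  hap_string <- function(k) paste(hap_mat[k, ], collapse = "")

  mult0 <- ifelse(HA == HB, 1, 2)
  # sparse incidence matrices: individuals x pairs and haplotypes x pair-slots
  make_inc <- function(ha, hb, ind) {
    P <- length(ha)
    list(
      Mi = Matrix::sparseMatrix(i = match(ind, sort(unique(ind))),
                                j = seq_len(P), x = 1,
                                dims = c(length(unique(ind)), P)),
      Mh = Matrix::sparseMatrix(i = c(ha, hb), j = rep(seq_len(P), 2L), x = 1,
                                dims = c(K, P)),
      ind_pos = match(ind, sort(unique(ind))))
  }
  inc0 <- if (length(HA)) make_inc(HA, HB, IND) else NULL
  # After a short burn-in, pairs whose posterior weight is negligible are
  # dropped from the E-step (they cannot recover mass once their haplotypes'
  # frequencies collapse); each individual always keeps its best pair. This
  # is a standard EM acceleration and leaves the fixed point unchanged at
  # the reported tolerance.
  run_em <- function(p0, prune_at = 3L, prune_tol = 1e-10) {
    ha <- HA; hb <- HB; mult <- mult0; ind <- IND
    inc <- inc0
    p <- p0; ll <- -Inf
    for (iter in seq_len(max_iter)) {
      w <- p[ha] * p[hb] * mult
      denom <- as.vector(inc$Mi %*% w)
      ll_new <- sum(log(pmax(denom, .Machine$double.xmin)))
      wn <- w / denom[inc$ind_pos]
      p <- as.vector(inc$Mh %*% wn)
      p <- p / sum(p)
      if (abs(ll_new - ll) < tol) { ll <- ll_new; break }
      ll <- ll_new
      if (iter == prune_at && length(ha) > 4L * length(unique(ind))) {
        top <- tapply(wn, inc$ind_pos, max)
        keep <- wn > prune_tol | wn >= top[inc$ind_pos]
        ha <- ha[keep]; hb <- hb[keep]; mult <- mult[keep]; ind <- ind[keep]
        inc <- make_inc(ha, hb, ind)
      }
    }
    list(p = p, ll = ll)
  }

  best <- NULL
  if (K > 0L) {
    with_seed(seed, {
      for (r in seq_len(n_restarts)) {
        p0 <- if (r == 1L) rep(1 / K, K) else { x <- stats::rexp(K); x / sum(x) }
        fit <- run_em(p0)
        if (is.null(best) || fit$ll > best$ll + 1e-12) best <- fit
      }
    })
  }

  h1 <- matrix(NA_integer_, n, S, dimnames = list(ids, NULL))
  h2 <- h1
  conf <- stats::setNames(rep(NA_real_, n), ids)
  for (i in which(!fallback)) {
    ka <- HA[IND == i]; kb <- HB[IND == i]
    post <- best$p[ka] * best$p[kb] * ifelse(ka == kb, 1, 2)
    tot <- sum(post)
    post <- if (tot > 0) post / tot else rep(1 / length(post), length(post))
    top <- which(post == max(post))
    if (length(top) > 1L) {  # lexicographic tie-break on the sorted pair
      keys <- vapply(top, function(t) {
        a <- hap_string(ka[t]); b <- hap_string(kb[t])
        paste(sort(c(a, b)), collapse = "|")
      }, character(1L))
      top <- top[order(keys)][1L]
    }
    a <- hap_mat[ka[top], ]
    b <- hap_mat[kb[top], ]
    if (paste(a, collapse = "") > paste(b, collapse = "")) { tmp <- a; a <- b; b <- tmp }
    mis <- is.na(g[i, ])
    a[mis] <- NA_integer_; b[mis] <- NA_integer_  # phasing does not impute
    h1[i, ] <- a; h2[i, ] <- b
    conf[i] <- max(post)
  }

  if (any(fallback)) {
    pool <- if (!is.null(best)) {
      keep <- best$p > 1e-6
      list(h = hap_mat[keep, , drop = FALSE], w = best$p[keep])
    } else NULL
    for (i in which(fallback)) {
      ph <- greedy_phase(g[i, ], pool)
      h1[i, ] <- ph$h1; h2[i, ] <- ph$h2
      conf[i] <- 0
    }
  }

  structure(list(locus = locus, ids = ids, h1 = h1, h2 = h2,
                 alleles = snp$alleles, snp_positions = snp$positions,
                 locus_length = locus_length, confidence = conf),
            class = "haplotype_set")
}

# Greedy site-by-site phasing against a frequency-weighted haplotype pool:
# at each heterozygous site hap1 takes the allele favoured by the pool
# haplotypes consistent with the already-placed sites.
greedy_phase <- function(g, pool) {
  S <- length(g)
  h1 <- rep(NA_integer_, S); h2 <- h1
  hom <- !is.na(g) & g != 1L
  h1[hom] <- g[hom] / 2L; h2[hom] <- h1[hom]
  het <- which(!is.na(g) & g == 1L)
  active <- if (!is.null(pool)) rep(TRUE, nrow(pool$h)) else logical(0L)
  if (!is.null(pool)) {
    cons <- vapply(seq_len(nrow(pool$h)), function(r) {
      all(pool$h[r, hom] == h1[hom], na.rm = TRUE)
    }, logical(1L))
    if (any(cons)) active <- cons
  }
  placed <- integer(0L)
  for (s in het) {
    allele <- 0L
    if (!is.null(pool) && any(active)) {
      w0 <- sum(pool$w[active & pool$h[, s] == 0L])
      w1 <- sum(pool$w[active & pool$h[, s] == 1L])
      allele <- if (w1 > w0) 1L else 0L
    }
    h1[s] <- allele; h2[s] <- 1L - allele
    placed <- c(placed, s)
    if (!is.null(pool)) {
      nxt <- active & pool$h[, s] == allele
      if (any(nxt)) active <- nxt else active <- rep(TRUE, nrow(pool$h))
    }
  }
  list(h1 = h1, h2 = h2)
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set> ", x$locus, ": ", length(x$ids), " accessions, ",
      ncol(x$h1), " SNP sites\n", sep = "")
  invisible(x)
}

#' Phased haplotypes as a character matrix
#'
#' Expands a `haplotype_set` into a (2 x accessions) x SNPs character matrix
#' of bases, rows named `id/1`, `id/2`; `NA` marks missing sites. When allele
#' base labels are unknown, alleles are reported as `"0"`/`"1"`.
#'
#' @param hs a `haplotype_set`.
#' @export
hap_char_matrix <- function(hs) {
  n <- length(hs$ids); S <- ncol(hs$h1)
  out <- matrix(NA_character_, 2L * n, S)
  rownames(out) <- paste0(rep(hs$ids, each = 2L), "/", rep(1:2, n))
  for (i in seq_len(n)) {
    for (which_h in 1:2) {
      al <- if (which_h == 1L) hs$h1[i, ] else hs$h2[i, ]
      row <- 2L * (i - 1L) + which_h
      if (!is.null(hs$alleles) && S > 0L) {
        ok <- !is.na(al)
        out[row, ok] <- hs$alleles[cbind(al[ok] + 1L, which(ok))]
      } else if (S > 0L) {
        out[row, ] <- as.character(al)
      }
    }
  }
  out
}

#' Inter-haplotype differences per accession
#'
#' Hamming distance between each accession's two phased haplotypes over the
#' sites where both are non-missing. For an F1 hybrid this approximates twice
#' the parental clades' divergence at the locus; for a non-hybrid it reflects
#' within-species diversity.
#'
#' @param hs a `haplotype_set`.
#' @return named integer vector per accession.
#' @export
interhap_differences <- function(hs) {
  vapply(seq_along(hs$ids), function(i) {
    a <- hs$h1[i, ]; b <- hs$h2[i, ]
    ok <- !is.na(a) & !is.na(b)
    sum(a[ok] != b[ok])
  }, integer(1L)) |> stats::setNames(hs$ids)
}

#' Export phased haplotypes as FASTA
#'
#' Writes the SNP-column haplotypes with `/1`, `/2` id suffixes; missing
#' sites are written as `N`.
#'
#' @param hs a `haplotype_set`.
#' @param path output FASTA.
#' @export
write_phased_fasta <- function(hs, path) {
  m <- hap_char_matrix(hs)
  m[is.na(m)] <- "N"
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(">", rownames(m)[i]), con)
    writeLines(paste(m[i, ], collapse = ""), con)
  }
  invisible(path)
}
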