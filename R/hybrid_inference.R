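# Hybrid detection: inter-haplotype difference outliers per clade, parental
# clade assignment from labeled haplotype pools, SNP-array heterozygosity
# outliers, chlorotype definition/collapse, and maternal-parent inference
# from the (maternally inherited) chloroplast haplotype.

#' Mean inter-haplotype difference per accession
#'
#' Averages the per-locus Hamming distance between each accession's two
#' phased haplotypes over the loci where it was sequenced. F1 hybrids between
#' clades carry one haplotype from each parent at every locus, so their mean
#' is elevated to roughly twice the between-clade divergence.
#'
#' @param hap_sets list of `haplotype_set` objects (one per locus).
#' @return named numeric vector; accessions absent from every locus are
#'   excluded (with a message).
#' @export
dbar_statistic <- function(hap_sets) {
  per_locus <- lapply(hap_sets, interhap_differences)
  ids <- unique(unlist(lapply(per_locus, names)))
  vals <- vapply(ids, function(a) {
    x <- unlist(lapply(per_locus, function(v) v[a]))
    mean(x, na.rm = TRUE)
  }, numeric(1L))
  names(vals) <- ids
  vals
}

#' Flag outliers within clade groups (Tukey boxplot rule)
#'
#' An accession is flagged when its value exceeds `Q3 + 1.5 * IQR` of its
#' clade group (quartiles by linear interpolation, the standard boxplot
#' fence). Groups with fewer than 4 members are compared against the pooled
#' distribution instead.
#'
#' @param values named numeric vector.
#' @param grouping group (clade) label per value, same order.
#' @return named logical vector.
#' @export
flag_outliers <- function(values, grouping) {
  stopifnot(length(values) == length(grouping))
  out <- stats::setNames(rep(FALSE, length(values)), names(values))
  pooled_fence <- tukey_upper_fence(values)
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    if (length(idx) >= 4L) {
      fence <- tukey_upper_fence(values[idx])
    } else {
      message("group '", g, "' has < 4 members; using pooled fence")
      fence <- pooled_fence
    }
    out[idx] <- values[idx] > fence
  }
  out
}

# Labeled haplotype pool for one locus: haplotypes of accessions with a known
# clade, excluding hybrids and the focal accession.
labeled_pool <- function(hs, accessions, exclude) {
  keep <- hs$ids %in% accessions$accession_id &
    !(hs$ids %in% exclude)
  cl <- accessions$clade_label[match(hs$ids, accessions$accession_id)]
  keep <- keep & !is.na(cl) & cl != "UNKNOWN"
  idx <- which(keep)
  pool <- rbind(hs$h1[idx, , drop = FALSE], hs$h2[idx, , drop = FALSE])
  list(pool = pool, clades = rep(cl[idx], 2L))
}

#' Assign parental clades to a putative hybrid
#'
#' Maps each of the accession's two haplotypes at each locus to the clade of
#' its nearest labeled haplotype (known hybrids and the accession itself are
#' excluded from the pools). The parental pair is the two most frequent clade
#' labels across loci; each must be supported by at least `min_support` of
#' the informative loci, otherwise `UNKNOWN`. A non-hybrid yields the pair
#' `(clade, clade)`.
#'
#' @param accession focal accession id.
#' @param hap_sets list of `haplotype_set` objects.
#' @param accessions an [accession_table].
#' @param exclude accessions to drop from the labeled pools (known or flagged
#'   hybrids); the focal accession is always excluded.
#' @param min_support per-clade locus-support threshold (default 0.25).
#' @return list with `parental_clades` (length-2 character), `evidence`
#'   (per-locus data frame of the two clade calls and distances).
#' @export
assign_parents <- function(accession, hap_sets, accessions,
                           exclude = character(0L), min_support = 0.25) {
  exclude <- union(exclude, accession)
  ev <- list()
  for (hs in hap_sets) {
    i <- match(accession, hs$ids)
    if (is.na(i) || ncol(hs$h1) == 0L) next
    lp <- labeled_pool(hs, accessions, exclude)
    if (!nrow(lp$pool)) next
    a1 <- nearest_clade(hs$h1[i, ], lp$pool, lp$clades)
    a2 <- nearest_clade(hs$h2[i, ], lp$pool, lp$clades)
    ev[[length(ev) + 1L]] <- data.frame(
      locus = hs$locus, clade1 = a1$clade, clade2 = a2$clade,
      dist1 = a1$distance, dist2 = a2$distance, stringsAsFactors = FALSE)
  }
  if (!length(ev))
    return(list(parental_clades = c("UNKNOWN", "UNKNOWN"),
                evidence = data.frame()))
  ev <- do.call(rbind, ev)
  informative <- ev$clade1 != "UNKNOWN" | ev$clade2 != "UNKNOWN"
  n_inf <- sum(informative)
  if (n_inf == 0L)
    return(list(parental_clades = c("UNKNOWN", "UNKNOWN"), evidence = ev))
  evi <- ev[informative, , drop = FALSE]
  labs <- c(evi$clade1, evi$clade2)
  labs <- labs[labs != "UNKNOWN"]
  freq <- sort(table(labs), decreasing = TRUE)
  # presence per locus, used for the support threshold
  pres <- function(cl) sum(evi$clade1 == cl | evi$clade2 == cl)
  both <- function(cl) sum(evi$clade1 == cl & evi$clade2 == cl)
  cands <- names(freq)[order(-as.integer(freq), names(freq))]
  p1 <- if (length(cands) && pres(cands[1L]) >= min_support * n_inf)
    cands[1L] else "UNKNOWN"
  p2 <- "UNKNOWN"
  if (p1 != "UNKNOWN") {
    rest <- setdiff(cands, p1)
    rest <- rest[vapply(rest, pres, integer(1L)) >= min_support * n_inf]
    if (length(rest)) {
      # compare best remaining clade against a homozygous-p1 interpretation
      if (both(p1) > max(vapply(rest, pres, integer(1L))))
        p2 <- p1
      else
        p2 <- rest[1L]
    } else if (both(p1) >= min_support * n_inf) {
      p2 <- p1
    }
  }
  list(parental_clades = sort(c(p1, p2)), evidence = ev)
}

#' Observed heterozygosity from SNP-array calls
#'
#' Fraction of an accession's non-missing calls that are heterozygous
#' (call 1).
#'
#' @param gm a [genotype_matrix].
#' @return named numeric vector per accession.
#' @export
array_heterozygosity <- function(gm) {
  het <- rowSums(gm$calls == 1L, na.rm = TRUE)
  n <- rowSums(!is.na(gm$calls))
  stats::setNames(ifelse(n > 0, het / n, NA_real_), gm$ids)
}

#' Define chlorotypes from chloroplast SNPs
#'
#' Restricts to chloroplast-flagged SNPs, treats heterozygous calls as
#' missing (the chloroplast is haploid), keeps only loci that are biallelic
#' across the sample, and groups accessions by their multilocus string.
#'
#' @param gm a [genotype_matrix].
#' @return data frame of class `chlorotype_assignment` with columns
#'   `accession_id`, `chlorotype_id`, `snp_string` (`?` = missing; `NA` id
#'   for accessions missing at every informative locus); attribute
#'   `informative_snps` lists the SNP ids used.
#' @export
define_chlorotypes <- function(gm) {
  cp <- which(gm$snp_meta$genome == "chloroplast")
  if (!length(cp)) stop("no chloroplast-flagged SNPs in metadata")
  calls <- gm$calls[, cp, drop = FALSE]
  calls[calls == 1L] <- NA_integer_
  informative <- vapply(seq_len(ncol(calls)), function(j) {
    length(unique(stats::na.omit(calls[, j]))) == 2L
  }, logical(1L))
  calls <- calls[, informative, drop = FALSE]
  chars <- matrix("?", nrow(calls), ncol(calls))
  chars[!is.na(calls)] <- ifelse(calls[!is.na(calls)] == 0L, "0", "1")
  strings <- apply(chars, 1L, paste, collapse = "")
  unassigned <- ncol(calls) == 0L | !grepl("[01]", strings)
  if (any(unassigned))
    message(sum(unassigned), " accession(s) missing at all informative ",
            "chloroplast loci left unassigned")
  ids <- rep(NA_character_, length(strings))
  seen <- character(0L)
  for (i in which(!unassigned)) {
    hit <- match(strings[i], seen)
    if (is.na(hit)) { seen <- c(seen, strings[i]); hit <- length(seen) }
    ids[i] <- paste0("C", hit)
  }
  out <- data.frame(accession_id = gm$ids, chlorotype_id = ids,
                    snp_string = strings, stringsAsFactors = FALSE)
  attr(out, "informative_snps") <- gm$snp_ids[cp][informative]
  class(out) <- c("chlorotype_assignment", class(out))
  out
}

# Mismatches between two chlorotype strings over shared non-missing loci;
# Inf when nothing is shared.
chlorotype_distance <- function(a, b) {
  x <- strsplit(a, "")[[1L]]; y <- strsplit(b, "")[[1L]]
  ok <- x != "?" & y != "?"
  if (!any(ok)) return(Inf)
  sum(x[ok] != y[ok])
}

#' Collapse chlorotypes by single linkage
#'
#' Joins chlorotypes whose multilocus strings differ by at most `t`
#' mismatches (over shared non-missing loci), chaining transitively
#' (single-linkage clustering). The group id is the lexicographically
#' smallest member string.
#'
#' @param assignment a `chlorotype_assignment`.
#' @param t mismatch threshold (default 1; `t = 0` is the identity
#'   partition).
#' @return the assignment with an added `collapsed_group_id` column.
#' @export
collapse_chlorotypes <- function(assignment, t = 1L) {
  ok <- !is.na(assignment$chlorotype_id)
  strings <- unique(assignment$snp_string[ok])
  k <- length(strings)
  comp <- seq_len(k)
  if (k > 1L) for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    if (chlorotype_distance(strings[i], strings[j]) <= t) {
      ci <- comp[i]; cj <- comp[j]
      if (ci != cj) comp[comp == cj] <- ci
    }
  }
  group_of <- vapply(seq_len(k), function(i) min(strings[comp == comp[i]]),
                     character(1L))
  assignment$collapsed_group_id <- NA_character_
  assignment$collapsed_group_id[ok] <-
    group_of[match(assignment$snp_string[ok], strings)]
  assignment
}

#' Infer the maternal (female-parent) clade of a hybrid
#'
#' The chloroplast is maternally inherited, so a hybrid's collapsed
#' chlorotype group identifies the female lineage: if exactly one of the two
#' parental clades has non-hybrid members sharing the group, that clade is
#' maternal. If both share it the direction is undecidable (`UNKNOWN`); if
#' neither shares it the result is `UNKNOWN` with the nearest clade and its
#' chlorotype distance reported.
#'
#' @param accession hybrid accession id.
#' @param parental_clades length-2 clade pair from [assign_parents].
#' @param collapsed a collapsed `chlorotype_assignment`.
#' @param accessions an [accession_table].
#' @param exclude accessions not usable as clade references (hybrids).
#' @return list with `maternal_clade`, `nearest_clade`, `nearest_distance`.
#' @export
infer_maternal <- function(accession, parental_clades, collapsed, accessions,
                           exclude = character(0L)) {
  exclude <- union(exclude, accession)
  row <- collapsed[collapsed$accession_id == accession, ]
  res <- list(maternal_clade = "UNKNOWN", nearest_clade = NA_character_,
              nearest_distance = NA_real_)
  if (!nrow(row) || is.na(row$collapsed_group_id)) return(res)
  ref <- collapsed[!(collapsed$accession_id %in% exclude) &
                     !is.na(collapsed$collapsed_group_id), ]
  ref_clade <- accessions$clade_label[match(ref$accession_id,
                                            accessions$accession_id)]
  sharing <- unique(ref_clade[ref$collapsed_group_id == row$collapsed_group_id])
  sharing <- sharing[!is.na(sharing)]
  par <- setdiff(unique(parental_clades), "UNKNOWN")
  hit <- intersect(par, sharing)
  if (length(hit) == 1L) {
    res$maternal_clade <- hit
  } else if (length(hit) == 0L && nrow(ref)) {
    d <- vapply(ref$snp_string, chlorotype_distance, numeric(1L),
                a = row$snp_string)
    dmin <- min(d)
    nc <- unique(ref_clade[d == dmin])
    res$nearest_clade <- if (length(nc) == 1L) nc else "UNKNOWN"
    res$nearest_distance <- dmin
  }
  res
}

#' Full hybrid report
#'
#' Runs the complete detection procedure: the inter-haplotype difference
#' statistic with per-clade Tukey outlier flags, parental-clade assignment
#' for known plus newly flagged hybrids, SNP-array heterozygosity with its
#' own outlier flags, chlorotype definition and collapse, and maternal-clade
#' inference.
#'
#' @param hap_sets list of `haplotype_set` objects.
#' @param accessions an [accession_table].
#' @param gm optional [genotype_matrix] (enables array heterozygosity and
#'   chlorotypes).
#' @param collapse_t chlorotype collapse threshold (default 1).
#' @return data frame (class `hybrid_report`) with one row per accession:
#'   `dbar`, `clade_group`, `outlier`, `parent1`, `parent2`,
#'   `maternal_clade`, `array_het`, `array_outlier`, and
#'   `confirmed_hybrid` (outlier whose haplotypes resolve to two distinct
#'   parental clades). Per-locus evidence is in the `evidence` attribute,
#'   the collapsed chlorotype table in `chlorotypes`.
#' @export
hybrid_report <- function(hap_sets, accessions, gm = NULL, collapse_t = 1L) {
  dbar <- dbar_statistic(hap_sets)
  grp <- accessions$clade_label[match(names(dbar), accessions$accession_id)]
  flags <- flag_outliers(dbar, grp)
  known <- accessions$accession_id[accessions$known_hybrid]
  hybrids <- union(known[known %in% names(dbar)], names(flags)[flags])
  parents <- lapply(stats::setNames(hybrids, hybrids), function(a) {
    assign_parents(a, hap_sets, accessions, exclude = hybrids)
  })
  chloro <- NULL; ahet <- NULL; aflags <- NULL
  if (!is.null(gm)) {
    ahet <- array_heterozygosity(gm)
    agrp <- accessions$clade_label[match(names(ahet), accessions$accession_id)]
    aflags <- flag_outliers(ahet, agrp)
    chloro <- collapse_chlorotypes(define_chlorotypes(gm), t = collapse_t)
  }
  ids <- names(dbar)
  rep_df <- data.frame(
    accession_id = ids,
    dbar = unname(dbar),
    clade_group = grp,
    outlier = unname(flags),
    parent1 = NA_character_, parent2 = NA_character_,
    maternal_clade = NA_character_,
    array_het = if (is.null(ahet)) NA_real_ else unname(ahet[ids]),
    array_outlier = if (is.null(aflags)) NA else unname(aflags[ids]),
    stringsAsFactors = FALSE
  )
  for (a in hybrids) {
    i <- match(a, rep_df$accession_id)
    pc <- parents[[a]]$parental_clades
    rep_df$parent1[i] <- pc[1L]; rep_df$parent2[i] <- pc[2L]
    if (!is.null(chloro)) {
      m <- infer_maternal(a, pc, chloro, accessions, exclude = hybrids)
      rep_df$maternal_clade[i] <- m$maternal_clade
    }
  }
  # an outlier is a confirmed interspecific hybrid only when its two
  # haplotype lineages resolve to two distinct clades; a (clade, clade)
  # pair is the non-hybrid signature
  rep_df$confirmed_hybrid <- rep_df$outlier &
    !is.na(rep_df$parent1) & rep_df$parent1 != "UNKNOWN" &
    !is.na(rep_df$parent2) & rep_df$parent2 != "UNKNOWN" &
    rep_df$parent1 != rep_df$parent2
  attr(rep_df, "evidence") <- lapply(parents, `[[`, "evidence")
  attr(rep_df, "chlorotypes") <- chloro
  class(rep_df) <- c("hybrid_report", class(rep_df))
  rep_df
}

#' Write a hybrid report (TSV + JSON)
#' @param report a `hybrid_report`.
#' @param tsv_path,json_path output files (either may be `NULL`).
#' @export
write_hybrid_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(report), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(report), json_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  invisible(report)
}
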