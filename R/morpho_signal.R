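# Morphometric analysis: trait preparation from per-leaf measurements, PCA
# of leaf measures and ordinal OIV descriptors, Abouheif's permutation test
# for phylogenetic autocorrelation, phylogenetic PCA (pPCA), and selection of
# top-loading variables.

#' Prepare accession-level traits from per-leaf measurements
#'
#' Takes per-accession medians of each measured parameter, then averages
#' parameters measured on the left and right leaf halves (columns named
#' `<base>_L` / `<base>_R` become `<base>`), and computes the circularity
#' `Circ = 4 * pi * area / perimeter^2` when `area` and `perimeter` columns
#' are present. Accessions with fewer than `min_leaves` leaves are kept with
#' a warning.
#'
#' @param raw data frame with columns `accession_id`, `leaf` and one numeric
#'   column per measured parameter.
#' @param min_leaves minimum leaves per accession before warning (default 3).
#' @param trait_type optional named vector of types for the derived traits;
#'   unnamed traits default to `length`.
#' @return a [trait_table].
#' @export
prepare_traits <- function(raw, min_leaves = 3L, trait_type = NULL) {
  stopifnot(all(c("accession_id", "leaf") %in% names(raw)))
  params <- setdiff(names(raw), c("accession_id", "leaf"))
  counts <- table(raw$accession_id)
  low <- names(counts)[counts < min_leaves]
  if (length(low))
    warning("accession(s) with fewer than ", min_leaves, " leaves: ",
            paste(low, collapse = ", "))
  ids <- unique(raw$accession_id)
  med <- sapply(params, function(p) {
    vapply(ids, function(a) stats::median(raw[[p]][raw$accession_id == a],
                                          na.rm = TRUE), numeric(1L))
  })
  med <- matrix(med, nrow = length(ids),
                dimnames = list(ids, params))
  # average left/right paired parameters after the medians
  lefts <- grep("_L$", colnames(med), value = TRUE)
  for (l in lefts) {
    base <- sub("_L$", "", l)
    r <- paste0(base, "_R")
    if (r %in% colnames(med)) {
      med <- cbind(med, (med[, l] + med[, r]) / 2)
      colnames(med)[ncol(med)] <- base
      med <- med[, setdiff(colnames(med), c(l, r)), drop = FALSE]
    }
  }
  if (all(c("area", "perimeter") %in% colnames(med))) {
    med <- cbind(med, Circ = 4 * pi * med[, "area"] / med[, "perimeter"]^2)
  }
  tt <- if (is.null(trait_type)) rep("length", ncol(med))
        else unname(ifelse(colnames(med) %in% names(trait_type),
                           trait_type[colnames(med)], "length"))
  trait_table(med, tt)
}

#' Principal component analysis of a trait table
#'
#' Centered eigen-decomposition, unit-variance scaled by default (ordinal
#' OIV codes are treated as numeric). Zero-variance traits are dropped with a
#' message when scaling.
#'
#' @param tt a [trait_table] (no missing values).
#' @param scale scale traits to unit variance (default `TRUE`).
#' @return list of class `pca_result`: `eigenvalues`, `percent` (variance per
#'   axis, sums to 100), `loadings`, `scores`, `scaled`.
#' @export
trait_pca <- function(tt, scale = TRUE) {
  X <- tt$values
  if (anyNA(X)) stop("trait table contains missing values")
  if (ncol(X) < 1L || nrow(X) < 3L) stop("need >= 1 trait and >= 3 accessions")
  if (scale) {
    v <- apply(X, 2L, stats::var)
    if (any(v == 0)) {
      message("dropping zero-variance trait(s): ",
              paste(colnames(X)[v == 0], collapse = ", "))
      X <- X[, v > 0, drop = FALSE]
    }
  }
  p <- stats::prcomp(X, center = TRUE, scale. = scale)
  ev <- p$sdev^2
  structure(list(eigenvalues = ev,
                 percent = 100 * ev / sum(ev),
                 loadings = p$rotation,
                 scores = p$x,
                 scaled = scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", length(x$eigenvalues), " axes; PC1 ",
      sprintf("%.1f%%", x$percent[1L]),
      if (length(x$percent) > 1L)
        sprintf(", PC1+PC2 %.1f%%", sum(x$percent[1:2])) else "",
      "\n", sep = "")
  invisible(x)
}

#' Abouheif phylogenetic proximity matrix
#'
#' Tip-pair proximity `1 / prod(dd)` over the internal nodes on the path
#' between the two tips, where `dd` is each node's number of direct
#' descendants; the diagonal is zero. Returned raw and row-normalized. On a
#' star tree all off-diagonal proximities are equal, and the associated
#' Moran statistic reduces to the uniform-weight case.
#'
#' @param tree rooted `phylo` containing all scored accessions.
#' @param tips optional tip subset/order (defaults to `tree$tip.label`).
#' @return list with `raw` and `W` (row-normalized), dimnames = tips.
#' @export
abouheif_proximity <- function(tree, tips = NULL) {
  if (is.null(tips)) tips <- tree$tip.label
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("tip(s) missing from tree: ", paste(missing, collapse = ", "))
  if (length(tips) < 2L) stop("need >= 2 tips")
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  n_children <- tabulate(tree$edge[, 1L], nbins = n_tip + tree$Nnode)
  ancestors <- function(v) {
    out <- integer(0L)
    while (parent[v] != 0L) { v <- parent[v]; out <- c(out, v) }
    out
  }
  tip_idx <- match(tips, tree$tip.label)
  anc <- lapply(tip_idx, ancestors)
  k <- length(tips)
  A <- matrix(0, k, k, dimnames = list(tips, tips))
  for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    common <- intersect(anc[[i]], anc[[j]])
    mrca <- common[1L]  # ancestors are ordered tip -> root
    path <- c(setdiff(anc[[i]], common), setdiff(anc[[j]], common), mrca)
    A[i, j] <- 1 / prod(n_children[path])
    A[j, i] <- A[i, j]
  }
  W <- A / rowSums(A)
  list(raw = A, W = W)
}

#' Abouheif's permutation test for phylogenetic autocorrelation
#'
#' The observed statistic is the Moran-type autocorrelation
#' `C = z' W z / z' z` with `z` the centered trait and `W` the row-normalized
#' Abouheif proximity; the one-sided upper p-value comes from random
#' permutations of the trait over the tips, with the add-one correction
#' `p = (#{C* >= C} + 1) / (n_perm + 1)`.
#'
#' @param x named numeric trait vector (names = tips of `prox`).
#' @param prox result of [abouheif_proximity].
#' @param n_perm permutations (default 999).
#' @param seed RNG seed (default 1).
#' @return list of class `phylo_signal`: `cmean`, `p_value`, `n_perm`.
#'   Constant traits are flagged with `NA` statistics.
#' @export
abouheif_test <- function(x, prox, n_perm = 999L, seed = 1L) {
  W <- prox$W
  if (!is.null(names(x))) x <- x[rownames(W)]
  if (stats::var(x) == 0) {
    return(structure(list(cmean = NA_real_, p_value = NA_real_,
                          n_perm = n_perm, constant = TRUE),
                     class = "phylo_signal"))
  }
  z <- x - mean(x)
  cobs <- as.numeric(z %*% W %*% z) / sum(z^2)
  perm <- with_seed(seed, {
    Z <- replicate(n_perm, sample(z))
    colSums((W %*% Z) * Z) / sum(z^2)
  })
  p <- (sum(perm >= cobs) + 1) / (n_perm + 1)
  structure(list(cmean = cobs, p_value = p, n_perm = n_perm,
                 constant = FALSE),
            class = "phylo_signal")
}

#' Phylogenetic signal table for all traits
#'
#' Runs [abouheif_test] per trait and reports the significance flags used in
#' morphometric summaries (p < 0.01, p < 0.05).
#'
#' @param tt a [trait_table].
#' @param prox result of [abouheif_proximity] over the table's accessions.
#' @param n_perm,seed passed to [abouheif_test]; each trait gets a distinct
#'   derived seed for independence.
#' @return data frame with `trait`, `cmean`, `p_value`, `sig_01`, `sig_05`.
#' @export
phylo_signal_table <- function(tt, prox, n_perm = 999L, seed = 1L) {
  rows <- lapply(seq_along(tt$traits), function(j) {
    r <- abouheif_test(stats::setNames(tt$values[, j], tt$ids), prox,
                       n_perm = n_perm, seed = seed + j)
    data.frame(trait = tt$traits[j], cmean = r$cmean, p_value = r$p_value,
               sig_01 = !is.na(r$p_value) && r$p_value < 0.01,
               sig_05 = !is.na(r$p_value) && r$p_value >= 0.01 && r$p_value < 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Phylogenetic principal component analysis (pPCA)
#'
#' Eigen-decomposes the proximity-weighted cross-product
#' `t(X) %*% Wsym %*% X / n` of the centered (and scaled) trait matrix, with
#' `Wsym` the symmetrized row-normalized Abouheif proximity. Positive
#' eigenvalues capture global (clade-level) structures, negative ones local
#' contrasts. With a uniform proximity (star tree) the axes coincide with
#' ordinary PCA axes up to the Moran weighting.
#'
#' @param tt a [trait_table] (no missing values).
#' @param prox result of [abouheif_proximity].
#' @param scale scale traits to unit variance (default `TRUE`).
#' @return list of class `ppca_result`: `eigenvalues` (signed, decreasing),
#'   `global` (logical per axis), `loadings`, `scores`.
#' @export
ppca <- function(tt, prox, scale = TRUE) {
  X <- tt$values[rownames(prox$W), , drop = FALSE]
  if (anyNA(X)) stop("trait table contains missing values")
  if (scale) {
    v <- apply(X, 2L, stats::var)
    X <- X[, v > 0, drop = FALSE]
  }
  X <- base::scale(X, center = TRUE, scale = scale)
  n <- nrow(X)
  Wsym <- (prox$W + t(prox$W)) / 2
  C <- t(X) %*% Wsym %*% X / n
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  scores <- X %*% e$vectors
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  loadings <- e$vectors
  dimnames(loadings) <- list(colnames(X), colnames(scores))
  structure(list(eigenvalues = e$values,
                 global = e$values > 0,
                 loadings = loadings,
                 scores = scores),
            class = "ppca_result")
}

#' Select traits with extreme first-axis loadings
#'
#' Keeps the traits whose PC1 loading falls below the 10th or above the 90th
#' percentile of the loading distribution (the most structured variables).
#' With fewer than 10 traits all are returned, with a message.
#'
#' @param loadings matrix of loadings (traits x axes) from [trait_pca] or
#'   [ppca].
#' @param axis axis to use (default 1).
#' @param probs lower/upper quantile cut-offs (default `c(0.1, 0.9)`).
#' @return character vector of selected trait names.
#' @export
select_top_loadings <- function(loadings, axis = 1L, probs = c(0.1, 0.9)) {
  a <- loadings[, axis]
  if (length(a) < 10L) {
    message("fewer than 10 traits; returning all")
    return(rownames(loadings))
  }
  q <- stats::quantile(a, probs, names = FALSE, type = 7)
  rownames(loadings)[a < q[1L] | a > q[2L]]
}
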