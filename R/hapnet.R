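# Median-joining haplotype networks (Bandelt et al. style, for the binary /
# few-state data produced by phased Sanger amplicons).
#
# The construction is: (1) pairwise Hamming distances among distinct
# haplotypes; (2) a minimum-spanning network keeping every link within
# epsilon of the level at which its endpoints' components first connect;
# (3) iterative insertion of majority-consensus median vectors (Steiner
# points) of connected triplets whenever they reduce the local connection
# cost; (4) pruning of inferred nodes of degree <= 2. Ties are broken
# lexicographically so the result is deterministic.

hamming_all <- function(m) {
  n <- nrow(m)
  D <- matrix(0L, n, n)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d <- sum(m[i, ] != m[j, ])
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

# For every pair, the distance level at which the two components first become
# connected under ascending single-linkage merging.
connection_levels <- function(D) {
  n <- nrow(D)
  comp <- seq_len(n)
  T <- matrix(Inf, n, n); diag(T) <- 0
  for (d in sort(unique(D[upper.tri(D)]))) {
    ed <- which(D == d & upper.tri(D), arr.ind = TRUE)
    for (r in seq_len(nrow(ed))) {
      ci <- comp[ed[r, 1L]]; cj <- comp[ed[r, 2L]]
      if (ci != cj) comp[comp == cj] <- ci
    }
    newly <- outer(comp, comp, "==") & !is.finite(T)
    T[newly] <- d
    if (all(is.finite(T))) break
  }
  T
}

msn_edges <- function(D, epsilon = 0) {
  T <- connection_levels(D)
  n <- nrow(D)
  out <- NULL
  for (i in seq_len(max(0L, n - 1L))) for (j in (i + 1L):n) {
    if (D[i, j] <= T[i, j] + epsilon)
      out <- rbind(out, c(i, j, D[i, j]))
  }
  if (is.null(out)) out <- matrix(numeric(0L), 0L, 3L)
  colnames(out) <- c("from", "to", "weight")
  out
}

# Per-site majority of three haplotypes; NULL when some site has three
# distinct states (no majority).
triplet_median <- function(a, b, c) {
  m <- ifelse(a == b, a, ifelse(a == c, a, ifelse(b == c, b, NA)))
  if (anyNA(m)) return(NULL)
  m
}

#' Build a median-joining haplotype network
#'
#' @param h character matrix of haplotypes (rows) over sites (columns); no
#'   missing states are allowed (drop such sites upstream). Duplicate rows
#'   are collapsed into multiplicities.
#' @param clades optional clade label per input row; collected per node as a
#'   membership multiset.
#' @param epsilon minimum-spanning-network relaxation (default 0, the usual
#'   strict network).
#' @param max_medians safety cap on inserted median vectors.
#' @return object of class `haplo_network`: `seqs` (node x site character
#'   matrix), `multiplicity`, `inferred`, `clade_counts` (list of tables),
#'   `edges` (data frame from/to/weight with node indices).
#' @export
build_mj_network <- function(h, clades = NULL, epsilon = 0, max_medians = 64L) {
  if (anyNA(h)) stop("missing states not allowed in network input")
  if (is.null(rownames(h))) rownames(h) <- paste0("h", seq_len(nrow(h)))
  keys <- apply(h, 1L, paste, collapse = "")
  if (length(unique(nchar(keys))) > 1L) stop("haplotype length mismatch")
  ord <- order(keys)
  keys <- keys[ord]; h <- h[ord, , drop = FALSE]
  if (!is.null(clades)) clades <- clades[ord]
  uk <- unique(keys)
  if (length(uk) < 2L) stop("need >= 2 distinct haplotypes")
  first <- match(uk, keys)
  seqs <- h[first, , drop = FALSE]
  rownames(seqs) <- paste0("H", seq_along(uk))
  multiplicity <- as.integer(table(factor(keys, levels = uk)))
  clade_counts <- lapply(uk, function(k) {
    if (is.null(clades)) table(character(0L)) else table(clades[keys == k])
  })
  inferred <- rep(FALSE, nrow(seqs))

  repeat {
    D <- hamming_all(seqs)
    E <- msn_edges(D, epsilon)
    adj <- matrix(FALSE, nrow(seqs), nrow(seqs))
    if (nrow(E)) adj[E[, 1:2, drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    n <- nrow(seqs)
    best <- NULL
    if (n >= 3L && sum(inferred) < max_medians && nrow(E)) {
      node_keys <- apply(seqs, 1L, paste, collapse = "")
      # connected triplets: an edge (i, j) plus a third node adjacent to
      # either endpoint
      seen <- character(0L)
      for (e in seq_len(nrow(E))) {
        i <- E[e, 1L]; j <- E[e, 2L]
        thirds <- setdiff(which(adj[i, ] | adj[j, ]), c(i, j))
        for (k in thirds) {
          tkey <- paste(sort(c(i, j, k)), collapse = "-")
          if (tkey %in% seen) next
          seen <- c(seen, tkey)
          m <- triplet_median(seqs[i, ], seqs[j, ], seqs[k, ])
          if (is.null(m)) next
          mkey <- paste(m, collapse = "")
          if (mkey %in% node_keys) next
          dm <- sum(m != seqs[i, ]) + sum(m != seqs[j, ]) + sum(m != seqs[k, ])
          dd <- sort(c(D[i, j], D[i, k], D[j, k]))
          gain <- (dd[1L] + dd[2L]) - dm   # local Steiner cost reduction
          if (gain > 0 && (is.null(best) || gain > best$gain ||
                           (gain == best$gain && mkey < best$key))) {
            best <- list(gain = gain, key = mkey, m = m)
          }
        }
      }
    }
    if (is.null(best)) break
    seqs <- rbind(seqs, best$m)
    rownames(seqs)[nrow(seqs)] <- paste0("MV", sum(inferred) + 1L)
    multiplicity <- c(multiplicity, 0L)
    clade_counts <- c(clade_counts, list(table(character(0L))))
    inferred <- c(inferred, TRUE)
  }

  # final edge set, then prune inferred nodes of degree <= 2
  D <- hamming_all(seqs)
  E <- msn_edges(D, epsilon)
  edges <- as.data.frame(E)
  repeat {
    deg <- tabulate(c(edges$from, edges$to), nbins = nrow(seqs))
    drop <- which(inferred & deg <= 2L)
    if (!length(drop)) break
    v <- drop[1L]
    inc <- which(edges$from == v | edges$to == v)
    nbr <- setdiff(unique(c(edges$from[inc], edges$to[inc])), v)
    w <- sum(edges$weight[inc])
    edges <- edges[-inc, , drop = FALSE]
    if (length(nbr) == 2L) {  # merge through the removed node
      a <- min(nbr); b <- max(nbr)
      ex <- which(edges$from == a & edges$to == b)
      if (length(ex)) edges$weight[ex] <- min(edges$weight[ex], w)
      else edges <- rbind(edges, data.frame(from = a, to = b, weight = w))
    }
    # reindex: drop node v
    keep <- setdiff(seq_len(nrow(seqs)), v)
    remap <- match(seq_len(nrow(seqs)), keep)
    seqs <- seqs[keep, , drop = FALSE]
    multiplicity <- multiplicity[keep]
    clade_counts <- clade_counts[keep]
    inferred <- inferred[keep]
    edges$from <- remap[edges$from]; edges$to <- remap[edges$to]
  }
  rownames(edges) <- NULL
  structure(list(seqs = seqs, multiplicity = multiplicity,
                 inferred = inferred, clade_counts = clade_counts,
                 edges = edges, epsilon = epsilon),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("<haplo_network> ", sum(!x$inferred), " observed + ", sum(x$inferred),
      " median nodes, ", nrow(x$edges), " edges, total cost ",
      mj_network_cost(x), "\n", sep = "")
  invisible(x)
}

#' Total connection cost of a network
#'
#' Weight of a minimum spanning tree over the network's nodes (observed +
#' median vectors) under Hamming distance; with no medians this equals the
#' plain MST cost of the observed haplotypes.
#'
#' @param net a `haplo_network`.
#' @export
mj_network_cost <- function(net) {
  D <- hamming_all(net$seqs)
  mst_cost(D)
}

# Prim's MST total weight.
mst_cost <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  cost <- 0
  for (step in seq_len(n - 1L)) {
    sub <- D[in_tree, !in_tree, drop = FALSE]
    cost <- cost + min(sub)
    j <- which(!in_tree)[which(sub == min(sub), arr.ind = TRUE)[1L, 2L]]
    in_tree[j] <- TRUE
  }
  cost
}

#' Nearest labeled clade of a haplotype
#'
#' Assigns a haplotype to the clade of its minimum-Hamming neighbour in a
#' labeled haplotype pool; a tie across different clades yields `UNKNOWN`.
#' Sites missing in the query are excluded from each comparison.
#'
#' @param hap character (or allele) vector; `NA` allowed.
#' @param pool matrix of labeled haplotypes; `NA` sites are skipped per
#'   comparison.
#' @param pool_clades clade label per pool row.
#' @return list with `clade` and `distance`.
#' @export
nearest_clade <- function(hap, pool, pool_clades) {
  if (!nrow(pool)) stop("empty labeled haplotype pool")
  ok <- !is.na(hap)
  d <- vapply(seq_len(nrow(pool)),
              function(r) sum(pool[r, ok] != hap[ok], na.rm = TRUE),
              numeric(1L))
  dmin <- min(d)
  cl <- unique(pool_clades[d == dmin])
  list(clade = if (length(cl) == 1L) cl else "UNKNOWN", distance = dmin)
}

#' Convert a haplotype network to an igraph graph
#' @param net a `haplo_network`.
#' @export
as_igraph <- function(net) {
  n <- nrow(net$seqs)
  shares <- vapply(seq_len(n), function(i) {
    tb <- net$clade_counts[[i]]
    if (!length(tb)) "" else paste(names(tb), as.integer(tb), sep = ":", collapse = ",")
  }, character(1L))
  verts <- data.frame(name = rownames(net$seqs),
                      multiplicity = net$multiplicity,
                      inferred = as.integer(net$inferred),
                      cladeshares = shares,
                      stringsAsFactors = FALSE)
  ed <- data.frame(from = rownames(net$seqs)[net$edges$from],
                   to = rownames(net$seqs)[net$edges$to],
                   weight = net$edges$weight)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}
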