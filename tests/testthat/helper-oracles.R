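# Independent brute-force oracles. These are written directly from the
# textbook definitions and share no code with the package implementations.

# --- diversity statistics on a complete-data haplotype character matrix ----

oracle_S <- function(h) {
  sum(vapply(seq_len(ncol(h)), function(j) length(unique(h[, j])) > 1L,
             logical(1L)))
}

oracle_theta_w <- function(h, L = ncol(h)) {
  n <- nrow(h)
  oracle_S(h) / (sum(1 / seq_len(n - 1L)) * L)
}

oracle_pi <- function(h, L = ncol(h)) {
  n <- nrow(h)
  tot <- 0; np <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + sum(h[i, ] != h[j, ]) / L
    np <- np + 1
  }
  tot / np
}

oracle_mean_pairwise_count <- function(h) {
  n <- nrow(h)
  tot <- 0; np <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + sum(h[i, ] != h[j, ])
    np <- np + 1
  }
  tot / np
}

oracle_he <- function(h) {
  n <- nrow(h)
  counts <- table(apply(h, 1L, paste, collapse = ""))
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

oracle_tajima_d <- function(h) {
  n <- nrow(h)
  S <- oracle_S(h)
  if (S == 0L) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1L)); a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (oracle_mean_pairwise_count(h) - S / a1) /
    sqrt(e1 * S + e2 * S * (S - 1))
}

# random complete haplotype alignment with at least one segregating site
random_hap_matrix <- function(n, S) {
  repeat {
    h <- matrix(sample(c("A", "C", "G", "T"), n * S, replace = TRUE,
                       prob = c(0.4, 0.1, 0.1, 0.4)), n, S)
    # make most columns monomorphic so S is moderate
    mono <- runif(S) < 0.5
    h[, mono] <- matrix(rep(h[1L, mono], each = n), n)
    if (oracle_S(h) >= 1L) return(h)
  }
}

# --- neutral coalescent haplotypes (infinite sites) ------------------------
# Coalescent genealogy from ape::rcoal; mutations dropped on branches at
# rate theta/2 per coalescent time unit; one new biallelic column each.
coalescent_haplotypes <- function(n, theta) {
  tr <- ape::rcoal(n)
  desc <- vector("list", n + tr$Nnode)
  for (v in seq_len(n)) desc[[v]] <- v
  # accumulate tip descendants bottom-up
  for (e in ape::postorder(tr)) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  cols <- list()
  for (e in seq_len(nrow(tr$edge))) {
    k <- rpois(1L, theta / 2 * tr$edge.length[e])
    carriers <- desc[[tr$edge[e, 2L]]]
    if (k > 0L && length(carriers) < n)
      for (m in seq_len(k)) {
        col <- rep("A", n); col[carriers] <- "T"
        cols[[length(cols) + 1L]] <- col
      }
  }
  if (!length(cols)) matrix("A", n, 1L) else do.call(cbind, cols)
}

# --- brute-force Steiner minimum for haplotype networks --------------------
# Minimum total MST weight over the observed binary haplotypes plus at most
# max_extra added candidate points. Candidates are all binary strings over
# the sites that vary among the observed haplotypes (a Steiner point
# deviating at an invariant site can always be improved by matching it, so
# this restriction is lossless).
oracle_steiner_min <- function(h, max_extra = 2L) {
  hm <- matrix(as.integer(h == "1"), nrow(h))
  S <- ncol(hm)
  variable <- which(colSums(hm) %% nrow(hm) != 0L)
  base <- hm[1L, ]
  cand_var <- as.matrix(expand.grid(rep(list(0:1), length(variable))))
  cand <- matrix(rep(base, each = nrow(cand_var)), nrow(cand_var), S)
  cand[, variable] <- as.matrix(cand_var)
  key_obs <- do.call(paste0, as.data.frame(hm))
  key_cand <- do.call(paste0, as.data.frame(cand))
  cand <- cand[!(key_cand %in% key_obs) & !duplicated(key_cand), ,
               drop = FALSE]
  all_pts <- rbind(hm, cand)
  m <- nrow(all_pts)
  Dall <- all_pts %*% t(1 - all_pts) + (1 - all_pts) %*% t(all_pts)
  n_obs <- nrow(hm)
  mst_w <- function(nodes) {
    D <- Dall[nodes, nodes, drop = FALSE]
    n <- length(nodes)
    if (n < 2L) return(0)
    dist_to_tree <- D[1L, ]
    used <- c(TRUE, rep(FALSE, n - 1L))
    w <- 0
    for (s in seq_len(n - 1L)) {
      j <- which(!used)[which.min(dist_to_tree[!used])]
      w <- w + dist_to_tree[j]
      used[j] <- TRUE
      dist_to_tree <- pmin(dist_to_tree, D[j, ])
    }
    w
  }
  best <- mst_w(seq_len(n_obs))
  extra <- setdiff(seq_len(m), seq_len(n_obs))
  if (max_extra >= 1L) for (i in extra)
    best <- min(best, mst_w(c(seq_len(n_obs), i)))
  if (max_extra >= 2L && length(extra) >= 2L)
    for (a in seq_len(length(extra) - 1L)) for (b in (a + 1L):length(extra)) {
      best <- min(best, mst_w(c(seq_len(n_obs), extra[a], extra[b])))
    }
  best
}

# --- exhaustive NJ check ---------------------------------------------------
# Least-squares branch fit of a distance matrix on a fixed topology; returns
# the residual sum of squares and fitted tree distances.
oracle_ls_fit <- function(topo, D) {
  tips <- rownames(D)
  n <- length(tips)
  pairs <- utils::combn(n, 2L)
  A <- matrix(0, ncol(pairs), nrow(topo$edge))
  for (k in seq_len(ncol(pairs))) {
    i <- match(tips[pairs[1L, k]], topo$tip.label)
    j <- match(tips[pairs[2L, k]], topo$tip.label)
    path <- oracle_tip_path(topo, i, j)
    A[k, path] <- 1
  }
  d <- D[t(pairs)]
  fit <- stats::lm.fit(A, d)
  sum(fit$residuals^2)
}

oracle_tip_path <- function(tr, i, j) {
  # edge indices on the path between tips i and j
  parent <- integer(max(tr$edge))
  pedge <- integer(max(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    parent[tr$edge[e, 2L]] <- tr$edge[e, 1L]
    pedge[tr$edge[e, 2L]] <- e
  }
  anc <- function(v) {
    out <- v
    while (parent[v] != 0L) { v <- parent[v]; out <- c(out, v) }
    out
  }
  ai <- anc(i); aj <- anc(j)
  mrca <- intersect(ai, aj)[1L]
  nodes <- c(ai[seq_len(match(mrca, ai) - 1L)],
             aj[seq_len(match(mrca, aj) - 1L)])
  pedge[nodes]
}

# a random additive distance matrix together with its generating topology
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 3)
  D <- ape::cophenetic.phylo(tr)
  D <- D[sort(rownames(D)), sort(rownames(D))]
  list(D = D, tree = tr)
}
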