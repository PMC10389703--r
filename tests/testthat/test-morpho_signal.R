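test_that("trait preparation: medians, left/right averaging, circularity", {
  raw <- data.frame(
    accession_id = rep(c("a", "b"), each = 3L),
    leaf = rep(1:3, 2L),
    vein = c(1, 2, 9, 4, 4, 4),
    ang_L = c(10, 10, 10, 20, 22, 24),
    ang_R = c(30, 30, 30, 26, 28, 30),
    area = rep(pi * 4, 6L),       # circle of radius 2
    perimeter = rep(2 * pi * 2, 6L))
  expect_warning(tt <- prepare_traits(raw, min_leaves = 4L), "fewer than 4")
  tt <- suppressWarnings(prepare_traits(raw))
  expect_equal(tt$values["a", "vein"], 2)           # median of 1,2,9
  expect_equal(tt$values["a", "ang"], (10 + 30) / 2)  # medians then average
  expect_equal(tt$values["b", "ang"], (22 + 28) / 2)
  expect_equal(unname(tt$values[, "Circ"]), c(1, 1), tolerance = 1e-12)
  # single leaf: median is that leaf
  raw1 <- raw[raw$leaf == 1L, ]
  tt1 <- suppressWarnings(prepare_traits(raw1))
  expect_equal(tt1$values["a", "vein"], 1)
})

test_that("PCA degenerate cases and variance bookkeeping", {
  one <- trait_table(matrix(rnorm(6), 6L, 1L,
                            dimnames = list(paste0("a", 1:6), "t1")), "length")
  p1 <- trait_pca(one)
  expect_equal(p1$percent, 100)
  x <- rnorm(8)
  two <- trait_table(cbind(t1 = x, t2 = 2 * x) |>
                       `rownames<-`(paste0("a", 1:8)), c("length", "length"))
  p2 <- trait_pca(two)
  expect_equal(p2$percent, c(100, 0), tolerance = 1e-9)
  set.seed(2)
  m <- matrix(rnorm(60), 10L, 6L,
              dimnames = list(paste0("a", 1:10), paste0("t", 1:6)))
  p3 <- trait_pca(trait_table(m, rep("length", 6L)))
  expect_equal(sum(p3$percent), 100, tolerance = 1e-9)
  expect_true(all(diff(p3$eigenvalues) <= 1e-12))
  expect_lt(max(abs(crossprod(p3$scores)[lower.tri(matrix(0, 6, 6))])), 1e-8)
  # zero-variance trait dropped when scaling
  m2 <- cbind(m, const = 1)
  expect_message(p4 <- trait_pca(trait_table(m2, rep("length", 7L))), "zero-variance")
  expect_equal(nrow(p4$loadings), 6L)
})

test_that("Abouheif proximity: star closed form and cherry ordering", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  pr <- abouheif_proximity(star)
  off <- pr$raw[upper.tri(pr$raw)]
  expect_true(all(abs(off - off[1]) < 1e-12))
  expect_equal(unname(diag(pr$raw)), rep(0, 5))
  cherry <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  pc <- abouheif_proximity(cherry)
  expect_gt(pc$raw["a", "b"], pc$raw["a", "c"])
  expect_error(abouheif_proximity(cherry, tips = c("a", "zz")), "missing")
  expect_error(abouheif_proximity(ape::read.tree(text = "(a:1,b:1);"),
                                  tips = "a"), ">= 2 tips")
})

test_that("on a star tree the Moran statistic reduces to -1/(n-1) for any trait", {
  star <- ape::read.tree(text = paste0("(", paste0("t", 1:12, ":1", collapse = ","), ");"))
  pr <- abouheif_proximity(star)
  set.seed(3)
  for (r in 1:5) {
    z <- stats::setNames(rnorm(12), paste0("t", 1:12))
    res <- abouheif_test(z, pr, n_perm = 19L, seed = r)
    expect_equal(res$cmean, -1 / 11, tolerance = 1e-10)
  }
})

test_that("permutation p-values are valid and constant traits are flagged", {
  tr <- ape::compute.brlen(ape::stree(16, "balanced"), 1)
  pr <- abouheif_proximity(tr)
  const <- abouheif_test(stats::setNames(rep(1, 16), tr$tip.label), pr)
  expect_true(is.na(const$cmean))
  # p-value formula has the add-one correction
  z <- stats::setNames(rnorm(16), tr$tip.label)
  res <- abouheif_test(z, pr, n_perm = 99L, seed = 1)
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
  expect_identical(res, abouheif_test(z, pr, n_perm = 99L, seed = 1))
})

test_that("pPCA with a uniform (star) proximity spans the PCA axes", {
  set.seed(4)
  star <- ape::read.tree(text = paste0("(", paste0("a", 1:15, ":1", collapse = ","), ");"))
  m <- matrix(rnorm(15 * 5), 15L, 5L,
              dimnames = list(paste0("a", 1:15), paste0("t", 1:5)))
  tt <- trait_table(m, rep("length", 5L))
  pr <- abouheif_proximity(star)
  pp <- ppca(tt, pr)
  pc <- trait_pca(tt)
  # uniform W on centered data gives -X'X/(n-1): same eigenvectors, reversed
  # eigenvalue order; compare axis subspaces by absolute correlations
  cors <- abs(diag(stats::cor(pp$loadings[, ncol(pp$loadings):1],
                              pc$loadings)))
  expect_true(all(cors > 1 - 1e-8))
  expect_true(all(pp$eigenvalues < 1e-12))  # a star has no global structure
})

test_that("top-loading selection keeps the 10/90 percentile extremes", {
  lds <- matrix(c(sort(rnorm(20)), rnorm(20)), 20L, 2L,
                dimnames = list(paste0("t", 1:20), c("PC1", "PC2")))
  sel <- select_top_loadings(lds)
  q <- stats::quantile(lds[, 1L], c(0.1, 0.9), names = FALSE)
  expect_setequal(sel, rownames(lds)[lds[, 1L] < q[1] | lds[, 1L] > q[2]])
  small <- lds[1:6, , drop = FALSE]
  expect_message(sel2 <- select_top_loadings(small), "fewer than 10")
  expect_equal(sel2, rownames(small))
})

test_that("Brownian traits on the simulated tree carry detectable signal", {
  sim <- small_sim()
  keep <- sim$accessions$accession_id[!grepl("^HYB", sim$accessions$accession_id)]
  pr <- abouheif_proximity(sim$tree, tips = keep)
  tt <- trait_table(sim$leaf_traits$values[keep, , drop = FALSE],
                    sim$leaf_traits$trait_type)
  tab <- phylo_signal_table(tt, pr, n_perm = 199L, seed = 1)
  expect_equal(nrow(tab), ncol(tt$values))
  expect_gt(mean(tab$p_value < 0.05), 0.5)
})
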