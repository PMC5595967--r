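# Fingerprint distances, complete-linkage clustering, the Z-score display
# transform and the ordered heatmap matrix.

test_that("fingerprint distances are Euclidean on raw percentages", {
  fps <- tibble::tibble(compound = c("a", "b"),
                        g1 = c(55, 52), s = c(10, 6),
                        g2m = c(30, 30), subg1 = c(5, 5))
  d <- fingerprint_dist(fps)
  expect_equal(as.numeric(d), 5) # 3-4-5
  same <- fingerprint_dist(fps[c(1, 1), ])
  expect_equal(as.numeric(same), 0)
})

test_that("fingerprint distances satisfy metric properties", {
  set.seed(3)
  fps <- tibble::tibble(
    compound = sprintf("c%03d", 1:100),
    g1 = NA_real_, s = NA_real_, g2m = NA_real_, subg1 = NA_real_
  )
  m <- t(replicate(100, random_fingerprint()))
  fps[, c("g1", "s", "g2m", "subg1")] <- as.data.frame(m)
  dm <- as.matrix(fingerprint_dist(fps))
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  for (i in 1:50) {
    ijk <- sample(100, 3)
    expect_lte(dm[ijk[1], ijk[3]],
               dm[ijk[1], ijk[2]] + dm[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("complete linkage reproduces hand-solved toy cases", {
  # two leaves at distance d: a single merge at height d
  d2 <- dist(c(0, 7))
  t2 <- complete_linkage(d2)
  expect_equal(nrow(t2$merges), 1)
  expect_equal(t2$merges$height, 7)
  # 1-D points {0, 1, 10}: merge (0,1) at height 1, then at height 10
  t3 <- complete_linkage(dist(c(0, 1, 10)))
  expect_equal(t3$merges$height, c(1, 10))
  expect_setequal(c(t3$merges$a[1], t3$merges$b[1]), c(-1L, -2L))
})

test_that("complete linkage matches the brute-force oracle for n <= 8", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    pts <- matrix(rnorm(n * 2), ncol = 2)
    d <- dist(pts)
    tree <- complete_linkage(d)
    expect_equal(tree$merges$height, bf_complete_heights(d), tolerance = 1e-9)
  }
})

test_that("merge heights are non-decreasing and permutation-invariant", {
  set.seed(13)
  pts <- matrix(rnorm(16), ncol = 2)
  tree <- complete_linkage(dist(pts))
  expect_true(all(diff(tree$merges$height) >= -1e-12))
  expect_setequal(tree$leaf_order, seq_len(nrow(pts)))
  perm <- sample(nrow(pts))
  tree_p <- complete_linkage(dist(pts[perm, ]))
  expect_equal(sort(tree_p$merges$height), sort(tree$merges$height),
               tolerance = 1e-12)
})

test_that("invalid distance input is rejected", {
  m <- matrix(c(0, 1, 2, 0), 2)
  expect_error(complete_linkage(m), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2)
  expect_error(complete_linkage(neg), "non-negative")
})

test_that("Z-score transform normalises each fingerprint row exactly", {
  row <- tibble::tibble(compound = "x", g1 = 1, s = 2, g2m = 3, subg1 = 4)
  z <- zscore_transform(row)
  expect_equal(unlist(z[1, c("g1", "s", "g2m", "subg1")]),
               c(g1 = -1.1619, s = -0.3873, g2m = 0.3873, subg1 = 1.1619),
               tolerance = 1e-4)
  # every non-degenerate row has mean 0 and sample sd 1
  set.seed(5)
  fps <- tibble::tibble(compound = sprintf("r%d", 1:20),
                        g1 = runif(20, 0, 60), s = runif(20, 0, 30),
                        g2m = runif(20, 0, 60), subg1 = runif(20, 0, 20))
  zm <- as.matrix(zscore_transform(fps)[, c("g1", "s", "g2m", "subg1")])
  expect_equal(unname(rowMeans(zm)), rep(0, 20), tolerance = 1e-12)
  expect_equal(unname(apply(zm, 1, sd)), rep(1, 20), tolerance = 1e-12)
  # constant row maps to zeros with a warning
  flat <- tibble::tibble(compound = "flat", g1 = 25, s = 25, g2m = 25, subg1 = 25)
  expect_warning(zf <- zscore_transform(flat), "zero-variance")
  expect_equal(unname(unlist(zf[1, c("g1", "s", "g2m", "subg1")])), rep(0, 4))
})

test_that("the ordered matrix follows the dendrogram leaf order", {
  set.seed(17)
  fps <- tibble::tibble(compound = sprintf("d%02d", 1:6),
                        g1 = runif(6, 10, 60), s = runif(6, 0, 20),
                        g2m = runif(6, 10, 60), subg1 = runif(6, 0, 15))
  fps[, c("g1", "s", "g2m", "subg1")] <-
    100 * fps[, c("g1", "s", "g2m", "subg1")] /
    rowSums(fps[, c("g1", "s", "g2m", "subg1")])
  tree <- cluster_fingerprints(fps)
  z <- zscore_transform(fps)
  ord <- ordered_matrix(tree, z)
  expect_equal(ord$compound, fps$compound[tree$leaf_order])
  expect_equal(nrow(ord), 6)
  # deterministic: same inputs, same ordered matrix
  ord2 <- ordered_matrix(cluster_fingerprints(fps), zscore_transform(fps))
  expect_identical(ord, ord2)
  expect_error(ordered_matrix(tree, z[1:3, ]), "dimension mismatch")
})

test_that("clustering operates on raw fingerprints, not the Z-scored display", {
  # two drugs with identical Z-scores but very different raw magnitudes must
  # not be at distance zero
  fps <- tibble::tibble(compound = c("small", "large"),
                        g1 = c(26, 10), s = c(24, 30),
                        g2m = c(26, 10), subg1 = c(24, 50))
  dz <- dist(as.matrix(zscore_transform(fps)[, c("g1", "s", "g2m", "subg1")]))
  draw <- fingerprint_dist(fps)
  expect_gt(as.numeric(draw), 1)
  expect_gt(as.numeric(draw), as.numeric(dz))
})

test_that("heatmap plot builds and tree exports round-trip", {
  set.seed(19)
  fps <- tibble::tibble(compound = sprintf("h%d", 1:5),
                        g1 = runif(5, 20, 60), s = runif(5, 5, 20),
                        g2m = runif(5, 20, 60), subg1 = runif(5, 0, 10))
  tree <- cluster_fingerprints(fps)
  p <- plot_fingerprint_heatmap(tree, zscore_transform(fps))
  expect_s3_class(p, "ggplot")
  tmp <- tempfile(fileext = ".nwk")
  write_newick(tree, tmp)
  expect_true(file.exists(tmp))
  nwk <- readLines(tmp)
  expect_true(all(sapply(fps$compound, grepl, x = nwk[1], fixed = TRUE)))
  tmp2 <- tempfile(fileext = ".csv")
  write_merges(tree, tmp2)
  back <- readr::read_csv(tmp2, show_col_types = FALSE)
  expect_equal(back$height, tree$merges$height)
  glc <- glance(tree)
  expect_equal(glc$n_leaves, 5)
  expect_equal(glc$n_merges, 4)
})
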