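test_that("PCA matches a direct eigendecomposition of the correlation matrix", {
  set.seed(31)
  x <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4),
                                               c("a", "b", "c")))
  p <- runPCA(x)
  oracle <- eigen(cor(x), symmetric = TRUE)$values
  expect_equal(p$eigenvalues, oracle, tolerance = 1e-10)
  # trace conservation: eigenvalues sum to the number of variables
  expect_equal(sum(p$eigenvalues), 3, tolerance = 1e-10)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
  # score columns are uncorrelated
  expect_lt(max(abs(cov(p$scores)[lower.tri(diag(3))])), 1e-10)
  # sign convention: largest-magnitude loading positive
  for (cc in 1:3) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, cc])), cc], 0)
  }

  # rank-1 case: two perfectly correlated variables
  y <- cbind(v1 = 1:5, v2 = 2 * (1:5) + 3)
  p1 <- runPCA(y)
  expect_equal(p1$eigenvalues, c(2, 0), tolerance = 1e-10)
  expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-10)

  z <- cbind(v1 = 1:5, flat = rep(2, 5))
  expect_error(runPCA(z), "flat")
})

test_that("eigenvalue weighting gives columns variance = eigenvalue", {
  set.seed(32)
  x <- matrix(rnorm(60), 12, 5)
  colnames(x) <- paste0("v", 1:5)
  p <- runPCA(x)
  w <- weightScores(p, 5)
  for (cc in 1:5) {
    expect_equal(var(w[, cc]), p$eigenvalues[cc], tolerance = 1e-10)
  }
  # all components: pairwise squared distances equal those on the
  # standardized variable matrix (Parseval-type identity)
  xs <- scale(x)
  expect_equal(as.matrix(dist(w)), as.matrix(dist(xs)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # degenerate axis is identically zero
  y <- cbind(v1 = rnorm(6), v2 = rnorm(6))
  y <- cbind(y, v3 = y[, 1] + y[, 2])  # rank 2: third eigenvalue 0
  pw <- weightScores(runPCA(y), 3)
  expect_true(all(pw[, 3] == 0))
  expect_error(weightScores(p, 0), "positive")
})

test_that("Calinski-Harabasz agrees with hand-computed sums of squares", {
  # 6 points in 1-D, labels {1,1,1,2,2,2}: B and W by hand
  pts <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  lab <- c(1, 1, 1, 2, 2, 2)
  # group means 1 and 11, grand mean 6: B = 3*25 + 3*25 = 150; W = 2 + 2 = 4
  ch <- cwpsoil:::calinskiHarabasz(pts, lab)
  expect_equal(ch, (150 / 1) / (4 / 4), tolerance = 1e-12)
})

test_that("the K-means cascade recovers planted cluster counts", {
  set.seed(33)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  pts <- do.call(rbind, lapply(1:4, function(g) {
    sweep(matrix(rnorm(20, 0, 0.3), 10, 2), 2, centers[g, ], `+`)
  }))
  rownames(pts) <- paste0("p", 1:40)
  eco <- selectEcoregions(pts, 2:8, seed = 34)
  expect_identical(eco$k_selected, 4L)
  expect_identical(unname(eco$k_selected),
                   as.integer(names(which.max(eco$ch_values))))
  # labels relabelled by descending size: label 1 is the largest cluster
  sizes <- table(eco$labels)
  expect_true(all(diff(as.integer(sizes)) <= 0))

  # two coincident point clouds: CH maximal at k = 2
  two <- rbind(matrix(rnorm(30, 0, 0.2), 15, 2),
               matrix(rnorm(30, 8, 0.2), 15, 2))
  rownames(two) <- paste0("q", 1:30)
  eco2 <- selectEcoregions(two, 2:5, seed = 35)
  expect_identical(eco2$k_selected, 2L)

  expect_error(selectEcoregions(pts, 1:4), "k = 1")
})

test_that("axis tests combine signed-rank p-values with Bonferroni letters", {
  # all-positive scores, n = 10: exact two-sided signed-rank p = 2/1024
  sc <- cbind(PC1 = c(seq(1, 5.5, by = 0.5), -seq(1, 5.5, by = 0.5)),
              PC2 = c(-1, 1, -2, 2, rep(c(-0.5, 0.5), 8)))
  rownames(sc) <- sprintf("s%02d", 1:20)
  sites <- data.frame(site_id = rownames(sc),
                      cwp_species = rep(c("cwpA", "cwpB"), each = 10),
                      latitude = 0, longitude = 0)
  res <- testAxisDifferences(sc, sites, nAxes = 2)
  p1 <- res$wilcoxon_p[res$cwp_species == "cwpA" & res$axis == 1]
  expect_equal(p1, 2 / 1024, tolerance = 1e-12)
  # symmetric scores around zero are non-significant
  pSym <- res$wilcoxon_p[res$cwp_species == "cwpA" & res$axis == 2]
  expect_gt(pSym, 0.95)
  # opposite groups on PC1 get different letters; equal distributions on a
  # shared axis keep the same letter
  l1 <- res$letter[res$axis == 1]
  expect_false(l1[1] == l1[2])
  sc2 <- cbind(PC1 = rep(c(-1, 0, 1, 2), 5))
  rownames(sc2) <- sprintf("s%02d", 1:20)
  res2 <- testAxisDifferences(sc2, sites, nAxes = 1)
  expect_identical(res2$letter[1], res2$letter[2])
})
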