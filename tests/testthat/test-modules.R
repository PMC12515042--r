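test_that("within-site standardization follows the printed formula", {
  x <- matrix(c(2, 4, 6), nrow = 1, dimnames = list("p1", paste0("t", 1:3)))
  z <- moduleZscore(x)$z
  expect_equal(unname(z[1, ]), c(-1, 0, 1), tolerance = 1e-12)

  const <- matrix(5, 2, 3, dimnames = list(paste0("p", 1:2),
                                           paste0("t", 1:3)))
  expect_warning(zc <- moduleZscore(const), "zero-spread")
  expect_true(all(zc$z == 0))

  expect_error(moduleZscore(matrix(1:3, 3, 1)), "standardize")

  set.seed(41)
  big <- matrix(rnorm(500), 10, 50,
                dimnames = list(paste0("p", 1:10), paste0("t", 1:50)))
  zb <- moduleZscore(big)$z
  expect_lt(max(abs(rowMeans(zb))), 1e-12)
  expect_lt(max(abs(apply(zb, 1, sd) - 1)), 1e-12)

  # per-taxon alternative standardizes columns across populations
  zt <- moduleZscore(big, margin = "taxon")$z
  expect_lt(max(abs(colMeans(zt))), 1e-12)
  expect_lt(max(abs(apply(zt, 2, sd) - 1)), 1e-12)
})

test_that("module abundances average z-scores per module and site", {
  x <- matrix(c(2, 4, 6,
                1, 5, 3), nrow = 2, byrow = TRUE,
              dimnames = list(paste0("p", 1:2), c("tA", "tB", "tC")))
  z <- moduleZscore(x)$z
  mem <- c(tA = 1L, tB = 1L, tC = 2L)
  ma <- moduleAbundance(z, mem)
  # hand-computed: p1 z = (-1, 0, 1); p2 z = (-1, 1, 0)
  expect_equal(unname(ma[, "1"]), c(mean(c(-1, 0)), mean(c(-1, 1))),
               tolerance = 1e-12)
  expect_equal(unname(ma[, "2"]), c(1, 0), tolerance = 1e-12)
  # singleton module column equals the taxon's z column
  expect_equal(unname(ma[, "2"]), unname(z[, "tC"]))
  # all taxa in one module: row-mean of z is 0 for every site
  all1 <- moduleAbundance(z, c(tA = 1L, tB = 1L, tC = 1L))
  expect_lt(max(abs(all1)), 1e-12)
  # size-weighted module means per site sum to zero when modules partition
  # all standardized taxa
  sizes <- table(mem)
  weighted <- ma %*% as.integer(sizes[colnames(ma)])
  expect_lt(max(abs(weighted)), 1e-12)
  expect_error(moduleAbundance(z, c(tA = 1L)), "cover")
})

test_that("module completeness counts present nodes per population", {
  pres <- matrix(c(1, 1, 0,
                   1, 0, 0,
                   0, 1, 1,
                   0, 1, 0), nrow = 4, byrow = TRUE,
                 dimnames = list(c("a", "b", "c", "d"), paste0("p", 1:3)))
  mem <- c(a = 1L, b = 1L, c = 1L, d = 1L)
  eco <- setNames(c("E1", "E1", "E2"), paste0("p", 1:3))
  comp <- moduleCompleteness(pres, mem, eco)
  byPop <- comp$by_population
  expect_equal(byPop$completeness[byPop$site_id == "p1"], 0.5)
  expect_equal(byPop$completeness[byPop$site_id == "p2"], 0.75)
  expect_equal(comp$by_ecoregion$mean_completeness[
    comp$by_ecoregion$ecoregion == "E1"], mean(c(0.5, 0.75)))
  expect_identical(comp$by_ecoregion$n_populations[
    comp$by_ecoregion$ecoregion == "E1"], 2L)
  # full presence means completeness 1 everywhere
  compFull <- moduleCompleteness(pres * 0 + 1, mem, eco)
  expect_true(all(compFull$by_ecoregion$mean_completeness == 1))
  # adding presences never decreases completeness
  pres2 <- pres; pres2["d", "p1"] <- 1
  comp2 <- moduleCompleteness(pres2, mem, eco)
  expect_true(all(comp2$by_population$completeness >=
                    byPop$completeness))
})

test_that("group comparisons produce Bonferroni letters", {
  set.seed(43)
  # two identical groups share a letter
  v <- rep(rnorm(8), 2)
  g <- rep(c("A", "B"), each = 8)
  res <- compareGroups(v, g)
  expect_identical(unname(res$letters["A"]), unname(res$letters["B"]))
  expect_true(all(res$pairwise$p.value > 0.99))
  # well-separated groups get different letters
  v2 <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  res2 <- compareGroups(v2, rep(c("A", "B"), each = 10))
  expect_false(res2$letters[["A"]] == res2$letters[["B"]])
  # three groups, two equal + one shifted: letter pattern {a, a, b}
  v3 <- c(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1), rnorm(10, 5, 0.1))
  res3 <- compareGroups(v3, rep(c("A", "B", "C"), each = 10))
  expect_identical(unname(res3$letters["A"]), unname(res3$letters["B"]))
  expect_false(res3$letters[["A"]] == res3$letters[["C"]])
  # letters invariant to group ordering
  ord <- sample(30)
  res4 <- compareGroups(v3[ord], rep(c("A", "B", "C"), each = 10)[ord])
  expect_identical(res4$letters, res3$letters)
  # singleton groups are excluded with a warning
  expect_warning(compareGroups(c(v2, 1), c(rep(c("A", "B"), each = 10),
                                           "C")), "single")
})
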