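test_that("co-presence tail probabilities match closed forms", {
  # N=10, both taxa in 5 sites, all 5 shared: C(5,5)C(5,0)/C(10,5) = 1/252
  expect_equal(copresencePvalue(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  # saturated taxon: co-presence forced, never significant
  expect_equal(copresencePvalue(12, 12, 7, 7), 1, tolerance = 1e-12)
  # tail from the feasible minimum is the whole distribution
  expect_equal(copresencePvalue(20, 8, 9, 0), 1, tolerance = 1e-12)
  # identical presence in 5 of 20 sites: 1/C(20,5)
  expect_equal(copresencePvalue(20, 5, 5, 5), 1 / choose(20, 5),
               tolerance = 1e-12)
  # symmetry in the two taxa
  expect_equal(copresencePvalue(30, 12, 7, 5), copresencePvalue(30, 7, 12, 5),
               tolerance = 1e-12)
  # nonincreasing in j (tail monotonicity)
  js <- 0:8
  ps <- copresencePvalue(25, 10, 8, js)
  expect_true(all(diff(ps) <= 1e-15))
  expect_error(copresencePvalue(10, 5, 5, 6), "feasible")
  # large-N stability in log space
  expect_true(is.finite(copresencePvalue(20000, 9000, 8000, 4300)))
  expect_gt(copresencePvalue(20000, 9000, 8000, 3600), 0)
})

test_that("network construction matches brute-force pair testing", {
  # 4-taxon, 8-site toy matrix; oracle enumerates the hypergeometric pmf
  pres <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0,
                   1, 1, 1, 1, 0, 0, 0, 0,
                   0, 0, 0, 0, 1, 1, 1, 0,
                   1, 0, 0, 0, 1, 1, 1, 1),
                 nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("t", 1:4), paste0("s", 1:8)))
  net <- buildNetwork(pres, alpha = 0.05)
  oracleEdges <- character(0)
  for (pair in combn(4, 2, simplify = FALSE)) {
    a <- pres[pair[1], ]; b <- pres[pair[2], ]
    p <- bruteForceTail(8, sum(a), sum(b), sum(a & b))
    if (p < 0.05) {
      oracleEdges <- c(oracleEdges,
                       paste(paste0("t", pair[1]), paste0("t", pair[2])))
    }
  }
  got <- paste(net@edges$taxon_a, net@edges$taxon_b)
  expect_setequal(got, oracleEdges)
  # disjoint taxa never get a co-presence edge
  expect_false("t1 t3" %in% got)
  # uninformative (absent or saturated) taxa are skipped but kept as nodes
  pres2 <- rbind(pres, t5 = rep(1, 8), t6 = rep(0, 8))
  net2 <- buildNetwork(pres2)
  expect_true(all(c("t5", "t6") %in% net2@nodes))
  expect_false(any(c("t5", "t6") %in%
                     c(net2@tests$taxon_a, net2@tests$taxon_b)))
  # edge set invariant under site permutation
  perm <- buildNetwork(pres[, sample(8)])
  expect_setequal(paste(perm@edges$taxon_a, perm@edges$taxon_b), got)
})

test_that("walktrap recovers planted communities and maximises modularity", {
  # two 4-cliques joined by a single bridge: the canonical instance
  nodes <- c(paste0("a", 1:4), paste0("b", 1:4))
  cliqueEdges <- function(v) t(combn(v, 2))
  em <- rbind(cliqueEdges(nodes[1:4]), cliqueEdges(nodes[5:8]),
              c("a1", "b1"))
  # presence matrix engineered so exactly these pairs are significant is
  # unnecessary here: construct the network object directly
  net <- new("CooccurrenceNetwork", kingdom = "toy", nodes = nodes,
             edges = data.frame(taxon_a = em[, 1], taxon_b = em[, 2],
                                j_obs = 1L, p_value = 0.01,
                                stringsAsFactors = FALSE),
             tests = data.frame(), membership = integer(0),
             modularity = NA_real_, mainModules = integer(0), alpha = 0.05)
  net <- detectModules(net, steps = 4, seed = 1)
  mem <- moduleMembership(net)
  expect_identical(length(unique(mem)), 2L)
  expect_identical(length(unique(mem[1:4])), 1L)
  expect_identical(length(unique(mem[5:8])), 1L)
  expect_gt(networkModularity(net), 0.3)

  # exhaustive oracle: walktrap's partition attains the maximum modularity
  # over all partitions of the 8 nodes
  g <- cwpsoil:::asIgraph(net)
  bestQ <- -Inf
  parts <- function(n) {  # restricted growth strings enumerate set partitions
    out <- list()
    rec <- function(prefix, maxLab) {
      if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
      for (lab in 1:(maxLab + 1)) rec(c(prefix, lab), max(maxLab, lab))
    }
    rec(integer(0), 0L)
    out
  }
  for (p in parts(8)) bestQ <- max(bestQ, igraph::modularity(g, p))
  expect_equal(networkModularity(net), bestQ, tolerance = 1e-10)

  # single clique collapses to one module
  one <- new("CooccurrenceNetwork", kingdom = "toy", nodes = nodes[1:4],
             edges = data.frame(taxon_a = cliqueEdges(nodes[1:4])[, 1],
                                taxon_b = cliqueEdges(nodes[1:4])[, 2],
                                j_obs = 1L, p_value = 0.01,
                                stringsAsFactors = FALSE),
             tests = data.frame(), membership = integer(0),
             modularity = NA_real_, mainModules = integer(0), alpha = 0.05)
  expect_identical(length(unique(moduleMembership(
    detectModules(one, seed = 1)))), 1L)

  # edgeless network: singleton modules, modularity 0 by convention
  none <- new("CooccurrenceNetwork", kingdom = "toy", nodes = c("x", "y"),
              edges = data.frame(taxon_a = character(0),
                                 taxon_b = character(0), j_obs = integer(0),
                                 p_value = numeric(0)),
              tests = data.frame(), membership = integer(0),
              modularity = NA_real_, mainModules = integer(0), alpha = 0.05)
  none <- detectModules(none, seed = 1)
  expect_identical(unname(moduleMembership(none)), 1:2)
  expect_identical(networkModularity(none), 0)
})

test_that("main-module flagging applies the size threshold", {
  nodes <- sprintf("n%02d", 1:12)
  mem <- setNames(c(rep(1L, 6), rep(2L, 4), 3L, 4L), nodes)
  net <- new("CooccurrenceNetwork", kingdom = "toy", nodes = nodes,
             edges = data.frame(taxon_a = character(0),
                                taxon_b = character(0), j_obs = integer(0),
                                p_value = numeric(0)),
             tests = data.frame(), membership = mem, modularity = 0,
             mainModules = integer(0), alpha = 0.05)
  expect_identical(mainModuleIds(mainModules(net, 5)), 1L)
  expect_identical(mainModuleIds(mainModules(net, 4)), c(1L, 2L))
  expect_identical(mainModuleIds(mainModules(net, 1)), 1:4)
})
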