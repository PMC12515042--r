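test_that("VIF filtering drops collinear predictors iteratively", {
  set.seed(51)
  n <- 200
  # orthogonal predictors: all VIF 1, nothing dropped
  q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  colnames(q) <- c("u", "v", "w")
  vf <- vifFilter(q, threshold = 5)
  expect_identical(sort(vf$retained), c("u", "v", "w"))
  expect_lt(max(abs(vf$vif - 1)), 0.01)  # orthonormal up to centering

  # correlation 0.9 gives VIF 1/(1-0.81) > 5: one of the pair is dropped
  x1 <- rnorm(n)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  # rescale to achieve exact sample correlation 0.9 via residual trick
  e <- resid(lm(x2 ~ x1))
  x2 <- 0.9 * scale(x1)[, 1] + sqrt(1 - 0.81) * scale(e)[, 1]
  pr <- cbind(a = scale(x1)[, 1], b = x2)
  r2 <- summary(lm(pr[, "b"] ~ pr[, "a"]))$r.squared
  expect_equal(1 / (1 - r2), 1 / (1 - 0.81), tolerance = 1e-6)
  vf2 <- vifFilter(pr, threshold = 5)
  expect_identical(length(vf2$retained), 1L)
  expect_identical(length(vf2$dropped), 1L)

  # exact duplicate: infinite VIF handled, one copy dropped first
  dup <- cbind(x = x1, y = rnorm(n), x_copy = x1)
  vf3 <- vifFilter(dup, threshold = 5)
  expect_identical(length(vf3$retained), 2L)
  expect_true(vf3$dropped[1] %in% c("x", "x_copy"))
  expect_true(all(is.finite(vf3$vif)))
})

test_that("the mixed model separates fixed, group, and residual variance", {
  set.seed(52)
  n <- 120
  g <- rep(sprintf("g%02d", 1:10), each = 12)
  x <- data.frame(x1 = rnorm(n))
  # pure group offsets: no fixed signal, R2m ~ 0, R2c large
  offs <- setNames(rnorm(10, 0, 2), unique(g))
  y <- offs[g] + rnorm(n, 0, 0.3)
  fit <- fitDriverLMM(y, x, g)
  expect_lt(abs(fit$coefficients[["x1"]]), 0.15)
  expect_lt(fit$R2m, 0.05)
  expect_gt(fit$R2c, 0.9)
  expect_true(fit$R2m <= fit$R2c && fit$R2c <= 1)

  # noise-free linear response: exact slope, R2m = R2c = 1
  y2 <- 2 * scale(x$x1)[, 1]
  fit2 <- fitDriverLMM(y2, x, g)
  expect_equal(unname(fit2$coefficients["x1"]), 2, tolerance = 1e-6)
  expect_equal(fit2$R2m, 1, tolerance = 1e-6)
  expect_equal(fit2$R2c, 1, tolerance = 1e-6)

  # standardization leaves R2m/R2c invariant
  xw <- data.frame(x1 = 100 + 50 * x$x1)
  y3 <- offs[g] + 0.8 * scale(x$x1)[, 1] + rnorm(n, 0, 0.5)
  fa <- fitDriverLMM(y3, x, g)
  fb <- fitDriverLMM(y3, xw, g)
  expect_equal(fa$R2m, fb$R2m, tolerance = 1e-6)
  expect_equal(fa$R2c, fb$R2c, tolerance = 1e-6)
})

test_that("backward AIC keeps signal and discards noise", {
  set.seed(53)
  n <- 125
  g <- rep(sprintf("g%02d", 1:10), length.out = n)
  keptStrong <- 0L; droppedNoise <- 0L
  nSim <- 30
  for (s in seq_len(nSim)) {
    x <- data.frame(strong = rnorm(n), noise = rnorm(n))
    y <- 1.0 * scale(x$strong)[, 1] + rnorm(n, 0, 1)
    fit <- backwardAIC(y, x, g)
    if ("strong" %in% fit$fixed_vars) keptStrong <- keptStrong + 1L
    if (!"noise" %in% fit$fixed_vars) droppedNoise <- droppedNoise + 1L
  }
  expect_gte(keptStrong, 0.9 * nSim)
  expect_gte(droppedNoise, 0.7 * nSim)

  # single useless candidate at large n is dropped (AIC penalty dominates)
  set.seed(54)
  x0 <- data.frame(junk = rnorm(400))
  g0 <- rep(sprintf("g%02d", 1:10), each = 40)
  y0 <- rnorm(400)
  fit0 <- backwardAIC(y0, x0, g0)
  expect_length(fit0$fixed_vars, 0L)
  expect_gte(nrow(fit0$aic_trace), 2L)
  expect_true(all(diff(fit0$aic_trace$aic) < 0))
})

test_that("parametric bootstrap intervals are deterministic and calibrated", {
  set.seed(55)
  n <- 125
  g <- rep(sprintf("g%02d", 1:10), length.out = n)
  x <- data.frame(pH = rnorm(n))
  y <- 0.5 * scale(x$pH)[, 1] + rnorm(n, 0, 0.5) +
    setNames(rnorm(10, 0, 0.5), unique(g))[g]
  fit <- fitDriverLMM(y, x, g)
  ci <- bootstrapCI(fit, nBoot = 100, seed = 7)
  expect_identical(ci, bootstrapCI(fit, nBoot = 100, seed = 7))
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  ph <- ci[ci$term == "pH", ]
  expect_true(ph$lower < 0.5 + 3 * 0.1 && ph$upper > 0.5 - 3 * 0.1)
})

test_that("hierarchical partitioning satisfies its algebraic identities", {
  set.seed(56)
  n <- 150
  g <- rep(sprintf("g%02d", 1:10), each = 15)
  # three near-orthogonal predictors in three groups
  q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  x <- data.frame(a = q[, 1], b = q[, 2], c = q[, 3])
  y <- 3 * q[, 1] + 2 * q[, 2] + rnorm(n, 0, 0.3)
  groups <- list(ga = "a", gb = "b", gc = "c")
  fit <- fitDriverLMM(y, x, g)
  pr <- partitionR2(fit, groups)
  # totals sum exactly to the full model's marginal R2
  expect_equal(sum(pr$total), attr(pr, "R2m"), tolerance = 1e-9)
  # orthogonal predictors: shared variance ~ 0, unique ~ total
  expect_lt(max(abs(pr$shared)), 0.02)
  expect_true(all(pr$unique <= pr$total + 1e-9))

  # single group: total = unique = R2m, shared = 0
  fit1 <- fitDriverLMM(y, x["a"], g)
  pr1 <- partitionR2(fit1, list(only = "a"))
  expect_equal(pr1$total, attr(pr1, "R2m"), tolerance = 1e-12)
  expect_equal(pr1$shared, 0, tolerance = 1e-12)

  # enumeration oracle at g = 3: Shapley totals from explicit orderings
  r2sub <- function(vars) {
    cwpsoil:::lmmFitOnce(fit$data, vars, REML = TRUE)$R2m
  }
  perms <- list(c("ga", "gb", "gc"), c("ga", "gc", "gb"),
                c("gb", "ga", "gc"), c("gb", "gc", "ga"),
                c("gc", "ga", "gb"), c("gc", "gb", "ga"))
  inc <- setNames(numeric(3), c("ga", "gb", "gc"))
  for (p in perms) {
    sofar <- character(0)
    for (gg in p) {
      vars <- unlist(groups[c(sofar, gg)], use.names = FALSE)
      prev <- unlist(groups[sofar], use.names = FALSE)
      inc[gg] <- inc[gg] + (r2sub(vars) - r2sub(prev)) / 6
      sofar <- c(sofar, gg)
    }
  }
  expect_equal(pr$total, unname(inc[pr$group]), tolerance = 1e-9)

  # group with no selected terms contributes zero
  pr0 <- partitionR2(fit, c(groups, list(gd = character(0))))
  expect_equal(pr0$total[pr0$group == "gd"], 0)
})

test_that("residual normality uses the Anderson-Darling statistic", {
  # direct formula evaluation on a fixed 10-value vector
  x <- c(0.1, -0.4, 1.2, 0.5, -0.9, 0.3, -0.2, 0.8, -1.1, 0.6)
  z <- sort((x - mean(x)) / sd(x))
  n <- length(z)
  u <- pnorm(z)
  A2 <- -n - mean((2 * seq_len(n) - 1) * (log(u) + log(1 - rev(u))))
  got <- residualNormality(x)
  expect_equal(got$statistic, A2, tolerance = 1e-10)
  expect_error(residualNormality(rnorm(5)), ">= 8")
  expect_true(is.na(residualNormality(rep(1, 10))$statistic))

  # heavy-tailed residuals are rejected most of the time
  set.seed(57)
  rej <- mean(vapply(1:50, function(i) {
    residualNormality(rt(500, df = 2))$p_value < 0.05
  }, logical(1)))
  expect_gte(rej, 0.8)
})
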