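test_that("fisher_exact_2x2 matches exhaustive hypergeometric enumeration", {
  # [[3,1],[1,3]]: cross-product OR 9; p from full enumeration at margins 4/4
  res <- fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(res$odds_ratio, 9)
  probs <- dhyper(0:4, 4, 4, 4)
  expect_equal(res$p_value, sum(probs[probs <= dhyper(3, 4, 4, 4) * (1 + 1e-7)]))

  res <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 1)

  # zero cells: continuity-corrected OR stays finite
  res <- fisher_exact_2x2(matrix(c(0, 4, 4, 0), 2, byrow = TRUE))
  expect_true(is.finite(res$odds_ratio))
  expect_equal(res$odds_ratio, (0.5 * 0.5) / (4.5 * 4.5))

  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")

  # oracle equivalence against stats::fisher.test on all tables with total <= 16
  for (tot in c(8, 12, 16)) {
    for (rep in 1:40) {
      set.seed(tot * 100 + rep)
      cts <- as.vector(rmultinom(1, tot, rep(0.25, 4)))
      m <- matrix(cts, 2)
      expect_equal(fisher_exact_2x2(m)$p_value, fisher.test(m)$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("wilcoxon_rank_sum is exact for small samples and symmetric", {
  # identical multisets: no evidence
  expect_gte(wilcoxon_rank_sum(c(1, 5, 9), c(1, 5, 9))$p_value, 0.99)

  # complete separation of 3 vs 3: exact p = 2/20
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_true(res$exact)
  expect_equal(res$statistic, 6)
  expect_equal(res$p_value, 0.1)

  # two-sided p unchanged by swapping the samples
  set.seed(2)
  x <- rnorm(8); y <- rnorm(9, 1)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value, wilcoxon_rank_sum(y, x)$p_value)

  # large-sample path tracks stats::wilcox.test with continuity correction
  set.seed(3)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("bh_fdr reproduces the step-up adjustment", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(8)
  p <- runif(50)^2
  expect_equal(bh_fdr(p), p.adjust(p, "BH"))
  # adjusted >= raw, monotone in rank order, invariant to input order
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("stepwise_glm selects by AIC with the documented preprocessing", {
  set.seed(42)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-0.5 + 1.5 * d$x1))
  fit <- stepwise_glm(d, "y", "logistic", c("x1", "x2", "x3", "x4"))
  expect_true("x1" %in% fit$selected)
  expect_equal(fit$n_dropped_rows, 0L)

  # intercept-only AIC closed form: -2 l(p-hat) + 2
  d0 <- data.frame(y = rep(c(0, 1), c(30, 10)))
  d0$z <- rnorm(40, sd = 1e-8) + 1  # constant-ish noise column
  p_hat <- 0.25
  ll <- 10 * log(p_hat) + 30 * log(1 - p_hat)
  fit0 <- stepwise_glm(cbind(d0, x = rnorm(40)), "y", "logistic", "x")
  if (identical(fit0$selected, character(0)))
    expect_equal(fit0$aic, -2 * ll + 2, tolerance = 1e-6)

  # correlated covariates: the later one is excluded before fitting
  d$x5 <- d$x1 * 0.95 + rnorm(n, sd = 0.2)
  fit <- stepwise_glm(d, "y", "logistic", c("x1", "x5", "x2"))
  expect_equal(fit$excluded_covariates, "x5")

  # incomplete rows dropped and counted
  d_na <- d; d_na$x2[1:7] <- NA
  fit <- stepwise_glm(d_na, "y", "logistic", c("x1", "x2"))
  expect_equal(fit$n_dropped_rows, 7L)

  # negative-binomial burden model with log transforms recovers a signal
  set.seed(43)
  sv <- rpois(n, 20)
  mu <- exp(0.2 + 0.08 * log1p(sv))
  d2 <- data.frame(burden = rnbinom(n, size = 2, mu = mu * exp(rnorm(n, 0, .1))),
                   sv_burden = sv, noise = rnorm(n))
  fit2 <- stepwise_glm(d2, "burden", "negative_binomial",
                       c("sv_burden", "noise"), log_covariates = "sv_burden")
  expect_s3_class(fit2$model, "negbin")
  expect_true(all(fit2$coefficients$ratio > 0))

  # trace is recorded and reproducible
  expect_true(any(grepl("AIC", fit2$trace)))
})
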