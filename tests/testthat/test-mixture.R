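# Normality testing, EM mixture fitting, model selection and subgroup
# assignment.

test_that("Lilliefors statistic equals the direct ECDF computation", {
  x <- c(0.2, 0.9, 1.4, 2.2, 3.1)
  res <- test_normality(x, n_mc = 200, seed = 1)
  # independent direct computation of max |ECDF - Phi_hat|
  n <- length(x); xs <- sort(x)
  ph <- pnorm((xs - mean(x)) / sd(x))
  d_direct <- max(c(abs((1:n) / n - ph), abs(ph - (0:(n - 1)) / n)))
  expect_equal(res$statistic, d_direct)
})

test_that("Lilliefors statistic matches the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(2)
  x <- rnorm(60, 1.3, 0.2)
  res <- test_normality(x, n_mc = 500, seed = 1)
  ref <- nortest::lillie.test(x)
  expect_equal(res$statistic, unname(ref$statistic))
})

test_that("near-normal samples are not flagged, bimodal samples are", {
  # exact normal quantiles: essentially zero distance to normality
  xq <- qnorm(ppoints(300))
  expect_gt(test_normality(xq, n_mc = 2000, seed = 3)$p, 0.05)
  # two components 4 SD apart
  flagged <- 0L
  for (i in 1:20) {
    set.seed(100 + i)
    g <- rgmix(200, c(0.5, 0.5), c(0, 4), c(1, 1))
    if (test_normality(g$values, n_mc = 2000, seed = i)$p < 0.01)
      flagged <- flagged + 1L
  }
  expect_gte(flagged, 19L)
  expect_error(test_normality(rep(1, 10)), "zero variance")
})

test_that("single-component fit is the closed-form ML solution", {
  set.seed(4)
  x <- rnorm(40, 1.3, 0.2)
  f <- fit_gaussian_mixture(x, K = 1)
  expect_equal(f$means, mean(x))
  expect_equal(f$sds, sqrt(mean((x - mean(x))^2)))  # 1/n ML variance
  expect_equal(f$loglik, sum(dnorm(x, f$means, f$sds, log = TRUE)))
  expect_true(f$converged)
})

test_that("well-separated components are recovered nearly exactly", {
  set.seed(5)
  x <- c(rnorm(50, 0, 0.01), rnorm(50, 10, 0.01))
  f <- fit_gaussian_mixture(x, K = 2, seed = 6)
  expect_equal(f$means, c(0, 10), tolerance = 0.01)
  expect_equal(f$weights, c(0.5, 0.5), tolerance = 0.01)
  expect_lt(f$means[1], f$means[2])  # ascending order contract
})

test_that("identical values refuse a 2-component fit", {
  expect_error(fit_gaussian_mixture(rep(1.3, 20), K = 2), "refused")
  expect_warning(f <- fit_gaussian_mixture(rep(1.3, 20), K = 1),
                 "degenerate")
  expect_equal(f$means, 1.3)
})

test_that("EM log-likelihood never decreases across iterations", {
  set.seed(7)
  for (i in 1:8) {
    x <- rgmix(80, c(0.6, 0.4), c(1.2, 1.6), c(0.1, 0.15))$values
    f <- fit_gaussian_mixture(x, K = 2, n_restarts = 5, seed = i)
    expect_true(all(diff(f$loglik_trace) >= -1e-9))
  }
})

test_that("fits are invariant to input permutation", {
  set.seed(8)
  x <- rgmix(100, c(0.7, 0.3), c(1.2, 1.6), c(0.08, 0.1))$values
  f1 <- fit_gaussian_mixture(x, K = 2, seed = 9)
  f2 <- fit_gaussian_mixture(sample(x), K = 2, seed = 9)
  expect_equal(f1$means, f2$means, tolerance = 1e-6)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("EM attains at least the dense grid-search likelihood on tiny n", {
  grid_loglik <- function(x) {
    # independent oracle: dense grid over two means, two SDs and the weight
    mus <- seq(min(x), max(x), length.out = 12)
    sgs <- seq(sd(x) / 5, sd(x) * 1.5, length.out = 6)
    ws <- seq(0.1, 0.9, length.out = 5)
    best <- -Inf
    for (m1 in mus) for (m2 in mus) for (s1 in sgs) for (s2 in sgs)
      for (w in ws) {
        ll <- sum(log(w * dnorm(x, m1, s1) + (1 - w) * dnorm(x, m2, s2)))
        if (ll > best) best <- ll
      }
    best
  }
  set.seed(10)
  for (i in 1:5) {
    x <- round(rnorm(10, 1.3, 0.2), 2)
    f <- fit_gaussian_mixture(x, K = 2, n_restarts = 20, seed = i)
    expect_gte(f$loglik, grid_loglik(x) - 1e-6)
  }
})

test_that("EM likelihood is comparable to the reference implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust resolves helpers only when attached
  set.seed(11)
  x <- rgmix(150, c(110, 13) / 123, c(1.23, 1.52), c(0.08, 0.08))$values
  f <- fit_gaussian_mixture(x, K = 2, seed = 12)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(f$loglik, mc$loglik, tolerance = 0.02)
  expect_equal(sort(f$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("two-component likelihood dominates one-component on any sample", {
  set.seed(13)
  for (i in 1:5) {
    x <- rnorm(60, 1.3, 0.15)
    f1 <- fit_gaussian_mixture(x, K = 1)
    f2 <- fit_gaussian_mixture(x, K = 2, n_restarts = 10, seed = i)
    expect_gte(f2$loglik, f1$loglik - 1e-8)
  }
})

test_that("BIC selection prefers parsimony under the null and ties", {
  set.seed(14)
  chosen1 <- 0L
  for (i in 1:25) {
    x <- rnorm(123, 1.26, 0.16)
    f1 <- fit_gaussian_mixture(x, K = 1)
    f2 <- fit_gaussian_mixture(x, K = 2, n_restarts = 10, seed = i)
    if (select_model(f1, f2)$K == 1) chosen1 <- chosen1 + 1L
  }
  expect_gte(chosen1, 21L)  # >= ~90% under a single normal
  # exact tie: identical BICs break toward the smaller K
  x <- rnorm(30, 1.3, 0.1)
  f1 <- fit_gaussian_mixture(x, K = 1)
  expect_identical(select_model(f1, f1)$K, 1L)
})

test_that("component assignment follows responsibilities with a high tie", {
  set.seed(15)
  g <- rgmix(200, c(0.5, 0.5), c(1.0, 2.0), c(0.1, 0.1))
  f <- fit_gaussian_mixture(g$values, K = 2, seed = 16)
  lab <- assign_components(f)
  expect_identical(lab[which.min(g$values)], "low")
  expect_identical(lab[which.max(g$values)], "high")
  # >= 3 SD separation: labels agree with the latent truth >= 95%
  truth <- ifelse(g$component == 1, "low", "high")
  expect_gte(mean(lab == truth), 0.95)
  f1 <- fit_gaussian_mixture(g$values, K = 1)
  expect_error(assign_components(f1), "K = 2")
  # a point exactly at the responsibility tie goes to the high component
  ftie <- f
  ftie$responsibilities[1, ] <- c(0.5, 0.5)
  expect_identical(assign_components(ftie)[1], "high")
})

test_that("subgroup characterization detects the ApoE4 enrichment", {
  # printed carrier counts: 9/13 high vs 28/110 low -> strong association
  lab <- rep(c("high", "low"), c(13, 110))
  apoe <- c(rep(c(TRUE, FALSE), c(9, 4)), rep(c(TRUE, FALSE), c(28, 82)))
  cohort <- tibble::tibble(apoe4 = apoe, sex = rep("f", 123),
                           age = rnorm(123, 65), education = rnorm(123, 16),
                           mmse = rnorm(123, 29))
  tab <- characterize_subgroups(lab, cohort)
  expect_lte(tab$p[tab$covariate == "apoe4"], 0.005)
  # identical subgroups: no signal
  lab2 <- rep(c("low", "high"), each = 50)
  co2 <- tibble::tibble(apoe4 = rep(c(TRUE, FALSE), 50),
                        age = rep(c(60, 70), 50))
  tab2 <- characterize_subgroups(lab2, co2, categorical = "apoe4",
                                 continuous = "age")
  expect_equal(tab2$p[tab2$covariate == "apoe4"], 1, tolerance = 1e-9)
  expect_gt(tab2$p[tab2$covariate == "age"], 0.99)
})

test_that("generator's component-linked ApoE4 enriches the high subgroup", {
  s <- default_stratum("HC", "younger")
  direction_ok <- 0L
  for (i in 1:10) {
    co <- generate_cohort(cohort_config(strata = s, seed = 800L + i))
    hi <- co$true_component == 2
    if (mean(co$apoe4[hi]) > mean(co$apoe4[!hi]))
      direction_ok <- direction_ok + 1L
  }
  expect_gte(direction_ok, 9L)
})
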