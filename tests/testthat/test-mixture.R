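test_that("standard deviation is the inverse square root of precision", {
  expect_equal(sd_from_precision(1), 1)
  expect_equal(sd_from_precision(400), 0.05)
  expect_equal(sd_from_precision(100), 0.1)
  expect_equal(sd_from_precision(c(4, 25)), c(0.5, 0.2))
  expect_error(sd_from_precision(0), "positive")
  expect_error(sd_from_precision(-3), "positive")
})

test_that("split R-hat matches an independent formula evaluation", {
  # brute-force evaluation of the split formula on two length-4 chains
  c1 <- c(0.10, 0.12, 0.11, 0.13)
  c2 <- c(0.20, 0.18, 0.19, 0.21)
  halves <- list(c1[1:2], c1[3:4], c2[1:2], c2[3:4])
  n <- 2
  W <- mean(sapply(halves, var))
  B <- n * var(sapply(halves, mean))
  expect_equal(gelman_rubin(list(c1, c2)),
               sqrt(((n - 1) / n * W + B / n) / W))

  # well-separated chains scream
  set.seed(1)
  expect_gt(gelman_rubin(list(rnorm(1000), rnorm(1000, 5))), 1.1)

  # zero between-(split-)chain variance with positive within-chain
  # variance returns exactly 1: every half of every chain has mean 2
  expect_identical(gelman_rubin(list(c(1, 3, 2, 2), c(0, 4, 3, 1))), 1)

  # permutations of one multiset with matching moments stay near 1
  set.seed(2)
  draws <- rnorm(3000)
  perms <- list(draws, sample(draws), sample(draws))
  expect_lt(abs(gelman_rubin(perms) - 1), 0.05)

  # constant-but-different chains cannot be diagnosed silently
  expect_warning(r <- gelman_rubin(list(rep(1, 4), rep(2, 4))), "undefined")
  expect_true(is.nan(r))
  expect_error(gelman_rubin(list(1:4)), "2 chains")
})

test_that("k = 1 posterior matches the conjugate closed form", {
  set.seed(99)
  x <- rnorm(1000, 0.11, 0.02)
  cfg <- test_config(k = 1, alpha = 1, seed = 5,
                     prior_mean_location = 0.10,
                     prior_mean_precision = 100,
                     precision_shape = 3, precision_rate = 3 * 4e-4)
  draws <- run_gibbs(x, cfg)
  mu <- unlist(lapply(draws$chains, function(ch) ch$mu[, 1]))

  # semi-conjugate closed form: with n = 1000 the posterior of tau is
  # sharply peaked, so E[mu] is the normal-normal posterior mean evaluated
  # at the posterior mean of tau to excellent accuracy
  tau_hat <- (3 + length(x) / 2) /
    (3 * 4e-4 + 0.5 * sum((x - mean(x))^2))
  m_expect <- (100 * 0.10 + tau_hat * sum(x)) / (100 + length(x) * tau_hat)
  mcse <- sd(mu) / sqrt(length(mu))
  expect_lt(abs(mean(mu) - m_expect), 3 * mcse + 1e-6)
})

test_that("weights stay on the simplex and sorted means stay ordered", {
  set.seed(3)
  sc <- table2_scenarios()[[8]]
  x <- simulate_thickness_sample(sc, 77)$values
  cfg <- test_config(k = 4, alpha = c(10, 35, 35, 20), seed = 2,
                     sort_means = TRUE)
  draws <- run_gibbs(x, cfg)
  for (ch in draws$chains) {
    expect_equal(rowSums(ch$weight), rep(1, nrow(ch$weight)))
    expect_true(all(ch$weight > 0))
    expect_true(all(ch$sigma > 0))
    expect_true(all(ch$mu[, 2] >= ch$mu[, 1]))
    expect_true(all(ch$mu[, 3] >= ch$mu[, 2]))
    expect_true(all(ch$mu[, 4] >= ch$mu[, 3]))
  }
})

test_that("fixed seeds reproduce draws exactly and validation guards hold", {
  x <- simulate_thickness_sample(table2_scenarios()[[1]], 13)$values
  cfg <- test_config(k = 2, alpha = c(20, 80), seed = 21)
  d1 <- run_gibbs(x, cfg)
  d2 <- run_gibbs(x, cfg)
  expect_identical(d1$chains, d2$chains)
  cfg2 <- test_config(k = 2, alpha = c(20, 80), seed = 22)
  expect_false(identical(run_gibbs(x, cfg2)$chains, d1$chains))

  expect_error(run_gibbs(numeric(0), cfg), "empty")
  expect_error(run_gibbs(rep(0.1, 50), cfg), "distinct")
  expect_error(mixture_config(k = 4, alpha = c(20, 80)), "length k")
  expect_error(mixture_config(k = 4, sort_means = FALSE), "sort_means")
  expect_error(mixture_config(iterations = 100, burn_in = 200), "burn_in")
})

test_that("posterior summaries report medians, central intervals and sigma per draw", {
  # hand-checked quantile definition on draws 1..100
  fake <- structure(list(chains = list(list(
    mu = cbind(1:100), sigma = cbind(sqrt(1 / (1:100))),
    weight = cbind(rep(1, 100)))),
    config = mixture_config(k = 1, alpha = 1), n = 10,
    data_range = c(0, 1)), class = "mixture_draws")
  s <- summarize_posterior(fake, credible_mass = 0.68)
  expect_equal(s$mu_median, 50.5)
  expect_equal(s$mu_lo, unname(quantile(1:100, 0.16)))
  expect_equal(s$mu_hi, unname(quantile(1:100, 0.84)))
  # sigma summarized from per-draw transforms, not from summarized precision
  expect_equal(s$sigma_median, unname(quantile(sqrt(1 / (1:100)), 0.5)))

  fake$chains[[1]]$mu <- cbind(rep(2, 100))
  s2 <- summarize_posterior(fake)
  expect_equal(s2$mu_lo, 2)
  expect_equal(s2$mu_median, 2)
  expect_equal(s2$mu_hi, 2)
})

test_that("empirical prior anchors separate real mixtures and merge plain normals", {
  set.seed(12)
  # a clearly bimodal mixture keeps nearly full anchor spread
  x_sep <- c(rnorm(150, 0.08, 0.02), rnorm(350, 0.16, 0.02))
  cal <- empirical_mixture_priors(x_sep, c(30, 70))
  expect_gt(cal$scale, 0.8)
  expect_lt(abs(cal$locations[1] - 0.08), 0.01)
  expect_lt(abs(cal$locations[2] - 0.16), 0.01)

  # a single normal shrinks the anchors together
  x_one <- rnorm(400, 0.11, 0.02)
  cal1 <- empirical_mixture_priors(x_one, c(25, 75))
  expect_lt(cal1$scale, 0.5)
  expect_lt(diff(cal1$locations), diff(cal1$slice_means))

  # descending listing mirrors the ascending anchors
  casc <- empirical_mixture_priors(x_sep, c(30, 70))
  cdesc <- empirical_mixture_priors(x_sep, c(70, 30),
                                    component_order = "descending")
  expect_equal(casc$locations, rev(cdesc$locations), tolerance = 1e-10)
})
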