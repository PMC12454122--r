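# Exchange-algorithm posterior, summaries, and goodness of fit.

fixture_net8 <- function() {
  directed_network(sprintf("n%d", 1:8),
                   from = c(1, 2, 3, 4, 5, 6, 7, 8, 1, 3, 5, 2),
                   to = c(2, 3, 4, 5, 6, 7, 8, 1, 4, 6, 8, 7))
}

test_that("exchange posterior matches the exact grid oracle on n = 8", {
  net <- fixture_net8()
  th_true <- c(intercept = -0.3, contagion_direct = 0.6)
  y <- as.integer(alaam_simulate(th_true, net, degree_effects = FALSE,
                                 n_draws = 1, burn_in = 2000, seed = 9)[1, ])
  prior_sd <- 3
  fit <- alaam(network = net, y = y, degree_effects = FALSE,
               iter = 8000, burn = 2000, aux_sweeps = 50, seed = 3,
               prior_sd = prior_sd)

  # grid oracle: exact posterior from 2^8 enumeration per grid point
  s_obs <- alaam_statistics(y, net, degree_effects = FALSE)
  base <- alaam_exact(c(intercept = 0, contagion_direct = 0), net,
                      degree_effects = FALSE)
  Smat <- base$stats
  grid <- seq(-4, 4, length.out = 41)
  lp <- outer(grid, grid, Vectorize(function(a, b) {
    lps <- Smat %*% c(a, b)
    lz <- max(lps) + log(sum(exp(lps - max(lps))))
    sum(c(a, b) * s_obs) - lz +
      dnorm(a, 0, prior_sd, log = TRUE) + dnorm(b, 0, prior_sd, log = TRUE)
  }))
  post <- exp(lp - max(lp)); post <- post / sum(post)

  # compare the contagion marginal: bin the exchange draws onto the grid
  marg <- colSums(post)
  half <- diff(grid[1:2]) / 2
  counts <- vapply(grid, function(g)
    mean(fit$draws[, "contagion_direct"] > g - half &
           fit$draws[, "contagion_direct"] <= g + half), numeric(1))
  counts <- counts / sum(counts)
  kl <- sum(ifelse(counts > 0, counts * log(counts / marg), 0))
  expect_lt(kl, 0.05)
  # and the intercept marginal mean
  expect_equal(mean(fit$draws[, "intercept"]), sum(rowSums(post) * grid),
               tolerance = 0.12)
})

test_that("constant outcomes are rejected as non-identified", {
  net <- fixture_net8()
  expect_error(alaam(network = net, y = rep(0L, 8)), "non-identified")
  expect_error(alaam(network = net, y = rep(1L, 8)), "non-identified")
})

test_that("the formula interface matches the explicit-vector interface", {
  net <- fixture_net8()
  set.seed(12)
  df <- data.frame(pro = c(0, 1, 0, 1, 1, 0, 0, 1), age = rnorm(8))
  f1 <- alaam(pro ~ age, data = df, network = net, iter = 300, burn = 200,
              aux_sweeps = 20, seed = 7)
  f2 <- alaam(network = net, y = df$pro, covariates = df["age"],
              iter = 300, burn = 200, aux_sweeps = 20, seed = 7)
  expect_equal(unname(f1$obs_stats), unname(f2$obs_stats))
  expect_equal(unname(coef(f1)), unname(coef(f2)))
})

test_that("posterior summary matches hand computation on 5 draws", {
  d <- matrix(c(-2, -1, 0.5, 1, 3), ncol = 1,
              dimnames = list(NULL, "theta"))
  ps <- posterior_summary(d)
  expect_equal(ps$median, 0.5)
  expect_equal(ps$prop_above_zero, 3 / 5)
  expect_equal(ps$lower, unname(quantile(d[, 1], 0.025)))
  expect_equal(posterior_summary(matrix(1:4, ncol = 1,
                                        dimnames = list(NULL, "x")))$prop_above_zero,
               1)
  sym <- matrix(c(-2, -1, 1, 2), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(posterior_summary(sym)$prop_above_zero, 0.5)
})

test_that("kin/non-kin scopes reduce correctly when the kin layer is empty", {
  net <- random_network(30, p = 0.12, seed = 6)
  nokin <- directed_network(net$roster, net$from, net$to, kin = FALSE)
  set.seed(8)
  y <- rbinom(30, 1, 0.4)
  s_all <- alaam_statistics(y, nokin, tie_scope = "all")
  s_nonkin <- alaam_statistics(y, nokin, tie_scope = "nonkin")
  expect_equal(s_all, s_nonkin)
  s_kin <- alaam_statistics(y, nokin, tie_scope = "kin")
  expect_equal(s_kin[["contagion_direct"]], 0)
  expect_equal(s_kin[["activity"]], 0)
})

test_that("goodness of fit: t-ratios behave and degenerate statistics yield NA", {
  net <- fixture_net8()
  y <- c(0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L)
  fit <- alaam(network = net, y = y, iter = 400, burn = 300,
               aux_sweeps = 20, seed = 9)
  gof <- goodness_of_fit(fit, n_sim = 60, seed = 10, sweeps = 40)
  expect_true(all(c("contagion_reciprocal", "contagion_transitive") %in%
                    gof$statistic))
  expect_true(all(is.finite(gof$sim_mean)))
  # statistics the model was fitted to should not be extreme
  direct <- gof[gof$statistic == "contagion_direct", ]
  expect_lt(abs(direct$t_ratio), 3)
  # a zero-variance statistic reports NA rather than crashing
  expect_true(all(is.na(gof$t_ratio[gof$sim_sd == 0])))
  expect_error(goodness_of_fit(fit, n_sim = 1), "n_sim")
})

test_that("posterior predictive simulation and conditional predictions run", {
  net <- fixture_net8()
  y <- c(0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L)
  fit <- alaam(network = net, y = y, iter = 300, burn = 200,
               aux_sweeps = 20, seed = 11)
  sims <- simulate(fit, nsim = 5, seed = 12, sweeps = 20)
  expect_equal(dim(sims), c(5L, 8L))
  expect_true(all(sims %in% 0:1))
  p <- predict(fit)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(residuals(fit), y - p)
})
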