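# Latent-network estimation from double-sampled reports.

make_reports <- function(out_edges, in_edges, reporters) {
  # out_edges / in_edges: data.frame(ego, alter)
  empty <- data.frame(ego = character(), generator = character(),
                      alter = character(), kin = logical(),
                      relationship = character(), stringsAsFactors = FALSE)
  mk <- function(e, gen) {
    if (is.null(e) || !nrow(e)) return(empty)
    data.frame(ego = e$ego, generator = gen, alter = e$alter, kin = FALSE,
               relationship = "x", stringsAsFactors = FALSE)
  }
  double_sampled_reports(rbind(mk(out_edges, "advice_out"),
                               mk(in_edges, "advice_in")),
                         pair = "advice", reporter_set = reporters)
}

test_that("noiseless limit: rho is 1 on reported ties, prior elsewhere", {
  reporters <- c("A", "B", "C", "D")
  reps <- make_reports(data.frame(ego = c("A", "B"), alter = c("B", "C")),
                       NULL, reporters)
  est <- latent_network(reps, fixed = list(lambda1 = 1, lambda0 = 0,
                                           mutuality = 0, density = 0.005),
                        iter = 400, burn = 100, seed = 1)
  expect_equal(est$rho["A", "B"], 1)
  expect_equal(est$rho["B", "C"], 1)
  # unreported pair with coverage: lambda1 = 1 forces rho = 0
  expect_equal(est$rho["A", "C"], 0)
  expect_error(latent_network(make_reports(NULL, NULL, reporters)),
               "empty report set")
})

test_that("threshold formula endpoints and strict comparison", {
  rho <- matrix(c(0, 0.05, 0.2, 0.9,
                  0, 0, 0, 0,
                  0, 0, 0, 0,
                  0, 0, 0, 0), 4, 4, byrow = TRUE,
                dimnames = list(letters[1:4], letters[1:4]))
  est <- list(rho = rho, eta_est = 0.3, roster = letters[1:4], pair = "advice")
  expect_equal(attr(threshold_ties(est, eta_est = 0), "t_rho"), 0.10)
  expect_equal(attr(threshold_ties(est, eta_est = 1), "t_rho"), 0.43)
  net <- threshold_ties(est)  # t = 0.33 * 0.3 + 0.10 = 0.199
  expect_setequal(paste(net$roster[net$from], net$roster[net$to]),
                  c("a c", "a d"))
  expect_error(threshold_ties(est, eta_est = 1.2), "\\[0, 1\\]")
})

test_that("union and intersection baselines behave as defined", {
  reporters <- c("A", "B")
  reps <- make_reports(data.frame(ego = "A", alter = "B"), NULL, reporters)
  u <- baseline_union(reps)
  i <- baseline_intersection(reps)
  expect_equal(paste(u$roster[u$from], u$roster[u$to]), "A B")
  expect_equal(length(i$from), 0L)

  # both sides report the same tie A -> B (B confirms via the in-generator)
  reps2 <- make_reports(data.frame(ego = "A", alter = "B"),
                        data.frame(ego = "B", alter = "A"), reporters)
  u2 <- baseline_union(reps2); i2 <- baseline_intersection(reps2)
  expect_equal(paste(u2$roster[u2$from], u2$roster[u2$to]), "A B")
  expect_equal(paste(i2$roster[i2$from], i2$roster[i2$to]), "A B")
})

test_that("intersection is contained in union on random report sets", {
  set.seed(31)
  ids <- sprintf("r%02d", 1:12)
  for (rep in 1:5) {
    oe <- data.frame(ego = sample(ids, 20, TRUE), alter = sample(ids, 20, TRUE))
    ie <- data.frame(ego = sample(ids, 20, TRUE), alter = sample(ids, 20, TRUE))
    oe <- oe[oe$ego != oe$alter, ]; ie <- ie[ie$ego != ie$alter, ]
    reps <- make_reports(oe, ie, ids)
    u <- baseline_union(reps); i <- baseline_intersection(reps)
    expect_true(all(paste(i$from, i$to) %in% paste(u$from, u$to)))
  }
})

test_that("posterior matches the exact 2^12 enumeration oracle on 4 nodes", {
  reporters <- c("A", "B", "C", "D")
  oe <- data.frame(ego = c("A", "B", "C"), alter = c("B", "A", "D"))
  ie <- data.frame(ego = c("B", "D"), alter = c("A", "C"))
  reps <- make_reports(oe, ie, reporters)
  l1 <- 0.8; l0 <- 0.05; m <- 1.5; p0 <- 0.1; a <- qlogis(p0)

  est <- latent_network(reps, prior_tie = p0,
                        fixed = list(lambda1 = l1, lambda0 = l0,
                                     mutuality = m, density = p0),
                        iter = 6000, burn = 500, seed = 2)

  # oracle: enumerate all 2^12 ordered-pair configurations
  roster <- reporters
  rc <- netcontagion:::report_counts(reps, roster)
  pairs <- which(row(rc$n_obs) != col(rc$n_obs), arr.ind = TRUE)
  np <- nrow(pairs)  # 12 ordered pairs
  post_num <- matrix(0, 4, 4); Z <- 0
  for (s in 0:(2^np - 1)) {
    Y <- matrix(0L, 4, 4)
    Y[pairs] <- bitwAnd(s, 2^(seq_len(np) - 1L)) > 0L
    lp <- 0
    for (d1 in 1:3) for (d2 in (d1 + 1):4) {
      lp <- lp + a * (Y[d1, d2] + Y[d2, d1]) + m * Y[d1, d2] * Y[d2, d1]
    }
    for (k in seq_len(np)) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      nob <- rc$n_obs[i, j]; npos <- rc$n_pos[i, j]
      pr <- if (Y[i, j] == 1L) l1 else l0
      lp <- lp + npos * log(pr) + (nob - npos) * log(1 - pr)
    }
    w <- exp(lp)
    post_num <- post_num + w * Y
    Z <- Z + w
  }
  oracle_rho <- post_num / Z
  expect_equal(est$rho[pairs], oracle_rho[pairs], tolerance = 0.025)
})

test_that("adding a confirming report never decreases rho", {
  reporters <- c("A", "B", "C")
  base <- make_reports(data.frame(ego = "A", alter = "B"), NULL, reporters)
  more <- make_reports(data.frame(ego = "A", alter = "B"),
                       data.frame(ego = "B", alter = "A"), reporters)
  fx <- list(lambda1 = 0.8, lambda0 = 0.05, mutuality = 0.5, density = 0.05)
  e1 <- latent_network(base, fixed = fx, prior_tie = 0.05,
                       iter = 4000, burn = 500, seed = 3)
  e2 <- latent_network(more, fixed = fx, prior_tie = 0.05,
                       iter = 4000, burn = 500, seed = 3)
  expect_gte(e2$rho["A", "B"] + 0.02, e1$rho["A", "B"])
})

test_that("latent estimate discriminates true ties from non-ties", {
  set.seed(17)
  cfg <- sim_config(n_zones = 2L, zone_sizes = c(60L, 60L),
                    zone_prevalence = c(0.1, 0.05))
  pop <- generate_population(cfg, seed = 4)
  nets <- generate_networks(pop, cfg, seed = 5)
  truth <- nets$advice
  reps <- simulate_reports(truth, reporters = pop$id, lambda1 = 0.8,
                           lambda0 = 0.002, cap = 10, seed = 6,
                           pair = "advice", zone = pop$zone)
  est <- latent_network(reps, iter = 800, burn = 300, seed = 7)
  A <- adjacency_matrix(truth)[est$roster, est$roster]
  off <- row(A) != col(A)
  mean_true <- mean(est$rho[off & A == 1])
  mean_false <- mean(est$rho[off & A == 0])
  expect_gt(mean_true, mean_false + 0.3)
  expect_true(all(est$rho >= 0 & est$rho <= 1))
  expect_gte(est$eta_est, 0); expect_lte(est$eta_est, 1)
  expect_equal(est$t_rho, 0.33 * est$eta_est + 0.10)
})
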