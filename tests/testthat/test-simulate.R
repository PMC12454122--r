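small_cfg <- function(...) {
  sim_config(n_zones = 2L, zone_sizes = c(50L, 50L),
             zone_prevalence = c(0.1, 0.05), ...)
}

test_that("generate_population assigns reporters and is deterministic", {
  cfg <- small_cfg(reporter_fraction = 0.5)
  pop <- generate_population(cfg, seed = 3)
  expect_equal(nrow(pop), 100L)
  expect_equal(sum(pop$is_reporter), 50L)
  expect_identical(pop, generate_population(cfg, seed = 3))
  expect_false(identical(pop, generate_population(cfg, seed = 4)))
  expect_error(generate_population(sim_config(n_zones = 1L, zone_sizes = 1L,
                                              zone_prevalence = 0.1)),
               "size >= 2")
})

test_that("gender ratio 1.0 lands in the binomial 99% band at n = 10000", {
  cfg <- sim_config(n_zones = 1L, zone_sizes = 10000L, gender_ratio = 1.0,
                    zone_prevalence = 0.05)
  pop <- generate_population(cfg, seed = 11)
  n_men <- sum(pop$gender == "man")
  band <- qbinom(c(0.005, 0.995), 10000L, 0.5)
  expect_gte(n_men, band[1L])
  expect_lte(n_men, band[2L])
})

test_that("generated networks cluster within zones", {
  cfg <- sim_config(n_zones = 4L, zone_sizes = rep(50L, 4L),
                    within_zone = 0.95, zone_prevalence = rep(0.05, 4L))
  pop <- generate_population(cfg, seed = 5)
  nets <- generate_networks(pop, cfg, seed = 6)
  for (net in nets) {
    expect_gte(attr(net, "within_zone_share"), 0.9)
  }
})

test_that("degenerate network configs behave as documented", {
  cfg <- small_cfg(mean_degree = c(chatting = 0, respect = 0, money = 0,
                                   advice = 0))
  pop <- generate_population(cfg, seed = 1)
  nets <- generate_networks(pop, cfg, seed = 1)
  expect_equal(length(nets$chatting$from), 0L)

  cfg2 <- small_cfg(kin_fraction = c(chatting = 1, respect = 1, money = 1,
                                     advice = 1))
  nets2 <- generate_networks(generate_population(cfg2, seed = 2), cfg2,
                             seed = 2)
  expect_true(all(nets2$chatting$kin))
})

test_that("noiseless reports reconstruct the reporters' true ties exactly", {
  net <- random_network(30, p = 0.1, seed = 9)
  reps <- simulate_reports(net, reporters = net$roster, lambda1 = 1,
                           lambda0 = 0, cap = Inf, seed = 2)
  rebuilt_out <- build_layer(rbind(reps$out_reports, reps$in_reports),
                             "advice_out", net$roster)
  rebuilt_in <- build_layer(rbind(reps$out_reports, reps$in_reports),
                            "advice_in", net$roster)
  truth <- sort(paste(net$from, net$to))
  expect_identical(sort(paste(rebuilt_out$from, rebuilt_out$to)), truth)
  expect_identical(sort(paste(rebuilt_in$from, rebuilt_in$to)), truth)
})

test_that("lambda1 = 0 yields no true-tie reports; counts follow the binomial band", {
  net <- random_network(30, p = 0.1, seed = 10)
  reps0 <- simulate_reports(net, reporters = net$roster, lambda1 = 0,
                            lambda0 = 0, cap = Inf, seed = 3)
  expect_equal(nrow(reps0$out_reports) + nrow(reps0$in_reports), 0L)

  # large fixture: reported true-tie count within the binomial 99% band
  set.seed(40)
  n <- 300L
  from <- rep(1:n, each = 12)
  to <- as.vector(vapply(1:n, function(i) sample(setdiff(1:n, i), 12),
                         integer(12)))
  big <- directed_network(sprintf("x%03d", 1:n), from, to)
  m <- length(big$from)
  reps <- simulate_reports(big, reporters = big$roster, lambda1 = 0.8,
                           lambda0 = 0, cap = Inf, seed = 4)
  band <- qbinom(c(0.005, 0.995), m, 0.8)
  expect_gte(nrow(reps$out_reports), band[1L])
  expect_lte(nrow(reps$out_reports), band[2L])
})

test_that("report cap keeps a subset of at most cap names per side", {
  net <- random_network(25, p = 0.5, seed = 12)
  reps <- simulate_reports(net, reporters = net$roster, lambda1 = 1,
                           lambda0 = 0, cap = 3L, seed = 5)
  counts <- table(reps$out_reports$ego)
  expect_true(all(counts <= 3L))
})

test_that("norm answers follow prevalence, bias and the decile grid", {
  cfg <- sim_config(n_zones = 1L, zone_sizes = 2000L, zone_prevalence = 0.1,
                    norm = list(anti_zero_prob = 0, decile_noise = 0.25,
                                normative_probs_pro = c(approve = 1,
                                                        disapprove = 0,
                                                        none_of_their_business = 0),
                                normative_probs_anti = c(approve = 0,
                                                         disapprove = 1,
                                                         none_of_their_business = 0)))
  y <- rep(c(0L, 1L), 1000L)
  na <- simulate_norm_answers(y, rep(1L, 2000L), 0.1, cfg, seed = 6)
  tab <- table(na$empirical_expectation_men)
  expect_equal(names(tab)[which.max(tab)], "10")
  expect_true(all(na$empirical_expectation_men %% 10 == 0))
  expect_true(all(na$normative_expectation[y == 1] == "approve"))

  cfg2 <- cfg; cfg2$norm$anti_zero_prob <- 1
  na2 <- simulate_norm_answers(y, rep(1L, 2000L), 0.1, cfg2, seed = 7)
  expect_true(all(na2$empirical_expectation_men[y == 0] == 0L))
})

test_that("selection generator: flat blocks are preference-independent, offsets order rates", {
  cfg <- sim_config(n_zones = 1L, zone_sizes = 80L, zone_prevalence = 0.3,
                    srm = list(intercept = -2, sd_sender = 0.3,
                               sd_receiver = 0.3, cor_sr = 0,
                               sd_dyad = 0.3, cor_dyad = 0.3))
  y <- rep(c(0L, 1L), 40L)
  flat <- matrix(0, 2, 2)
  sel <- simulate_selection_reports(y, NULL, flat, cfg, seed = 8)
  A <- adjacency_matrix(sel$network)
  g <- y + 1L
  tab <- matrix(0, 2, 2); tot <- matrix(0, 2, 2)
  for (i in 1:80) for (j in 1:80) {
    if (i == j) next
    tab[g[i], g[j]] <- tab[g[i], g[j]] + A[i, j]
    tot[g[i], g[j]] <- tot[g[i], g[j]] + 1
  }
  expect_gt(chisq.test(cbind(as.vector(tab),
                             as.vector(tot - tab)))$p.value, 0.01)

  hom <- matrix(c(0, 0, 0, 2), 2, 2)  # pro->pro +2
  sel2 <- simulate_selection_reports(y, NULL, hom, cfg, seed = 9)
  A2 <- adjacency_matrix(sel2$network)
  rate <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) {
    rate[a, b] <- mean(A2[g == a, g == b][row(A2[g == a, g == b]) !=
                                            col(A2[g == a, g == b])])
  }
  expect_true(rate[2, 2] > max(rate[1, 1], rate[1, 2], rate[2, 1]))

  cfg0 <- cfg; cfg0$srm$intercept <- -Inf
  sel0 <- simulate_selection_reports(y, NULL, flat, cfg0, seed = 10)
  expect_equal(length(sel0$network$from), 0L)
})

test_that("simulate_study is fully deterministic given (config, seed)", {
  cfg <- small_cfg()
  s1 <- simulate_study(cfg, seed = 21)
  s2 <- simulate_study(cfg, seed = 21)
  expect_identical(s1$respondents, s2$respondents)
  expect_identical(s1$nominations, s2$nominations)
  expect_identical(s1$truth$y, s2$truth$y)
})
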