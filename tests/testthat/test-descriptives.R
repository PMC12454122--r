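test_that("Jaccard toy cases and properties", {
  nm <- data.frame(
    ego = c(rep("E", 3), rep("E", 3), "F"),
    generator = c(rep("chatting", 3), rep("respect", 3), "chatting"),
    alter = c("a", "b", "c", "b", "c", "d", "a"),
    kin = FALSE, relationship = "x", stringsAsFactors = FALSE)
  j <- jaccard_overlap(nm, "chatting", "respect")
  expect_equal(unname(j$per_respondent["E"]), 0.5)  # {a,b,c} vs {b,c,d}
  expect_equal(j$mean, 0.5)                          # F only used chatting

  same <- nm; same$generator <- rep(c("chatting", "respect"), c(3, 4))
  same$alter <- c("a", "b", "c", "a", "b", "c", "z")
  same$ego <- "E"
  expect_equal(jaccard_overlap(same, "chatting", "respect")$mean, 0.75)

  nm2 <- nm
  nm2$alter[nm2$generator == "respect"] <- c("x", "y", "z")
  expect_equal(jaccard_overlap(nm2, "chatting", "respect")$mean, 0)

  # symmetry and bounds on a random fixture
  set.seed(8)
  rnm <- data.frame(ego = sample(LETTERS[1:5], 60, TRUE),
                    generator = sample(c("chatting", "respect"), 60, TRUE),
                    alter = sample(letters[1:8], 60, TRUE),
                    kin = FALSE, relationship = "x",
                    stringsAsFactors = FALSE)
  jab <- jaccard_overlap(rnm, "chatting", "respect")$mean
  jba <- jaccard_overlap(rnm, "respect", "chatting")$mean
  expect_equal(jab, jba)
  expect_gte(jab, 0); expect_lte(jab, 1)
  expect_true(is.na(jaccard_overlap(rnm, "advice_out", "advice_in")$mean))
})

test_that("network summary matches hand values on canonical graphs", {
  cyc <- directed_network(c("A", "B", "C"), c(1, 2, 3), c(2, 3, 1))
  s <- network_summary(cyc)
  expect_equal(s$reciprocity, 0)
  expect_equal(s$transitivity, 1)  # symmetrized cycle is a closed triangle
  expect_equal(s$density, 3 / 6)
  expect_equal(s$isolates, 0L)

  dy <- directed_network(c("A", "B", "C"), c(1, 2), c(2, 1))
  s2 <- network_summary(dy)
  expect_equal(s2$reciprocity, 1)
  expect_equal(s2$isolates, 1L)
})

test_that("network summary equals the brute-force oracle on a random fixture", {
  net <- random_network(30, p = 0.08, seed = 77)
  s <- network_summary(net)
  o <- oracle_network_summary(net)
  expect_equal(s$ties, o$ties)
  expect_equal(s$density, o$density)
  expect_equal(s$reciprocity, o$reciprocity)
  expect_equal(s$transitivity, o$transitivity)
  expect_equal(s$isolates, o$isolates)
})

test_that("centralities match hand values and the all-pairs oracle", {
  # star with k spokes pointing in
  star <- directed_network(c("hub", paste0("s", 1:4)), from = 2:5,
                           to = rep(1, 4))
  cp <- centrality_profile(star)
  expect_equal(cp$in_degree[1], 4)
  expect_equal(cp$in_degree[-1], rep(0, 4))

  path <- directed_network(c("A", "B", "C"), c(1, 2), c(2, 3))
  cpp <- centrality_profile(path)
  expect_equal(cpp$betweenness, c(0, 1, 0))

  net <- random_network(12, p = 0.18, seed = 13)
  got <- centrality_profile(net)
  expect_equal(got$betweenness, oracle_betweenness(net))
  expect_equal(got$harmonic, oracle_harmonic(net))
})

test_that("norm classification implements the joint criterion", {
  r <- toy_respondents()
  r$empirical_expectation_men <- c(0L, 10L, 0L)
  r$empirical_expectation_women <- c(0L, 0L, 0L)
  r$normative_expectation <- c("disapprove", "approve", "approve")
  cl <- classify_norms(r)
  f <- cl$respondent
  expect_false(f$empirical_expectation_present[1])
  expect_false(f$bicchieri_joint[1])
  expect_true(f$bicchieri_joint[2])   # men 10% + approve
  expect_false(f$bicchieri_joint[3])  # approve but 0% support
  expect_true(all(!f$bicchieri_joint | f$perceived_support_ge_10))
  r$empirical_expectation_men[1] <- 15L
  expect_error(classify_norms(r), "decile")
})

test_that("norm aggregates match a hand tally on a 20-row table", {
  set.seed(5)
  n <- 20L
  r <- data.frame(
    id = sprintf("i%02d", 1:n), age = 30L, gender = "woman",
    education = "none", zone = rep(1:2, each = 10),
    community_role = "no_role", religion = "muslim",
    pref_daughter = sample(c("yes", "no"), n, TRUE, c(0.3, 0.7)),
    pref_daughter_in_law = "no", is_reporter = TRUE,
    empirical_expectation_men = sample(seq(0L, 30L, 10L), n, TRUE),
    empirical_expectation_women = sample(seq(0L, 20L, 10L), n, TRUE),
    normative_expectation = sample(c("approve", "disapprove",
                                     "none_of_their_business"), n, TRUE),
    stringsAsFactors = FALSE)
  cl <- classify_norms(r)
  z1 <- r$zone == 1
  expect_equal(cl$by_zone$pct_zero_men[cl$by_zone$group == "1"],
               100 * sum(r$empirical_expectation_men[z1] == 0) / 10)
  expect_equal(cl$by_zone$pct_approve[cl$by_zone$group == "2"],
               100 * sum(r$normative_expectation[!z1] == "approve") / 10)
  joint <- (r$empirical_expectation_men >= 10 |
              r$empirical_expectation_women >= 10) &
    r$normative_expectation == "approve"
  expect_equal(cl$by_preference$pct_bicchieri_joint,
               sapply(split(joint, classify_preference(
                 r$pref_daughter, r$pref_daughter_in_law)),
                 function(v) 100 * mean(v)),
               ignore_attr = TRUE)
})

test_that("prevalence table computes per-zone profiles", {
  r <- toy_respondents()
  pt <- prevalence_table(r)
  expect_equal(pt$n, c(2L, 1L))
  expect_equal(pt$pct_pro[pt$zone == "1"], 50)
  expect_equal(pt$pct_pro[pt$zone == "2"], 0)
  r2 <- r; r2$pref_daughter <- NA; r2$pref_daughter_in_law <- NA
  expect_error(suppressMessages(prevalence_table(r2)), "missing")
})

test_that("prevalence ordering follows configured zone intercepts", {
  cfg <- sim_config(n_zones = 3L, zone_sizes = rep(1000L, 3L),
                    zone_prevalence = c(0.12, 0.06, 0.01))
  sim <- simulate_study(cfg, seed = 30)
  pt <- prevalence_table(sim$respondents)
  expect_true(all(diff(pt$pct_pro[order(pt$zone)]) < 0))
})

test_that("half-roster reporting biases reciprocity downward", {
  cfg <- sim_config(n_zones = 2L, zone_sizes = c(150L, 150L),
                    zone_prevalence = c(0.1, 0.05))
  pop <- generate_population(cfg, seed = 41)
  net <- generate_networks(pop, cfg, seed = 42)$money
  full <- simulate_reports(net, reporters = pop$id, lambda1 = 1, lambda0 = 0,
                           cap = Inf, seed = 43, pair = "money")
  half <- simulate_reports(net, reporters = pop$id[pop$is_reporter],
                           lambda1 = 1, lambda0 = 0, cap = Inf, seed = 44,
                           pair = "money")
  rfull <- network_summary(build_layer(full$out_reports, "borrow_out",
                                       pop$id))$reciprocity
  rhalf <- network_summary(build_layer(half$out_reports, "borrow_out",
                                       pop$id))$reciprocity
  expect_lte(rhalf, rfull)
})
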