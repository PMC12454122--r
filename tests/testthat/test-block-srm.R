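# Combined stochastic block + social relations model.

test_that("design likelihood is invariant to intercept/block reshuffling", {
  set.seed(2)
  pref <- sample(c("anti", "pro"), 12, TRUE)
  gender <- sample(c("man", "woman"), 12, TRUE)
  des <- srm_design(pref, gender)
  y <- rbinom(nrow(des$W), 1, 0.2)
  loglik <- function(beta) {
    eta <- as.vector(des$W %*% beta)
    sum(ifelse(y == 1, -log1p(exp(-eta)), -log1p(exp(eta))))
  }
  beta <- rnorm(ncol(des$W))
  shift <- beta
  shift[1:4] <- shift[1:4] + 0.7       # all preference blocks up
  shift[5:8] <- shift[5:8] - 0.7       # all gender blocks down
  expect_equal(loglik(beta), loglik(shift))
})

test_that("contrasts: reference is exactly zero; quantile oracle agrees", {
  set.seed(3)
  draws <- matrix(rnorm(400), 100, 4,
                  dimnames = list(NULL, c("pref_anti_anti", "pref_anti_pro",
                                          "pref_pro_anti", "pref_pro_pro")))
  ct <- block_contrasts(draws, reference = "pro-pro")
  ref <- ct[ct$combination == "pro-pro", ]
  expect_equal(ref$contrast_median, 0)
  expect_equal(ref$contrast_lower, 0)
  expect_equal(ref$contrast_upper, 0)

  # constructed difference: combo anti-anti = pro-pro + 1 exactly
  draws2 <- draws
  draws2[, "pref_anti_anti"] <- draws2[, "pref_pro_pro"] + 1
  ct2 <- block_contrasts(draws2, reference = "pro-pro")
  expect_equal(ct2$contrast_median[ct2$combination == "anti-anti"], 1)

  # independent quantile oracle for offsets (recentred draws)
  off <- draws - rowMeans(draws)
  d <- off[, "pref_anti_pro"] - off[, "pref_pro_pro"]
  expect_equal(ct$contrast_median[ct$combination == "anti-pro"],
               unname(quantile(d, 0.5, type = 7)))
  # narrowest window containing ceiling(0.95 m) of the sorted differences
  srt <- sort(d); k <- ceiling(0.95 * length(srt))
  widths <- srt[k:length(srt)] - srt[1:(length(srt) - k + 1)]
  j <- which.min(widths)
  expect_equal(ct$contrast_lower[ct$combination == "anti-pro"], srt[j])
  expect_equal(ct$contrast_upper[ct$combination == "anti-pro"], srt[j + k - 1])

  expect_error(block_contrasts(draws, reference = "pro-none"), "unknown")
})

test_that("hpdi returns the narrowest interval", {
  x <- c(rep(0, 90), seq(5, 10, length.out = 10))
  h <- hpdi(x, 0.9)
  expect_equal(h, c(0, 0))
  expect_equal(hpdi(1:100, 1), c(1, 100))
})

test_that("zero observed ties does not crash and drives the blocks negative", {
  pref <- rep(c("anti", "pro"), 10)
  net <- directed_network(sprintf("z%02d", 1:20))
  fit <- block_srm(net, pref, iter = 300, burn = 200, seed = 4,
                   dyad_effects = FALSE)
  expect_lt(max(coef(fit)[fit$block_cols]), 0)
})

test_that("homophily recovery: pro->pro offset ranks highest under a +1.5 block", {
  cfg <- sim_config(n_zones = 1L, zone_sizes = 80L, zone_prevalence = 0.25,
                    srm = list(intercept = -2.5, sd_sender = 0.4,
                               sd_receiver = 0.4, cor_sr = 0.2,
                               sd_dyad = 0.4, cor_dyad = 0.5))
  set.seed(11)
  y <- rbinom(80, 1, 0.25)
  hom <- matrix(c(0, 0, 0, 1.5), 2, 2, byrow = TRUE)
  sel <- simulate_selection_reports(y, NULL, hom, cfg, seed = 12)
  fit <- block_srm(sel$reports, pref = c("anti", "pro")[y + 1L],
                   iter = 1200, burn = 800, seed = 13)
  ct <- block_contrasts(fit, reference = "pro-pro")
  off <- setNames(ct$offset_median, ct$combination)
  expect_gt(off["pro-pro"], max(off[c("anti-anti", "anti-pro", "pro-anti")]))
})

test_that("null zone: all pairwise offset HPDIs overlap", {
  cfg <- sim_config(n_zones = 1L, zone_sizes = 80L, zone_prevalence = 0.25,
                    srm = list(intercept = -2.5, sd_sender = 0.4,
                               sd_receiver = 0.4, cor_sr = 0.2,
                               sd_dyad = 0.4, cor_dyad = 0.5))
  set.seed(21)
  y <- rbinom(80, 1, 0.25)
  sel <- simulate_selection_reports(y, NULL, matrix(0, 2, 2), cfg, seed = 22)
  fit <- block_srm(sel$reports, pref = c("anti", "pro")[y + 1L],
                   iter = 1200, burn = 800, seed = 23)
  ct <- block_contrasts(fit)
  for (a in 1:3) for (b in (a + 1):4) {
    expect_true(ct$offset_lower[a] <= ct$offset_upper[b] &&
                  ct$offset_lower[b] <= ct$offset_upper[a])
  }
})

test_that("fit_all_zones skips undersized zones and is deterministic", {
  cfg <- sim_config(n_zones = 3L, zone_sizes = c(40L, 40L, 12L),
                    zone_prevalence = c(0.25, 0.25, 0.25),
                    reporter_fraction = 1)
  sim <- simulate_study(cfg, seed = 31)
  sim$respondents$is_reporter[sim$respondents$zone == 3] <-
    c(rep(TRUE, 5), rep(FALSE, 7))
  zf <- fit_all_zones(sim$respondents, sim$nominations,
                      gender_blocks = FALSE, iter = 200, burn = 150, seed = 5)
  expect_equal(length(zf$contrasts), 2L)
  expect_match(zf$skipped[["3"]], "insufficient|no advice")
  zf2 <- fit_all_zones(sim$respondents, sim$nominations,
                       gender_blocks = FALSE, iter = 200, burn = 150, seed = 5)
  expect_identical(zf$contrasts, zf2$contrasts)
})
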