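# Latent-network estimation from double-sampled name-generator reports, and
# the deterministic union / intersection baselines.

# Tally, for every ordered pair over the roster, how many eligible
# statements exist (n_obs) and how many were positive (n_pos).  The ordered
# pair (i, j) can be observed by i through the out-side generator and by j
# through the in-side generator (whose nominations are stored in the
# reversed convention: ego e naming alter a asserts the tie a -> e).
report_counts <- function(reports, roster) {
  roster <- as.character(roster)
  n <- length(roster)
  is_rep <- roster %in% reports$reporter_set
  n_obs <- outer(is_rep, rep(1L, n)) + outer(rep(1L, n), is_rep)
  diag(n_obs) <- 0L
  n_pos <- matrix(0L, n, n)
  out <- reports$out_reports
  oe <- match(as.character(out$ego), roster)
  oa <- match(as.character(out$alter), roster)
  ok <- !is.na(oe) & !is.na(oa) & oe != oa
  n_self <- sum(!is.na(oe) & !is.na(oa) & oe == oa)
  idx <- cbind(oe[ok], oa[ok])
  n_pos[idx] <- n_pos[idx] + 1L
  inr <- reports$in_reports
  ie <- match(as.character(inr$ego), roster)
  ia <- match(as.character(inr$alter), roster)
  ok <- !is.na(ie) & !is.na(ia) & ie != ia
  n_self <- n_self + sum(!is.na(ie) & !is.na(ia) & ie == ia)
  idx <- cbind(ia[ok], ie[ok])  # tie alter -> ego
  n_pos[idx] <- n_pos[idx] + 1L
  if (n_self > 0L) warning(n_self, " self-report(s) dropped")
  n_pos <- pmin(n_pos, n_obs)  # duplicate statements collapse
  list(n_obs = n_obs, n_pos = n_pos, is_reporter = is_rep)
}

#' Estimate the latent network behind double-sampled reports
#'
#' Fits, by Gibbs sampling, a Bayesian latent-network model in which every
#' ordered pair carries a latent tie indicator, each unordered dyad has a
#' log-linear mutuality term, and each eligible reporter's statement about a
#' pair is Bernoulli(`lambda1`) when the latent tie exists and
#' Bernoulli(`lambda0`) otherwise.  Reporting rates carry Beta priors and
#' are updated conjugately; the mutuality log-odds `m` carries a Gaussian
#' prior and a random-walk update.  Pairs observable by both endpoints are
#' automatically weighted by both statements; pairs observable by neither
#' endpoint revert to the prior tie probability.
#'
#' The dyad prior is `P(y_ij, y_ji) ~ exp(a (y_ij + y_ji) + m y_ij y_ji)`
#' with `a` the network density log-odds, estimated under a Gaussian prior
#' centred at `qlogis(prior_tie)`, and `m` the mutuality log-odds.  The
#' mutuality estimate is `eta_est = E[P(Y_ji = 1 | Y_ij = 1)] =
#' E[plogis(a + m)]` over the posterior; the binarization threshold is
#' `t_rho = 0.33 * eta_est + 0.10` and a tie is declared where
#' `rho_ij > t_rho` (strict).
#'
#' @param reports a [double_sampled_reports()] object.
#' @param roster ids defining the node set; defaults to the reporter set
#'   (`scope = "reporters"`), or pass the full survey roster with
#'   `scope = "full"`.
#' @param scope `"reporters"` fits among reporters only; `"full"` fits over
#'   the supplied roster, treating pairs without an eligible reporter as
#'   prior-determined.
#' @param prior_tie centre of the density prior: the prior tie probability
#'   for an ordered pair.
#' @param priors list with `lambda1` and `lambda0` Beta parameters (each
#'   length 2), `mutuality_sd` for the Gaussian prior on `m`, and
#'   `density_sd` for the Gaussian prior on `a` around
#'   `qlogis(prior_tie)`.
#' @param fixed optional list fixing `lambda1`, `lambda0`, `mutuality`
#'   and/or `density` (the latter as a probability, fixing
#'   `a = qlogis(density)`) at known values (used for noiseless limits and
#'   exact enumeration checks).
#' @param iter,burn retained and burn-in Gibbs iterations.
#' @param seed integer seed.
#' @return object of class `latent_network`: `rho` (posterior tie
#'   probability matrix), `eta_est`, `t_rho`, `binarized`
#'   (a [directed_network()]), `draws` (lambda1, lambda0, mutuality),
#'   `lambda` posterior means, `coverage` (eligible-statement counts),
#'   `reporter_set`, `settings`.
#' @export
latent_network <- function(reports, roster = reports$reporter_set,
                           scope = c("reporters", "full"),
                           prior_tie = 0.005,
                           priors = list(lambda1 = c(9, 1),
                                         lambda0 = c(1, 99),
                                         mutuality_sd = 3,
                                         density_sd = 2),
                           fixed = list(),
                           iter = 1500L, burn = 500L, seed = 1L) {
  scope <- match.arg(scope)
  if (scope == "reporters") roster <- reports$reporter_set
  if (nrow(reports$out_reports) + nrow(reports$in_reports) == 0L) {
    stop("empty report set")
  }
  rc <- report_counts(reports, roster)
  n <- length(roster)

  ut <- which(upper.tri(rc$n_obs), arr.ind = TRUE)
  active <- rc$n_obs[ut] + rc$n_obs[ut[, c(2L, 1L)]] > 0L
  di <- ut[active, 1L]; dj <- ut[active, 2L]
  fix_lambda <- !is.null(fixed$lambda1) || !is.null(fixed$lambda0)
  fix_m <- !is.null(fixed$mutuality)
  fix_a <- !is.null(fixed$density)
  set.seed(seed)
  res <- latent_gibbs_cpp(
    rc$n_obs[cbind(di, dj)], rc$n_pos[cbind(di, dj)],
    rc$n_obs[cbind(dj, di)], rc$n_pos[cbind(dj, di)],
    a_init = qlogis(if (fix_a) fixed$density else prior_tie),
    a_prior_mean = qlogis(prior_tie),
    a_prior_sd = priors$density_sd %||% 2,
    m_init = if (fix_m) fixed$mutuality else 0,
    m_sd = priors$mutuality_sd,
    l1_a = priors$lambda1[1L], l1_b = priors$lambda1[2L],
    l0_a = priors$lambda0[1L], l0_b = priors$lambda0[2L],
    lambda1_init = if (!is.null(fixed$lambda1)) fixed$lambda1 else 0.8,
    lambda0_init = if (!is.null(fixed$lambda0)) fixed$lambda0 else 0.01,
    fix_lambda = fix_lambda, fix_m = fix_m, fix_a = fix_a,
    iter = as.integer(iter), burn = as.integer(burn), prop_sd = 0.25)

  m_draws <- res$draws[, 3L]
  a_draws <- res$draws[, 4L]
  # prior marginal tie probability for pairs observable by no reporter
  prior_marg <- mean((exp(a_draws) + exp(2 * a_draws + m_draws)) /
                       (1 + 2 * exp(a_draws) + exp(2 * a_draws + m_draws)))
  rho <- matrix(prior_marg, n, n, dimnames = list(roster, roster))
  diag(rho) <- 0
  rho[cbind(di, dj)] <- res$rho_ij
  rho[cbind(dj, di)] <- res$rho_ji
  eta_est <- mean(plogis(a_draws + m_draws))
  est <- structure(list(
    rho = rho, eta_est = eta_est, t_rho = 0.33 * eta_est + 0.10,
    draws = data.frame(lambda1 = res$draws[, 1L], lambda0 = res$draws[, 2L],
                       mutuality = m_draws, density = a_draws),
    lambda = c(lambda1 = mean(res$draws[, 1L]),
               lambda0 = mean(res$draws[, 2L])),
    density = mean(plogis(a_draws)),
    coverage = rc$n_obs, reporter_set = reports$reporter_set,
    roster = roster, pair = reports$pair, prior_tie = prior_tie,
    scope = scope, mh_acceptance = res$mh_acceptance,
    settings = list(iter = iter, burn = burn, seed = seed, priors = priors,
                    fixed = fixed)),
    class = "latent_network")
  est$binarized <- threshold_ties(est)
  est
}

#' @export
print.latent_network <- function(x, ...) {
  cat(sprintf(
    paste0("<latent_network '%s' (%s scope): n = %d, eta_est = %.3f, ",
           "t_rho = %.3f,\n  lambda1 = %.3f, lambda0 = %.4f, %d binarized ties>\n"),
    x$pair, x$scope, length(x$roster), x$eta_est, x$t_rho,
    x$lambda["lambda1"], x$lambda["lambda0"], n_ties(x$binarized)))
  invisible(x)
}

#' @export
summary.latent_network <- function(object, ...) {
  list(eta_est = object$eta_est, t_rho = object$t_rho,
       lambda = object$lambda,
       n_ties = n_ties(object$binarized),
       rho_quantiles = quantile(object$rho[row(object$rho) != col(object$rho)],
                                c(0.5, 0.9, 0.99, 1)))
}

#' Binarize a latent-network estimate with the mutuality threshold
#'
#' Declares a tie wherever the posterior tie probability strictly exceeds
#' `t_rho = 0.33 * eta_est + 0.10`.
#'
#' @param estimate a `latent_network` fit (or any list with elements `rho`,
#'   `eta_est`, `roster`).
#' @param eta_est override the mutuality estimate (must lie in [0, 1]).
#' @return a [directed_network()].
#' @export
threshold_ties <- function(estimate, eta_est = estimate$eta_est) {
  if (!is.finite(eta_est) || eta_est < 0 || eta_est > 1) {
    stop("eta_est must lie in [0, 1]")
  }
  t_rho <- 0.33 * eta_est + 0.10
  idx <- which(estimate$rho > t_rho & row(estimate$rho) != col(estimate$rho),
               arr.ind = TRUE)
  net <- directed_network(estimate$roster, idx[, 1L], idx[, 2L],
                          layer = paste0(estimate$pair %||% "latent",
                                         "_latent"))
  attr(net, "t_rho") <- t_rho
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic union baseline
#'
#' A tie exists iff either side of the double-sampled generator reported it.
#'
#' @param reports a [double_sampled_reports()].
#' @param roster node set (defaults to the reporter set).
#' @return a [directed_network()].
#' @export
baseline_union <- function(reports, roster = reports$reporter_set) {
  rc <- report_counts(reports, roster)
  idx <- which(rc$n_pos >= 1L, arr.ind = TRUE)
  directed_network(roster, idx[, 1L], idx[, 2L],
                   layer = paste0(reports$pair, "_union"))
}

#' Deterministic intersection baseline
#'
#' A tie exists only where both sides reported it; pairs where either
#' endpoint could not report are excluded (the network's `"eligible"`
#' attribute marks the pairs in the intersection's denominator).
#'
#' @inheritParams baseline_union
#' @return a [directed_network()] with attribute `"eligible"` (logical
#'   matrix of double-coverage pairs).
#' @export
baseline_intersection <- function(reports, roster = reports$reporter_set) {
  rc <- report_counts(reports, roster)
  eligible <- rc$n_obs == 2L
  idx <- which(rc$n_pos >= 2L & eligible, arr.ind = TRUE)
  net <- directed_network(roster, idx[, 1L], idx[, 2L],
                          layer = paste0(reports$pair, "_intersection"))
  attr(net, "eligible") <- eligible
  net
}

#' Tie-recovery accuracy of an estimated network
#'
#' Compares an estimated directed network against the true network over the
#' ordered pairs covered by at least one eligible reporter (or an explicit
#' pair mask), reporting sensitivity, specificity and balanced accuracy.
#'
#' @param estimate a [directed_network()] (e.g. a binarized latent network
#'   or a baseline).
#' @param truth the true [directed_network()] (roster must contain the
#'   estimate's roster).
#' @param coverage logical or integer matrix over the estimate's roster;
#'   pairs with a positive entry enter the evaluation.  Defaults to all
#'   off-diagonal pairs.
#' @return named vector: `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `n_pairs`.
#' @export
tie_recovery <- function(estimate, truth, coverage = NULL) {
  roster <- estimate$roster
  Ahat <- adjacency_matrix(estimate)
  Atru <- adjacency_matrix(truth)[roster, roster]
  mask <- row(Ahat) != col(Ahat)
  if (!is.null(coverage)) mask <- mask & (coverage > 0)
  pred <- Ahat[mask]; tru <- Atru[mask]
  sens <- if (any(tru == 1)) mean(pred[tru == 1] == 1) else NA_real_
  spec <- if (any(tru == 0)) mean(pred[tru == 0] == 0) else NA_real_
  c(sensitivity = sens, specificity = spec,
    balanced_accuracy = mean(c(sens, spec)), n_pairs = sum(mask))
}

#' Histogram of posterior tie probabilities with the binarization threshold
#'
#' @param x a `latent_network` fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.latent_network <- function(x, ...) {
  off <- x$rho[row(x$rho) != col(x$rho)]
  graphics::hist(off[off > 0.01], breaks = 40,
                 main = sprintf("posterior tie probabilities (t_rho = %.3f)",
                                x$t_rho),
                 xlab = expression(rho[ij]), ...)
  graphics::abline(v = x$t_rho, lty = 2)
  invisible(x)
}
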