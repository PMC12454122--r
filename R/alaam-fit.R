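# Bayesian ALAAM fitting by the exchange algorithm.  The posterior
# p(theta | y) ~ exp(theta . s(y)) / Z(theta) * p(theta) has an intractable
# Z(theta); the exchange algorithm cancels it by drawing an auxiliary
# attribute vector y' from the model at the proposed theta' and accepting
# with ratio
#   p(theta') exp(theta' . s(y)) exp(theta . s(y'))
#   ---------------------------------------------- .
#   p(theta)  exp(theta . s(y))  exp(theta' . s(y'))

#' Fit an autologistic actor-attribute model
#'
#' Estimates the posterior over ALAAM coefficients for an observed binary
#' attribute on a fixed directed network, using exchange-algorithm MCMC with
#' Gaussian priors.  Each step proposes `theta'` from an adaptive
#' multivariate random walk, draws an auxiliary attribute vector at
#' `theta'` by `aux_sweeps` full Gibbs sweeps started at the observed
#' vector, and accepts with the exchange ratio (which cancels the
#' intractable normalizing constant).  Proposal adaptation is frozen after
#' burn-in, preserving detailed balance for the retained draws.
#'
#' @param formula optional model formula, e.g. `pro ~ age + gender`; the
#'   response is the 0/1 attribute and terms are expanded with
#'   [stats::model.matrix()] (its intercept column is dropped: the ALAAM
#'   intercept statistic plays that role).
#' @param data data frame for `formula`, rows aligned to the roster.
#' @param network a [directed_network()].
#' @param y 0/1 attribute vector (alternative to `formula`).
#' @param covariates numeric covariate data frame/matrix (alternative to
#'   `formula`).
#' @param contagion enabled contagion variants (see [alaam_statistics()]).
#' @param tie_scope `"all"`, `"kin"` or `"nonkin"`.
#' @param degree_effects include out-degree activity and in-degree
#'   popularity statistics (the activity statistic is the lower-order effect
#'   of direct contagion and is included by default).
#' @param prior_mean,prior_sd Gaussian prior on every coefficient
#'   (recycled).
#' @param iter retained exchange iterations (after burn-in).
#' @param burn burn-in iterations.
#' @param thin keep every `thin`-th retained draw.
#' @param aux_sweeps full Gibbs sweeps for each auxiliary draw; the key
#'   approximation knob of the sampler.
#' @param seed integer seed.
#' @param init initial coefficient vector (default: logit of the observed
#'   prevalence for the intercept, zero elsewhere).
#' @return object of class `alaam`: `draws` (iterations x parameters),
#'   `acceptance`, `model` metadata, `y_obs`, `obs_stats`, `settings`.
#' @export
alaam <- function(formula = NULL, data = NULL, network, y = NULL,
                  covariates = NULL, contagion = "direct",
                  tie_scope = "all", degree_effects = TRUE,
                  prior_mean = 0, prior_sd = 5,
                  iter = 2000L, burn = 500L, thin = 1L,
                  aux_sweeps = 50L, seed = 1L, init = NULL) {
  if (!is.null(formula)) {
    mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
    y <- as.integer(stats::model.response(mf))
    if (!all(y %in% 0:1)) {
      y <- as.integer(y == max(y))  # factor coded 1/2
    }
    mm <- stats::model.matrix(attr(mf, "terms"), mf)
    covariates <- mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
  }
  y <- as.integer(y)
  if (length(y) != n_nodes(network)) stop("y length must match roster size")
  if (anyNA(y)) stop("missing values in the outcome")
  if (all(y == 0L) || all(y == 1L)) {
    stop("outcome non-identified: attribute vector is constant")
  }
  model <- alaam_build(network, covariates, contagion, tie_scope,
                       degree_effects)
  p <- length(model$stat_names)
  s_obs <- alaam_stats_from_model(model, y)
  cont_names <- grep("^contagion_", model$stat_names, value = TRUE)
  for (cn in cont_names) {
    if (s_obs[[cn]] == 0 && all(y >= 0)) {
      # a contagion count of 0 in the data is legitimate, but a statistic
      # that cannot vary (no qualifying pairs at all) is not identified
      npairs <- if (cn == "contagion_transitive") {
        if (is.null(model$triads)) 0L else ncol(model$triads)
      } else nrow(model$pairs[[sub("contagion_", "", cn)]])
      if (npairs == 0L) {
        warning("statistic ", cn, " is constant on this network; ",
                "its coefficient is prior-determined")
      }
    }
  }

  prior_mean <- rep_len(prior_mean, p)
  prior_sd <- rep_len(prior_sd, p)
  log_prior <- function(th) sum(stats::dnorm(th, prior_mean, prior_sd,
                                             log = TRUE))

  set.seed(seed)
  theta <- setNames(numeric(p), model$stat_names)
  theta["intercept"] <- qlogis(mean(y))
  if (!is.null(init)) {
    theta[names(align_theta(init, model))] <- align_theta(init, model)
  }

  total <- burn + iter
  keep <- floor(iter / thin)
  draws <- matrix(NA_real_, keep, p, dimnames = list(NULL, model$stat_names))
  log_scale <- 0
  base_scale <- 2.38 / sqrt(p)
  chol_cov <- diag(0.1, p)
  hist_draws <- matrix(NA_real_, total, p)
  n_acc <- 0L; n_acc_kept <- 0L
  lp_cur <- log_prior(theta)
  k <- 0L

  for (it in seq_len(total)) {
    z <- rnorm(p)
    prop <- theta + base_scale * exp(log_scale) * as.vector(chol_cov %*% z)
    y_aux <- gibbs_from_model(model, prop, init = y,
                              burn_in = aux_sweeps, n_draws = 1L, thin = 0L)
    s_aux <- alaam_stats_from_model(model, as.integer(y_aux[1L, ]))
    lp_prop <- log_prior(prop)
    log_alpha <- sum((prop - theta) * (s_obs - s_aux)) + lp_prop - lp_cur
    acc <- log(runif(1L)) < log_alpha
    if (acc) {
      theta <- prop
      lp_cur <- lp_prop
      n_acc <- n_acc + 1L
    }
    hist_draws[it, ] <- theta
    if (it <= burn) {
      # Robbins-Monro scale adaptation toward 0.234 acceptance, plus an
      # empirical-covariance proposal shape; frozen after burn-in.
      log_scale <- log_scale + 2 * (min(exp(log_alpha), 1) - 0.234) / sqrt(it)
      if (it >= 200L && it %% 50L == 0L) {
        emp <- stats::cov(hist_draws[100L:it, , drop = FALSE])
        ch <- tryCatch(chol(emp + diag(1e-8 + 1e-4 * mean(diag(emp)), p)),
                       error = function(e) NULL)
        if (!is.null(ch)) chol_cov <- t(ch)
      }
    } else {
      if (acc) n_acc_kept <- n_acc_kept + 1L
      j <- it - burn
      if (j %% thin == 0L && k < keep) {
        k <- k + 1L
        draws[k, ] <- theta
      }
    }
  }

  structure(list(draws = draws[seq_len(k), , drop = FALSE],
                 acceptance = n_acc / total,
                 acceptance_sampling = n_acc_kept / iter,
                 y_obs = y, obs_stats = s_obs,
                 model = list(stat_names = model$stat_names,
                              contagion = model$contagion,
                              tie_scope = tie_scope, layer = network$layer,
                              n = model$n),
                 network = network, covariates = covariates,
                 degree_effects = degree_effects,
                 settings = list(iter = iter, burn = burn, thin = thin,
                                 aux_sweeps = aux_sweeps, seed = seed,
                                 prior_mean = prior_mean,
                                 prior_sd = prior_sd)),
            class = "alaam")
}

#' Posterior summary table
#'
#' Per parameter: posterior median, central 95% credible interval, and the
#' proportion of draws above zero (the quantity printed alongside the
#' contagion posteriors).
#'
#' @param draws draw matrix (iterations x parameters) or an `alaam` fit.
#' @return data frame with columns `parameter`, `median`, `lower`, `upper`,
#'   `prop_above_zero`.
#' @export
posterior_summary <- function(draws) {
  if (inherits(draws, "alaam")) draws <- draws$draws
  draws <- as.matrix(draws)
  data.frame(
    parameter = colnames(draws),
    median = apply(draws, 2L, median),
    lower = apply(draws, 2L, quantile, 0.025),
    upper = apply(draws, 2L, quantile, 0.975),
    prop_above_zero = apply(draws, 2L, function(x) mean(x > 0)),
    row.names = NULL
  )
}

#' @export
print.alaam <- function(x, ...) {
  cat(sprintf(
    "ALAAM fit (exchange algorithm) on layer '%s' (%s ties), n = %d\n",
    x$model$layer, x$model$tie_scope, x$model$n))
  cat(sprintf("%d retained draws, acceptance %.2f\n",
              nrow(x$draws), x$acceptance))
  print(posterior_summary(x), digits = 3)
  invisible(x)
}

#' @export
summary.alaam <- function(object, ...) {
  out <- posterior_summary(object)
  attr(out, "acceptance") <- object$acceptance
  attr(out, "settings") <- object$settings
  class(out) <- c("summary.alaam", "data.frame")
  out
}

#' @export
print.summary.alaam <- function(x, ...) {
  cat(sprintf("ALAAM posterior summary (acceptance %.2f)\n",
              attr(x, "acceptance")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' @export
coef.alaam <- function(object, ...) {
  apply(object$draws, 2L, median)
}

#' @export
plot.alaam <- function(x, parameters = grep("^contagion_",
                                            colnames(x$draws), value = TRUE),
                       ...) {
  if (!length(parameters)) parameters <- colnames(x$draws)[1L]
  old <- graphics::par(mfrow = c(length(parameters), 1L),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in parameters) {
    d <- density(x$draws[, p])
    plot(d, main = p, xlab = "coefficient", ...)
    graphics::abline(v = 0, lty = 2)
    graphics::mtext(sprintf("P(>0) = %.2f", mean(x$draws[, p] > 0)),
                    side = 3, line = -1.2, adj = 0.98, cex = 0.8)
  }
  invisible(x)
}

#' Posterior-predictive attribute draws from a fitted ALAAM
#'
#' @param object an `alaam` fit.
#' @param nsim number of simulated attribute vectors.
#' @param seed integer seed.
#' @param sweeps Gibbs sweeps per simulation (each chain starts at the
#'   observed vector).
#' @param ... unused.
#' @return `nsim x n` integer matrix.
#' @export
simulate.alaam <- function(object, nsim = 1L, seed = 1L, sweeps = 100L, ...) {
  set.seed(seed)
  rows <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  model <- alaam_build(object$network, object$covariates,
                       object$model$contagion, object$model$tie_scope,
                       object$degree_effects)
  out <- matrix(NA_integer_, nsim, model$n)
  for (i in seq_len(nsim)) {
    th <- object$draws[rows[i], ]
    out[i, ] <- gibbs_from_model(model, th, init = object$y_obs,
                                 burn_in = sweeps, n_draws = 1L, thin = 0L)
  }
  out
}

#' Conditional attribute probabilities from a fitted ALAAM
#'
#' Returns `P(y_i = 1 | y_-i = observed)` at the posterior median
#' coefficients -- the model's node-level fitted probabilities.
#'
#' @param object an `alaam` fit.
#' @param ... unused.
#' @export
predict.alaam <- function(object, ...) {
  model <- alaam_build(object$network, object$covariates,
                       object$model$contagion, object$model$tie_scope,
                       object$degree_effects)
  th <- coef(object)
  y <- object$y_obs
  vapply(seq_len(model$n), function(i) {
    y1 <- y; y1[i] <- 1L
    y0 <- y; y0[i] <- 0L
    d <- alaam_stats_from_model(model, y1) - alaam_stats_from_model(model, y0)
    plogis(sum(th * d))
  }, numeric(1L))
}

#' Residuals of a fitted ALAAM
#'
#' Observed attribute minus the conditional fitted probability.
#'
#' @param object an `alaam` fit.
#' @param ... unused.
#' @export
residuals.alaam <- function(object, ...) {
  object$y_obs - predict(object)
}

#' Goodness-of-fit simulation for a fitted ALAAM
#'
#' For `n_sim` posterior draws, simulates an attribute vector from the model
#' and computes the full statistic set, including contagion variants that
#' were not in the fitted model.  Reports the simulated mean and SD of each
#' statistic and the observed statistic's t-ratio `(obs - mean) / SD`
#' (`NA` when the simulated SD is zero).
#'
#' @param fit an `alaam` fit.
#' @param n_sim number of posterior-predictive simulations (>= 2).
#' @param seed integer seed.
#' @param sweeps Gibbs sweeps per simulation.
#' @param variants statistic set to audit (defaults to all contagion
#'   variants plus the fitted statistics).
#' @return data frame of class `alaam_gof` with columns `statistic`,
#'   `observed`, `sim_mean`, `sim_sd`, `t_ratio`.
#' @export
goodness_of_fit <- function(fit, n_sim = 100L, seed = 1L, sweeps = 100L,
                            variants = CONTAGION_VARIANTS) {
  if (n_sim < 2L) stop("n_sim must be >= 2")
  audit <- alaam_build(fit$network, fit$covariates,
                       check_contagion(union(fit$model$contagion, variants)),
                       fit$model$tie_scope, fit$degree_effects)
  obs <- alaam_stats_from_model(audit, fit$y_obs)
  sims <- simulate(fit, nsim = n_sim, seed = seed, sweeps = sweeps)
  sim_stats <- t(apply(sims, 1L, function(y)
    alaam_stats_from_model(audit, y)))
  m <- colMeans(sim_stats)
  s <- apply(sim_stats, 2L, sd)
  out <- data.frame(statistic = audit$stat_names, observed = as.numeric(obs),
                    sim_mean = m, sim_sd = s,
                    t_ratio = ifelse(s > 0, (as.numeric(obs) - m) / s,
                                     NA_real_),
                    row.names = NULL)
  class(out) <- c("alaam_gof", "data.frame")
  out
}
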