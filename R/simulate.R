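# Synthetic study generator: populations, multi-layer networks, capped noisy
# name-generator reports, and preference vectors under known influence or
# selection regimes.

#' Derive a stage seed from a master seed
#'
#' Deterministic splitting rule used by every multi-stage routine: stage k of
#' a run with master seed m uses `(m * 7919 + k * 104729) mod (2^31 - 1)`.
#'
#' @param master integer master seed.
#' @param stage integer stage index.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 7919 + as.numeric(stage) * 104729) %%
               2147483646) + 1L
}

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the study conditions: nine administrative zones of unequal size
#' (about 5,000 adults in total), roughly half of respondents sampled as
#' network reporters, up to ten nominations per name generator, four latent
#' relationship layers with strong within-zone mixing and layer-specific
#' reciprocity, kin-labelled ties, and a low-prevalence binary preference
#' whose zone-level prevalence spans roughly 1--12%.
#'
#' @param n_zones number of zones.
#' @param zone_sizes integer vector (length `n_zones`) of zone populations.
#' @param gender_ratio men per woman.
#' @param age_range inclusive age bounds (years); ages are drawn from a
#'   shifted gamma giving a median near 30.
#' @param education_probs probabilities over the four education levels.
#' @param role_prob probability of holding a community role.
#' @param religion_probs probabilities over religions.
#' @param reporter_fraction fraction of respondents flagged as network
#'   reporters.
#' @param nomination_cap maximum nominations per (ego, generator).
#' @param layers character vector of latent layers to generate.
#' @param mean_degree named mean out-degree per layer.
#' @param reciprocity named target reciprocity per layer (share of ties whose
#'   reverse tie also exists).
#' @param within_zone proportion of ties falling within the ego's zone.
#' @param kin_fraction named kin share of ties per layer.
#' @param lambda1 reporting sensitivity: probability a reporter reports each
#'   of their true ties.
#' @param lambda0 false-positive rate: probability a reporter reports each
#'   non-tie (within their own zone).
#' @param zone_prevalence per-zone baseline preference prevalence.
#' @param regime `"null"`, `"influence"` or `"selection"`.
#' @param theta_contagion ALAAM direct-contagion coefficient (influence
#'   regime).
#' @param influence_layer layer carrying the contagion (influence regime).
#' @param block_matrix 2x2 log-odds offsets, rows = focal preference
#'   (anti, pro), cols = target preference (selection regime).
#' @param srm list of social-relations parameters for the selection-regime
#'   dyadic generator: `intercept`, `sd_sender`, `sd_receiver`, `cor_sr`,
#'   `sd_dyad`, `cor_dyad`.
#' @param norm list controlling norm-answer generation: `anti_zero_prob`
#'   (probability an anti respondent reports a 0% decile regardless of the
#'   true prevalence), `decile_noise` (probability of +/- one decile of
#'   reporting noise), `normative_probs_pro` / `normative_probs_anti`
#'   (categorical probabilities over approve / disapprove /
#'   none_of_their_business).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_zones = 9L,
                       zone_sizes = c(1031L, 640L, 590L, 430L, 420L, 380L,
                                      350L, 1122L, 200L),
                       gender_ratio = 0.97,
                       age_range = c(15L, 90L),
                       education_probs = c(none = 0.235, some_primary = 0.465,
                                           completed_primary = 0.12,
                                           some_secondary_plus = 0.18),
                       role_prob = 0.05,
                       religion_probs = c(muslim = 0.941, orthodox = 0.058,
                                          other = 0.001),
                       reporter_fraction = 0.493,
                       nomination_cap = 10L,
                       layers = c("chatting", "respect", "money", "advice"),
                       mean_degree = c(chatting = 3, respect = 2.7,
                                       money = 3.4, advice = 3.5),
                       reciprocity = c(chatting = 0.18, respect = 0.03,
                                       money = 0.42, advice = 0.44),
                       within_zone = 0.95,
                       kin_fraction = c(chatting = 0.55, respect = 0.35,
                                        money = 0.6, advice = 0.65),
                       lambda1 = 0.8,
                       lambda0 = 0.002,
                       zone_prevalence = c(0.121, 0.09, 0.07, 0.055, 0.04,
                                           0.03, 0.025, 0.023, 0.014),
                       regime = c("null", "influence", "selection"),
                       theta_contagion = 0.5,
                       influence_layer = "chatting",
                       block_matrix = matrix(0, 2, 2,
                                             dimnames = list(c("anti", "pro"),
                                                             c("anti", "pro"))),
                       srm = list(intercept = -3.2, sd_sender = 0.5,
                                  sd_receiver = 0.5, cor_sr = 0.2,
                                  sd_dyad = 0.5, cor_dyad = 0.5),
                       norm = list(anti_zero_prob = 0.8, decile_noise = 0.25,
                                   normative_probs_pro =
                                     c(approve = 0.031, disapprove = 0.778,
                                       none_of_their_business = 0.191),
                                   normative_probs_anti =
                                     c(approve = 0.004, disapprove = 0.905,
                                       none_of_their_business = 0.091))) {
  regime <- match.arg(regime)
  if (length(zone_sizes) != n_zones) stop("zone_sizes must have length n_zones")
  if (any(zone_sizes < 2L)) stop("every zone must have size >= 2")
  if (nomination_cap < 1L) stop("nomination_cap must be >= 1")
  stopifnot(lambda1 >= 0, lambda1 <= 1, lambda0 >= 0, lambda0 <= 1,
            reporter_fraction >= 0, reporter_fraction <= 1,
            within_zone >= 0, within_zone <= 1)
  if (length(zone_prevalence) != n_zones) {
    stop("zone_prevalence must have length n_zones")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config: %d zones (n = %d), regime '%s', %d%% reporters,\n",
    "  layers: %s>\n"),
    x$n_zones, sum(x$zone_sizes), x$regime,
    round(100 * x$reporter_fraction), paste(x$layers, collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic respondent population
#'
#' Draws covariates per the configured distributions and assigns the network
#' reporter flag to `floor(reporter_fraction * n)` respondents uniformly at
#' random.  Preference and norm-expectation columns are left `NA`; they are
#' filled by the regime simulators (see [simulate_study()]).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return respondent data frame in the package schema.
#' @export
generate_population <- function(config, seed = 1L) {
  if (any(config$zone_sizes < 2L)) stop("every zone must have size >= 2")
  set.seed(seed)
  n <- sum(config$zone_sizes)
  zone <- rep(seq_len(config$n_zones), config$zone_sizes)
  p_man <- config$gender_ratio / (1 + config$gender_ratio)
  age <- round(config$age_range[1L] + rgamma(n, shape = 2, scale = 8.5))
  age <- pmin(age, config$age_range[2L])
  resp <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    age = age,
    gender = sample(c("man", "woman"), n, TRUE, c(p_man, 1 - p_man)),
    education = sample(EDUCATION_LEVELS, n, TRUE, config$education_probs),
    zone = zone,
    community_role = sample(c("role", "no_role"), n, TRUE,
                            c(config$role_prob, 1 - config$role_prob)),
    religion = sample(names(config$religion_probs), n, TRUE,
                      config$religion_probs),
    pref_daughter = NA_character_,
    pref_daughter_in_law = NA_character_,
    is_reporter = FALSE,
    empirical_expectation_men = NA_integer_,
    empirical_expectation_women = NA_integer_,
    normative_expectation = NA_character_,
    stringsAsFactors = FALSE
  )
  n_rep <- floor(config$reporter_fraction * n)
  resp$is_reporter[sample.int(n, n_rep)] <- TRUE
  resp
}

#' Generate the latent multi-layer networks
#'
#' Per layer, each node's out-degree is Poisson with the configured mean;
#' alters are drawn within the ego's zone with probability `within_zone`
#' (uniformly over the whole remaining roster otherwise), each drawn tie is
#' reciprocated with probability `r/(2-r)` to hit the target reciprocity `r`,
#' and kin flags are Bernoulli with the layer's kin fraction.
#'
#' @param population respondent data frame from [generate_population()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return named list of [directed_network()] objects; each carries an
#'   attribute `"within_zone_share"` with the realized within-zone tie share.
#' @export
generate_networks <- function(population, config, seed = 1L) {
  set.seed(seed)
  n <- nrow(population)
  zone <- population$zone
  zone_members <- split(seq_len(n), zone)
  nets <- list()
  for (layer in config$layers) {
    md <- config$mean_degree[[layer]]
    max_within <- min(lengths(zone_members)) - 1L
    if (md > max_within) {
      warning("mean degree ", md, " infeasible for smallest zone; truncated")
      md <- max_within
    }
    deg <- rpois(n, md)
    from <- integer(0); to <- integer(0)
    for (i in seq_len(n)) {
      if (deg[i] == 0L) next
      within <- rbinom(1L, deg[i], config$within_zone)
      pool_w <- setdiff(zone_members[[zone[i]]], i)
      pool_b <- if (within < deg[i]) setdiff(seq_len(n), c(pool_w, i)) else integer(0)
      alters <- c(sample(pool_w, min(within, length(pool_w))),
                  if (length(pool_b)) sample(pool_b, min(deg[i] - within,
                                                         length(pool_b))))
      from <- c(from, rep.int(i, length(alters)))
      to <- c(to, alters)
    }
    r <- config$reciprocity[[layer]]
    p_back <- if (r >= 1) 1 else r / (2 - r)
    back <- runif(length(from)) < p_back
    from2 <- c(from, to[back]); to2 <- c(to, from[back])
    kin <- runif(length(from2)) < config$kin_fraction[[layer]]
    net <- directed_network(population$id, from2, to2, kin, layer = layer)
    same_zone <- zone[net$from] == zone[net$to]
    attr(net, "within_zone_share") <-
      if (n_ties(net)) mean(same_zone) else NA_real_
    nets[[layer]] <- net
  }
  nets
}

#' Draw a preference vector under the influence (contagion) regime
#'
#' A single draw from the ALAAM joint distribution obtained by Gibbs sampling
#' (see [alaam_simulate()]), after `burn_in` full systematic sweeps.  With a
#' zero contagion coefficient and no covariate effects this reduces to
#' independent logistic draws.
#'
#' @param network a [directed_network()].
#' @param covariates data frame of node covariates aligned to the roster
#'   (may be `NULL` for an intercept-only model).
#' @param theta named coefficient vector; names follow
#'   [alaam_statistics()] naming (e.g. `intercept`, `contagion_direct`,
#'   covariate columns).
#' @param burn_in full Gibbs sweeps before the returned draw.
#' @param seed integer seed.
#' @return integer 0/1 vector over the roster.
#' @export
simulate_influence_attribute <- function(network, covariates = NULL, theta,
                                         burn_in = 1000L, seed = 1L) {
  if (any(!is.finite(theta))) stop("non-finite theta")
  draws <- alaam_simulate(theta, network, covariates,
                          contagion = "direct", n_draws = 1L,
                          burn_in = burn_in, thin = 1L, seed = seed)
  as.integer(draws[1L, ])
}

#' Emit capped, noisy name-generator reports from a true network
#'
#' Each reporter reports each of their true ties with probability `lambda1`
#' and each within-zone non-tie with probability `lambda0`; if more than
#' `cap` survive on one side of one generator, a uniform random subset of
#' size `cap` is kept.  Non-reporters emit nothing.  Out-side reports cover
#' the reporter's outgoing ties; in-side reports cover incoming ties (and
#' are recorded in the reversed convention [build_layer()] expects).
#'
#' @param true_network a [directed_network()].
#' @param reporters ids of respondents able to report.
#' @param lambda1,lambda0 reporting sensitivity and false-positive rate.
#' @param cap nomination cap (use `Inf` for uncapped).
#' @param seed integer seed.
#' @param pair `"money"` or `"advice"`: which double-sampled generator pair
#'   the reports are labelled as.
#' @param zone optional zone vector aligned to the roster; false positives
#'   are drawn within the reporter's zone (cross-zone ties are rare in the
#'   emulated study).  If `NULL`, false positives range over the roster.
#' @return a [double_sampled_reports()] object.
#' @export
simulate_reports <- function(true_network, reporters, lambda1 = 0.8,
                             lambda0 = 0.002, cap = 10L, seed = 1L,
                             pair = c("advice", "money"), zone = NULL) {
  stopifnot(lambda1 >= 0, lambda1 <= 1, lambda0 >= 0, lambda0 <= 1)
  pair <- match.arg(pair)
  gens <- if (pair == "money") c("borrow_out", "borrow_in")
          else c("advice_out", "advice_in")
  set.seed(seed)
  roster <- true_network$roster
  n <- length(roster)
  rep_idx <- match(as.character(reporters), roster)
  if (anyNA(rep_idx)) stop("reporter id absent from roster")
  out_by <- split(true_network$to, true_network$from)
  in_by <- split(true_network$from, true_network$to)
  kin_key <- paste(true_network$from, true_network$to)
  kin_map <- setNames(true_network$kin, kin_key)

  one_side <- function(i, true_alters) {
    hits <- true_alters[runif(length(true_alters)) < lambda1]
    pool <- if (is.null(zone)) setdiff(seq_len(n), c(i, true_alters))
            else setdiff(which(zone == zone[i]), c(i, true_alters))
    fp <- pool[runif(length(pool)) < lambda0]
    named <- c(hits, fp)
    if (length(named) > cap) named <- sample(named, cap)
    named
  }
  rows_out <- list(); rows_in <- list()
  for (i in rep_idx) {
    named <- one_side(i, out_by[[as.character(i)]])
    if (length(named)) {
      k <- kin_map[paste(i, named)]
      rows_out[[length(rows_out) + 1L]] <- data.frame(
        ego = roster[i], generator = gens[1L], alter = roster[named],
        kin = unname(!is.na(k) & k), relationship = "sim",
        stringsAsFactors = FALSE)
    }
    named <- one_side(i, in_by[[as.character(i)]])
    if (length(named)) {
      k <- kin_map[paste(named, i)]
      rows_in[[length(rows_in) + 1L]] <- data.frame(
        ego = roster[i], generator = gens[2L], alter = roster[named],
        kin = unname(!is.na(k) & k), relationship = "sim",
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(ego = character(), generator = character(),
                      alter = character(), kin = logical(),
                      relationship = character(), stringsAsFactors = FALSE)
  nom <- rbind(if (length(rows_out)) do.call(rbind, rows_out) else empty,
               if (length(rows_in)) do.call(rbind, rows_in) else empty)
  double_sampled_reports(nom, pair = pair,
                         reporter_set = roster[rep_idx])
}

#' Draw latent ties and reports under the selection (homophily) regime
#'
#' Latent ties for one zone are drawn from the block + social-relations
#' generative model: `logit P(Y_ij = 1) = intercept + B[g_i, g_j] + s_i +
#' r_j + d_ij`, with bivariate-normal sender/receiver effects and
#' reciprocity-correlated dyad effects, then double-sampled reports are
#' emitted through [simulate_reports()].
#'
#' @param attributes integer 0/1 preference vector (1 = pro).
#' @param covariates respondent data frame for the zone's members (used for
#'   ids; may be `NULL`, in which case ids are generated).
#' @param block_matrix 2x2 log-odds offsets, rows = focal (anti, pro),
#'   cols = target.
#' @param config a [sim_config()] (reporting model and SRM parameters).
#' @param seed integer seed.
#' @return list with elements `network` (the latent [directed_network()])
#'   and `reports` (a [double_sampled_reports()]; every zone member is a
#'   reporter, matching the per-zone homophily analyses).
#' @export
simulate_selection_reports <- function(attributes, covariates = NULL,
                                       block_matrix, config = sim_config(),
                                       seed = 1L) {
  set.seed(seed)
  n <- length(attributes)
  ids <- if (!is.null(covariates)) as.character(covariates$id)
         else sprintf("Z%04d", seq_len(n))
  p <- config$srm
  sr <- matrix(rnorm(2L * n), n, 2L)
  sr[, 2L] <- p$cor_sr * sr[, 1L] + sqrt(1 - p$cor_sr^2) * sr[, 2L]
  s <- p$sd_sender * sr[, 1L]
  r <- p$sd_receiver * sr[, 2L]
  g <- attributes + 1L  # 1 = anti, 2 = pro
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      z1 <- rnorm(1L); z2 <- rnorm(1L)
      d_ij <- p$sd_dyad * z1
      d_ji <- p$sd_dyad * (p$cor_dyad * z1 + sqrt(1 - p$cor_dyad^2) * z2)
      pr_ij <- plogis(p$intercept + block_matrix[g[i], g[j]] + s[i] + r[j] + d_ij)
      pr_ji <- plogis(p$intercept + block_matrix[g[j], g[i]] + s[j] + r[i] + d_ji)
      if (runif(1L) < pr_ij) { from <- c(from, i); to <- c(to, j) }
      if (runif(1L) < pr_ji) { from <- c(from, j); to <- c(to, i) }
    }
  }
  net <- directed_network(ids, from, to, kin = FALSE, layer = "advice")
  reports <- simulate_reports(net, reporters = ids,
                              lambda1 = config$lambda1,
                              lambda0 = config$lambda0,
                              cap = config$nomination_cap,
                              seed = stage_seed(seed, 1L), pair = "advice")
  list(network = net, reports = reports)
}

#' Simulate norm-expectation answers
#'
#' Empirical-expectation deciles are drawn around the respondent's true zone
#' prevalence (rounded to the nearest 10%), with anti respondents reporting
#' the 0% decile with probability `norm$anti_zero_prob` regardless, and
#' symmetric one-decile reporting noise with probability
#' `norm$decile_noise`.  The normative answer is categorical conditional on
#' own preference.
#'
#' @param attributes integer 0/1 preference vector.
#' @param zone integer zone label per respondent.
#' @param zone_prevalence true prevalence per zone (proportion, 0-1).
#' @param config a [sim_config()] (its `norm` component is used).
#' @param seed integer seed.
#' @return data frame with columns `empirical_expectation_men`,
#'   `empirical_expectation_women`, `normative_expectation`.
#' @export
simulate_norm_answers <- function(attributes, zone, zone_prevalence,
                                  config = sim_config(), seed = 1L) {
  set.seed(seed)
  n <- length(attributes)
  nm <- config$norm
  base_dec <- round(zone_prevalence[zone] * 10) * 10L
  one_col <- function() {
    dec <- base_dec
    noise <- sample(c(-10L, 0L, 10L), n, TRUE,
                    c(nm$decile_noise / 2, 1 - nm$decile_noise,
                      nm$decile_noise / 2))
    dec <- pmin(pmax(dec + noise, 0L), 100L)
    zero <- attributes == 0L & runif(n) < nm$anti_zero_prob
    dec[zero] <- 0L
    dec
  }
  men <- one_col(); women <- one_col()
  normative <- character(n)
  pro <- attributes == 1L
  if (any(pro)) {
    normative[pro] <- sample(names(nm$normative_probs_pro), sum(pro), TRUE,
                             nm$normative_probs_pro)
  }
  if (any(!pro)) {
    normative[!pro] <- sample(names(nm$normative_probs_anti), sum(!pro), TRUE,
                              nm$normative_probs_anti)
  }
  data.frame(empirical_expectation_men = men,
             empirical_expectation_women = women,
             normative_expectation = normative,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study with known ground truth
#'
#' Composes the generator stages in dependency order: population, latent
#' networks, preference vector under the configured regime (independent
#' Bernoulli per zone under `"null"` and `"selection"`; an ALAAM draw with
#' the configured contagion coefficient under `"influence"`; under
#' `"selection"` the advice layer is regenerated per zone from the block +
#' social-relations model), norm answers, and capped noisy reports for all
#' six name generators.
#'
#' @param config a [sim_config()].
#' @param seed master seed; stage seeds are derived via [stage_seed()].
#' @return list of class `sim_study`: `respondents`, `nominations`,
#'   `truth` (true networks, true attribute vector, generating parameters),
#'   `config`, `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  pop <- generate_population(config, stage_seed(seed, 1L))
  nets <- generate_networks(pop, config, stage_seed(seed, 2L))
  n <- nrow(pop)
  zone <- pop$zone

  if (config$regime == "influence") {
    theta <- c(setNames(qlogis(config$zone_prevalence),
                        paste0("zone_intercept", seq_len(config$n_zones))),
               contagion_direct = config$theta_contagion)
    zmat <- outer(zone, seq_len(config$n_zones), `==`) * 1
    colnames(zmat) <- paste0("zone_intercept", seq_len(config$n_zones))
    y <- simulate_influence_attribute(nets[[config$influence_layer]],
                                      as.data.frame(zmat), theta,
                                      burn_in = 1000L,
                                      seed = stage_seed(seed, 3L))
  } else {
    set.seed(stage_seed(seed, 3L))
    y <- rbinom(n, 1L, config$zone_prevalence[zone])
  }

  if (config$regime == "selection" && "advice" %in% config$layers) {
    sel_nets <- list()
    for (z in seq_len(config$n_zones)) {
      idx <- which(zone == z)
      sel <- simulate_selection_reports(y[idx], pop[idx, , drop = FALSE],
                                        config$block_matrix, config,
                                        seed = stage_seed(seed, 100L + z))
      sel_nets[[z]] <- sel$network
    }
    from <- character(0); to <- character(0)
    for (net in sel_nets) {
      from <- c(from, net$roster[net$from]); to <- c(to, net$roster[net$to])
    }
    nets$advice <- directed_network(pop$id, from, to, kin = FALSE,
                                    layer = "advice")
  }

  pref <- ifelse(y == 1L, "yes", "no")
  set.seed(stage_seed(seed, 4L))
  # split pro answers across daughter / daughter-in-law the way the survey
  # observed them: both 52.3%, daughter-in-law only 34.8%, daughter only 12.9%
  which_pro <- which(y == 1L)
  combo <- sample(c("both", "dil", "d"), length(which_pro), TRUE,
                  c(0.523, 0.348, 0.129))
  pop$pref_daughter <- ifelse(y == 1L, "yes", "no")
  pop$pref_daughter_in_law <- ifelse(y == 1L, "yes", "no")
  pop$pref_daughter[which_pro[combo == "dil"]] <- "no"
  pop$pref_daughter_in_law[which_pro[combo == "d"]] <- "no"

  norms <- simulate_norm_answers(y, zone, config$zone_prevalence, config,
                                 seed = stage_seed(seed, 5L))
  pop$empirical_expectation_men <- norms$empirical_expectation_men
  pop$empirical_expectation_women <- norms$empirical_expectation_women
  pop$normative_expectation <- norms$normative_expectation

  reporters <- pop$id[pop$is_reporter]
  noms <- list()
  single <- intersect(c("chatting", "respect"), config$layers)
  for (layer in single) {
    rp <- simulate_reports(nets[[layer]], reporters,
                           lambda1 = config$lambda1, lambda0 = config$lambda0,
                           cap = config$nomination_cap,
                           seed = stage_seed(seed, 6L + match(layer, config$layers)),
                           pair = "advice", zone = zone)
    out <- rp$out_reports
    out$generator <- layer
    noms[[layer]] <- out
  }
  for (layer in intersect(c("money", "advice"), config$layers)) {
    rp <- simulate_reports(nets[[layer]], reporters,
                           lambda1 = config$lambda1, lambda0 = config$lambda0,
                           cap = config$nomination_cap,
                           seed = stage_seed(seed, 6L + match(layer, config$layers)),
                           pair = layer, zone = zone)
    noms[[paste0(layer, "_out")]] <- rp$out_reports
    noms[[paste0(layer, "_in")]] <- rp$in_reports
  }
  nominations <- do.call(rbind, c(noms, list(make.row.names = FALSE)))

  structure(list(respondents = pop, nominations = nominations,
                 truth = list(networks = nets, y = y,
                              zone_prevalence = config$zone_prevalence,
                              regime = config$regime,
                              theta_contagion =
                                if (config$regime == "influence")
                                  config$theta_contagion else NULL,
                              block_matrix =
                                if (config$regime == "selection")
                                  config$block_matrix else NULL),
                 config = config, seed = seed),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "<sim_study: n = %d, regime '%s', %d nominations, prevalence %.1f%%>\n",
    nrow(x$respondents), x$truth$regime, nrow(x$nominations),
    100 * mean(x$truth$y)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Writes the respondent and nomination CSV tables [read_tables()] consumes,
#' plus a ground-truth JSON (true attribute vector, generating parameters,
#' seed) and per-layer true-network edge lists.
#'
#' @param sim a `sim_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tables(sim$respondents, sim$nominations,
               file.path(dir, "respondents.csv"),
               file.path(dir, "nominations.csv"))
  for (layer in names(sim$truth$networks)) {
    net <- sim$truth$networks[[layer]]
    write.csv(data.frame(from = net$roster[net$from],
                         to = net$roster[net$to], kin = net$kin),
              file.path(dir, paste0("true_network_", layer, ".csv")),
              row.names = FALSE)
  }
  truth <- list(y = sim$truth$y, regime = sim$truth$regime,
                zone_prevalence = sim$truth$zone_prevalence,
                theta_contagion = sim$truth$theta_contagion,
                seed = sim$seed)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
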