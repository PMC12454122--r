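# Autologistic actor-attribute model (ALAAM): statistics, exact enumeration,
# and Gibbs simulation.  The model places an exponential-family distribution
# on a binary node attribute y conditional on a fixed directed network:
#   P(y) = exp(theta . s(y)) / Z(theta)
# where s(y) stacks node-level statistics (intercept, degree activity /
# popularity, covariate main effects) and contagion statistics counting
# co-occurrence of the attribute across (symmetrized) ties.

CONTAGION_VARIANTS <- c("direct", "reciprocal", "indirect", "closed_indirect",
                        "transitive")

check_contagion <- function(contagion) {
  if (is.null(contagion)) return(character(0))
  contagion <- unique(as.character(contagion))
  bad <- setdiff(contagion, CONTAGION_VARIANTS)
  if (length(bad)) stop("unknown contagion variant: ", bad[1L])
  if (length(contagion) && !"direct" %in% contagion &&
      length(setdiff(contagion, "direct"))) {
    stop("contagion hierarchy: 'direct' must be enabled when any other ",
         "contagion variant is")
  }
  contagion
}

scope_network <- function(network, tie_scope = c("all", "kin", "nonkin")) {
  tie_scope <- match.arg(tie_scope)
  switch(tie_scope,
         all = network,
         kin = split_kin(network)$kin,
         nonkin = split_kin(network)$nonkin)
}

# Precompute everything the statistics and the Gibbs kernel need for a fixed
# network: the node-constant change-statistic matrix A and, per contagion
# variant, upper-triangular pair lists plus CSR neighbour structures.
alaam_build <- function(network, covariates = NULL,
                        contagion = "direct",
                        tie_scope = "all", degree_effects = TRUE) {
  contagion <- check_contagion(contagion)
  network <- scope_network(network, tie_scope)
  n <- n_nodes(network)
  X <- adjacency_matrix(network)
  dimnames(X) <- NULL
  S <- pmax(X, t(X))          # x+_ij = max(x_ij, x_ji), symmetrized
  M <- X * t(X)               # mutual ties

  A <- matrix(1, n, 1L, dimnames = list(NULL, "intercept"))
  if (degree_effects) {
    A <- cbind(A, activity = rowSums(X), popularity = colSums(X))
  }
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates))
    if (nrow(C) != n) stop("covariate rows must match roster size")
    if (!is.numeric(C)) stop("covariates must be numeric (expand factors first)")
    if (is.null(colnames(C))) colnames(C) <- paste0("x", seq_len(ncol(C)))
    A <- cbind(A, C)
  }

  pair_mats <- list()
  if (length(intersect(c("indirect", "closed_indirect"), contagion))) {
    S2 <- (S %*% S) > 0
    diag(S2) <- FALSE
  }
  for (v in setdiff(contagion, "transitive")) {
    pair_mats[[v]] <- switch(v,
      direct = S,
      reciprocal = M,
      indirect = (S == 0) * S2,
      closed_indirect = (S == 1) * S2)
  }

  to_csr <- function(mat) {
    idx <- lapply(seq_len(n), function(i) which(mat[i, ] != 0) - 1L)
    list(ptr = c(0L, cumsum(lengths(idx))), idx = as.integer(unlist(idx)))
  }
  to_pairs <- function(mat) which(upper.tri(mat) & mat != 0, arr.ind = TRUE)

  tri <- list(); triads <- NULL
  if ("transitive" %in% contagion) {
    trip <- list()
    for (i in seq_len(n)) {
      nb <- which(S[i, ] != 0)
      prs <- if (length(nb) >= 2L) {
        cmb <- utils::combn(nb, 2L)
        cmb[, S[cmb[1L, ] + (cmb[2L, ] - 1L) * n] != 0, drop = FALSE]
      } else matrix(integer(0), 2L, 0L)
      trip[[i]] <- prs
    }
    tri <- list(ptr = c(0L, cumsum(vapply(trip, ncol, 1L))),
                j = as.integer(unlist(lapply(trip, function(m) m[1L, ]))) - 1L,
                k = as.integer(unlist(lapply(trip, function(m) m[2L, ]))) - 1L)
    # unordered triads (i<j<k, all three symmetrized ties present)
    tl <- list()
    for (i in seq_len(n)) {
      prs <- trip[[i]]
      keep <- prs[1L, ] > i  # ensures i < j < k once
      if (any(keep)) tl[[length(tl) + 1L]] <-
          rbind(i, prs[, keep, drop = FALSE])
    }
    triads <- if (length(tl)) do.call(cbind, tl) else matrix(integer(0), 3L, 0L)
  }

  list(n = n, A = A, contagion = contagion,
       pairs = lapply(pair_mats, to_pairs),
       csr = lapply(pair_mats, to_csr),
       tri = tri, triads = triads,
       stat_names = c(colnames(A),
                      if (length(contagion)) paste0("contagion_", contagion)))
}

alaam_stats_from_model <- function(model, y) {
  y <- as.numeric(y)
  s <- as.vector(crossprod(model$A, y))
  names(s) <- colnames(model$A)
  for (v in setdiff(model$contagion, "transitive")) {
    pr <- model$pairs[[v]]
    s[paste0("contagion_", v)] <-
      if (nrow(pr)) sum(y[pr[, 1L]] * y[pr[, 2L]]) else 0
  }
  if ("transitive" %in% model$contagion) {
    tr <- model$triads
    s["contagion_transitive"] <-
      if (ncol(tr)) sum(y[tr[1L, ]] * y[tr[2L, ]] * y[tr[3L, ]]) else 0
  }
  s[model$stat_names]
}

#' ALAAM sufficient statistics
#'
#' Computes the full statistic vector for an observed attribute vector:
#' intercept (count of attribute holders), degree activity and popularity,
#' covariate main effects, and the enabled contagion statistics.  All
#' contagion statistics use the symmetrized tie indicator
#' `x+_ij = max(x_ij, x_ji)`:
#' \describe{
#'   \item{direct}{`sum_{i<j} y_i y_j x+_ij`}
#'   \item{reciprocal}{`sum_{i<j} y_i y_j x_ij x_ji`}
#'   \item{indirect}{pairs of attribute holders not tied but joined by a
#'     two-path}
#'   \item{closed_indirect}{pairs of attribute holders tied and joined by a
#'     two-path}
#'   \item{transitive}{unordered triads with all three members holding the
#'     attribute and all three symmetrized ties present}
#' }
#'
#' @param y 0/1 attribute vector indexed to the roster.
#' @param network a [directed_network()] on the same roster.
#' @param covariates numeric data frame/matrix of node covariates (factors
#'   must already be expanded to indicators), or `NULL`.
#' @param contagion subset of
#'   `r paste(CONTAGION_VARIANTS, collapse = ", ")`; any variant beyond
#'   `direct` requires `direct` (hierarchy).  `NULL` for none.
#' @param tie_scope `"all"`, `"kin"` or `"nonkin"` ties.
#' @param degree_effects include activity/popularity statistics.
#' @return named numeric vector of statistics.
#' @export
alaam_statistics <- function(y, network, covariates = NULL,
                             contagion = "direct", tie_scope = "all",
                             degree_effects = TRUE) {
  if (length(y) != n_nodes(network)) stop("y length must match roster size")
  model <- alaam_build(network, covariates, contagion, tie_scope,
                       degree_effects)
  alaam_stats_from_model(model, y)
}

all_states <- function(n) {
  if (n > 15L) stop("exact enumeration limited to n <= 15 (2^n states)")
  m <- 2L^n
  Y <- matrix(0L, m, n)
  for (j in seq_len(n)) {
    Y[, j] <- bitwAnd(seq_len(m) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  Y
}

#' Exact ALAAM distribution on a small roster
#'
#' Enumerates all `2^n` attribute vectors and normalizes
#' `P(y) = exp(theta . s(y)) / Z`.  Serves as the oracle against which the
#' Gibbs sampler and the exchange-algorithm posterior are validated.
#'
#' @inheritParams alaam_statistics
#' @param theta named coefficient vector over the model's statistics.
#' @return list with `states` (2^n x n 0/1 matrix), `stats`, `prob`,
#'   `moments` (exact E[s]), and `logZ`.
#' @export
alaam_exact <- function(theta, network, covariates = NULL,
                        contagion = "direct", tie_scope = "all",
                        degree_effects = TRUE) {
  model <- alaam_build(network, covariates, contagion, tie_scope,
                       degree_effects)
  theta <- align_theta(theta, model)
  Y <- all_states(model$n)
  sv <- vapply(seq_len(nrow(Y)),
               function(r) alaam_stats_from_model(model, Y[r, ]),
               numeric(length(model$stat_names)))
  Smat <- if (is.matrix(sv)) t(sv) else matrix(sv, ncol = 1L)
  colnames(Smat) <- model$stat_names
  lp <- as.vector(Smat %*% theta)
  lz <- max(lp) + log(sum(exp(lp - max(lp))))
  prob <- exp(lp - lz)
  list(states = Y, stats = Smat, prob = prob,
       moments = colSums(prob * Smat), logZ = lz)
}

align_theta <- function(theta, model) {
  if (is.null(names(theta))) {
    if (length(theta) != length(model$stat_names)) {
      stop("theta length must match the ", length(model$stat_names),
           " enabled statistics")
    }
    names(theta) <- model$stat_names
    return(theta)
  }
  full <- setNames(numeric(length(model$stat_names)), model$stat_names)
  unknown <- setdiff(names(theta), model$stat_names)
  if (length(unknown)) stop("theta names not among model statistics: ",
                            paste(unknown, collapse = ", "))
  full[names(theta)] <- theta
  full
}

#' Simulate attribute vectors from an ALAAM by Gibbs sampling
#'
#' Systematic-scan Gibbs over the full conditionals
#' `logit P(y_i = 1 | y_-i) = theta . [s(y: y_i = 1) - s(y: y_i = 0)]`.
#'
#' @inheritParams alaam_exact
#' @param n_draws number of retained draws.
#' @param burn_in full sweeps before the first retained draw.
#' @param thin sweeps between retained draws.
#' @param seed integer seed.
#' @param init initial 0/1 vector (defaults to independent draws from the
#'   intercept-only marginal).
#' @return `n_draws x n` integer matrix of attribute vectors.
#' @export
alaam_simulate <- function(theta, network, covariates = NULL,
                           contagion = "direct", tie_scope = "all",
                           degree_effects = TRUE, n_draws = 1L,
                           burn_in = 100L, thin = 10L, seed = 1L,
                           init = NULL) {
  if (any(!is.finite(theta))) stop("non-finite theta")
  model <- alaam_build(network, covariates, contagion, tie_scope,
                       degree_effects)
  theta <- align_theta(theta, model)
  set.seed(seed)
  if (is.null(init)) {
    p0 <- plogis(theta[["intercept"]])
    init <- rbinom(model$n, 1L, p0)
  }
  gibbs_from_model(model, theta, init, burn_in, n_draws, thin)
}

gibbs_from_model <- function(model, theta, init, burn_in, n_draws, thin) {
  p_const <- ncol(model$A)
  eta <- as.vector(model$A %*% theta[seq_len(p_const)])
  cont <- setdiff(model$contagion, "transitive")
  theta_cont <- if (length(cont))
    theta[paste0("contagion_", cont)] else numeric(0)
  theta_tri <- if ("transitive" %in% model$contagion)
    theta[["contagion_transitive"]] else 0
  alaam_gibbs_cpp(eta, model$csr[cont], as.numeric(theta_cont),
                  model$tri, theta_tri, as.integer(init),
                  as.integer(burn_in), as.integer(n_draws), as.integer(thin))
}
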