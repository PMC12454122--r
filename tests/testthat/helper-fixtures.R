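# Shared fixtures and independent brute-force oracles.  Oracles are written
# as plain double/triple loops over adjacency matrices, deliberately not
# sharing code with the package internals.

toy_respondents <- function() {
  data.frame(
    id = c("A", "B", "C"),
    age = c(25L, 40L, 31L),
    gender = c("man", "woman", "woman"),
    education = c("none", "some_primary", "some_secondary_plus"),
    zone = c(1L, 1L, 2L),
    community_role = c("no_role", "role", "no_role"),
    religion = c("muslim", "muslim", "orthodox"),
    pref_daughter = c("no", "yes", "no"),
    pref_daughter_in_law = c("no", "no", "no"),
    is_reporter = c(TRUE, TRUE, FALSE),
    empirical_expectation_men = c(0L, 10L, 0L),
    empirical_expectation_women = c(0L, 20L, 10L),
    normative_expectation = c("disapprove", "approve",
                              "none_of_their_business"),
    stringsAsFactors = FALSE
  )
}

toy_nominations <- function() {
  data.frame(
    ego = c("A", "A", "B"),
    generator = c("chatting", "chatting", "advice_in"),
    alter = c("B", "UNMATCHED", "A"),
    kin = c(TRUE, FALSE, FALSE),
    relationship = c("brother", "friend", "friend"),
    stringsAsFactors = FALSE
  )
}

random_network <- function(n, p = 0.15, seed = 1, kin_p = 0.4) {
  set.seed(seed)
  A <- matrix(rbinom(n * n, 1L, p), n, n)
  diag(A) <- 0L
  idx <- which(A == 1L, arr.ind = TRUE)
  directed_network(sprintf("v%02d", seq_len(n)), idx[, 1L], idx[, 2L],
                   kin = runif(nrow(idx)) < kin_p, layer = "fixture")
}

# --- ALAAM statistic oracle: explicit loops --------------------------------
oracle_alaam_stats <- function(y, net, covariates = NULL,
                               degree_effects = TRUE) {
  X <- adjacency_matrix(net)
  n <- length(y)
  Xs <- matrix(0L, n, n)
  for (i in 1:n) for (j in 1:n) Xs[i, j] <- max(X[i, j], X[j, i])
  out <- c(intercept = sum(y))
  if (degree_effects) {
    act <- 0; pop <- 0
    for (i in 1:n) {
      act <- act + y[i] * sum(X[i, ])
      pop <- pop + y[i] * sum(X[, i])
    }
    out <- c(out, activity = act, popularity = pop)
  }
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    for (k in seq_len(ncol(C))) {
      out[colnames(C)[k]] <- sum(y * C[, k])
    }
  }
  direct <- recip <- indir <- closed <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (y[i] * y[j] == 0) next
    two_path <- FALSE
    for (k in 1:n) {
      if (k != i && k != j && Xs[i, k] == 1 && Xs[k, j] == 1) two_path <- TRUE
    }
    if (Xs[i, j] == 1) direct <- direct + 1
    if (X[i, j] == 1 && X[j, i] == 1) recip <- recip + 1
    if (Xs[i, j] == 0 && two_path) indir <- indir + 1
    if (Xs[i, j] == 1 && two_path) closed <- closed + 1
  }
  trans <- 0
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (y[i] * y[j] * y[k] == 1 &&
          Xs[i, j] == 1 && Xs[i, k] == 1 && Xs[j, k] == 1) trans <- trans + 1
    }
  }
  c(out, contagion_direct = direct, contagion_reciprocal = recip,
    contagion_indirect = indir, contagion_closed_indirect = closed,
    contagion_transitive = trans)
}

# --- network summary oracle ------------------------------------------------
oracle_network_summary <- function(net) {
  X <- adjacency_matrix(net)
  n <- nrow(X)
  ties <- sum(X)
  recip <- if (ties) sum(X == 1 & t(X) == 1) / ties else NA_real_
  S <- (X + t(X)) > 0
  closed <- 0; paths <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (i != j && j != k && i != k && S[i, j] && S[j, k]) {
      paths <- paths + 1
      if (S[i, k]) closed <- closed + 1
    }
  }
  isolates <- sum(sapply(1:n, function(i) sum(X[i, ]) + sum(X[, i]) == 0))
  list(ties = ties, density = ties / (n * (n - 1)), reciprocity = recip,
       transitivity = if (paths) closed / paths else NaN, isolates = isolates)
}

# --- centrality oracle: Floyd-Warshall all-pairs shortest paths ------------
oracle_distances <- function(X) {
  n <- nrow(X)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[X == 1] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_harmonic <- function(net) {
  D <- oracle_distances(adjacency_matrix(net))
  sapply(seq_len(nrow(D)), function(i) {
    d <- D[i, -i]
    sum(1 / d[is.finite(d)])
  })
}

# path-counting betweenness oracle (counts all shortest paths through v)
oracle_betweenness <- function(net) {
  X <- adjacency_matrix(net)
  n <- nrow(X)
  D <- oracle_distances(X)
  # number of shortest paths between each pair, by DP over path length
  npaths <- matrix(0, n, n)
  for (s in 1:n) for (t in 1:n) {
    if (s == t || !is.finite(D[s, t])) next
    cnt <- function(u, v) {
      if (u == v) return(1)
      tot <- 0
      for (w in which(X[u, ] == 1)) {
        if (D[u, v] == 1 + D[w, v]) tot <- tot + cnt(w, v)
      }
      tot
    }
    npaths[s, t] <- cnt(s, t)
  }
  bw <- numeric(n)
  for (v in 1:n) for (s in 1:n) for (t in 1:n) {
    if (length(unique(c(s, t, v))) < 3) next
    if (!is.finite(D[s, t])) next
    if (D[s, v] + D[v, t] == D[s, t]) {
      bw[v] <- bw[v] + npaths[s, v] * npaths[v, t] / npaths[s, t]
    }
  }
  bw
}
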