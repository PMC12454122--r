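# Layer-overlap, structural, centrality and norm-expectation descriptives.

#' Jaccard overlap between two name generators
#'
#' For every respondent who nominated at least one matched alter under both
#' generators, computes the Jaccard coefficient `|A intersect B| / |A union
#' B|` of their matched-alter id sets, and returns the mean over such
#' respondents (ego-wise aggregation).  With `pooled = TRUE` a single
#' coefficient over the pooled alter sets of all respondents is returned
#' instead.
#'
#' @param nominations nomination data frame.
#' @param generator_a,generator_b generator labels.
#' @param pooled pool alters over respondents before comparing.
#' @return list with `mean` (the coefficient; `NA` if no respondent used
#'   both generators) and `per_respondent` (named vector, ego-wise mode).
#' @export
jaccard_overlap <- function(nominations, generator_a, generator_b,
                            pooled = FALSE) {
  ok <- !is.na(nominations$alter) & nominations$alter != UNMATCHED
  nm <- nominations[ok, , drop = FALSE]
  setsA <- with(nm[nm$generator == generator_a, ],
                split(as.character(alter), as.character(ego)))
  setsB <- with(nm[nm$generator == generator_b, ],
                split(as.character(alter), as.character(ego)))
  if (pooled) {
    A <- unique(unlist(setsA)); B <- unique(unlist(setsB))
    u <- length(union(A, B))
    return(list(mean = if (u) length(intersect(A, B)) / u else NA_real_,
                per_respondent = NULL))
  }
  both <- intersect(names(setsA), names(setsB))
  if (!length(both)) return(list(mean = NA_real_, per_respondent = NULL))
  per <- vapply(both, function(e) {
    A <- unique(setsA[[e]]); B <- unique(setsB[[e]])
    length(intersect(A, B)) / length(union(A, B))
  }, numeric(1L))
  list(mean = mean(per), per_respondent = per)
}

#' Jaccard overlap matrix over all name-generator pairs
#'
#' @param nominations nomination data frame.
#' @param generators generator labels to include.
#' @param pooled see [jaccard_overlap()].
#' @return symmetric numeric matrix of mean coefficients (diagonal 1 where
#'   the generator was used).
#' @export
jaccard_matrix <- function(nominations, generators = GENERATORS,
                           pooled = FALSE) {
  k <- length(generators)
  out <- matrix(NA_real_, k, k, dimnames = list(generators, generators))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (b < a) { out[a, b] <- out[b, a]; next }
    out[a, b] <- jaccard_overlap(nominations, generators[a], generators[b],
                                 pooled = pooled)$mean
  }
  out
}

#' Structural summary of one network layer
#'
#' Ties, density `ties / (n (n - 1))`, reciprocity (proportion of ties whose
#' reverse tie also exists), transitivity (global clustering of the
#' symmetrized graph: closed two-paths over all two-paths), and isolates
#' (roster members with zero in- and out-degree -- counted against the full
#' roster, so never-nominated non-reporters count).
#'
#' @param net a [directed_network()].
#' @return one-row data frame: `layer`, `n`, `ties`, `density`,
#'   `reciprocity`, `transitivity`, `isolates`.
#' @export
network_summary <- function(net) {
  n <- n_nodes(net)
  if (n == 0L) stop("empty roster")
  ties <- n_ties(net)
  A <- adjacency_matrix(net)
  recip <- if (ties) sum(A * t(A)) / ties else NA_real_
  g <- as_igraph(net)
  trans <- igraph::transitivity(igraph::as_undirected(g, mode = "collapse"),
                                type = "global")
  isolates <- sum(rowSums(A) + colSums(A) == 0L)
  data.frame(layer = net$layer, n = n, ties = ties,
             density = ties / (n * (n - 1)),
             reciprocity = recip, transitivity = trans,
             isolates = isolates, stringsAsFactors = FALSE)
}

#' Node centrality profile
#'
#' In-degree, out-degree, directed shortest-path betweenness, and harmonic
#' centrality (sum of inverse directed distances to all other nodes;
#' unreachable nodes contribute zero).  When a preference class per node is
#' supplied, group means by class are attached.
#'
#' @param net a [directed_network()].
#' @param preference optional factor/vector of node classes.
#' @return data frame (one row per node: `id`, `in_degree`, `out_degree`,
#'   `betweenness`, `harmonic`) with attribute `"group_means"` when
#'   `preference` is given.
#' @export
centrality_profile <- function(net, preference = NULL) {
  g <- as_igraph(net)
  out <- data.frame(
    id = net$roster,
    in_degree = igraph::degree(g, mode = "in"),
    out_degree = igraph::degree(g, mode = "out"),
    betweenness = igraph::betweenness(g, directed = TRUE),
    harmonic = igraph::harmonic_centrality(g, mode = "out",
                                           normalized = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(preference)) {
    gm <- aggregate(out[c("in_degree", "out_degree", "betweenness",
                          "harmonic")],
                    by = list(preference = preference), FUN = mean)
    attr(out, "group_means") <- gm
  }
  out
}

#' Classify norm expectations and the joint social-norm criterion
#'
#' Per respondent: whether any empirical expectation is above zero, whether
#' the perceived support reaches the 10% decile for men or women, whether
#' the normative expectation is approval, and the joint criterion
#' (perceived support of 10% or more for men or women AND expected
#' approval) that defines a social norm in the Bicchieri sense.
#'
#' @param respondents respondent data frame (norm-answer columns and
#'   preference answers present).
#' @return list with `respondent` (per-respondent logical flags),
#'   `by_zone` and `by_preference` aggregate tables (percent stating 0% for
#'   men and women, percent per normative category, percent meeting the
#'   joint criterion).
#' @export
classify_norms <- function(respondents) {
  men <- respondents$empirical_expectation_men
  women <- respondents$empirical_expectation_women
  for (v in list(men, women)) {
    bad <- !is.na(v) & (v %% 10 != 0 | v < 0 | v > 100)
    if (any(bad)) stop("out-of-range empirical-expectation decile")
  }
  pref <- classify_preference(respondents$pref_daughter,
                              respondents$pref_daughter_in_law)
  flags <- data.frame(
    id = respondents$id,
    preference = pref,
    empirical_expectation_present = (men > 0) | (women > 0),
    perceived_support_ge_10 = (men >= 10) | (women >= 10),
    normative_approval = respondents$normative_expectation == "approve",
    stringsAsFactors = FALSE
  )
  flags$bicchieri_joint <- flags$perceived_support_ge_10 &
    flags$normative_approval

  agg <- function(split_var) {
    idx <- split(seq_len(nrow(respondents)), split_var)
    do.call(rbind, lapply(names(idx), function(g) {
      i <- idx[[g]]
      data.frame(
        group = g, n = length(i),
        pct_zero_men = 100 * mean(men[i] == 0, na.rm = TRUE),
        pct_zero_women = 100 * mean(women[i] == 0, na.rm = TRUE),
        pct_approve = 100 * mean(respondents$normative_expectation[i] ==
                                   "approve", na.rm = TRUE),
        pct_disapprove = 100 * mean(respondents$normative_expectation[i] ==
                                      "disapprove", na.rm = TRUE),
        pct_none_business = 100 *
          mean(respondents$normative_expectation[i] ==
                 "none_of_their_business", na.rm = TRUE),
        pct_bicchieri_joint = 100 * mean(flags$bicchieri_joint[i],
                                         na.rm = TRUE),
        stringsAsFactors = FALSE)
    }))
  }
  list(respondent = flags,
       by_zone = agg(respondents$zone),
       by_preference = agg(pref))
}

#' Per-zone preference prevalence and demographic profile
#'
#' @param respondents respondent data frame.
#' @return data frame with one row per zone: `zone`, `n`, `gender_ratio`
#'   (men per woman), `median_age`, `pct_some_secondary_plus`, `pct_pro`.
#' @export
prevalence_table <- function(respondents) {
  pref <- classify_preference(respondents$pref_daughter,
                              respondents$pref_daughter_in_law)
  if (all(is.na(pref))) stop("preference answers missing for all respondents")
  zs <- split(seq_len(nrow(respondents)), respondents$zone)
  do.call(rbind, lapply(names(zs), function(z) {
    i <- zs[[z]]
    nmen <- sum(respondents$gender[i] == "man")
    nwomen <- sum(respondents$gender[i] == "woman")
    data.frame(
      zone = z, n = length(i),
      gender_ratio = if (nwomen) nmen / nwomen else NA_real_,
      median_age = median(respondents$age[i]),
      pct_some_secondary_plus =
        100 * mean(respondents$education[i] == "some_secondary_plus"),
      pct_pro = 100 * mean(pref[i] == "pro", na.rm = TRUE),
      stringsAsFactors = FALSE)
  }))
}
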