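# Combined stochastic block + social relations model for one zone's
# double-sampled advice layer: preference-combination (and optionally
# gender-combination) block offsets, focal/target/dyad covariates,
# sender/receiver random effects, dyadic reciprocity, and an optional
# measurement layer for raw double-sampled reports.

PREF_LEVELS <- c("anti", "pro")

combo_names <- function(levels, prefix) {
  as.vector(outer(levels, levels,
                  function(a, b) paste0(prefix, "_", a, "_", b)))
}

#' Build the ordered-pair design for a block + social relations model
#'
#' Rows are dyad-major: rows `2d - 1` and `2d` are the ordered pairs
#' `(i, j)` and `(j, i)` of unordered dyad `d` (over all `i < j`).  The
#' block indicator columns act as per-combination intercepts; there is no
#' separate global intercept column (the reported global intercept is the
#' mean of the block offsets, which are recentred to sum to zero).
#'
#' @param pref factor/character of preference (`anti`/`pro`) per node.
#' @param gender optional factor/character (`man`/`woman`) for gender
#'   blocks.
#' @param covariates optional numeric data frame (focal and target effects
#'   are both built from it).
#' @param dyad_covariates optional named list of n x n numeric matrices.
#' @return list with `W` (design matrix), `row_i`, `row_j` (1-based node
#'   indices per row), and `block_cols` (names of the preference-block
#'   columns).
#' @export
srm_design <- function(pref, gender = NULL, covariates = NULL,
                       dyad_covariates = NULL) {
  n <- length(pref)
  pref <- factor(as.character(pref), levels = PREF_LEVELS)
  if (anyNA(pref)) stop("preference must be 'anti' or 'pro'")
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  row_i <- as.vector(rbind(i, j))
  row_j <- as.vector(rbind(j, i))

  gi <- as.integer(pref)[row_i]; gj <- as.integer(pref)[row_j]
  pref_cols <- combo_names(PREF_LEVELS, "pref")
  Wp <- matrix(0, length(row_i), 4L, dimnames = list(NULL, pref_cols))
  Wp[cbind(seq_along(row_i),
           match(paste0("pref_", PREF_LEVELS[gi], "_", PREF_LEVELS[gj]),
                 pref_cols))] <- 1
  W <- Wp
  if (!is.null(gender)) {
    glev <- c("man", "woman")
    gd <- factor(as.character(gender), levels = glev)
    if (anyNA(gd)) stop("gender must be 'man' or 'woman'")
    gcols <- combo_names(glev, "gender")
    Wg <- matrix(0, length(row_i), 4L, dimnames = list(NULL, gcols))
    ggi <- as.integer(gd)[row_i]; ggj <- as.integer(gd)[row_j]
    Wg[cbind(seq_along(row_i),
             match(paste0("gender_", glev[ggi], "_", glev[ggj]), gcols))] <- 1
    W <- cbind(W, Wg)
  }
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates))
    if (nrow(C) != n) stop("covariate rows must match the zone roster")
    Wf <- C[row_i, , drop = FALSE]
    colnames(Wf) <- paste0("focal_", colnames(C))
    Wt <- C[row_j, , drop = FALSE]
    colnames(Wt) <- paste0("target_", colnames(C))
    W <- cbind(W, Wf, Wt)
  }
  if (!is.null(dyad_covariates)) {
    for (nmk in names(dyad_covariates)) {
      Mx <- dyad_covariates[[nmk]]
      W <- cbind(W, setNames(data.frame(Mx[cbind(row_i, row_j)]),
                             paste0("dyad_", nmk))[[1L]])
      colnames(W)[ncol(W)] <- paste0("dyad_", nmk)
    }
  }
  list(W = as.matrix(W), row_i = row_i, row_j = row_j,
       block_cols = pref_cols)
}

#' Fit a combined stochastic block + social relations model
#'
#' Models the latent ordered-pair tie probability within one zone as
#' `logit P(Y_ij = 1) = B_pref[g_i, g_j] + B_gender[h_i, h_j] + focal(i) +
#' target(j) + dyad(i, j) + s_i + r_j + d_ij`, with bivariate-normal
#' sender/receiver effects and reciprocity-correlated dyad effects.  When
#' `outcome` is a [double_sampled_reports()] object the latent ties are
#' estimated jointly with a shared reporting sensitivity and false-positive
#' rate (no pre-estimation of the network is required); when it is a
#' [directed_network()] the tie matrix is treated as observed.
#'
#' @param outcome a [double_sampled_reports()] (measurement mode) or a
#'   [directed_network()] (pre-binarized mode) for one zone's members.
#' @param pref preference (`anti`/`pro`) per roster member.
#' @param gender optional gender per member; enables gender blocks.
#' @param covariates optional numeric data frame of focal/target covariates
#'   (e.g. standardized age, education level, community role).
#' @param dyad_covariates optional named list of n x n binary matrices
#'   (e.g. chatting tie, respect tie, latent money tie).
#' @param dyad_effects include reciprocity-correlated dyad random effects.
#' @param prior_sd Gaussian prior SD for fixed effects and block offsets.
#' @param sd_prior_scale half-Normal prior scale for random-effect SDs.
#' @param reporting_priors Beta parameters for sensitivity and
#'   false-positive rate (measurement mode).
#' @param iter,burn,thin MCMC controls (retained draws = `iter / thin`).
#' @param seed integer seed.
#' @return object of class `block_srm` with elements `draws` (named matrix:
#'   block offsets, coefficients, `sigma_sender`, `sigma_receiver`,
#'   `cor_sr`, `sigma_dyad`, `cor_dyad`, and in measurement mode
#'   `sensitivity`, `false_positive_rate`), `roster`, `mode`, `settings`.
#' @export
block_srm <- function(outcome, pref, gender = NULL, covariates = NULL,
                      dyad_covariates = NULL, dyad_effects = TRUE,
                      prior_sd = 2.5, sd_prior_scale = 1,
                      reporting_priors = list(lambda1 = c(9, 1),
                                              lambda0 = c(1, 99)),
                      iter = 1500L, burn = 1000L, thin = 1L, seed = 1L) {
  reports_mode <- inherits(outcome, "double_sampled_reports")
  roster <- if (reports_mode) outcome$reporter_set else outcome$roster
  n <- length(roster)
  if (n < 10L) stop("insufficient dyads: zone has fewer than 10 members")
  pref <- factor(as.character(pref), levels = PREF_LEVELS)
  if (length(pref) != n) stop("pref length must match the roster")
  keep <- !is.na(pref)
  if (any(!keep)) {
    message(sum(!keep), " member(s) with missing attributes excluded")
    roster <- roster[keep]
    pref <- pref[keep]
    if (!is.null(gender)) gender <- gender[keep]
    if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
    if (!is.null(dyad_covariates)) {
      dyad_covariates <- lapply(dyad_covariates,
                                function(m) m[keep, keep, drop = FALSE])
    }
    n <- length(roster)
    if (n < 10L) stop("insufficient dyads: zone has fewer than 10 members")
    if (reports_mode) {
      outcome <- double_sampled_reports(
        rbind(outcome$out_reports, outcome$in_reports),
        pair = outcome$pair, reporter_set = roster)
    }
  }

  des <- srm_design(pref, gender, covariates, dyad_covariates)
  Rn <- nrow(des$W)
  if (reports_mode) {
    rc <- report_counts(outcome, roster)
    nobs <- rc$n_obs[cbind(des$row_i, des$row_j)]
    npos <- rc$n_pos[cbind(des$row_i, des$row_j)]
    y <- rep(-1L, Rn)
    dens <- max(sum(npos >= 1L) / Rn, 1 / Rn)
  } else {
    A <- adjacency_matrix(outcome)
    y <- A[cbind(des$row_i, des$row_j)]
    nobs <- npos <- rep(0L, Rn)
    dens <- max(mean(y), 1 / Rn)
  }
  beta_init <- setNames(numeric(ncol(des$W)), colnames(des$W))
  beta_init[des$block_cols] <- qlogis(min(max(dens, 1e-4), 1 - 1e-4))

  set.seed(seed)
  res <- srm_mcmc_cpp(des$W, des$row_i - 1L, des$row_j - 1L,
                      as.integer(y), as.integer(nobs), as.integer(npos),
                      reports_mode, dyad_effects,
                      prior_sd, sd_prior_scale,
                      reporting_priors$lambda1[1L], reporting_priors$lambda1[2L],
                      reporting_priors$lambda0[1L], reporting_priors$lambda0[2L],
                      as.integer(iter), as.integer(burn), as.integer(thin),
                      beta_init)
  draws <- res$draws
  colnames(draws) <- c(colnames(des$W), "sigma_sender", "sigma_receiver",
                       "cor_sr", "sigma_dyad", "cor_dyad",
                       "sensitivity", "false_positive_rate")
  if (!reports_mode) {
    draws <- draws[, setdiff(colnames(draws),
                             c("sensitivity", "false_positive_rate")),
                   drop = FALSE]
  }
  if (!dyad_effects) {
    draws <- draws[, setdiff(colnames(draws), c("sigma_dyad", "cor_dyad")),
                   drop = FALSE]
  }
  structure(list(draws = draws, roster = roster, pref = pref,
                 block_cols = des$block_cols,
                 gender_blocks = !is.null(gender),
                 mode = if (reports_mode) "reports" else "network",
                 random_effects = res$random_effects,
                 settings = list(iter = iter, burn = burn, thin = thin,
                                 seed = seed, prior_sd = prior_sd,
                                 sd_prior_scale = sd_prior_scale,
                                 dyad_effects = dyad_effects)),
            class = "block_srm")
}

#' @export
print.block_srm <- function(x, ...) {
  cat(sprintf(
    "<block_srm (%s mode): n = %d, %d retained draws>\n",
    x$mode, length(x$roster), nrow(x$draws)))
  print(block_contrasts(x), digits = 3)
  invisible(x)
}

#' @export
summary.block_srm <- function(object, ...) {
  d <- object$draws
  data.frame(parameter = colnames(d),
             median = apply(d, 2L, median),
             lower = apply(d, 2L, function(v) hpdi(v)[1L]),
             upper = apply(d, 2L, function(v) hpdi(v)[2L]),
             row.names = NULL)
}

#' @export
coef.block_srm <- function(object, ...) {
  apply(object$draws, 2L, median)
}

#' Highest posterior density interval
#'
#' The narrowest interval containing `prob` of the draws.
#'
#' @param x numeric draw vector.
#' @param prob interval mass.
#' @return length-2 numeric vector (lower, upper).
#' @export
hpdi <- function(x, prob = 0.95) {
  x <- sort(x)
  m <- length(x)
  k <- max(1L, ceiling(prob * m))
  if (k >= m) return(c(x[1L], x[m]))
  widths <- x[k:m] - x[seq_len(m - k + 1L)]
  j <- which.min(widths)
  c(x[j], x[j + k - 1L])
}

#' Block-offset and contrast table from a block-SRM fit
#'
#' Per draw, the preference-block offsets are recentred to sum to zero (the
#' mean, plus the mean of the gender blocks when present, is the global
#' intercept the offsets are plotted against); contrasts are per-draw
#' differences against the reference combination, so the reference's
#' contrast with itself is exactly zero.
#'
#' @param fit a `block_srm` fit (or a draw matrix containing the block
#'   columns).
#' @param reference reference combination, `"focal-target"` form, e.g.
#'   `"pro-pro"`.
#' @param prob HPDI mass.
#' @return data frame of class `srm_contrasts` with one row per preference
#'   combination: offset median and HPDI, contrast median and HPDI.
#' @export
block_contrasts <- function(fit, reference = "pro-pro", prob = 0.95) {
  draws <- if (inherits(fit, "block_srm")) fit$draws else as.matrix(fit)
  bc <- combo_names(PREF_LEVELS, "pref")
  if (!all(bc %in% colnames(draws))) stop("draws lack block-offset columns")
  B <- draws[, bc, drop = FALSE]
  off <- B - rowMeans(B)
  combos <- sub("^pref_", "", bc)
  combos <- gsub("_", "-", combos)
  ref_col <- match(gsub("-", "_", paste0("pref_", reference)), bc)
  if (is.na(ref_col)) stop("unknown reference combination: ", reference)
  ctr <- off - off[, ref_col]
  out <- data.frame(
    combination = combos,
    offset_median = apply(off, 2L, median),
    offset_lower = apply(off, 2L, function(v) hpdi(v, prob)[1L]),
    offset_upper = apply(off, 2L, function(v) hpdi(v, prob)[2L]),
    contrast_median = apply(ctr, 2L, median),
    contrast_lower = apply(ctr, 2L, function(v) hpdi(v, prob)[1L]),
    contrast_upper = apply(ctr, 2L, function(v) hpdi(v, prob)[2L]),
    row.names = NULL
  )
  attr(out, "reference") <- reference
  attr(out, "intercept_median") <-
    median(rowMeans(draws[, grep("^(pref|gender)_", colnames(draws)),
                          drop = FALSE]))
  class(out) <- c("srm_contrasts", "data.frame")
  out
}

#' Fit the homophily model independently in every zone
#'
#' Runs one block-SRM per zone over that zone's network reporters, using the
#' zone's advice reports (measurement mode).  Zones failing preconditions
#' (fewer than 10 reporting members) are reported as skipped, not fatal.
#'
#' @param respondents respondent data frame.
#' @param nominations nomination data frame.
#' @param dyad_networks optional named list of [directed_network()] layers
#'   supplying dyad covariates (e.g. chatting, respect, latent money).
#' @param gender_blocks include gender blocks.
#' @param reference reference combination for contrasts.
#' @param iter,burn MCMC controls per zone.
#' @param seed master seed; zone z uses `stage_seed(seed, z)`.
#' @return list of class `srm_zone_fits`: `contrasts` (per-zone
#'   [block_contrasts()] tables), `fits`, `skipped` (zone -> reason).
#' @export
fit_all_zones <- function(respondents, nominations, dyad_networks = NULL,
                          gender_blocks = TRUE, reference = "pro-pro",
                          iter = 1200L, burn = 800L, seed = 1L) {
  zones <- sort(unique(respondents$zone))
  fits <- list(); contrasts <- list(); skipped <- list()
  for (z in zones) {
    zr <- respondents[respondents$zone == z & respondents$is_reporter, ,
                      drop = FALSE]
    res <- tryCatch({
      if (nrow(zr) < 10L) stop("insufficient dyads: zone has fewer than 10 members")
      roster <- zr$id
      noms <- nominations[nominations$ego %in% roster, , drop = FALSE]
      reports <- double_sampled_reports(noms, pair = "advice",
                                        reporter_set = roster)
      if (nrow(reports$out_reports) + nrow(reports$in_reports) == 0L) {
        stop("no advice reports in zone")
      }
      pref <- classify_preference(zr$pref_daughter, zr$pref_daughter_in_law)
      cov <- data.frame(
        age = as.numeric(scale(zr$age)),
        education = match(zr$education, EDUCATION_LEVELS) - 1L,
        role = as.integer(zr$community_role == "role"))
      dyads <- if (!is.null(dyad_networks)) {
        lapply(dyad_networks, function(net) {
          adjacency_matrix(net)[roster, roster, drop = FALSE]
        })
      } else NULL
      block_srm(reports, pref = pref,
                gender = if (gender_blocks) zr$gender else NULL,
                covariates = cov, dyad_covariates = dyads,
                iter = iter, burn = burn, seed = stage_seed(seed, z))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[as.character(z)]] <- conditionMessage(res)
    } else {
      fits[[as.character(z)]] <- res
      contrasts[[as.character(z)]] <- block_contrasts(res, reference)
    }
  }
  if (!length(fits)) stop("all zones failed: ",
                          paste(unlist(skipped), collapse = "; "))
  structure(list(contrasts = contrasts, fits = fits, skipped = skipped),
            class = "srm_zone_fits")
}

#' @export
print.srm_zone_fits <- function(x, ...) {
  cat(sprintf("<srm_zone_fits: %d zone(s) fitted, %d skipped>\n",
              length(x$fits), length(x$skipped)))
  for (z in names(x$contrasts)) {
    cat("zone ", z, ":\n", sep = "")
    print.data.frame(x$contrasts[[z]], digits = 3)
  }
  invisible(x)
}

#' Forest plot of block offsets or contrasts
#'
#' @param x an `srm_contrasts` table.
#' @param what `"offset"` or `"contrast"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.srm_contrasts <- function(x, what = c("offset", "contrast"), ...) {
  what <- match.arg(what)
  med <- x[[paste0(what, "_median")]]
  lo <- x[[paste0(what, "_lower")]]
  hi <- x[[paste0(what, "_upper")]]
  k <- nrow(x)
  plot(med, seq_len(k), xlim = range(lo, hi), yaxt = "n",
       xlab = paste(what, "(log-odds)"), ylab = "", pch = 19, ...)
  graphics::axis(2, at = seq_len(k), labels = x$combination, las = 1)
  graphics::segments(lo, seq_len(k), hi, seq_len(k))
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
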