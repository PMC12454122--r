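# Config-driven end-to-end orchestration: simulate (or load) -> build layers
# -> estimate latent networks -> descriptives -> ALAAMs per layer and tie
# scope -> per-zone homophily fits -> manifest.

#' Build ALAAM covariates from a respondent table
#'
#' Standardized age, a gender indicator, ordinal education, and zone
#' indicator columns with the largest zone as the reference category.
#'
#' @param respondents respondent data frame.
#' @param roster ids defining row order.
#' @return numeric data frame aligned to `roster`.
#' @export
alaam_covariates <- function(respondents, roster = respondents$id) {
  idx <- match(as.character(roster), respondents$id)
  if (anyNA(idx)) stop("roster id absent from respondent table")
  r <- respondents[idx, , drop = FALSE]
  out <- data.frame(
    age = as.numeric(scale(r$age)),
    gender_woman = as.integer(r$gender == "woman"),
    education = match(r$education, EDUCATION_LEVELS) - 1L)
  zones <- sort(unique(r$zone))
  if (length(zones) > 1L) {
    ref <- zones[which.max(tabulate(match(r$zone, zones)))]
    for (z in setdiff(zones, ref)) {
      out[[paste0("zone", z)]] <- as.integer(r$zone == z)
    }
  }
  out
}

#' Assemble a pipeline run configuration
#'
#' @param sim a [sim_config()] to simulate inputs, or `NULL` when reading
#'   from disk.
#' @param respondent_path,nomination_path input CSVs (used when `sim` is
#'   `NULL`).
#' @param layers network layers to analyse.
#' @param alaam list of ALAAM settings: `iter`, `burn`, `aux_sweeps`,
#'   `contagion`, `tie_scopes`.
#' @param latent list of latent-network settings: `iter`, `burn`, `scope`.
#' @param homophily list of homophily settings: `iter`, `burn`,
#'   `gender_blocks`, `reference`, or `NULL` to skip the stage.
#' @param seed master seed; every stage derives its own via [stage_seed()].
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, respondent_path = NULL,
                       nomination_path = NULL,
                       layers = c("chatting", "respect", "money", "advice"),
                       alaam = list(iter = 1000L, burn = 500L,
                                    aux_sweeps = 30L, contagion = "direct",
                                    tie_scopes = "all"),
                       latent = list(iter = 800L, burn = 300L,
                                     scope = "reporters"),
                       homophily = list(iter = 800L, burn = 600L,
                                        gender_blocks = TRUE,
                                        reference = "pro-pro"),
                       seed = 1L) {
  if (is.null(sim) && (is.null(respondent_path) || is.null(nomination_path))) {
    stop("provide either a sim config or input table paths")
  }
  if (!is.null(respondent_path) && !file.exists(respondent_path)) {
    stop("input file not found: ", respondent_path)
  }
  if (!is.null(nomination_path) && !file.exists(nomination_path)) {
    stop("input file not found: ", nomination_path)
  }
  structure(list(sim = sim, respondent_path = respondent_path,
                 nomination_path = nomination_path, layers = layers,
                 alaam = alaam, latent = latent, homophily = homophily,
                 seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `sim` mapping is
#' passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    sim_args <- y$sim
    if (!is.null(sim_args$block_matrix)) {
      sim_args$block_matrix <- matrix(unlist(sim_args$block_matrix), 2L, 2L,
                                      byrow = TRUE,
                                      dimnames = list(c("anti", "pro"),
                                                      c("anti", "pro")))
    }
    y$sim <- do.call(sim_config, sim_args)
  }
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing per-stage outputs under
#' `out_dir` and a machine-readable JSON manifest recording every stage's
#' status, seed and outputs.  A stage failure is recorded and its dependents
#' are skipped; completed artifacts are left intact.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return the manifest (invisibly also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "netcontagion",
                   version = as.character(utils::packageVersion("netcontagion")),
                   seed = config$seed, stages = list())
  record <- function(stage, status, outputs = NULL, error = NULL, seed = NULL) {
    manifest$stages[[stage]] <<- list(status = status, seed = seed,
                                      outputs = outputs, error = error)
  }
  run_stage <- function(stage, deps, seed, fun) {
    failed <- vapply(deps, function(d) {
      st <- manifest$stages[[d]]
      is.null(st) || st$status != "ok"
    }, logical(1L))
    if (any(failed)) {
      record(stage, "skipped", error = paste("dependency failed:",
                                             paste(deps[failed],
                                                   collapse = ", ")))
      return(NULL)
    }
    res <- tryCatch(fun(seed), error = function(e) e)
    if (inherits(res, "error")) {
      record(stage, "failed", error = conditionMessage(res), seed = seed)
      NULL
    } else {
      record(stage, "ok", outputs = res$outputs, seed = seed)
      res$value
    }
  }

  # -- stage 1: inputs --------------------------------------------------
  data <- run_stage("inputs", character(0), stage_seed(config$seed, 1L),
                    function(seed) {
    if (!is.null(config$sim)) {
      sim <- simulate_study(config$sim, seed)
      write_simulation(sim, file.path(out_dir, "data"))
      list(value = list(respondents = sim$respondents,
                        nominations = sim$nominations, truth = sim$truth),
           outputs = file.path("data", c("respondents.csv",
                                         "nominations.csv",
                                         "ground_truth.json")))
    } else {
      td <- read_tables(config$respondent_path, config$nomination_path)
      list(value = td, outputs = character(0))
    }
  })

  # -- stage 2: observed layers ----------------------------------------
  layers <- run_stage("layers", "inputs", stage_seed(config$seed, 2L),
                      function(seed) {
    roster <- data$respondents$id
    nets <- list()
    outs <- character(0)
    for (g in intersect(c("chatting", "respect"), config$layers)) {
      nets[[g]] <- build_layer(data$nominations, g, roster)
      f <- file.path(out_dir, paste0("layer_", g, ".graphml"))
      write_graphml(nets[[g]], f)
      outs <- c(outs, basename(f))
    }
    list(value = nets, outputs = outs)
  })

  # -- stage 3: latent networks for double-sampled generators ----------
  latent <- run_stage("latent", "inputs", stage_seed(config$seed, 3L),
                      function(seed) {
    reporters <- data$respondents$id[data$respondents$is_reporter]
    ests <- list(); outs <- character(0)
    pairs <- intersect(c("money", "advice"), config$layers)
    for (k in seq_along(pairs)) {
      pr <- pairs[k]
      reports <- double_sampled_reports(data$nominations, pair = pr,
                                        reporter_set = reporters)
      est <- latent_network(reports, scope = config$latent$scope,
                            roster = data$respondents$id,
                            iter = config$latent$iter,
                            burn = config$latent$burn,
                            seed = stage_seed(seed, k))
      ests[[pr]] <- est
      idx <- which(est$rho > 0.01 & row(est$rho) != col(est$rho),
                   arr.ind = TRUE)
      write.csv(data.frame(i = est$roster[idx[, 1L]],
                           j = est$roster[idx[, 2L]],
                           rho = est$rho[idx]),
                file.path(out_dir, paste0("rho_", pr, ".csv")),
                row.names = FALSE)
      jsonlite::write_json(
        list(pair = pr, eta_est = est$eta_est, t_rho = est$t_rho,
             lambda1 = unname(est$lambda["lambda1"]),
             lambda0 = unname(est$lambda["lambda0"]),
             n_ties = n_ties(est$binarized)),
        file.path(out_dir, paste0("latent_", pr, ".json")),
        auto_unbox = TRUE, digits = NA)
      write_graphml(est$binarized,
                    file.path(out_dir, paste0("layer_", pr, ".graphml")))
      outs <- c(outs, paste0(c("rho_", "latent_", "layer_"), pr,
                             c(".csv", ".json", ".graphml")))
    }
    list(value = ests, outputs = outs)
  })

  all_nets <- c(layers, lapply(latent, function(e) e$binarized))

  # -- stage 4: descriptives -------------------------------------------
  run_stage("descriptives", c("inputs", "layers"),
            stage_seed(config$seed, 4L), function(seed) {
    outs <- character(0)
    summaries <- do.call(rbind, lapply(all_nets, network_summary))
    write.csv(summaries, file.path(out_dir, "network_summaries.csv"),
              row.names = FALSE)
    jm <- jaccard_matrix(data$nominations)
    write.csv(jm, file.path(out_dir, "jaccard.csv"))
    pref <- classify_preference(data$respondents$pref_daughter,
                                data$respondents$pref_daughter_in_law)
    cent <- lapply(names(all_nets), function(g) {
      cp <- centrality_profile(all_nets[[g]],
                               preference = pref[match(all_nets[[g]]$roster,
                                                       data$respondents$id)])
      cp$layer <- g
      cp
    })
    write.csv(do.call(rbind, cent), file.path(out_dir, "centrality.csv"),
              row.names = FALSE)
    norms <- classify_norms(data$respondents)
    write.csv(norms$by_zone, file.path(out_dir, "norms_by_zone.csv"),
              row.names = FALSE)
    write.csv(norms$by_preference,
              file.path(out_dir, "norms_by_preference.csv"),
              row.names = FALSE)
    write.csv(prevalence_table(data$respondents),
              file.path(out_dir, "prevalence.csv"), row.names = FALSE)
    list(value = NULL,
         outputs = c("network_summaries.csv", "jaccard.csv",
                     "centrality.csv", "norms_by_zone.csv",
                     "norms_by_preference.csv", "prevalence.csv"))
  })

  # -- stage 5: ALAAM fits ---------------------------------------------
  run_stage("alaam", c("inputs", "layers"), stage_seed(config$seed, 5L),
            function(seed) {
    outs <- character(0)
    k <- 0L
    for (g in names(all_nets)) {
      net <- all_nets[[g]]
      y <- preference_vector(data$respondents, net$roster)
      cov <- alaam_covariates(data$respondents, net$roster)
      for (scope in config$alaam$tie_scopes) {
        k <- k + 1L
        fit <- alaam(network = net, y = y, covariates = cov,
                     contagion = config$alaam$contagion, tie_scope = scope,
                     iter = config$alaam$iter, burn = config$alaam$burn,
                     aux_sweeps = config$alaam$aux_sweeps,
                     seed = stage_seed(seed, k))
        base <- sprintf("alaam_%s_%s", g, scope)
        write.csv(fit$draws, file.path(out_dir, paste0(base, "_draws.csv")),
                  row.names = FALSE)
        write.csv(posterior_summary(fit),
                  file.path(out_dir, paste0(base, "_summary.csv")),
                  row.names = FALSE)
        outs <- c(outs, paste0(base, c("_draws.csv", "_summary.csv")))
      }
    }
    list(value = NULL, outputs = outs)
  })

  # -- stage 6: per-zone homophily fits --------------------------------
  if (!is.null(config$homophily)) {
    run_stage("homophily", c("inputs", "layers"),
              stage_seed(config$seed, 6L), function(seed) {
      dyads <- all_nets[intersect(c("chatting", "respect", "money"),
                                  names(all_nets))]
      zf <- fit_all_zones(data$respondents, data$nominations,
                          dyad_networks = if (length(dyads)) dyads else NULL,
                          gender_blocks = config$homophily$gender_blocks,
                          reference = config$homophily$reference,
                          iter = config$homophily$iter,
                          burn = config$homophily$burn, seed = seed)
      rows <- do.call(rbind, lapply(names(zf$contrasts), function(z) {
        cbind(zone = z, zf$contrasts[[z]])
      }))
      write.csv(rows, file.path(out_dir, "homophily_contrasts.csv"),
                row.names = FALSE)
      jsonlite::write_json(zf$skipped,
                           file.path(out_dir, "homophily_skipped.json"),
                           auto_unbox = TRUE)
      list(value = NULL,
           outputs = c("homophily_contrasts.csv", "homophily_skipped.json"))
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
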