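#' Run configuration for the staged analysis pipeline
#'
#' Bundles everything a full run needs: the design, the generative
#' parameters used by the `simulate` stage, estimation options, and an
#' output directory.  The configuration round-trips through JSON unchanged
#' (see [run_stage()]'s manifest).
#'
#' @param out_dir output directory (created if absent).
#' @param design a [design_config()].
#' @param params a [generative_params()].
#' @param observers observer ids to simulate.
#' @param seed master seed; every stage derives its streams from it.
#' @param cov_zero use the `cov[L,B] = 0` constraint in the quadruple-pass
#'   stage?
#' @param n_boot bootstrap resamples for CI stages.
#' @param ci_level bootstrap confidence level.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, design = design_config(),
                       params = generative_params(),
                       observers = c("obs1", "obs2", "obs3"),
                       seed = 1L, cov_zero = FALSE, n_boot = 200L,
                       ci_level = 0.68) {
  structure(list(out_dir = out_dir, design = design, params = params,
                 observers = observers, seed = as.integer(seed),
                 cov_zero = cov_zero, n_boot = as.integer(n_boot),
                 ci_level = ci_level),
            class = "run_config")
}

pipeline_stages <- c("simulate", "fit-thresholds", "fit-dvc", "quad-pass",
                     "partition")

artifact_path <- function(config, name) file.path(config$out_dir, name)

# tiny FNV-1a hash of the serialised configuration, for the manifest
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[setdiff(names(config), "out_dir")]),
                           collapse = "\n"))
  h <- 216613626
  for (b in bytes) h <- (bitwXor(as.integer(h), as.integer(b)) * 16777) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(config, stage, outputs) {
  man_path <- artifact_path(config, "manifest.json")
  man <- if (file.exists(man_path))
    jsonlite::read_json(man_path, simplifyVector = FALSE) else list()
  man[[stage]] <- list(config_hash = config_hash(config),
                       seed = config$seed,
                       package_version = as.character(utils::packageVersion("doublepass")),
                       outputs = outputs,
                       time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

check_manifest <- function(config, stages) {
  man_path <- artifact_path(config, "manifest.json")
  if (!file.exists(man_path)) return(invisible(NULL))
  man <- jsonlite::read_json(man_path, simplifyVector = FALSE)
  for (s in stages) {
    if (!is.null(man[[s]]) && man[[s]]$config_hash != config_hash(config))
      warning("stale manifest: stage '", s,
              "' was produced under a different configuration")
  }
  invisible(NULL)
}

require_artifact <- function(config, name, producer) {
  p <- artifact_path(config, name)
  if (!file.exists(p))
    stop("missing input artifact '", name, "'; run the '", producer,
         "' stage first")
  p
}

# write a data.frame atomically (write to temp, then rename)
write_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run one stage of the analysis pipeline
#'
#' Stages: `simulate` (synthetic observers -> trial CSVs), `fit-thresholds`
#' (constrained log-linear threshold fits -> threshold table),
#' `fit-dvc` (per-experiment double-pass correlations), `quad-pass`
#' (quasi-quadruple-pass correlations), `partition` (variance components).
#' Each stage reads its inputs from the configured output directory, writes
#' CSV outputs atomically, and records its configuration hash and seed in
#' `manifest.json`.  Rerunning a stage with the same configuration
#' reproduces its outputs byte-for-byte.
#'
#' @param stage one of `"simulate"`, `"fit-thresholds"`, `"fit-dvc"`,
#'   `"quad-pass"`, `"partition"`.
#' @param config a [run_config()].
#' @param quiet suppress progress messages?
#' @return the stage's principal table, invisibly.
#' @export
run_stage <- function(stage, config, quiet = FALSE) {
  stage <- match.arg(stage, pipeline_stages)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  out <- switch(
    stage,
    "simulate" = {
      recs <- lapply(seq_along(config$observers), function(i) {
        sched <- build_design(config$design, observer_id = config$observers[i])
        simulate_observer(sched, config$params,
                          seed = derive_seed(config$seed, 1000L + i))
      })
      for (i in seq_along(recs)) {
        path <- artifact_path(config, paste0("trials_",
                                             config$observers[i], ".csv"))
        write_trials(recs[[i]], path)
        say("simulate: wrote ", path)
      }
      write_manifest(config, "simulate",
                     paste0("trials_", config$observers, ".csv"))
      invisible(do.call(rbind, recs))
    },
    "fit-thresholds" = {
      check_manifest(config, "simulate")
      rows <- list()
      for (obs in config$observers) {
        rec <- read_trials(require_artifact(config,
                                            paste0("trials_", obs, ".csv"),
                                            "simulate"))
        for (ex in unique(rec$experiment)) for (bn in unique(rec$contrast_bin)) {
          fit <- fit_thresholds(rec[rec$experiment == ex &
                                      rec$contrast_bin == bn, ])
          say(sprintf("fit-thresholds: %s/%s/%s m=%.4f b=%.4f logLik=%.1f",
                      obs, ex, bn, fit$m, fit$b, fit$loglik))
          rows[[length(rows) + 1L]] <-
            data.frame(observer_id = obs, experiment = ex, contrast_bin = bn,
                       pedestal_arcmin = as.numeric(names(fit$sigma_t)),
                       m = fit$m, b = fit$b,
                       sigma_t = as.numeric(fit$sigma_t),
                       threshold = as.numeric(fit$thresholds),
                       loglik = fit$loglik, stringsAsFactors = FALSE)
        }
      }
      tab <- do.call(rbind, rows)
      write_atomic(tab, artifact_path(config, "thresholds.csv"))
      write_manifest(config, "fit-thresholds", "thresholds.csv")
      invisible(tab)
    },
    "fit-dvc" = {
      thr <- read.csv(require_artifact(config, "thresholds.csv",
                                       "fit-thresholds"))
      rows <- list()
      for (obs in config$observers) {
        rec <- read_trials(require_artifact(config,
                                            paste0("trials_", obs, ".csv"),
                                            "simulate"))
        for (ex in unique(rec$experiment)) for (bn in unique(rec$contrast_bin)) {
          sub <- rec[rec$experiment == ex & rec$contrast_bin == bn, ]
          cnt <- tabulate_agreement(sub)
          tsub <- thr[thr$observer_id == obs & thr$experiment == ex &
                        thr$contrast_bin == bn, ]
          st <- setNames(tsub$sigma_t, tsub$pedestal_arcmin)
          fit <- fit_dvc(cnt, st)
          say(sprintf("fit-dvc: %s/%s/%s rho = %s", obs, ex, bn,
                      paste(round(fit$rho, 3), collapse = ", ")))
          rows[[length(rows) + 1L]] <-
            cbind(observer_id = obs, experiment = ex, as.data.frame(fit))
        }
      }
      tab <- do.call(rbind, rows)
      write_atomic(tab, artifact_path(config, "dvc.csv"))
      write_manifest(config, "fit-dvc", "dvc.csv")
      invisible(tab)
    },
    "quad-pass" = {
      thr <- read.csv(require_artifact(config, "thresholds.csv",
                                       "fit-thresholds"))
      rows <- list()
      for (obs in config$observers) {
        rec <- read_trials(require_artifact(config,
                                            paste0("trials_", obs, ".csv"),
                                            "simulate"))
        for (bn in unique(rec$contrast_bin)) {
          sub <- rec[rec$contrast_bin == bn, ]
          cnt <- tabulate_agreement(sub)  # 4-pass grouping inferred
          stf <- thr[thr$observer_id == obs & thr$experiment == "flattened" &
                       thr$contrast_bin == bn, ]
          stn <- thr[thr$observer_id == obs & thr$experiment == "natural" &
                       thr$contrast_bin == bn, ]
          fit <- fit_quadpass(cnt,
                              setNames(stf$sigma_t, stf$pedestal_arcmin),
                              setNames(stn$sigma_t, stn$pedestal_arcmin),
                              cov_zero = config$cov_zero)
          say(sprintf("quad-pass: %s/%s fitted %d conditions", obs, bn,
                      nrow(fit)))
          rows[[length(rows) + 1L]] <- cbind(observer_id = obs,
                                             as.data.frame(fit))
        }
      }
      tab <- do.call(rbind, rows)
      write_atomic(tab, artifact_path(config, "quadpass.csv"))
      write_manifest(config, "quad-pass", "quadpass.csv")
      invisible(tab)
    },
    "partition" = {
      qp <- read.csv(require_artifact(config, "quadpass.csv", "quad-pass"))
      comps <- lapply(seq_len(nrow(qp)), function(i)
        as.data.frame(solve_components(qp$rho_flat[i], qp$rho_nat[i],
                                       qp$rho_cross[i], qp$sigma_t_flat[i],
                                       qp$sigma_t_nat[i])))
      tab <- cbind(qp[, c("observer_id", "pedestal", "bin")],
                   do.call(rbind, comps))
      write_atomic(tab, artifact_path(config, "components.csv"))
      write_manifest(config, "partition", "components.csv")
      say("partition: wrote components for ", nrow(tab), " conditions")
      invisible(tab)
    })
  out
}

#' Run the full pipeline
#'
#' Convenience wrapper running every stage of [run_stage()] in order.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages?
#' @return list of stage tables.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  res <- lapply(pipeline_stages, run_stage, config = config, quiet = quiet)
  names(res) <- pipeline_stages
  invisible(res)
}
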