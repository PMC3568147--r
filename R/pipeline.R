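#' Default run configuration
#'
#' A run configuration is a plain list, fully serializable as YAML or JSON,
#' from which a simulation / fitting / analysis run is reproducible given
#' only the seed. Geometry and family constants live here rather than being
#' hard-coded at call sites.
#'
#' @return A named list with components `workspace`, `conditions`, `cohort`,
#'   `fit`, `analysis`, `master_seed` and `output_dir`.
#' @export
default_run_config <- function() {
  list(
    workspace = list(width = 21.7, depth = 7, y_end = 7),
    conditions = list(
      list(weighted_dimension = "alpha", W = 0.8, w = 0.2, max_cents = 50),
      list(weighted_dimension = "beta", W = 0.8, w = 0.2, max_cents = 50)
    ),
    cohort = list(n_participants_per_condition = 8, n_targets = 50,
                  n_trials = 25, G = 200),
    fit = list(G = 100, n_starts = 2, maxit = 200),
    analysis = list(quiver_bin_width = 0.1, quiver_min_n = 5,
                    n_per_session = 10, last_trials = 5),
    master_seed = 1,
    output_dir = "trajlearn_run"
  )
}

#' Read and validate a run configuration
#'
#' Accepts YAML (`.yml`/`.yaml`) or JSON (`.json`). Missing sections fall
#' back to [default_run_config()]; unknown top-level keys are a schema
#' error.
#'
#' @param path config file path, or `NULL` for the defaults.
#' @return A validated run-config list.
#' @export
read_run_config <- function(path = NULL) {
  base <- default_run_config()
  if (is.null(path)) return(base)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    stop("config must be .yaml/.yml or .json: ", path, call. = FALSE)
  }
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(base, cfg)
  if (!is.numeric(out$master_seed) || length(out$master_seed) != 1L) {
    stop("config key master_seed must be a single number", call. = FALSE)
  }
  out
}

config_conditions <- function(config) {
  lapply(config$conditions, function(cc) {
    reward_config(cc$weighted_dimension, W = cc$W, w = cc$w,
                  max_cents = cc$max_cents)
  })
}

#' Simulate a synthetic cohort to disk
#'
#' Generates the configured cohort and writes one trial-log CSV per
#' synthetic participant, a frozen JSON snapshot of the resolved
#' configuration, a run manifest (seed, counts, package version) and the
#' true per-participant learner parameters.
#'
#' @param config a run-config list ([read_run_config()]) or a path to one.
#' @param out_dir output directory (created if missing); defaults to the
#'   config's `output_dir`.
#' @param seed overrides the config's `master_seed` when non-NULL.
#' @return Invisibly, the directory containing the written logs.
#' @export
run_simulate <- function(config = NULL, out_dir = NULL, seed = NULL) {
  if (is.null(config) || is.character(config)) config <- read_run_config(config)
  if (!is.null(seed)) config$master_seed <- seed
  if (is.null(out_dir)) out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cc <- cohort_config(
    n_participants_per_condition = config$cohort$n_participants_per_condition,
    n_targets = config$cohort$n_targets,
    n_trials = config$cohort$n_trials,
    conditions = config_conditions(config),
    G = config$cohort$G,
    master_seed = config$master_seed)
  log <- generate_cohort(cc)
  for (pid in unique(log$participant_id)) {
    write_trial_log(log[log$participant_id == pid, , drop = FALSE],
                    file.path(out_dir, paste0(pid, ".csv")))
  }
  utils::write.csv(attr(log, "learners"),
                   file.path(out_dir, "true_learners.csv"), row.names = FALSE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package = "trajlearn",
                   version = as.character(utils::packageVersion("trajlearn")),
                   master_seed = config$master_seed,
                   n_participants = length(unique(log$participant_id)),
                   n_records = nrow(log))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Fit the learner to every trial log in a directory
#'
#' Reads each `*.csv` trial log (skipping the run's own metadata files),
#' fits the 4-parameter model per participant, and writes one fit-result
#' JSON per participant plus a cohort-level CSV of fitted parameters.
#' Unreadable logs are skipped and recorded; the run fails only if no log
#' can be fitted.
#'
#' @param log_dir directory of trial-log CSVs (e.g. from [run_simulate()]).
#' @param config run-config list or path (uses the `fit` section).
#' @param out_dir output directory; defaults to `log_dir`.
#' @return Invisibly, a list with `params` (cohort parameter data frame),
#'   `failures` (named character vector of error messages) and `status`
#'   (0 = all fitted, 2 = partial).
#' @export
run_fit <- function(log_dir, config = NULL, out_dir = log_dir) {
  if (is.null(config) || is.character(config)) config <- read_run_config(config)
  files <- pipeline_trial_logs(log_dir)
  if (!length(files)) stop("no trial logs found in ", log_dir, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- list()
  failures <- character(0)
  for (f in files) {
    res <- tryCatch({
      recs <- read_trial_log(f)
      fit <- fit_learner(recs, G = config$fit$G,
                         max_cents = recs_max_cents(recs, config),
                         n_starts = config$fit$n_starts,
                         control = list(maxit = config$fit$maxit))
      pid <- recs$participant_id[1L]
      jsonlite::write_json(
        list(participant_id = pid,
             condition = recs$condition[1L],
             params = as.list(coef(fit)),
             loss = fit$loss,
             variance_explained = fit$variance_explained,
             r2_by_dim = fit$r2_by_dim,
             n_trials_used = fit$n_trials_used,
             diagnostics = fit$diagnostics[c("evals", "convergence")]),
        file.path(out_dir, paste0(pid, "_fit.json")),
        auto_unbox = TRUE, digits = NA)
      data.frame(participant_id = pid, condition = recs$condition[1L],
                 as.data.frame(as.list(coef(fit))), loss = fit$loss,
                 variance_explained = fit$variance_explained)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failures[basename(f)] <- res else {
      params[[length(params) + 1L]] <- res
    }
  }
  if (!length(params)) {
    stop("all trial logs failed to fit; first error: ", failures[1L],
         call. = FALSE)
  }
  params <- do.call(rbind, params)
  utils::write.csv(params, file.path(out_dir, "cohort_fits.csv"),
                   row.names = FALSE)
  if (length(failures)) {
    warning(length(failures), " log(s) skipped: ",
            paste(names(failures), collapse = ", "), call. = FALSE)
  }
  invisible(list(params = params, failures = failures,
                 status = if (length(failures)) 2L else 0L))
}

# Trial-log CSVs in a run directory, excluding the pipeline's own outputs.
pipeline_trial_logs <- function(log_dir) {
  own <- c("true_learners.csv", "cohort_fits.csv", "learning_curves.csv",
           "asymptotes.csv", "quiver.csv", "meta_learning.csv")
  files <- list.files(log_dir, pattern = "\\.csv$", full.names = TRUE)
  files[!basename(files) %in% own]
}

recs_max_cents <- function(recs, config) {
  for (cc in config$conditions) {
    if (paste0(cc$weighted_dimension, "_reward") == recs$condition[1L]) {
      return(cc$max_cents)
    }
  }
  50
}

#' Summarize a cohort run
#'
#' Emits the behavioral summary tables per condition: trial-indexed learning
#' curves, exponential decay-constant / asymptote table, quiver summary of
#' trial-to-trial changes (with model vectors when fit results are
#' available) and the session-wise meta-learning table. Optionally renders
#' learning-curve and quiver figures as PNG.
#'
#' @param log_dir directory of trial-log CSVs.
#' @param config run-config list or path.
#' @param out_dir output directory for the summary CSVs; defaults to
#'   `log_dir`.
#' @param fits optional fits for model quiver vectors: a `"cohort_fits"`
#'   object, or the path to a `cohort_fits.csv` written by [run_fit()]
#'   (default: looked up in `log_dir`). Missing fits produce an
#'   observed-only quiver with a warning.
#' @param figures also write `learning_curves.png` and `quiver.png`.
#' @return Invisibly, a named list of the summary data frames.
#' @export
run_analyze <- function(log_dir, config = NULL, out_dir = log_dir,
                        fits = NULL, figures = FALSE) {
  if (is.null(config) || is.character(config)) config <- read_run_config(config)
  files <- pipeline_trial_logs(log_dir)
  if (!length(files)) stop("no trial logs found in ", log_dir, call. = FALSE)
  records <- do.call(rbind, lapply(files, read_trial_log))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  curves <- do.call(rbind, lapply(unique(records$condition), function(cond) {
    do.call(rbind, lapply(c("alpha_error", "beta_error", "reward"),
                          function(m) {
      d <- learning_curves(records[records$condition == cond, ], by = m)
      cbind(data.frame(condition = cond, measure = m), d)
    }))
  }))
  asym <- asymptote_summary(records)

  fit_params <- resolve_fit_params(fits, log_dir)
  if (is.null(fit_params)) {
    warning("no fit results available; quiver has observed vectors only",
            call. = FALSE)
  }
  quiv <- do.call(rbind, lapply(unique(records$condition), function(cond) {
    rc <- records[records$condition == cond, ]
    q <- quiver_summary(rc, fits = fit_params,
                        bin_width = config$analysis$quiver_bin_width,
                        min_n = config$analysis$quiver_min_n,
                        G = config$fit$G)
    cbind(data.frame(condition = cond), q)
  }))
  meta <- meta_learning_summary(records,
                                n_per_session = config$analysis$n_per_session,
                                last_trials = config$analysis$last_trials)

  tables <- list(learning_curves = curves, asymptotes = asym,
                 quiver = quiv, meta_learning = meta)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (figures) {
    grDevices::png(file.path(out_dir, "learning_curves.png"), 1200, 400)
    plot_learning_curves(records)
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "quiver.png"), 600, 600)
    plot_quiver(quiv)
    grDevices::dev.off()
  }
  invisible(tables)
}

resolve_fit_params <- function(fits, log_dir) {
  if (inherits(fits, "cohort_fits")) return(fits_to_params(fits$params))
  if (is.character(fits) && file.exists(fits)) {
    return(fits_to_params(utils::read.csv(fits)))
  }
  default_csv <- file.path(log_dir, "cohort_fits.csv")
  if (is.null(fits) && file.exists(default_csv)) {
    return(fits_to_params(utils::read.csv(default_csv)))
  }
  NULL
}

fits_to_params <- function(df) {
  out <- lapply(seq_len(nrow(df)), function(i) {
    learner_params(df$lam[i], df$w_alpha[i], df$w_beta[i], df$kappa[i], 0)
  })
  names(out) <- df$participant_id
  out
}
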