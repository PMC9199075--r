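config_defaults <- function() {
  list(
    seed = 0L,
    method = "iht_d",
    stability = list(B = 250L, subsample_fraction = 0.5, M = 20L,
                     epsilon = 0.1, pi_threshold = 0.8),
    solver = list(alpha = 0.2, ridge_lambda = 1e-5, max_iter = 200L,
                  tol = 1e-8, debias_max_steps = 100L,
                  descent_monitor_c = 1e-6)
  )
}

merge_checked <- function(defaults, given, prefix = "") {
  if (is.null(given)) return(defaults)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (k in names(given)) {
    defaults[[k]] <- if (is.list(defaults[[k]]))
      merge_checked(defaults[[k]], given[[k]], paste0(prefix, k, "."))
    else given[[k]]
  }
  defaults
}

#' Load a run configuration with defaults
#'
#' Reads a YAML (or JSON) configuration file, validates that every key is
#' known (unknown keys are rejected by name), and fills missing keys with
#' the standard defaults: `B = 250`, `M = 20`, `epsilon = 0.1`,
#' `pi_threshold = 0.8`, `alpha = 0.2`, `ridge_lambda = 1e-5`. An empty file
#' yields the all-defaults configuration.
#'
#' @param path file path (`.json` is parsed as JSON, anything else as YAML).
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  given <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  cfg <- merge_checked(config_defaults(), given)
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' @param cfg a `run_config` (or plain list with the same shape).
#' @param path output YAML path.
#' @return Invisibly, the path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Materialize solver and stability configs from a run configuration
#'
#' @param cfg a `run_config` from [load_config()].
#' @return List with `solver` (a `solver_config`) and `stability` (a
#'   `stability_config`), both seeded from the master seed.
#' @export
configs_from_run <- function(cfg) {
  s <- cfg$solver
  st <- cfg$stability
  list(solver = solver_config(cfg$method, alpha = s$alpha,
                              ridge_lambda = s$ridge_lambda,
                              max_iter = s$max_iter, tol = s$tol,
                              debias_max_steps = s$debias_max_steps,
                              descent_monitor_c = s$descent_monitor_c,
                              seed = cfg$seed),
       stability = stability_config(B = st$B,
                                    subsample_fraction = st$subsample_fraction,
                                    M = st$M, epsilon = st$epsilon,
                                    pi_threshold = st$pi_threshold,
                                    seed = cfg$seed))
}

#' Write a selection report (JSON + stability-profile CSV)
#'
#' The JSON report carries the stable support, the refit coefficients at
#' full precision, the lambda grid (raw and normalized `lambda* =
#' lambda / lambda_max`), configuration echo and software version. The
#' importance profile is written alongside as CSV with one row per lambda
#' and one column per dictionary component (plus the leading `lambda_star`
#' column), for external stability plots.
#'
#' @param result a `selection_result`.
#' @param path output JSON path; the CSV lands at the same path with
#'   suffix `_profile.csv`.
#' @return Invisibly, the JSON path.
#' @export
write_selection_report <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  report <- list(
    stable_support = as.list(result$stable_support),
    coefficients = as.list(result$coefficients),
    lambda = list(values = result$path$lambdas,
                  lambda_max = result$path$lambda_max,
                  lambda_min = result$path$lambda_min,
                  lambda_star = result$path$lambdas / result$path$lambda_max),
    config = list(method = result$solver$method,
                  alpha = result$solver$alpha,
                  ridge_lambda = result$solver$ridge_lambda,
                  B = result$stability$B,
                  M = result$stability$M,
                  epsilon = result$stability$epsilon,
                  pi_threshold = result$stability$pi_threshold,
                  seed = result$stability$seed),
    n = result$n, p = result$p,
    version = as.character(utils::packageVersion("pdestride"))
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  prof <- data.frame(lambda_star = result$profile$lambdas /
                       result$path$lambda_max,
                     result$profile$pi, check.names = FALSE)
  utils::write.csv(prof, profile_csv_path(path), row.names = FALSE)
  invisible(path)
}

profile_csv_path <- function(path) sub("(\\.json)?$", "_profile.csv", path)

#' Read a selection report written by [write_selection_report()]
#'
#' @param path JSON report path.
#' @return The report as a list (`stable_support` as character vector,
#'   `coefficients` as named numeric vector).
#' @export
read_selection_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = FALSE)
  rep$stable_support <- vapply(rep$stable_support, as.character, "")
  rep$coefficients <- vapply(rep$coefficients, as.numeric, 0)
  rep
}
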