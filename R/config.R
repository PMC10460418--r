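#' Default configuration
#'
#' Pinned hyperparameters and thresholds for the whole pipeline. The original
#' method publications rarely print classifier hyperparameters, so explicit,
#' reproducible defaults are pinned here and can be overridden from a YAML
#' config file.
#'
#' @return nested list of settings: `$ml` (per-algorithm hyperparameters),
#'   `$weights` (DEG q-value threshold, distance cap, candidate-call cutoff).
#' @export
qtg_config <- function() {
  list(
    ml = list(
      neuralnet = list(size = 8, maxit = 500, decay = 0.01),
      svm = list(kernel = "radial", cost = 1),
      xgboost = list(nrounds = 200, max_depth = 4, eta = 0.3),
      bagging = list(ntree = 100),
      logistic_regression = list(lambda = 0.01)
    ),
    weights = list(
      q_threshold = 0.05,
      distance_cap = 6,
      cutoff = 0.5
    )
  )
}

#' Read a YAML configuration file, merged over the defaults
#'
#' @param path path to a YAML file with any subset of the [qtg_config()] keys.
#' @return the merged configuration list.
#' @export
read_config <- function(path) {
  cfg <- qtg_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (k in names(over)) {
      if (is.list(base[[k]]) && is.list(over[[k]]))
        base[[k]] <- merge_lists(base[[k]], over[[k]])
      else base[[k]] <- over[[k]]
    }
    base
  }
  merge_lists(cfg, user)
}
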