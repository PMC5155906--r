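#' Run configuration
#'
#' A declarative YAML configuration drives the command-line pipeline. The
#' schema has three blocks, all optional, with unknown keys rejected:
#'
#' * `study`: `groups` (map of treatment label to session count) and
#'   `seed`.
#' * `agents`: `kind` (`nash`, `inequity_averse` or `empirical`) and
#'   `params` (overrides for that kind's constructor).
#' * `analysis`: `models` (subset of `success`, `contribution`,
#'   `rank_difference`, `ultimatum`), `n_boot`, `seed`.
#'
#' @param path Path to a YAML file.
#' @return A validated config list with all defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(
    study = list(
      groups = list(control = 6L, earned = 6L, random = 6L,
                    earned_no_coop = 3L, random_no_coop = 3L),
      seed = 1L
    ),
    agents = list(kind = "empirical", params = list()),
    analysis = list(
      models = c("success", "contribution", "rank_difference", "ultimatum"),
      n_boot = 100L, seed = 1L
    )
  )
}

validate_run_config <- function(raw) {
  if (is.null(raw)) raw <- list()
  cfg <- default_run_config()
  bad <- setdiff(names(raw), names(cfg))
  if (length(bad)) {
    stop("unknown config block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (block in names(raw)) {
    extra <- setdiff(names(raw[[block]]), names(cfg[[block]]))
    if (length(extra)) {
      stop(sprintf("unknown key(s) in `%s`: %s", block,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    cfg[[block]][names(raw[[block]])] <- raw[[block]]
  }
  groups <- unlist(cfg$study$groups)
  bad_tr <- setdiff(names(groups), treatment_labels())
  if (length(bad_tr)) {
    stop("unknown treatment(s) in `study.groups`: ",
         paste(bad_tr, collapse = ", "), call. = FALSE)
  }
  if (!cfg$agents$kind %in% c("nash", "inequity_averse", "empirical")) {
    stop("`agents.kind` must be nash, inequity_averse or empirical",
         call. = FALSE)
  }
  bad_m <- setdiff(cfg$analysis$models,
                   c("success", "contribution", "rank_difference", "ultimatum"))
  if (length(bad_m)) {
    stop("unknown model(s): ", paste(bad_m, collapse = ", "), call. = FALSE)
  }
  stopifnot(cfg$analysis$n_boot >= 1)
  cfg
}

# Materialize the agent-params object a config block describes.
config_agent_params <- function(agents) {
  switch(agents$kind,
    nash = nash_params(),
    inequity_averse = do.call(inequity_averse_params, agents$params),
    empirical = do.call(empirical_params, agents$params)
  )
}

# Materialize the study design a config describes.
config_study_design <- function(cfg, config = game_config()) {
  study_design(
    groups = unlist(cfg$study$groups),
    agent_params = config_agent_params(cfg$agents),
    seed = cfg$study$seed,
    config = config
  )
}
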