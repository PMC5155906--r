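#' Study design for synthetic data generation
#'
#' Describes one synthetic study: sessions (groups of ten) per treatment,
#' the agent parameters used in each treatment, and the master seed. The
#' defaults reproduce the study scale: 6 groups each for the three
#' cooperation treatments and 3 each for the splitting-only treatments,
#' i.e. 24 sessions and 240 simulated participants, 180 of them in
#' treatments with a cooperation phase.
#'
#' @param groups Named integer vector: sessions per treatment. Names must
#'   be treatment labels; omitted treatments get zero sessions.
#' @param agent_params Either a single [agent_params][nash_params] object
#'   used for every treatment, or a named list keyed by treatment label.
#' @param seed Master seed; per-session seeds are derived from it.
#' @param config A [game_config()].
#' @return A `study_design` list.
#' @examples
#' design <- study_design(groups = c(control = 2, earned = 2), seed = 42)
#' @export
study_design <- function(groups = c(control = 6, earned = 6, random = 6,
                                    earned_no_coop = 3, random_no_coop = 3),
                         agent_params = empirical_params(),
                         seed = 1L,
                         config = game_config()) {
  bad <- setdiff(names(groups), treatment_labels())
  if (length(bad) || is.null(names(groups))) {
    stop("`groups` must be named by treatment label", call. = FALSE)
  }
  stopifnot(all(groups >= 0), all(groups == as.integer(groups)))
  if (inherits(agent_params, "agent_params")) {
    agent_params <- stats::setNames(
      rep(list(agent_params), length(groups)), names(groups))
  }
  missing_par <- setdiff(names(groups)[groups > 0], names(agent_params))
  if (length(missing_par)) {
    stop("no agent parameters for treatment(s): ",
         paste(missing_par, collapse = ", "), call. = FALSE)
  }
  structure(list(groups = groups, agent_params = agent_params,
                 seed = as.integer(seed), config = config),
            class = "study_design")
}

# Stream seeds derived from a parent seed so each stage of a session
# (hierarchy, schedule, decisions, lotteries) is independently reproducible.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate one session
#'
#' Plays one group of `group_size` agents through the full protocol of a
#' treatment: hierarchy formation (earned ranks from abstract skill scores,
#' random ranks from a uniform permutation, or none), a round-robin
#' schedule played in random order, and per dyad the cooperation stage
#' (when present) followed by the splitting stage on the 40-unit pot.
#' In the control condition the proposer of each dyad is drawn at random.
#'
#' @param treatment Treatment label.
#' @param agent_params An [agent_params][nash_params] object.
#' @param seed Session seed (all stage streams derive from it).
#' @param session_id Identifier written into the records.
#' @param config A [game_config()].
#' @return A tibble of trial records, one row per dyad-round, with columns
#'   `session_id`, `treatment`, `round`, `id_high`, `id_low`, `rank_high`,
#'   `rank_low`, `c_high`, `c_low`, `success`, `pot`, `offer`,
#'   `threshold_low`, `accepted`, `lottery_winner`, `payoff_high`,
#'   `payoff_low`. `high`/`low` mean proposer/responder in the control
#'   condition; fields for stages a treatment omits are `NA`.
#' @examples
#' trials <- generate_session("control", empirical_params(), seed = 1)
#' nrow(trials)  # 45
#' @export
generate_session <- function(treatment, agent_params, seed,
                             session_id = "s01", config = game_config()) {
  info <- treatment_info(treatment)
  n <- config$group_size
  streams <- derive_seeds(seed, 4L)

  ranks <- rep(NA_integer_, n)
  if (info$has_hierarchy) {
    set.seed(streams[1L])
    hier <- if (startsWith(info$label, "earned")) {
      form_hierarchy_earned(stats::rnorm(n))
    } else {
      form_hierarchy_random(n)
    }
    ranks <- hier$ranks
  }

  set.seed(streams[2L])
  sched <- round_robin_schedule(n)[sample.int(config$n_rounds)]

  set.seed(streams[3L])
  decision_seeds <- derive_seeds(streams[3L], config$n_rounds)
  set.seed(streams[4L])
  lottery_seeds <- derive_seeds(streams[4L], config$n_rounds)

  ids <- sprintf("%s_p%02d", session_id, seq_len(n))
  rows <- vector("list", config$n_rounds)
  for (t in seq_len(config$n_rounds)) {
    pairs <- sched[[t]]
    set.seed(decision_seeds[t])
    decided <- lapply(seq_len(nrow(pairs)), function(j) {
      a <- pairs[j, 1L]; b <- pairs[j, 2L]
      if (info$has_hierarchy) {
        hi <- if (ranks[a] < ranks[b]) a else b
      } else {
        hi <- if (stats::runif(1L) < 0.5) a else b  # random proposer
      }
      lo <- if (hi == a) b else a
      d <- if (info$has_hierarchy) ranks[lo] - ranks[hi] else NA_integer_
      c_high <- c_low <- NA_integer_
      success <- NA
      pot <- config$pot_success
      if (info$has_cooperation_phase) {
        c_high <- decide_contribution(agent_params, "high", info$label, d, t,
                                      config)
        c_low <- decide_contribution(agent_params, "low", info$label, d, t,
                                     config)
        coop <- resolve_cooperation(c_high, c_low, config)
        success <- coop$success
        pot <- coop$pot
      }
      offer <- threshold <- NA_integer_
      if (pot > 0L) {
        offer <- decide_offer(agent_params, info$label, d, config)
        threshold <- decide_threshold(agent_params, info$label, d, config)
      }
      list(hi = hi, lo = lo, d = d, c_high = c_high, c_low = c_low,
           success = success, pot = pot, offer = offer, threshold = threshold)
    })
    set.seed(lottery_seeds[t])
    rows[[t]] <- dplyr::bind_rows(lapply(decided, function(z) {
      accepted <- NA
      winner <- NA_character_
      share_high <- share_low <- 0L
      if (z$pot > 0L) {
        p_low <- lottery_probability(info$label, z$d)
        split <- resolve_split(z$offer, z$threshold, p_low, z$pot)
        accepted <- split$accepted
        winner <- split$lottery_winner
        share_high <- split$share_high
        share_low <- split$share_low
      }
      pay <- trial_payoffs(z$c_high, z$c_low, share_high, share_low,
                           info$has_cooperation_phase, config)
      tibble::tibble(
        session_id = session_id, treatment = info$label, round = t,
        id_high = ids[z$hi], id_low = ids[z$lo],
        rank_high = if (info$has_hierarchy) ranks[z$hi] else NA_integer_,
        rank_low = if (info$has_hierarchy) ranks[z$lo] else NA_integer_,
        c_high = z$c_high, c_low = z$c_low, success = z$success, pot = z$pot,
        offer = z$offer, threshold_low = z$threshold, accepted = accepted,
        lottery_winner = winner,
        payoff_high = pay[["high"]], payoff_low = pay[["low"]]
      )
    }))
  }
  dplyr::bind_rows(rows)
}

#' Simulate a full study
#'
#' Generates every session of a [study_design()], deriving one child seed
#' per session from the master seed, and stacks all trial records.
#'
#' @param design A [study_design()].
#' @return A tibble of trial records for all sessions, with attributes
#'   `design` and `session_seeds`.
#' @examples
#' trials <- generate_study(study_design(groups = c(control = 1), seed = 9))
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  groups <- design$groups[design$groups > 0]
  n_sessions <- sum(groups)
  session_seeds <- derive_seeds(design$seed, n_sessions)
  out <- vector("list", n_sessions)
  i <- 0L
  for (tr in names(groups)) {
    for (g in seq_len(groups[[tr]])) {
      i <- i + 1L
      sid <- sprintf("%s_g%02d", tr, g)
      out[[i]] <- generate_session(tr, design$agent_params[[tr]],
                                   seed = session_seeds[i], session_id = sid,
                                   config = design$config)
    }
  }
  trials <- dplyr::bind_rows(out)
  attr(trials, "design") <- design
  attr(trials, "session_seeds") <- session_seeds
  trials
}

trial_cols <- function() {
  readr::cols(
    session_id = readr::col_character(),
    treatment = readr::col_character(),
    round = readr::col_integer(),
    id_high = readr::col_character(),
    id_low = readr::col_character(),
    rank_high = readr::col_integer(),
    rank_low = readr::col_integer(),
    c_high = readr::col_integer(),
    c_low = readr::col_integer(),
    success = readr::col_logical(),
    pot = readr::col_integer(),
    offer = readr::col_integer(),
    threshold_low = readr::col_integer(),
    accepted = readr::col_logical(),
    lottery_winner = readr::col_character(),
    payoff_high = readr::col_integer(),
    payoff_low = readr::col_integer()
  )
}

#' Read and write trial-record CSV files
#'
#' One row per dyad-round with the column set of [generate_session()];
#' UTF-8, header row mandatory, empty fields for stages a treatment omits.
#'
#' @param trials A trial-record tibble.
#' @param path File path.
#' @return `read_trials()` returns the trial tibble; `write_trials()`
#'   returns `trials` invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials[, names(trial_cols()$cols)], path, na = "")
  invisible(trials)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_csv(path, col_types = trial_cols(), na = "")
}

#' Write a simulated study to a directory
#'
#' One CSV per session plus a `manifest.yaml` recording the design, the
#' master and per-session seeds, and the package version.
#'
#' @param trials Output of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_study <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- attr(trials, "design")
  for (sid in unique(trials$session_id)) {
    write_trials(trials[trials$session_id == sid, ],
                 file.path(dir, paste0(sid, ".csv")))
  }
  manifest <- list(
    package = "hiercoop",
    version = as.character(utils::packageVersion("hiercoop")),
    master_seed = if (is.null(design)) NA else design$seed,
    groups = if (is.null(design)) NULL else as.list(design$groups),
    session_seeds = as.list(stats::setNames(
      attr(trials, "session_seeds"), unique(trials$session_id))),
    n_trials = nrow(trials)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read all session CSVs of a study directory
#'
#' @param dir Directory written by [write_study()].
#' @return A trial tibble stacking every session file.
#' @export
read_study <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no session CSVs in ", dir, call. = FALSE)
  dplyr::bind_rows(lapply(files, read_trials))
}
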