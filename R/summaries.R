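#' Per-figure summary tables
#'
#' Condenses a trial dataset into the summary tables behind the study's
#' figures: per-player cooperative successes and mean contributions by
#' treatment, success and contributions across rounds, contributions by
#' role and by signed rank difference, contributions split by cooperative
#' outcome, and mean offers and stated acceptance thresholds against the
#' rank-difference group k with the 4k equilibrium prediction alongside.
#'
#' @param trials A trial tibble.
#' @param config A [game_config()].
#' @return A named list of tibbles:
#' \describe{
#'   \item{success_by_treatment}{mean per-player successes (out of
#'     `n_rounds`) per cooperation treatment.}
#'   \item{contribution_by_treatment}{mean contribution per treatment.}
#'   \item{success_by_round}{mean success rate per round and treatment.}
#'   \item{contribution_by_role}{mean contribution by treatment and role.}
#'   \item{contribution_by_role_round}{mean contribution by hierarchy
#'     presence, role and round.}
#'   \item{contribution_by_rank_diff}{mean focal contribution by signed
#'     rank difference (negative = focal higher-ranked).}
#'   \item{contribution_by_outcome}{mean contribution by treatment, role
#'     and cooperative success.}
#'   \item{split_by_k}{mean offer and threshold per treatment and k, with
#'     the `4k` equilibrium column (20 in the control condition).}
#' }
#' @export
summarize_figures <- function(trials, config = game_config()) {
  long <- focal_records(trials, config)
  coop <- long |> dplyr::filter(!is.na(.data$success))

  success_by_treatment <- coop |>
    dplyr::summarise(successes = sum(.data$success),
                     .by = c("treatment", "focal_id")) |>
    dplyr::summarise(mean_successes = mean(.data$successes),
                     n_players = dplyr::n(), .by = "treatment")

  contribution_by_treatment <- coop |>
    dplyr::summarise(mean_contribution = mean(.data$contribution),
                     n = dplyr::n(), .by = "treatment")

  success_by_round <- coop |>
    dplyr::summarise(success_rate = mean(.data$success),
                     .by = c("treatment", "round"))

  contribution_by_role <- coop |>
    dplyr::mutate(role = ifelse(.data$treatment == "control", "either",
                                .data$role)) |>
    dplyr::summarise(mean_contribution = mean(.data$contribution),
                     .by = c("treatment", "role"))

  contribution_by_role_round <- coop |>
    dplyr::mutate(hierarchy = .data$treatment != "control",
                  role = ifelse(.data$treatment == "control", "either",
                                .data$role)) |>
    dplyr::summarise(mean_contribution = mean(.data$contribution),
                     .by = c("hierarchy", "role", "round"))

  contribution_by_rank_diff <- coop |>
    dplyr::filter(!is.na(.data$d_signed)) |>
    dplyr::summarise(mean_contribution = mean(.data$contribution),
                     n = dplyr::n(), .by = "d_signed") |>
    dplyr::arrange(.data$d_signed)

  contribution_by_outcome <- coop |>
    dplyr::mutate(role = ifelse(.data$treatment == "control", "either",
                                .data$role)) |>
    dplyr::summarise(mean_contribution = mean(.data$contribution),
                     .by = c("treatment", "role", "success"))

  split_by_k <- long |>
    dplyr::filter(.data$role == "low", .data$pot > 0L, !is.na(.data$offer)) |>
    dplyr::summarise(mean_offer = mean(.data$offer),
                     mean_threshold = mean(.data$threshold_low),
                     n = dplyr::n(), .by = c("treatment", "k")) |>
    dplyr::mutate(nash = ifelse(is.na(.data$k), config$threshold, 4 * .data$k)) |>
    dplyr::arrange(.data$treatment, .data$k)

  list(
    success_by_treatment = success_by_treatment,
    contribution_by_treatment = contribution_by_treatment,
    success_by_round = success_by_round,
    contribution_by_role = contribution_by_role,
    contribution_by_role_round = contribution_by_role_round,
    contribution_by_rank_diff = contribution_by_rank_diff,
    contribution_by_outcome = contribution_by_outcome,
    split_by_k = split_by_k
  )
}

#' Rank-earnings correlation
#'
#' Spearman rank correlation between hierarchy status (recoded so larger
#' means higher status: `group_size + 1 - rank`) and a player's total
#' earnings in units across the session. Positive values mean
#' higher-ranked players earn more.
#'
#' @param trials A trial tibble (hierarchy treatments are selected
#'   internally).
#' @param config A [game_config()].
#' @return A list with `rho` (`NA` when earnings or ranks are constant),
#'   `n_players`, and `method`.
#' @export
rank_earnings_correlation <- function(trials, config = game_config()) {
  per_player <- focal_records(trials, config) |>
    dplyr::filter(!is.na(.data$rank_focal)) |>
    dplyr::summarise(
      status = config$group_size + 1L - .data$rank_focal[1L],
      total_units = sum(.data$payoff),
      .by = c("session_id", "focal_id")
    )
  if (!nrow(per_player)) stop("no hierarchy records", call. = FALSE)
  rho <- if (stats::sd(per_player$total_units) == 0 ||
             stats::sd(per_player$status) == 0) {
    warning("constant earnings or status: correlation undefined",
            call. = FALSE)
    NA_real_
  } else {
    stats::cor(per_player$status, per_player$total_units, method = "spearman")
  }
  list(rho = rho, n_players = nrow(per_player), method = "spearman")
}
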