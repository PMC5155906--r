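#' Resolve the cooperation stage
#'
#' Both players simultaneously contribute integer amounts from their
#' endowment. If the combined contribution reaches the threshold the pot
#' doubles and enters the splitting phase; otherwise the contributions are
#' lost and no splitting takes place.
#'
#' @param c_high,c_low Integer contributions of the higher- and lower-ranked
#'   player (proposer/responder in the control condition), in
#'   `[0, endowment]`.
#' @param config A [game_config()].
#' @return A list with `c_high`, `c_low`, `success` and `pot`.
#' @examples
#' resolve_cooperation(10, 10)$pot  # 40
#' @export
resolve_cooperation <- function(c_high, c_low, config = game_config()) {
  check_contribution(c_high, config)
  check_contribution(c_low, config)
  success <- (c_high + c_low) >= config$threshold
  list(
    c_high = as.integer(c_high), c_low = as.integer(c_low),
    success = success,
    pot = if (success) config$pot_success else 0L
  )
}

check_contribution <- function(c, config) {
  if (length(c) != 1L || is.na(c) || c != as.integer(c) ||
      c < 0L || c > config$endowment) {
    stop("contributions must be integers in [0, endowment]", call. = FALSE)
  }
  invisible(c)
}

#' Resolve the splitting stage
#'
#' The proposer offers `offer` units of the pot to the responder, who
#' accepts whenever the offer reaches their stated acceptance threshold
#' (acceptance at indifference). On rejection a lottery assigns the whole
#' pot to the responder/lower-ranked player with probability `p_low`.
#' Rejection draws use the current RNG state; seed the session for
#' reproducibility.
#'
#' @param offer Units offered to the responder, in `[0, pot]`.
#' @param threshold Responder's minimum acceptable offer, in `[0, pot]`.
#' @param p_low Probability that the lower-ranked player wins the lottery.
#' @param pot Units being split.
#' @return A list with `offer`, `accepted`, `lottery_winner`
#'   (`"high"`, `"low"` or `"none"`), `share_high` and `share_low`.
#' @examples
#' set.seed(1)
#' resolve_split(20, 20, 0.5)$accepted  # TRUE
#' @export
resolve_split <- function(offer, threshold, p_low, pot = 40L) {
  stopifnot(
    length(offer) == 1L, offer >= 0, offer <= pot, offer == as.integer(offer),
    length(threshold) == 1L, threshold >= 0, threshold <= pot,
    p_low >= 0, p_low <= 1
  )
  offer <- as.integer(offer)
  if (offer >= threshold) {
    return(list(offer = offer, accepted = TRUE, lottery_winner = "none",
                share_high = as.integer(pot) - offer, share_low = offer))
  }
  low_wins <- stats::runif(1L) < p_low
  list(
    offer = offer, accepted = FALSE,
    lottery_winner = if (low_wins) "low" else "high",
    share_high = if (low_wins) 0L else as.integer(pot),
    share_low = if (low_wins) as.integer(pot) else 0L
  )
}

#' Per-trial payoffs and euro conversion
#'
#' In treatments with a cooperation phase each player keeps the uncontributed
#' part of the endowment plus their share of the pot; in splitting-only
#' treatments the payoff is the pot share alone.
#'
#' @param c_high,c_low Contributions, `NA` in splitting-only treatments.
#' @param share_high,share_low Pot shares realized in the splitting phase
#'   (0 when cooperation failed).
#' @param has_cooperation_phase Whether the treatment includes the
#'   contribution stage.
#' @param config A [game_config()].
#' @return `trial_payoffs()`: named integer vector with elements `high` and
#'   `low`. `payout_euros()`: euros, rounded to cents.
#' @examples
#' trial_payoffs(10, 10, 20, 20)  # 30 30
#' payout_euros(45)               # 3
#' @export
trial_payoffs <- function(c_high, c_low, share_high, share_low,
                          has_cooperation_phase = TRUE,
                          config = game_config()) {
  if (has_cooperation_phase) {
    if (is.na(c_high) || is.na(c_low)) {
      stop("contributions are required when the cooperation phase is present",
           call. = FALSE)
    }
    out <- c(high = config$endowment - c_high + share_high,
             low = config$endowment - c_low + share_low)
  } else {
    out <- c(high = share_high, low = share_low)
  }
  if (any(is.na(out)) || any(out < 0)) {
    stop("incomplete trial record: payoffs undefined", call. = FALSE)
  }
  as.integer(out) |> stats::setNames(c("high", "low"))
}

#' @rdname trial_payoffs
#' @param total_units Accumulated units to convert.
#' @export
payout_euros <- function(total_units, config = game_config()) {
  round(total_units / config$units_per_euro, 2)
}
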