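#' Agent behavioral parameters
#'
#' Three policy families map a player's state (treatment, role, rank
#' difference, round) to a contribution, an offer and an acceptance
#' threshold:
#'
#' * `nash_params()` — fully rational risk-neutral play: the subgame-perfect
#'   offer/threshold and the default contribution-equilibrium selection.
#' * `inequity_averse_params()` — Fehr-Schmidt utility
#'   `U_i = x_i - alpha * max(x_j - x_i, 0) - beta * max(x_i - x_j, 0)`;
#'   best responses computed on the integer grid. `alpha = beta = 0`
#'   reproduces the rational agent exactly.
#' * `empirical_params()` — a stochastic calibration reproducing the
#'   qualitative behavioral patterns: lower-ranked contributions rise with
#'   k (fall with rank distance) and fall over rounds, higher-ranked
#'   contributions do the opposite; offers sit above the 4k anchor by more
#'   at large rank distances; stated acceptance thresholds sit above
#'   offers. All values overridable.
#'
#' Default empirical calibration (units): lower-ranked contribution
#' `10 + 1.0 k - 0.5 t_c`, higher-ranked `10 - 0.5 k + 0.5 t_c` (`t_c` the
#' mean-centered round), no-hierarchy contribution mean 11 with no slopes;
#' offer shift above the 4k anchor `max(0, 8 - 1.5 k)`; threshold shift
#' `offer shift + 5`; no-hierarchy mean offer 15 and mean threshold 20
#' (offers 25% below thresholds); Gaussian decision noise with sd 3.
#'
#' @param alpha,beta Disadvantageous/advantageous inequity weights
#'   (`alpha >= beta >= 0`).
#' @param ... Overrides for the empirical calibration fields listed above.
#' @return An `agent_params` list with a `kind` field.
#' @examples
#' empirical_params(noise_sd = 0)$noise_sd  # 0
#' @export
nash_params <- function() {
  structure(list(kind = "nash"), class = "agent_params")
}

#' @rdname nash_params
#' @export
inequity_averse_params <- function(alpha = 0.5, beta = 0.25) {
  stopifnot(alpha >= beta, beta >= 0)
  structure(list(kind = "inequity_averse", alpha = alpha, beta = beta),
            class = "agent_params")
}

#' @rdname nash_params
#' @export
empirical_params <- function(...) {
  defaults <- list(
    kind = "empirical",
    contrib_intercept_low = 10, contrib_slope_k_low = 1.0,
    contrib_slope_t_low = -0.5,
    contrib_intercept_high = 10, contrib_slope_k_high = -0.5,
    contrib_slope_t_high = 0.5,
    contrib_mean_control = 11,
    offer_shift_base = 8, offer_shift_slope_k = -1.5,
    threshold_shift_extra = 5,
    offer_mean_control = 15, threshold_mean_control = 20,
    noise_sd = 3
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    stop("unknown empirical parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(over)] <- over
  stopifnot(defaults$noise_sd >= 0)
  structure(defaults, class = "agent_params")
}

clip_int <- function(x, lo, hi) as.integer(pmin(pmax(round(x), lo), hi))

# Offer shift above the Nash anchor for hierarchy states (>= 0 by clamping).
empirical_offer_shift <- function(params, k) {
  pmax(0, params$offer_shift_base + params$offer_shift_slope_k * k)
}

#' Contribution decision
#'
#' @param params An `agent_params` object.
#' @param role `"high"` or `"low"` (proposer/responder in the control
#'   condition; roles only matter under hierarchy).
#' @param treatment Treatment label (must have a cooperation phase).
#' @param d Rank difference (hierarchy treatments).
#' @param t Round index 1..`n_rounds`.
#' @param config A [game_config()].
#' @return Integer contribution in `[0, endowment]`. Empirical decisions
#'   draw noise from the current RNG state.
#' @export
decide_contribution <- function(params, role = c("high", "low"),
                                treatment = "control", d = NA_integer_, t = 1L,
                                config = game_config()) {
  role <- match.arg(role)
  info <- treatment_info(treatment)
  if (!info$has_cooperation_phase) {
    stop("no contribution decision in splitting-only treatments",
         call. = FALSE)
  }
  switch(params$kind,
    nash = {
      cont <- continuation_values(treatment, d, config)
      sel <- select_contribution_profile(cont$cont_high, cont$cont_low, config)
      if (role == "high") sel$c_high else sel$c_low
    },
    inequity_averse = {
      ia_contribution(params, role, treatment, d, config)
    },
    empirical = {
      t_c <- t - (config$n_rounds + 1) / 2
      mu <- if (!info$has_hierarchy) {
        params$contrib_mean_control
      } else {
        k <- k_from_rank_difference(d)
        if (role == "high") {
          params$contrib_intercept_high + params$contrib_slope_k_high * k +
            params$contrib_slope_t_high * t_c
        } else {
          params$contrib_intercept_low + params$contrib_slope_k_low * k +
            params$contrib_slope_t_low * t_c
        }
      }
      clip_int(mu + stats::rnorm(1L, 0, params$noise_sd), 0L, config$endowment)
    },
    stop("unknown agent kind: ", params$kind, call. = FALSE)
  )
}

#' Offer and acceptance-threshold decisions
#'
#' The rational agent plays the subgame-perfect offer and threshold; the
#' inequity-averse agent maximizes Fehr-Schmidt utility on the integer
#' grid; the empirical agent adds its calibrated shifts and noise to the
#' Nash anchor (no-hierarchy states use the calibrated control means).
#'
#' @inheritParams decide_contribution
#' @return Integer units in `[0, pot]`.
#' @export
decide_offer <- function(params, treatment = "control", d = NA_integer_,
                         config = game_config()) {
  pot <- config$pot_success
  switch(params$kind,
    nash = spe_split(lottery_probability(treatment, d), pot)$offer_star,
    inequity_averse = ia_split(params, lottery_probability(treatment, d),
                               pot)$offer,
    empirical = {
      info <- treatment_info(treatment)
      mu <- if (!info$has_hierarchy) {
        params$offer_mean_control
      } else {
        k <- k_from_rank_difference(d)
        spe_split(k / 10, pot)$offer_star + empirical_offer_shift(params, k)
      }
      clip_int(mu + stats::rnorm(1L, 0, params$noise_sd), 0L, pot)
    },
    stop("unknown agent kind: ", params$kind, call. = FALSE)
  )
}

#' @rdname decide_offer
#' @export
decide_threshold <- function(params, treatment = "control", d = NA_integer_,
                             config = game_config()) {
  pot <- config$pot_success
  switch(params$kind,
    nash = spe_split(lottery_probability(treatment, d), pot)$accept_star,
    inequity_averse = ia_split(params, lottery_probability(treatment, d),
                               pot)$threshold,
    empirical = {
      info <- treatment_info(treatment)
      mu <- if (!info$has_hierarchy) {
        params$threshold_mean_control
      } else {
        k <- k_from_rank_difference(d)
        spe_split(k / 10, pot)$accept_star +
          empirical_offer_shift(params, k) + params$threshold_shift_extra
      }
      clip_int(mu + stats::rnorm(1L, 0, params$noise_sd), 0L, pot)
    },
    stop("unknown agent kind: ", params$kind, call. = FALSE)
  )
}

# --- Fehr-Schmidt machinery -------------------------------------------------

fs_utility <- function(x_self, x_other, alpha, beta) {
  x_self - alpha * pmax(x_other - x_self, 0) - beta * pmax(x_self - x_other, 0)
}

# Splitting-phase best responses under Fehr-Schmidt utility, on the integer
# offer grid with acceptance at indifference. The proposer knows the
# responder's acceptance rule (common parameters).
ia_split <- function(params, p_low, pot) {
  a <- params$alpha
  b <- params$beta
  offers <- 0:pot
  u_acc_low <- fs_utility(offers, pot - offers, a, b)
  eu_rej_low <- p_low * fs_utility(pot, 0, a, b) +
    (1 - p_low) * fs_utility(0, pot, a, b)
  acceptable <- u_acc_low >= eu_rej_low
  threshold <- if (any(acceptable)) offers[which(acceptable)[1L]] else pot + 1L
  u_high <- ifelse(
    acceptable,
    fs_utility(pot - offers, offers, a, b),
    p_low * fs_utility(0, pot, a, b) + (1 - p_low) * fs_utility(pot, 0, a, b)
  )
  best <- which(u_high == max(u_high))
  # ties broken toward an accepted offer (the proposer avoids the lottery at
  # indifference), then toward keeping more of the pot
  best_acc <- best[acceptable[best]]
  pick <- if (length(best_acc)) best_acc[1L] else best[1L]
  list(offer = as.integer(offers[pick]),
       threshold = as.integer(min(threshold, pot)))
}

# Contribution best response to the partner playing the selected equilibrium
# profile, with continuation values from the inequity-averse splitting
# solution. Ties prefer successful cooperation, then the smaller contribution.
ia_contribution <- function(params, role, treatment, d, config) {
  p_low <- lottery_probability(treatment, d)
  split <- ia_split(params, p_low, config$pot_success)
  cont_low <- min(split$offer, config$pot_success)
  cont_high <- config$pot_success - cont_low
  sel <- select_contribution_profile(cont_high, cont_low, config)
  partner_c <- if (role == "high") sel$c_low else sel$c_high
  cont_self <- if (role == "high") cont_high else cont_low
  cont_other <- if (role == "high") cont_low else cont_high
  E <- config$endowment
  c_grid <- 0:E
  success <- (c_grid + partner_c) >= config$threshold
  x_self <- E - c_grid + ifelse(success, cont_self, 0)
  x_other <- E - partner_c + ifelse(success, cont_other, 0)
  u <- fs_utility(x_self, x_other, params$alpha, params$beta)
  cand <- which(u == max(u))
  succ_cand <- cand[success[cand]]
  pick <- if (length(succ_cand)) succ_cand[1L] else cand[1L]
  as.integer(c_grid[pick])
}
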