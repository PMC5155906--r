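#' Subgame-perfect solution of the splitting phase
#'
#' Backward induction on the integer offer grid, assuming risk neutrality
#' and acceptance at indifference. Rejection gives the responder an expected
#' `p_low * pot`, so the smallest acceptable integer offer is
#' `ceiling(p_low * pot)`, and the proposer offers exactly that. With the
#' k/10 lottery on the 40-unit pot this is the familiar 4k schedule.
#'
#' @param p_low Responder's probability of winning the rejection lottery.
#' @param pot Units being split.
#' @return List with `offer_star` and `accept_star` (equal by construction).
#' @examples
#' spe_split(0.1)$offer_star  # 4
#' spe_split(0.5)$offer_star  # 20
#' @export
spe_split <- function(p_low, pot = 40L) {
  stopifnot(p_low >= 0, p_low <= 1)
  accept_star <- as.integer(ceiling(p_low * pot))
  list(offer_star = accept_star, accept_star = accept_star)
}

#' Continuation values of the splitting phase
#'
#' Expected splitting-phase payoffs under the subgame-perfect play for a
#' given treatment and rank difference: the responder gets the equilibrium
#' offer, the proposer the remainder of the pot.
#'
#' @inheritParams lottery_probability
#' @param config A [game_config()].
#' @return List with `cont_high` and `cont_low` (units, summing to the pot).
#' @examples
#' continuation_values("earned", d = 9)  # 36 / 4
#' @export
continuation_values <- function(treatment, d = NA_integer_,
                                config = game_config()) {
  sol <- spe_split(lottery_probability(treatment, d), config$pot_success)
  list(cont_high = config$pot_success - sol$offer_star,
       cont_low = sol$offer_star)
}

#' Pure-strategy Nash equilibria of the contribution stage
#'
#' Enumerates the full integer contribution grid and keeps the profiles at
#' which neither player has a strictly profitable unilateral deviation,
#' given continuation values `cont_high`/`cont_low` that each player earns
#' from the splitting phase when cooperation succeeds. Payoffs are
#' `endowment - c + cont` on success and `endowment - c` on failure.
#'
#' @param cont_high,cont_low Splitting-phase continuation values (must sum
#'   to the successful pot).
#' @param config A [game_config()].
#' @return A tibble of equilibrium profiles with columns `c_high`, `c_low`,
#'   `success`, `payoff_high`, `payoff_low`.
#' @examples
#' eq <- contribution_equilibria(20, 20)
#' any(eq$c_high == 10 & eq$c_low == 10)  # TRUE
#' @export
contribution_equilibria <- function(cont_high, cont_low,
                                    config = game_config()) {
  stopifnot(cont_high + cont_low == config$pot_success,
            cont_high >= 0, cont_low >= 0)
  E <- config$endowment
  grid <- 0:E
  ch <- matrix(grid, nrow = E + 1L, ncol = E + 1L)          # rows: c_high
  cl <- matrix(grid, nrow = E + 1L, ncol = E + 1L, byrow = TRUE)
  success <- (ch + cl) >= config$threshold
  ph <- E - ch + ifelse(success, cont_high, 0)
  pl <- E - cl + ifelse(success, cont_low, 0)
  # best response allowing ties: payoff equals the column/row maximum
  ph_best <- matrix(apply(ph, 2L, max), nrow = E + 1L, ncol = E + 1L,
                    byrow = TRUE)
  pl_best <- matrix(apply(pl, 1L, max), nrow = E + 1L, ncol = E + 1L)
  is_eq <- (ph == ph_best) & (pl == pl_best)
  idx <- which(is_eq, arr.ind = TRUE)
  tibble::tibble(
    c_high = grid[idx[, 1L]],
    c_low = grid[idx[, 2L]],
    success = success[idx],
    payoff_high = ph[idx],
    payoff_low = pl[idx]
  ) |> dplyr::arrange(.data$c_high, .data$c_low)
}

#' Default contribution-equilibrium selection rule
#'
#' Picks, among the successful equilibria, the profile with the lower-ranked
#' player's exposure capped at their continuation value and at half the
#' threshold: `c_low = min(cont_low, threshold %/% 2)`,
#' `c_high = threshold - c_low`. Minimal individual exposure consistent with
#' certain success.
#'
#' @inheritParams contribution_equilibria
#' @return List with `c_high` and `c_low`.
#' @export
select_contribution_profile <- function(cont_high, cont_low,
                                        config = game_config()) {
  c_low <- min(cont_low, config$threshold %/% 2L)
  list(c_high = as.integer(config$threshold - c_low), c_low = as.integer(c_low))
}

#' Subgame-perfect equilibrium of the full game
#'
#' Composes the splitting-phase solution, the continuation values, and (for
#' treatments with a cooperation phase) the contribution-stage equilibrium
#' enumeration with the default selection rule.
#'
#' @inheritParams continuation_values
#' @param selection_rule Function `(cont_high, cont_low, config)` choosing
#'   one contribution equilibrium for play.
#' @return An `spe_result` list: `treatment`, `d`, `p_low`, `offer_star`,
#'   `accept_star`, `cont_high`, `cont_low`, `contribution_eq` (tibble or
#'   `NULL`), `selected_profile`.
#' @examples
#' spe_full_game("earned", d = 9)$offer_star  # 4
#' @export
spe_full_game <- function(treatment, d = NA_integer_, config = game_config(),
                          selection_rule = select_contribution_profile) {
  info <- treatment_info(treatment)
  p_low <- lottery_probability(treatment, d)
  sol <- spe_split(p_low, config$pot_success)
  cont <- continuation_values(treatment, d, config)
  res <- list(
    treatment = info$label, d = d, p_low = p_low,
    offer_star = sol$offer_star, accept_star = sol$accept_star,
    cont_high = cont$cont_high, cont_low = cont$cont_low,
    contribution_eq = NULL, selected_profile = NULL
  )
  if (info$has_cooperation_phase) {
    eq <- contribution_equilibria(cont$cont_high, cont$cont_low, config)
    stopifnot(nrow(eq) > 0L)  # (0,0) or a cooperative profile always survives
    sel <- selection_rule(cont$cont_high, cont$cont_low, config)
    stopifnot(any(eq$c_high == sel$c_high & eq$c_low == sel$c_low))
    res$contribution_eq <- eq
    res$selected_profile <- sel
  }
  structure(res, class = "spe_result")
}

#' @export
print.spe_result <- function(x, ...) {
  cat(sprintf("<spe_result> %s%s\n", x$treatment,
              if (!is.na(x$d)) sprintf(" (d = %d)", x$d) else ""))
  cat(sprintf("  p_low %.2f | offer* = accept* = %d | continuation %d / %d\n",
              x$p_low, x$offer_star, x$cont_high, x$cont_low))
  if (!is.null(x$contribution_eq)) {
    cat(sprintf("  %d contribution-stage pure equilibria; selected (%d, %d)\n",
                nrow(x$contribution_eq), x$selected_profile$c_high,
                x$selected_profile$c_low))
  }
  invisible(x)
}

#' Equilibrium table across treatments and rank differences
#'
#' @param config A [game_config()].
#' @return Tibble with one row per treatment x rank difference (control has
#'   a single row): `treatment`, `d`, `k`, `p_low`, `offer_star`,
#'   `accept_star`, `n_contribution_eq`.
#' @export
spe_table <- function(config = game_config()) {
  rows <- list(list(treatment = "control", d = NA_integer_))
  for (tr in setdiff(treatment_labels(), "control")) {
    for (d in seq_len(config$group_size - 1L)) {
      rows[[length(rows) + 1L]] <- list(treatment = tr, d = d)
    }
  }
  dplyr::bind_rows(lapply(rows, function(r) {
    res <- spe_full_game(r$treatment, r$d, config)
    tibble::tibble(
      treatment = r$treatment, d = r$d,
      k = if (is.na(r$d)) NA_integer_ else k_from_rank_difference(r$d),
      p_low = res$p_low, offer_star = res$offer_star,
      accept_star = res$accept_star,
      n_contribution_eq = if (is.null(res$contribution_eq)) NA_integer_
                          else nrow(res$contribution_eq)
    )
  }))
}
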