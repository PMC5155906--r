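#' Fixed experiment constants
#'
#' Bundles the constants of the two-stage game: each player's per-round
#' endowment, the contribution threshold for successful cooperation, the pot
#' entering the splitting phase after success (the threshold doubled), the
#' number of rounds per session, the group size, and the unit-to-euro
#' exchange rate used at payout.
#'
#' @param endowment Units each player holds per round.
#' @param threshold Combined contribution required for cooperative success.
#' @param pot_success Units entering the splitting phase after success.
#' @param n_rounds Rounds per session; the round-robin needs
#'   `group_size - 1`.
#' @param group_size Players per group (must be even).
#' @param units_per_euro Exchange rate applied to final unit totals.
#'
#' @return An object of class `game_config`: a validated named list.
#' @examples
#' cfg <- game_config()
#' cfg$pot_success  # 40
#' @export
game_config <- function(endowment = 20L, threshold = 20L, pot_success = 40L,
                        n_rounds = 9L, group_size = 10L,
                        units_per_euro = 15L) {
  cfg <- list(
    endowment = as.integer(endowment),
    threshold = as.integer(threshold),
    pot_success = as.integer(pot_success),
    n_rounds = as.integer(n_rounds),
    group_size = as.integer(group_size),
    units_per_euro = as.integer(units_per_euro)
  )
  stopifnot(
    all(vapply(cfg, function(x) length(x) == 1L && !is.na(x) && x > 0L, TRUE))
  )
  if (cfg$pot_success != 2L * cfg$threshold) {
    stop("`pot_success` must be twice `threshold`", call. = FALSE)
  }
  if (cfg$endowment != cfg$threshold) {
    stop("`endowment` must equal `threshold`", call. = FALSE)
  }
  if (cfg$group_size %% 2L != 0L) {
    stop("`group_size` must be even", call. = FALSE)
  }
  if (cfg$n_rounds != cfg$group_size - 1L) {
    stop("`n_rounds` must be `group_size - 1` (round robin)", call. = FALSE)
  }
  structure(cfg, class = "game_config")
}

#' @export
print.game_config <- function(x, ...) {
  cat("<game_config>\n")
  for (nm in names(x)) cat(sprintf("  %-15s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Treatment labels and flags
#'
#' The five treatments: `control` (no hierarchy), `earned` and `random`
#' (hierarchy with cooperation phase), `earned_no_coop` and `random_no_coop`
#' (hierarchy, splitting phase only).
#'
#' @param label Treatment label.
#' @return For `treatment_info()`, a list with `label`, `has_hierarchy` and
#'   `has_cooperation_phase`; `treatment_labels()` returns the five labels.
#' @examples
#' treatment_info("earned_no_coop")$has_cooperation_phase  # FALSE
#' @export
treatment_info <- function(label) {
  label <- match.arg(label, treatment_labels())
  list(
    label = label,
    has_hierarchy = label != "control",
    has_cooperation_phase = !endsWith(label, "_no_coop")
  )
}

#' @rdname treatment_info
#' @export
treatment_labels <- function() {
  c("control", "earned", "random", "earned_no_coop", "random_no_coop")
}

#' Rank-difference group k
#'
#' Maps a rank difference d (1..9 in groups of ten) to its five-level
#' grouping: k = 1 for d of 8 or 9, k = 2 for 6 or 7, k = 3 for 4 or 5,
#' k = 4 for 2 or 3, and k = 5 for d = 1. Larger k means more similar ranks.
#'
#' @param d Integer rank difference(s) in 1..9.
#' @return Integer vector of k values in 1..5.
#' @examples
#' k_from_rank_difference(c(9, 4, 1))  # 1 3 5
#' @export
k_from_rank_difference <- function(d) {
  if (length(d) == 0L) return(integer(0))
  if (any(is.na(d)) || any(d != as.integer(d)) || any(d < 1L) || any(d > 9L)) {
    stop("`d` must be integer rank differences in [1, 9]", call. = FALSE)
  }
  d <- as.integer(d)
  # d: 1 -> 5, 2:3 -> 4, 4:5 -> 3, 6:7 -> 2, 8:9 -> 1
  5L - (d %/% 2L)
}

#' Rejection-lottery probability for the lower-ranked player
#'
#' Probability that the lower-ranked player (or the responder, in the
#' control condition) wins the whole pot when an offer is rejected. Without
#' hierarchy the lottery is fair (0.5); with hierarchy the probability is
#' k/10, so closer ranks give the subordinate better odds.
#'
#' @param treatment Treatment label.
#' @param d Rank difference, required when the treatment has a hierarchy.
#' @return Probability in (0, 1) that the lower-ranked player wins.
#' @examples
#' lottery_probability("control")        # 0.5
#' lottery_probability("earned", d = 9)  # 0.1
#' @export
lottery_probability <- function(treatment, d = NA_integer_) {
  info <- treatment_info(treatment)
  if (!info$has_hierarchy) return(0.5)
  if (is.na(d)) stop("`d` is required for hierarchy treatments", call. = FALSE)
  k_from_rank_difference(d) / 10
}
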