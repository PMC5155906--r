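#' Treatment contrast codes
#'
#' Helmert-style orthogonal contrasts for the three cooperation-phase
#' treatments: `h1` compares the absence of hierarchy (+2) against the two
#' hierarchy conditions (-1 each); `h2` compares random (-1) against
#' earned (+1) hierarchy. Splitting-only treatments belong to a different
#' model family and are rejected.
#'
#' @param treatment Vector of cooperation-phase treatment labels.
#' @return A tibble with columns `h1` and `h2`, one row per input.
#' @examples
#' encode_contrasts("control")  # +2, 0
#' @export
encode_contrasts <- function(treatment) {
  ok <- c("control", "earned", "random")
  if (!all(treatment %in% ok)) {
    stop("contrast codes are defined for cooperation-phase treatments only",
         call. = FALSE)
  }
  tibble::tibble(
    h1 = ifelse(treatment == "control", 2, -1),
    h2 = dplyr::case_when(treatment == "earned" ~ 1,
                          treatment == "random" ~ -1,
                          .default = 0)
  )
}

#' Long (focal-player) view of trial records
#'
#' Expands each dyad-round row into two focal-player rows, the unit at
#' which the regression models operate: each row carries the focal
#' player's role, rank, contribution and payoff plus dyad-level fields.
#' `d_signed = rank_focal - rank_partner` is negative when the focal
#' player outranks the partner (so -8 means the focal player was ranked 1
#' against a partner ranked 9); `round_c` is the mean-centered round.
#'
#' @param trials A trial tibble from [generate_study()] or [read_trials()].
#' @param config A [game_config()].
#' @return A tibble with two rows per trial and columns `dyad_id`,
#'   `focal_id`, `partner_id`, `role`, `rank_focal`, `rank_partner`,
#'   `d_signed`, `abs_d`, `k`, `contribution`, plus the dyad-level fields.
#' @export
focal_records <- function(trials, config = game_config()) {
  base <- trials |>
    dplyr::mutate(
      dyad_id = paste(.data$session_id, pmin(.data$id_high, .data$id_low),
                      pmax(.data$id_high, .data$id_low), sep = ":"),
      round_c = .data$round - (config$n_rounds + 1) / 2,
      abs_d = abs(.data$rank_low - .data$rank_high)
    )
  hi <- base |>
    dplyr::mutate(
      focal_id = .data$id_high, partner_id = .data$id_low, role = "high",
      rank_focal = .data$rank_high, rank_partner = .data$rank_low,
      contribution = .data$c_high, payoff = .data$payoff_high
    )
  lo <- base |>
    dplyr::mutate(
      focal_id = .data$id_low, partner_id = .data$id_high, role = "low",
      rank_focal = .data$rank_low, rank_partner = .data$rank_high,
      contribution = .data$c_low, payoff = .data$payoff_low
    )
  k_or_na <- function(d) {
    out <- rep(NA_integer_, length(d))
    out[!is.na(d)] <- k_from_rank_difference(d[!is.na(d)])
    out
  }
  dplyr::bind_rows(hi, lo) |>
    dplyr::mutate(
      d_signed = .data$rank_focal - .data$rank_partner,
      k = k_or_na(.data$abs_d),
      rank_code = dplyr::case_when(.data$role == "high" & !is.na(.data$rank_focal) ~ 1,
                                   .data$role == "low" & !is.na(.data$rank_focal) ~ -1,
                                   .default = NA_real_)
    ) |>
    dplyr::select(-"id_high", -"id_low", -"rank_high", -"rank_low",
                  -"c_high", -"c_low", -"payoff_high", -"payoff_low")
}

#' Dyad-level bootstrap confidence intervals
#'
#' The resampling scheme behind every model family: in each replicate one
#' member of every dyad is selected at random as its representative, the
#' resulting one-row-per-dyad data are cluster-resampled with replacement
#' at the grouping unit (dyads, or individuals with all their selected
#' rows), and the model is refit. Point estimates are the mean of the
#' replicate coefficients; 95% confidence intervals are the 2.5/97.5
#' percentiles. Replicates whose fit errors out are dropped (the run fails
#' if more than `max_drop` of them do); replicates that only warn (e.g.
#' separation in a logistic fit) are kept and counted as flagged.
#'
#' @param data A focal-format tibble with columns `dyad_id` and `focal_id`.
#' @param fit_fun Function taking a data subset and returning a named
#'   numeric vector of coefficients.
#' @param n_boot Number of bootstrap replicates.
#' @param unit Grouping unit resampled with replacement: `"dyad"` or
#'   `"individual"`.
#' @param seed Seed for the resampling streams.
#' @param max_drop Maximum tolerated fraction of failed replicates.
#' @return A `bootstrap_fit`: tibble with columns `term`, `estimate`,
#'   `ci_low`, `ci_high` and attributes `n_boot`, `n_dropped`,
#'   `n_flagged`, `unit`, `seed`.
#' @export
dyad_bootstrap <- function(data, fit_fun, n_boot = 100,
                           unit = c("dyad", "individual"), seed = 1L,
                           max_drop = 0.2) {
  unit <- match.arg(unit)
  stopifnot(all(c("dyad_id", "focal_id") %in% names(data)), n_boot >= 1)
  set.seed(seed)
  dyad_rows <- split(seq_len(nrow(data)), data$dyad_id)
  coefs <- vector("list", n_boot)
  n_flagged <- 0L
  for (b in seq_len(n_boot)) {
    picked <- vapply(dyad_rows, function(ix) {
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
    }, integer(1))
    sub <- data[picked, , drop = FALSE]
    cluster <- if (unit == "dyad") sub$dyad_id else sub$focal_id
    groups <- split(seq_len(nrow(sub)), cluster)
    take <- unlist(groups[sample.int(length(groups), replace = TRUE)],
                   use.names = FALSE)
    flagged <- FALSE
    res <- tryCatch(
      withCallingHandlers(
        fit_fun(sub[take, , drop = FALSE]),
        warning = function(w) {
          flagged <<- TRUE
          invokeRestart("muffleWarning")
        }
      ),
      error = function(e) NULL
    )
    if (is.null(res) || anyNA(res)) next  # dropped replicate
    if (flagged) n_flagged <- n_flagged + 1L
    coefs[[b]] <- res
  }
  keep <- !vapply(coefs, is.null, TRUE)
  n_dropped <- sum(!keep)
  if (n_dropped > max_drop * n_boot) {
    stop(sprintf("bootstrap failed: %d of %d replicates dropped",
                 n_dropped, n_boot), call. = FALSE)
  }
  mat <- do.call(rbind, coefs[keep])
  fit <- tibble::tibble(
    term = colnames(mat),
    estimate = colMeans(mat),
    ci_low = apply(mat, 2L, stats::quantile, probs = 0.025, names = FALSE),
    ci_high = apply(mat, 2L, stats::quantile, probs = 0.975, names = FALSE)
  )
  structure(fit, class = c("bootstrap_fit", class(fit)),
            n_boot = n_boot, n_dropped = n_dropped, n_flagged = n_flagged,
            unit = unit, seed = seed)
}

#' @export
print.bootstrap_fit <- function(x, ...) {
  cat(sprintf("<bootstrap_fit> %d replicates (%d dropped, %d flagged), unit = %s\n",
              attr(x, "n_boot"), attr(x, "n_dropped"), attr(x, "n_flagged"),
              attr(x, "unit")))
  NextMethod()
}

glm_coefs <- function(formula, data, family = stats::gaussian()) {
  stats::coef(stats::glm(formula, family = family, data = data))
}

#' Cooperative-success model
#'
#' Logistic regression of dyad success on the hierarchy contrasts, the
#' mean-centered round, and the hierarchy-by-round interaction, with
#' dyad-level bootstrap confidence intervals. A positive `h1` coefficient
#' means success is more frequent without a hierarchy.
#'
#' @param trials Trial tibble (cooperation-phase treatments are selected
#'   internally).
#' @param n_boot,seed Passed to [dyad_bootstrap()].
#' @param config A [game_config()].
#' @return A [bootstrap_fit][dyad_bootstrap].
#' @export
fit_success_model <- function(trials, n_boot = 100, seed = 1L,
                              config = game_config()) {
  dat <- focal_records(trials, config) |>
    dplyr::filter(.data$treatment %in% c("control", "earned", "random"))
  if (!nrow(dat)) stop("no cooperation-phase records", call. = FALSE)
  dat <- dplyr::bind_cols(dat, encode_contrasts(dat$treatment))
  dyad_bootstrap(
    dat,
    function(df) glm_coefs(success ~ h1 + h2 + round_c + h1:round_c, df,
                           stats::binomial()),
    n_boot = n_boot, unit = "dyad", seed = seed
  )
}

#' Contribution model (rank as a binary role)
#'
#' Linear model of the contribution, expressed relative to the mean
#' contribution of the no-hierarchy condition, on the binary rank code
#' (+1 higher-, -1 lower-ranked), the mean-centered round, and their
#' interaction; hierarchy-treatment rows only, bootstrap grouped by
#' individual.
#'
#' @inheritParams fit_success_model
#' @return A [bootstrap_fit][dyad_bootstrap].
#' @export
fit_contribution_model <- function(trials, n_boot = 100, seed = 1L,
                                   config = game_config()) {
  dat <- focal_records(trials, config)
  ctrl_mean <- mean(dat$contribution[dat$treatment == "control"], na.rm = TRUE)
  if (is.nan(ctrl_mean)) ctrl_mean <- 0
  dat <- dat |>
    dplyr::filter(.data$treatment %in% c("earned", "random")) |>
    dplyr::mutate(contribution_rel = .data$contribution - ctrl_mean)
  if (!nrow(dat)) stop("no hierarchy cooperation records", call. = FALSE)
  dyad_bootstrap(
    dat,
    function(df) glm_coefs(contribution_rel ~ rank_code * round_c, df),
    n_boot = n_boot, unit = "individual", seed = seed
  )
}

#' Contribution model (continuous rank difference)
#'
#' Linear model of the contribution on the signed rank difference
#' (negative when the focal player outranks the partner) and the
#' mean-centered round. The top- and bottom-ranked players of each group
#' are excluded. A negative slope means lower-ranked players contribute
#' less the further below their partner they sit.
#'
#' @inheritParams fit_success_model
#' @return A [bootstrap_fit][dyad_bootstrap].
#' @export
fit_rank_difference_model <- function(trials, n_boot = 100, seed = 1L,
                                      config = game_config()) {
  dat <- focal_records(trials, config) |>
    dplyr::filter(.data$treatment %in% c("earned", "random"),
                  .data$rank_focal > 1L,
                  .data$rank_focal < config$group_size)
  if (!nrow(dat)) stop("no eligible hierarchy records", call. = FALSE)
  dyad_bootstrap(
    dat,
    function(df) glm_coefs(contribution ~ d_signed + round_c, df),
    n_boot = n_boot, unit = "individual", seed = seed
  )
}

#' Ultimatum model (offers and stated thresholds)
#'
#' Stacks every splitting-phase record of the hierarchy treatments into
#' offer rows (role -1, the proposer's offer) and threshold rows (role +1,
#' the responder's stated minimum), and regresses the value on the
#' presence of a cooperation phase (+1 present, -1 absent), the role code,
#' the absolute rank difference, and the mean-centered round; bootstrap
#' grouped by individual.
#'
#' @inheritParams fit_success_model
#' @return A [bootstrap_fit][dyad_bootstrap].
#' @export
fit_ultimatum_model <- function(trials, n_boot = 100, seed = 1L,
                                config = game_config()) {
  base <- focal_records(trials, config) |>
    dplyr::filter(.data$treatment != "control", .data$pot > 0L,
                  !is.na(.data$offer))
  if (!nrow(base)) stop("no hierarchy splitting-phase records", call. = FALSE)
  dat <- base |>
    dplyr::mutate(
      coop_present = ifelse(endsWith(.data$treatment, "_no_coop"), -1, 1),
      role_code = ifelse(.data$role == "low", 1, -1),  # +1 = receiving side
      value = ifelse(.data$role == "low", .data$threshold_low, .data$offer)
    )
  dyad_bootstrap(
    dat,
    function(df) glm_coefs(value ~ coop_present + role_code + abs_d + round_c,
                           df),
    n_boot = n_boot, unit = "individual", seed = seed
  )
}
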