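test_that("treatment contrasts are the documented orthogonal set", {
  expect_equal(encode_contrasts("control"), tibble::tibble(h1 = 2, h2 = 0))
  expect_equal(encode_contrasts("random"), tibble::tibble(h1 = -1, h2 = -1))
  expect_equal(encode_contrasts("earned"), tibble::tibble(h1 = -1, h2 = 1))
  balanced <- encode_contrasts(rep(c("control", "earned", "random"), 4))
  expect_equal(sum(balanced$h1 * balanced$h2), 0)
  expect_equal(colSums(balanced), c(h1 = 0, h2 = 0))
  expect_error(encode_contrasts("earned_no_coop"), "cooperation-phase")
})

test_that("design columns match a hand-built matrix on a toy dataset", {
  toy <- tibble::tibble(treatment = c("control", "control", "earned",
                                      "earned", "random", "random"),
                        round = c(1L, 9L, 1L, 9L, 5L, 5L))
  codes <- encode_contrasts(toy$treatment)
  hand <- cbind(h1 = c(2, 2, -1, -1, -1, -1),
                h2 = c(0, 0, 1, 1, -1, -1),
                round_c = toy$round - 5)
  expect_equal(as.matrix(cbind(codes, round_c = toy$round - 5)), hand,
               ignore_attr = TRUE)
})

test_that("the focal view uses the signed rank-difference convention", {
  trials <- generate_session("earned", empirical_params(), seed = 14)
  long <- focal_records(trials)
  expect_equal(nrow(long), 90L)
  top_vs_bottom <- long[long$rank_focal == 1L & long$rank_partner == 9L, ]
  expect_equal(top_vs_bottom$d_signed, -8L)
  expect_equal(top_vs_bottom$k, 1L)
  expect_equal(sort(unique(long$dyad_id)), unique(sort(long$dyad_id)))
  expect_equal(length(unique(long$dyad_id)), 45L)
  # mean-centered round spans -4..4
  expect_equal(range(long$round_c), c(-4, 4))
})

test_that("bootstrap CIs are deterministic and collapse at one replicate", {
  trials <- generate_study(study_design(
    groups = c(control = 2, earned = 1, random = 1), seed = 6))
  f1 <- fit_success_model(trials, n_boot = 25, seed = 42)
  f2 <- fit_success_model(trials, n_boot = 25, seed = 42)
  expect_identical(as.data.frame(f1), as.data.frame(f2))

  one <- fit_success_model(trials, n_boot = 1, seed = 9)
  expect_equal(one$ci_low, one$estimate)
  expect_equal(one$ci_high, one$estimate)
})

test_that("failing replicates are dropped and excess failure aborts the run", {
  long <- focal_records(generate_session("earned", empirical_params(),
                                         seed = 2))
  flaky <- local({
    calls <- 0L
    function(df) {
      calls <<- calls + 1L
      if (calls %% 2L == 0L) stop("no convergence")
      c(a = mean(df$contribution))
    }
  })
  fit <- dyad_bootstrap(long, flaky, n_boot = 10, seed = 1, max_drop = 0.6)
  expect_equal(attr(fit, "n_dropped"), 5L)
  expect_error(
    dyad_bootstrap(long, function(df) stop("always"), n_boot = 10, seed = 1),
    "dropped")
})

test_that("degenerate all-success data is flagged, not fatal", {
  trials <- generate_study(study_design(
    groups = c(control = 1, earned = 1, random = 1), nash_params(), seed = 3))
  expect_true(all(trials$success))
  fit <- fit_success_model(trials, n_boot = 10, seed = 2)
  expect_s3_class(fit, "bootstrap_fit")
  expect_gt(attr(fit, "n_flagged"), 0L)  # separation warnings retained
})

test_that("the contribution model recovers a generated rank-role gap", {
  gap_pars <- empirical_params(
    contrib_intercept_low = 8, contrib_slope_k_low = 0,
    contrib_slope_t_low = 0,
    contrib_intercept_high = 14, contrib_slope_k_high = 0,
    contrib_slope_t_high = 0)
  trials <- generate_study(study_design(
    groups = c(control = 2, earned = 4, random = 4),
    agent_params = list(control = empirical_params(), earned = gap_pars,
                        random = gap_pars),
    seed = 17))
  fit <- fit_contribution_model(trials, n_boot = 60, seed = 5)
  rank_row <- fit[fit$term == "rank_code", ]
  # +1 = higher rank; generated gap is (14 - 8) / 2 = +3 per unit code
  expect_gt(rank_row$ci_low, 0)
  expect_lt(abs(rank_row$estimate - 3), 0.5)
})

test_that("the rank-difference model excludes extreme ranks and matches lm", {
  trials <- generate_study(study_design(groups = c(earned = 4, random = 4),
                                        seed = 23))
  long <- focal_records(trials)
  kept <- long[long$rank_focal > 1L & long$rank_focal < 10L, ]
  full_fit <- stats::lm(contribution ~ d_signed + round_c, data = kept)
  fit <- fit_rank_difference_model(trials, n_boot = 60, seed = 6)
  slope <- fit[fit$term == "d_signed", ]
  expect_gt(slope$ci_high, coef(full_fit)[["d_signed"]] - 0.2)
  expect_lt(slope$ci_low, coef(full_fit)[["d_signed"]] + 0.2)
})

test_that("the ultimatum model separates roles and covers a true null", {
  # offers and thresholds generated identically with and without the
  # cooperation phase: the cooperation-presence CI must cover zero
  trials <- generate_study(study_design(
    groups = c(earned = 3, random = 3, earned_no_coop = 3,
               random_no_coop = 3), seed = 29))
  fit <- fit_ultimatum_model(trials, n_boot = 80, seed = 7)
  coop <- fit[fit$term == "coop_present", ]
  expect_lte(coop$ci_low, 0)
  expect_gte(coop$ci_high, 0)
  # receivers state more than proposers offer; values fall with rank distance
  expect_gt(fit[fit$term == "role_code", ]$ci_low, 0)
  expect_lt(fit[fit$term == "abs_d", ]$ci_high, 0)
})

test_that("summary tables mirror the figure conventions", {
  trials <- generate_study(study_design(
    groups = c(control = 2, earned = 2, random = 2, earned_no_coop = 1),
    seed = 19))
  tabs <- summarize_figures(trials)

  expect_true(all(tabs$success_by_treatment$mean_successes <= 9))
  expect_setequal(tabs$success_by_treatment$treatment,
                  c("control", "earned", "random"))
  # the -8 bin aggregates every focal-outranks-partner-by-8 trial, i.e.
  # both the (1, 9) and (2, 10) rank pairs, over cooperation treatments
  neg8 <- tabs$contribution_by_rank_diff[
    tabs$contribution_by_rank_diff$d_signed == -8, ]
  long <- focal_records(trials)
  expect_equal(neg8$n,
               sum(long$d_signed == -8 & !is.na(long$success), na.rm = TRUE))
  expect_equal(tabs$split_by_k$nash[!is.na(tabs$split_by_k$k)],
               4 * tabs$split_by_k$k[!is.na(tabs$split_by_k$k)])
  expect_equal(unique(tabs$split_by_k$nash[is.na(tabs$split_by_k$k)]), 20)

  # rational play makes the offers table the 4k line exactly
  nash_trials <- generate_study(study_design(
    groups = c(earned = 2), nash_params(), seed = 3))
  nash_split <- summarize_figures(nash_trials)$split_by_k
  expect_equal(nash_split$mean_offer, nash_split$nash)
  expect_equal(nash_split$mean_threshold, nash_split$nash)
})

test_that("rank-earnings correlation is positive under rational play", {
  nash_trials <- generate_study(study_design(
    groups = c(earned = 2, random = 2), nash_params(), seed = 37))
  res <- rank_earnings_correlation(nash_trials)
  expect_gt(res$rho, 0)
  expect_equal(res$n_players, 40L)

  emp <- generate_study(study_design(groups = c(earned = 4), seed = 41))
  expect_gt(rank_earnings_correlation(emp)$rho, 0)

  flat <- generate_session("earned", empirical_params(), seed = 2)
  flat$payoff_high <- 10L
  flat$payoff_low <- 10L
  expect_warning(res0 <- rank_earnings_correlation(flat), "undefined")
  expect_true(is.na(res0$rho))
})
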