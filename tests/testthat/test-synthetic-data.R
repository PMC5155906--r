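test_that("sessions have the round-robin shape for every treatment", {
  ctrl <- generate_session("control", empirical_params(), seed = 1)
  expect_equal(nrow(ctrl), 45L)
  expect_true(all(is.na(ctrl$rank_high)) && all(is.na(ctrl$rank_low)))

  noc <- generate_session("earned_no_coop", empirical_params(), seed = 2)
  expect_equal(nrow(noc), 45L)
  expect_true(all(is.na(noc$c_high)) && all(is.na(noc$c_low)))
  expect_true(all(noc$pot == 40L))
  expect_true(all(!is.na(noc$offer)))

  # every player appears once per round; every pair meets exactly once
  for (tr in list(ctrl, noc)) {
    for (t in 1:9) {
      ids <- c(tr$id_high[tr$round == t], tr$id_low[tr$round == t])
      expect_equal(length(unique(ids)), 10L)
    }
    pairs <- paste(pmin(tr$id_high, tr$id_low), pmax(tr$id_high, tr$id_low))
    expect_equal(length(unique(pairs)), 45L)
  }
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_session("random", empirical_params(), seed = 77)
  b <- generate_session("random", empirical_params(), seed = 77)
  expect_identical(a, b)

  d <- study_design(groups = c(control = 1, earned = 1), seed = 5)
  expect_identical(as.data.frame(generate_study(d)),
                   as.data.frame(generate_study(d)))
})

test_that("the default design reproduces the study scale", {
  trials <- generate_study(study_design(seed = 31))
  expect_equal(length(unique(trials$session_id)), 24L)
  players <- unique(c(paste(trials$session_id, trials$id_high),
                      paste(trials$session_id, trials$id_low)))
  expect_equal(length(players), 240L)
  coop <- trials[!is.na(trials$success), ]
  expect_equal(length(unique(coop$session_id)), 18L)  # 180 participants
  expect_equal(nrow(trials), 24L * 45L)

  small <- generate_study(study_design(
    groups = c(control = 1, earned = 1, random = 1, earned_no_coop = 1,
               random_no_coop = 1), seed = 8))
  expect_equal(length(unique(small$session_id)), 5L)
})

test_that("every generated record satisfies the payoff and split invariants", {
  trials <- generate_study(study_design(
    groups = c(control = 2, earned = 2, random_no_coop = 1), seed = 13))
  coop <- trials[!is.na(trials$success), ]
  expect_equal(coop$success, coop$c_high + coop$c_low >= 20L)
  expect_equal(coop$pot, ifelse(coop$success, 40L, 0L))

  split <- trials[!is.na(trials$offer), ]
  expect_true(all(split$offer >= 0L & split$offer <= split$pot))
  expect_equal(split$accepted, split$offer >= split$threshold_low)
  expect_true(all(split$lottery_winner[split$accepted] == "none"))
  expect_true(all(split$lottery_winner[!split$accepted] %in% c("high", "low")))

  # payoff accounting per treatment family
  has_coop <- !endsWith(trials$treatment, "_no_coop")
  share_high <- share_low <- rep(0L, nrow(trials))
  acc <- !is.na(trials$accepted) & trials$accepted
  rej <- !is.na(trials$accepted) & !trials$accepted
  share_low[acc] <- trials$offer[acc]
  share_high[acc] <- trials$pot[acc] - trials$offer[acc]
  share_low[rej] <- ifelse(trials$lottery_winner[rej] == "low",
                           trials$pot[rej], 0L)
  share_high[rej] <- ifelse(trials$lottery_winner[rej] == "high",
                            trials$pot[rej], 0L)
  expect_equal(trials$payoff_high,
               ifelse(has_coop, 20L - trials$c_high, 0L) + share_high)
  expect_equal(trials$payoff_low,
               ifelse(has_coop, 20L - trials$c_low, 0L) + share_low)
  expect_true(all(trials$payoff_high >= 0L & trials$payoff_low >= 0L))
})

test_that("fully rational groups always cooperate and settle every split", {
  trials <- generate_study(study_design(
    groups = c(control = 1, earned = 1, random = 1), nash_params(),
    seed = 4))
  expect_true(all(trials$success))
  expect_true(all(trials$accepted))
  expect_true(all(trials$lottery_winner == "none"))
})

test_that("default calibration yields more successes without hierarchy", {
  trials <- generate_study(study_design(
    groups = c(control = 40, earned = 40, random = 40), seed = 7))
  rate <- tapply(trials$success, trials$treatment != "control", mean)
  expect_gt(rate[["FALSE"]], rate[["TRUE"]])
})

test_that("trial CSVs round-trip and are byte-stable", {
  trials <- generate_session("earned", empirical_params(), seed = 21,
                             session_id = "rt")
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_trials(trials, f1)
  write_trials(trials, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_trials(f1)
  expect_equal(as.data.frame(back), as.data.frame(trials))

  dir <- tempfile("study")
  study <- generate_study(study_design(groups = c(control = 1, earned = 1),
                                       seed = 3))
  manifest <- write_study(study, dir)
  expect_equal(manifest$master_seed, 3L)
  expect_length(list.files(dir, pattern = "\\.csv$"), 2L)
  again <- read_study(dir)
  expect_equal(nrow(again), nrow(study))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  unlink(dir, recursive = TRUE)
})
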