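test_that("identical seeds give bit-identical surveys", {
  cfg <- simulation_config(n = 2000, seed = 17)
  expect_identical(simulate_survey(cfg), simulate_survey(cfg))
  expect_identical(simulate_survey(cfg, seed = 3), simulate_survey(cfg, seed = 3))
  expect_false(identical(simulate_survey(cfg, seed = 3), simulate_survey(cfg, seed = 4)))
})

test_that("per-respondent streams survive allocation changes", {
  # changing arm probabilities reinterprets the arm draw but leaves the dice
  # game columns of every respondent untouched
  base <- simulate_survey(simulation_config(n = 3000, seed = 5))
  alt <- simulate_survey(simulation_config(
    n = 3000, seed = 5, arm_probs = c(DQ = 0.7, CM = 0.1, UQ = 0.1, FR = 0.1)))
  for (col in c("game", "die", "won", "claim", "cheater")) {
    expect_identical(base[[col]], alt[[col]])
  }
})

test_that("Benford digit sampler matches the law", {
  pmf <- log10(1 + 1 / (1:9))
  expect_equal(sum(pmf), 1)
  set.seed(123)
  d <- sample_benford_digit(2e5)
  expect_true(all(d %in% 1:9))
  expect_lt(abs(mean(d <= 5) - 0.778), 0.004)
  expect_lt(abs(mean(d == 1) - log10(2)), 0.004)
})

test_that("honest direct questioning reproduces the cheat rate exactly", {
  dat <- simulate_arm("DQ", "prediction", 5000, seed = 2)
  expect_identical(dat$y, dat$cheater)
  expect_equal(mean(dat$y), mean(dat$cheater))
})

test_that("claim rates and routing match the design probabilities", {
  dat <- simulate_survey(simulation_config(
    n = 1e5, game_split = 1, seed = 19,
    p_incomplete = 0, p_screener_fail = 0, p_no_roll = 0))
  # Pr(X = 1) = 1/6 + (5/6) * 0.3, overall cheating around a quarter
  expect_lt(abs(mean(dat$claim) - (1 / 6 + 5 / 6 * 0.3)), 0.005)
  expect_lt(abs(mean(dat$cheater) - 0.25), 0.005)
  # Benford routing share of the UQ arm
  uq <- dat[dat$technique == "UQ", ]
  expect_lt(abs(mean(uq$uq_routed) - 0.778), 0.01)
  expect_identical(unique(uq$uq_routed[uq$benford_digit <= 5]), TRUE)
  # arm allocation
  expect_lt(max(abs(prop.table(table(dat$technique))[c("DQ", "CM", "UQ", "FR")] -
                      c(1, 3, 2, 2) / 8)), 0.01)
})

test_that("response instrument follows each design's procedure", {
  cm <- rrt_design("CM", p_z = 1 / 6)
  expect_identical(
    apply_response_instrument(c(1L, 1L, 0L, 0L), cm,
                              device = list(z = c(1L, 0L, 1L, 0L))),
    c(1L, 0L, 0L, 1L)
  )
  fr <- rrt_design("FR", p_yes = 2 / 12, p_no = 2 / 12)
  expect_identical(
    apply_response_instrument(c(0L, 1L, 1L), fr,
                              device = list(instruction = c("yes", "no", "answer"))),
    c(1L, 0L, 1L)
  )
  uq <- rrt_design("UQ", p_u = 0.25, p_z = 0.5)
  expect_identical(
    apply_response_instrument(c(1L, 1L), uq,
                              device = list(routed_sensitive = c(TRUE, FALSE),
                                            z = c(0L, 0L))),
    c(1L, 0L)
  )
  # self-protective and confused behavior
  expect_identical(
    apply_response_instrument(c(1L, 1L), fr,
                              device = list(instruction = c("yes", "yes")),
                              behavior = "self_protective"),
    c(0L, 0L)
  )
  expect_identical(
    apply_response_instrument(c(1L, 0L), cm, device = list(z = c(1L, 1L)),
                              behavior = "confused", u = c(0.2, 0.9)),
    c(1L, 0L)
  )
  expect_error(apply_response_instrument(c(1L, 0L), cm, device = list()), "`z`")
  expect_error(
    apply_response_instrument(1L, fr, device = list(instruction = "maybe")),
    "instructions"
  )
})

test_that("honest CM responses follow the forward mixture", {
  # population with pi = 0.2 and p_z = 1/6: Pr(Y = 1) = 0.70
  cm <- rrt_design("CM", p_z = 1 / 6)
  pi <- 0.2
  expect_equal(forward_mixture(cm, pi), 0.70)
  set.seed(6)
  n <- 5e4
  intended <- rbinom(n, 1, pi)
  z <- rbinom(n, 1, 1 / 6)
  yy <- apply_response_instrument(intended, cm, device = list(z = z))
  expect_lt(abs(mean(yy) - 0.70), 0.007)
})

test_that("prevalence is recovered for every design from honest simulated arms", {
  for (kind in c("DQ", "CM", "UQ", "FR")) {
    dat <- simulate_arm(kind, "prediction", 1e5, seed = 101)
    est <- estimate_prevalence(dat, default_designs()[[kind]], y)
    truth <- mean(dat$cheater)
    expect_lt(abs(est$pi_hat - truth), 3 * est$se)
  }
})

test_that("behavioral rates are recovered from observed-truth validation", {
  dat <- simulate_arm("DQ", "roll_a_six", 1e5, seed = 55,
                      behavior = behavior_model(0.6, 0.15),
                      cheat_propensity_rollsix = 0.1)
  v <- validate_observed_truth(dat, rrt_design("DQ"), response = y,
                               claim = claim, truth = won)
  expect_lt(abs(v$estimates["tpr"] - 0.6), 3 * v$se["tpr"])
  expect_lt(abs(v$estimates["fpr"] - 0.15), 3 * v$se["fpr"])
})

test_that("CM instrument confusion manufactures false positives", {
  honest <- simulate_arm("CM", "roll_a_six", 6e4, seed = 77)
  confused <- simulate_arm("CM", "roll_a_six", 6e4, seed = 77,
                           behavior = behavior_model(1, 0, p_instrument_confusion = 0.2))
  des <- default_designs()$CM
  v0 <- validate_observed_truth(honest, des, response = y, claim = claim, truth = won)
  v1 <- validate_observed_truth(confused, des, response = y, claim = claim, truth = won)
  expect_gt(v1$estimates["fpr"], 2 * v1$se["fpr"])    # strictly positive FPR
  expect_gt(v1$estimates["fpr"], v0$estimates["fpr"])
})

test_that("the A1-violation switch creates false losers only when enabled", {
  off <- simulate_survey(simulation_config(n = 2e4, game_split = 0, seed = 12,
                                           p_no_roll = 0, p_incomplete = 0,
                                           p_screener_fail = 0))
  expect_equal(sum(off$won == 1 & off$claim == 0), 0)
  on <- simulate_survey(simulation_config(n = 2e4, game_split = 0, seed = 12,
                                          p_no_roll = 0, p_incomplete = 0,
                                          p_screener_fail = 0,
                                          p_false_loser = 0.3))
  expect_gt(sum(on$won == 1 & on$claim == 0), 0)
})

test_that("simulation configuration round-trips through the key-value file", {
  cfg <- simulation_config(n = 1234, seed = 9,
                           behavior = behavior_model(0.4, 0.05, 0.1, 0.05))
  path <- withr::local_tempfile(fileext = ".yml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_identical(simulate_survey(cfg, seed = 1), simulate_survey(back, seed = 1))
})
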