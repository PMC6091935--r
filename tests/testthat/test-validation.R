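# Direct-counting oracle for observed-truth validation under DQ.
counting_oracle <- function(y, x, xstar) {
  cheat <- x != xstar
  tpr <- mean(y[cheat])
  fpr <- mean(y[!cheat])
  list(tpr = tpr, fpr = fpr,
       ccr = tpr * mean(cheat) + (1 - max(fpr, 0)) * mean(!cheat),
       cheat_rate = mean(cheat))
}

test_that("observed-truth validation matches direct counting on small DQ datasets", {
  dq <- rrt_design("DQ")
  # hand-constructed: 10 cheaters of whom 7 admit, 90 non-cheaters, none admit
  d <- tibble::tibble(
    y = rep(c(1L, 0L, 0L), c(7, 3, 90)),
    claim = rep(c(1L, 0L), c(10, 90)),
    won = 0L
  )
  v <- validate_observed_truth(d, dq, response = y, claim = claim, truth = won)
  expect_equal(unname(v$estimates["tpr"]), 0.7)
  expect_equal(unname(v$estimates["fpr"]), 0)
  expect_equal(unname(v$estimates["ccr"]), 0.97)
  expect_equal(unname(v$estimates["cheat_rate"]), 0.1)

  # randomized small datasets (<= 8 respondents) against the counting oracle
  set.seed(99)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    repeat {
      y <- rbinom(n, 1, 0.5); x <- rbinom(n, 1, 0.5); xs <- rbinom(n, 1, 0.3)
      if (any(x != xs) && any(x == xs)) break
    }
    d <- tibble::tibble(y = y, claim = x, won = xs)
    v <- validate_observed_truth(d, dq, response = y, claim = claim, truth = won)
    o <- counting_oracle(y, x, xs)
    expect_equal(unname(v$estimates["tpr"]), o$tpr)
    expect_equal(unname(v$estimates["fpr"]), o$fpr)
    expect_equal(unname(v$estimates["ccr"]), o$ccr)
    expect_equal(unname(v$estimates["cheat_rate"]), o$cheat_rate)
  }
})

test_that("all-honest data yields perfect classification", {
  d <- tibble::tibble(
    y = rep(c(1L, 0L), c(5, 45)),
    claim = rep(c(1L, 0L), c(5, 45)),
    won = 0L
  )
  v <- validate_observed_truth(d, rrt_design("DQ"), response = y,
                               claim = claim, truth = won)
  expect_equal(unname(v$estimates[c("tpr", "fpr", "ccr")]), c(1, 0, 1))
  expect_false(v$fpr_truncated)
})

test_that("observed-truth validation recovers a behavioral model under CM", {
  cm <- default_designs()$CM
  dat <- simulate_arm("CM", "roll_a_six", 1e5, seed = 21,
                      behavior = behavior_model(0.5, 0.1),
                      cheat_propensity_rollsix = 0.2)
  v <- validate_observed_truth(dat, cm, response = y, claim = claim, truth = won)
  expect_lt(abs(v$estimates["tpr"] - 0.5), 3 * v$se["tpr"])
  expect_lt(abs(v$estimates["fpr"] - 0.1), 3 * v$se["fpr"])
})

test_that("latent-truth identification reproduces the hand-evaluated formula", {
  # Pr(X=1) = 1/6 + 0.25, Pr(Y*=1|X=1) = 0.22, Pr(Y*=1|X=0) = 0.10 -> TPR = 0.30
  # exact counts under DQ: 1200 respondents, 500 claimants (110 admit), 700
  # non-claimants (70 admit); 500/1200 = 1/6 + 0.25
  d <- tibble::tibble(
    y = c(rep(c(1L, 0L), c(110, 390)), rep(c(1L, 0L), c(70, 630))),
    claim = rep(c(1L, 0L), c(500, 700))
  )
  v <- validate_latent_truth(d, rrt_design("DQ"), response = y, claim = claim)
  expect_equal(unname(v$estimates["tpr"]), 0.30, tolerance = 1e-12)
  expect_equal(unname(v$estimates["fpr"]), 0.10, tolerance = 1e-12)
  expect_equal(unname(v$estimates["cheat_rate"]), 0.25, tolerance = 1e-12)
  expect_equal(unname(v$estimates["ccr"]),
               0.30 * 0.25 + 0.90 * (700 / 1200 + 1 / 6), tolerance = 1e-12)
})

test_that("responses independent of the claim give TPR = FPR", {
  # same admission rate among claimants and non-claimants: numerator factorizes
  d <- tibble::tibble(
    y = c(rep(c(1L, 0L), c(60, 240)), rep(c(1L, 0L), c(120, 480))),
    claim = rep(c(1L, 0L), c(300, 600))
  )
  v <- validate_latent_truth(d, rrt_design("DQ"), response = y, claim = claim)
  expect_equal(unname(v$estimates["tpr"]), unname(v$estimates["fpr"]),
               tolerance = 1e-12)
  expect_equal(unname(v$estimates["fpr"]), 0.2, tolerance = 1e-12)
})

test_that("latent-truth estimates agree with observed truth when A1 + A2 hold", {
  for (kind in c("DQ", "CM")) {
    dat <- simulate_arm(kind, "prediction", 6e4, seed = 31,
                        behavior = behavior_model(0.3, 0.1),
                        cheat_propensity_prediction = 0.3)
    des <- default_designs()[[kind]]
    lat <- validate_latent_truth(dat, des, response = y, claim = claim)
    obs <- validate_observed_truth(dat, des, response = y, claim = claim, truth = won)
    for (m in c("tpr", "fpr", "ccr")) {
      se <- sqrt(lat$se[m]^2 + obs$se[m]^2)
      expect_lt(abs(lat$estimates[m] - obs$estimates[m]), 3 * se)
    }
  }
})

test_that("A2' never exceeds the A2 false positive rate and zeroes the winner term", {
  dat <- simulate_arm("CM", "prediction", 3e4, seed = 8,
                      behavior = behavior_model(0.3, 0.1))
  des <- default_designs()$CM
  a2 <- validate_latent_truth(dat, des, response = y, claim = claim)
  a2p <- validate_latent_truth(dat, des, response = y, claim = claim,
                               assumption = "A1_A2prime")
  expect_lte(a2p$estimates["fpr"], a2$estimates["fpr"])
  # explicit reweighting: FPR' = FPR * Pr(X=0) / (Pr(X=0) + 1/6)
  px0 <- mean(dat$claim == 0)
  expect_equal(unname(a2p$estimates["fpr"]),
               unname(a2$estimates["fpr"]) * px0 / (px0 + 1 / 6),
               tolerance = 1e-12)
})

test_that("latent-truth validation refuses unidentifiable cheating mass", {
  d <- tibble::tibble(y = rbinom(200, 1, 0.1), claim = rep(c(1L, 0L), c(20, 180)))
  expect_error(
    validate_latent_truth(d, rrt_design("DQ"), response = y, claim = claim),
    "No identifiable cheating mass"
  )
})

test_that("negative FPR is truncated only inside the CCR and flagged", {
  fr <- rrt_design("FR", p_yes = 1 / 6, p_no = 1 / 6)
  # non-cheaters answer below the forced-yes floor -> negative FPR
  d <- tibble::tibble(
    y = c(rep(c(1L, 0L), c(30, 20)), rep(c(1L, 0L), c(10, 140))),
    claim = rep(c(1L, 0L), c(50, 150)),
    won = 0L
  )
  v <- validate_observed_truth(d, fr, response = y, claim = claim, truth = won)
  expect_lt(v$estimates["fpr"], 0)
  expect_true(v$fpr_truncated)
  # CCR computed with FPR = 0
  expect_equal(unname(v$estimates["ccr"]),
               unname(v$estimates["tpr"]) * 0.25 + 1 * 0.75, tolerance = 1e-12)
  expect_true(v$estimates["ccr"] <= 1 && v$estimates["ccr"] >= 0)
})

test_that("analytic delta gradients match finite differences", {
  fd_jac <- function(f, m, eps = 1e-6) {
    vapply(seq_along(m), function(j) {
      hi <- m; lo <- m
      hi[j] <- hi[j] + eps; lo[j] <- lo[j] - eps
      (f(hi) - f(lo)) / (2 * eps)
    }, numeric(4))
  }
  mp <- list(p10 = 1 / 6, p11 = 5 / 6)
  delta <- mp$p11 - mp$p10
  cases <- list(
    function(m) rrtvalidate:::est_observed(m[1], m[2], m[3], mp$p10, delta),
    function(m) rrtvalidate:::est_latent(m[1], m[2], m[3], mp$p10, delta, 1 / 6),
    function(m) rrtvalidate:::est_latent(m[1], m[2], m[3], mp$p10, delta, 1 / 6,
                                         prime = TRUE)
  )
  m <- c(A = 0.42, B = 0.15, C = 0.12)
  for (fit_fun in cases) {
    fit <- fit_fun(m)
    num <- fd_jac(function(mm) fit_fun(mm)$est, m)
    expect_equal(unname(fit$jac), unname(num), tolerance = 1e-6)
  }
})

test_that("delta SE of a linear statistic equals its closed form", {
  set.seed(5)
  y <- rbinom(500, 1, 0.3)
  comp <- cbind(a = y)
  se <- delta_method_se(c(a = mean(y)), cov(comp) / length(y), matrix(1, 1, 1))
  expect_equal(unname(se), sqrt(mean(y) * (1 - mean(y)) / (length(y) - 1)))
})

test_that("bootstrap SEs are deterministic, vanish on constant data, and track delta", {
  dq <- rrt_design("DQ")
  # all admissions identical within groups -> zero variance in every metric
  d0 <- tibble::tibble(y = rep(c(1L, 0L), c(10, 40)),
                       claim = rep(c(1L, 0L), c(10, 40)), won = 0L)
  se0 <- bootstrap_se(d0, dq, response = y, claim = claim, truth = won,
                      B = 200, seed = 1)
  expect_equal(unname(se0[c("tpr", "fpr")]), c(0, 0))
  # determinism
  dat <- simulate_arm("CM", "prediction", 4000, seed = 3,
                      behavior = behavior_model(0.3, 0.1))
  des <- default_designs()$CM
  b1 <- bootstrap_se(dat, des, response = y, claim = claim, truth = NULL,
                     B = 300, seed = 11)
  b2 <- bootstrap_se(dat, des, response = y, claim = claim, truth = NULL,
                     B = 300, seed = 11)
  expect_identical(b1, b2)
  # agreement with the delta method on the same dataset
  vd <- validate_latent_truth(dat, des, response = y, claim = claim)
  vb <- validate_latent_truth(dat, des, response = y, claim = claim,
                              variance = "bootstrap", B = 1000, seed = 4)
  for (m in c("tpr", "fpr", "ccr", "cheat_rate")) {
    expect_lt(abs(vb$se[m] - vd$se[m]) / vd$se[m], 0.12)
  }
})

test_that("tidy and glance expose the validation result", {
  dat <- simulate_arm("DQ", "roll_a_six", 4000, seed = 13,
                      behavior = behavior_model(0.7, 0))
  v <- validate_observed_truth(dat, rrt_design("DQ"), response = y,
                               claim = claim, truth = won)
  td <- tidy(v)
  expect_equal(td$metric, c("tpr", "fpr", "ccr", "cheat_rate"))
  expect_true(all(td$ci_low <= td$estimate & td$estimate <= td$ci_high))
  g <- glance(v)
  expect_equal(g$assumption, "observed_truth")
  expect_equal(g$n, nrow(dat))
})
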