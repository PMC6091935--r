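# Shared fixtures: example designs, forward-mixture oracle, fast single-arm
# survey configurations.

fixture_designs <- function() {
  list(
    DQ = rrt_design("DQ"),
    CM = rrt_design("CM", p_z = 1 / 6),
    UQ = rrt_design("UQ", p_u = 0.25, p_z = 0.5),
    FR = rrt_design("FR", p_yes = 1 / 6, p_no = 1 / 6)
  )
}

# Forward misclassification mixture: Pr(Y = 1) for a given true prevalence.
forward_mixture <- function(design, pi) {
  mp <- misclassification_probs(design)
  mp$p11 * pi + mp$p10 * (1 - pi)
}

# Single-game, single-technique survey configuration without attrition.
arm_config <- function(kind, game, n, behavior = behavior_model(), ...) {
  probs <- c(DQ = 0, CM = 0, UQ = 0, FR = 0)
  probs[kind] <- 1
  simulation_config(
    n = n, game_split = if (game == "prediction") 1 else 0,
    arm_probs = probs, behavior = behavior,
    p_incomplete = 0, p_screener_fail = 0, p_no_roll = 0, ...
  )
}

# Simulated arm with the analysis-polarity cheating response attached.
simulate_arm <- function(kind, game, n, seed, behavior = behavior_model(), ...) {
  dat <- simulate_survey(arm_config(kind, game, n, behavior, ...), seed = seed)
  dat$y <- 1L - dat$resp_cheating
  dat
}
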