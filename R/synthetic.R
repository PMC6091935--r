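# Synthetic dice-game survey generator.
#
# Emulates the statistical structure of the validation survey: random
# assignment to one of two dice games and one of four question techniques,
# uniform die rolls, cheating propensities among losers, per-technique
# randomizing devices (birthday questions, Benford digits, forced-response
# fields) and a four-label response-behavior model (honest / liar /
# confused / self-protective).
#
# Randomness discipline: one master seed; each respondent consumes a fixed
# block of uniforms from a single stream (a row of an n x K matrix), so
# changing allocation probabilities or behavior parameters reinterprets a
# respondent's own draws without reshuffling anyone else's.

#' Response-behavior model for one technique arm
#'
#' Describes how respondents in a technique arm answer the sensitive
#' question. Two intent parameters set the behavioral true/false positive
#' rates, and two instrument parameters set non-compliance:
#'
#' @param p_truthful_cheater Probability that a respondent with the
#'   sensitive trait (a cheater) intends the truthful "yes" answer — the
#'   behavioral TPR*.
#' @param p_false_admit_noncheater Probability that a respondent without
#'   the trait intends a (false) "yes" — the behavioral FPR*.
#' @param p_instrument_confusion Probability that the final response
#'   ignores the instrument and is drawn uniformly from the response
#'   options (the crosswise-model confusion mechanism).
#' @param p_self_protective Probability of always emitting the design's
#'   self-protective response: "no" for DQ/UQ/FR; uniform for CM, which has
#'   no unambiguously safe option.
#' @return An object of class `rrt_behavior`.
#' @export
behavior_model <- function(p_truthful_cheater = 1, p_false_admit_noncheater = 0,
                           p_instrument_confusion = 0, p_self_protective = 0) {
  probs <- c(p_truthful_cheater, p_false_admit_noncheater,
             p_instrument_confusion, p_self_protective)
  if (any(probs < 0 | probs > 1)) abort("Behavior parameters must be probabilities.")
  if (p_instrument_confusion + p_self_protective > 1) {
    abort("`p_instrument_confusion` + `p_self_protective` must be <= 1.")
  }
  structure(
    list(p_truthful_cheater = p_truthful_cheater,
         p_false_admit_noncheater = p_false_admit_noncheater,
         p_instrument_confusion = p_instrument_confusion,
         p_self_protective = p_self_protective),
    class = "rrt_behavior"
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic survey. Defaults reproduce the
#' study conditions: arm allocation 1/8 DQ, 3/8 CM, 2/8 UQ, 2/8 FR; both
#' dice games with win probability 1/6; cheat propensity among losers 0.3
#' in the prediction game (overall cheating rate about 25%) and 0.06 in the
#' roll-a-six game (about 5%); recruitment attrition matching the reported
#' sample accounting (completion, screener and die-roll recording rates);
#' no false losers. The default behavior model is fully honest and
#' compliant — deviations are opt-in per technique.
#'
#' @param n Number of recruited respondents.
#' @param game_split Probability of assignment to the prediction game
#'   (the remainder play roll-a-six).
#' @param arm_probs Named allocation probabilities for `DQ`, `CM`, `UQ`,
#'   `FR`; must sum to 1.
#' @param win_prob Probability of a true win in either game (1/6).
#' @param cheat_propensity_prediction,cheat_propensity_rollsix Probability
#'   that a losing respondent claims a win, per game.
#' @param behavior A single [behavior_model()] applied to all techniques,
#'   or a named list with one model per technique.
#' @param designs Design catalogue as from [default_designs()].
#' @param item_prevalence Named true prevalences of the additional
#'   sensitive items carried through the comparative analysis. `NULL`
#'   drops them.
#' @param p_incomplete,p_screener_fail,p_no_roll Attrition probabilities:
#'   not completing the sensitive part, failing the screener, and having no
#'   recorded die roll.
#' @param p_false_loser Probability that a true winner fails to claim the
#'   bonus (an A1 violation; default 0).
#' @param seed Default master seed used by [simulate_survey()].
#' @return An object of class `rrt_sim_config`.
#' @export
simulation_config <- function(n = 6505,
                              game_split = 0.5,
                              arm_probs = c(DQ = 1 / 8, CM = 3 / 8, UQ = 2 / 8, FR = 2 / 8),
                              win_prob = 1 / 6,
                              cheat_propensity_prediction = 0.3,
                              cheat_propensity_rollsix = 0.06,
                              behavior = behavior_model(),
                              designs = default_designs(),
                              item_prevalence = c(shoplifting = 0.4,
                                                  tax_evasion = 0.25,
                                                  non_voting = 0.4),
                              p_incomplete = 32 / 6505,
                              p_screener_fail = 205 / 6473,
                              p_no_roll = 115 / 6268,
                              p_false_loser = 0,
                              seed = NULL) {
  if (n < 1) abort("`n` must be positive.")
  if (!setequal(names(arm_probs), c("DQ", "CM", "UQ", "FR"))) {
    abort("`arm_probs` must be named DQ, CM, UQ, FR.")
  }
  if (abs(sum(arm_probs) - 1) > 1e-9) abort("`arm_probs` must sum to 1.")
  probs <- c(game_split, win_prob, cheat_propensity_prediction,
             cheat_propensity_rollsix, p_incomplete, p_screener_fail,
             p_no_roll, p_false_loser)
  if (any(probs < 0 | probs > 1)) abort("All rates must be probabilities in [0, 1].")
  if (inherits(behavior, "rrt_behavior")) {
    behavior <- list(DQ = behavior, CM = behavior, UQ = behavior, FR = behavior)
  }
  if (!all(c("DQ", "CM", "UQ", "FR") %in% names(behavior)) ||
      !all(vapply(behavior, inherits, logical(1), "rrt_behavior"))) {
    abort("`behavior` must be a behavior_model() or a named list of them per technique.")
  }
  if (!all(c("DQ", "CM", "UQ", "FR") %in% names(designs))) {
    abort("`designs` must contain DQ, CM, UQ and FR designs.")
  }
  if (!is.null(item_prevalence)) {
    if (is.null(names(item_prevalence)) || any(item_prevalence < 0 | item_prevalence > 1)) {
      abort("`item_prevalence` must be a named vector of probabilities.")
    }
  }
  structure(
    list(n = as.integer(n), game_split = game_split,
         arm_probs = arm_probs[c("DQ", "CM", "UQ", "FR")],
         win_prob = win_prob,
         cheat_propensity_prediction = cheat_propensity_prediction,
         cheat_propensity_rollsix = cheat_propensity_rollsix,
         behavior = behavior, designs = designs,
         item_prevalence = item_prevalence,
         p_incomplete = p_incomplete, p_screener_fail = p_screener_fail,
         p_no_roll = p_no_roll, p_false_loser = p_false_loser, seed = seed),
    class = "rrt_sim_config"
  )
}

#' Draw Benford-distributed first digits
#'
#' Samples digits 1..9 with probability \eqn{\log_{10}(1 + 1/d)} by
#' inverse-CDF lookup — the distribution of first significant digits of
#' house numbers used as the unrelated-question RRT randomizing device.
#'
#' @param n Number of draws.
#' @return Integer vector of digits in 1..9.
#' @examples
#' set.seed(1); table(sample_benford_digit(1000))
#' @export
sample_benford_digit <- function(n) {
  benford_from_u(runif(n))
}

benford_from_u <- function(u) {
  findInterval(u, cumsum(benford_pmf())) + 1L
}

#' Apply a question technique's response instrument
#'
#' Maps a respondent's intended answer to the sensitive question onto the
#' observed response, given the technique design, the randomizing-device
#' outcome and the behavior label:
#'
#' * compliant respondents (`"honest"` or `"liar"` — lying is encoded in
#'   the intended answer): DQ reports the intended answer; CM reports
#'   "the same" (1) iff the intended answer equals the unrelated-question
#'   truth `z`; UQ reports the intended answer when routed to the
#'   sensitive question, else `z`; FR follows a forced "yes"/"no"
#'   instruction or answers the question;
#' * `"confused"` respondents answer uniformly at random;
#' * `"self_protective"` respondents answer "no" (DQ/UQ/FR) or uniformly
#'   at random (CM, which offers no safe option).
#'
#' @param intended Binary vector of intended answers (1 = sensitive "yes").
#' @param design An [rrt_design()].
#' @param device List of device outcomes: `z` (0/1 unrelated-question
#'   truth; CM and UQ), `routed_sensitive` (logical; UQ), `instruction`
#'   (`"answer"`, `"yes"`, `"no"`; FR). Unused for DQ.
#' @param behavior Character vector of labels (`"honest"`, `"liar"`,
#'   `"confused"`, `"self_protective"`); recycled if length 1.
#' @param u Uniform draws powering the random-response labels; defaults to
#'   fresh `runif()` draws.
#' @return Integer vector of observed responses (1 = "yes" / "the same").
#' @examples
#' apply_response_instrument(c(1, 0), rrt_design("CM", p_z = 1/6),
#'   device = list(z = c(1, 1)), behavior = "honest")
#' @export
apply_response_instrument <- function(intended, design, device = list(),
                                      behavior = "honest", u = NULL) {
  n <- length(intended)
  if (!all(intended %in% c(0, 1))) abort("`intended` must be binary.")
  behavior <- rep_len(behavior, n)
  bad <- setdiff(unique(behavior), c("honest", "liar", "confused", "self_protective"))
  if (length(bad)) abort(sprintf("Unknown behavior label(s): %s.", paste(bad, collapse = ", ")))
  if (is.null(u)) u <- runif(n)
  need <- function(field) {
    v <- device[[field]]
    if (is.null(v) || length(v) %not_in_len% n) {
      abort(sprintf("Device outcome `%s` (length %d) required for %s.",
                    field, n, design$kind))
    }
    v
  }
  compliant <- switch(design$kind,
    DQ = intended,
    CM = as.integer(intended == need("z")),
    UQ = {
      routed <- need("routed_sensitive")
      ifelse(routed, intended, need("z"))
    },
    FR = {
      instr <- need("instruction")
      bad_i <- setdiff(unique(instr), c("answer", "yes", "no"))
      if (length(bad_i)) abort("FR instructions must be 'answer', 'yes' or 'no'.")
      ifelse(instr == "yes", 1L, ifelse(instr == "no", 0L, intended))
    }
  )
  uniform <- as.integer(u < 0.5)
  safe <- if (design$kind == "CM") uniform else 0L
  out <- as.integer(compliant)
  out[behavior == "confused"] <- uniform[behavior == "confused"]
  out[behavior == "self_protective"] <-
    rep_len(safe, n)[behavior == "self_protective"]
  out
}

`%not_in_len%` <- function(len, n) !(len %in% c(1L, n))

# Draw unrelated-question truths for a technique: pick a catalogued question
# uniformly per respondent (u_pair) and evaluate its birthday truth (u_z).
draw_unrelated <- function(design, u_pair, u_z) {
  qs <- design$unrelated_question
  if (is.null(qs)) {
    list(question = rep(NA_character_, length(u_z)),
         z = as.integer(u_z < design$p_z))
  } else {
    pz <- theoretical_pz(qs)
    idx <- pmin(floor(u_pair * length(qs)) + 1L, length(qs))
    list(question = qs[idx], z = as.integer(u_z < pz[idx]))
  }
}

# Per-respondent uniform block layout (columns of the stream matrix).
.stream_cols <- c("complete", "screener", "roll", "game", "die", "cheat",
                  "false_loser", "arm", "behavior", "intent", "pair",
                  "device", "z2", "resp")
.item_cols <- c("true", "intent", "pair", "z", "resp")

#' Simulate a dice-game validation survey
#'
#' Generates one row per recruited respondent following the study's
#' data-generating sequence: game assignment, uniform die roll, win/lose,
#' cheat decision among losers, technique assignment, randomizing-device
#' outcome, behavior draw, observed response. Attrition flags (`completed`,
#' `screener_passed`, `roll_recorded`) are generated so that
#' [apply_exclusions()] reproduces the survey's sample accounting.
#'
#' Observed item responses are emitted in survey polarity, i.e. as answers
#' to the questionnaire wording: `resp_cheating` is the answer to "did you
#' honestly report?" and `resp_non_voting` to "did you vote?", so both are
#' reverse-coded relative to the sensitive trait and must pass through
#' [recode_items()] before estimation. Truth columns (`cheater`,
#' `true_*`) are in sensitive polarity (1 = trait present).
#'
#' Identical seeds yield bit-identical tables; each respondent owns a fixed
#' block of the uniform stream, so parameter changes never reshuffle other
#' respondents' draws.
#'
#' @param config An [simulation_config()] object.
#' @param seed Master seed; defaults to `config$seed`.
#' @return A tibble of respondent records.
#' @examples
#' dat <- simulate_survey(simulation_config(n = 500, seed = 1))
#' dplyr::count(dat, game, technique)
#' @export
simulate_survey <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "rrt_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  items <- names(config$item_prevalence)
  k_core <- length(.stream_cols)
  k <- k_core + length(items) * length(.item_cols)
  # Row-major fill: respondent i consumes uniforms (i-1)*k + 1 .. i*k.
  u <- matrix(runif(n * k), nrow = n, byrow = TRUE)
  colnames(u) <- c(.stream_cols,
                   if (length(items)) as.vector(t(outer(items, .item_cols, paste, sep = "."))))

  completed <- u[, "complete"] >= config$p_incomplete
  screener_passed <- u[, "screener"] >= config$p_screener_fail
  roll_recorded <- u[, "roll"] >= config$p_no_roll
  game <- ifelse(u[, "game"] < config$game_split, "prediction", "roll_a_six")
  die <- as.integer(ceiling(u[, "die"] * 6))
  won <- as.integer(die == 6)  # a 1/6 event in both games
  propensity <- ifelse(game == "prediction",
                       config$cheat_propensity_prediction,
                       config$cheat_propensity_rollsix)
  claim <- as.integer(won == 1 | u[, "cheat"] < propensity)
  false_loser <- won == 1 & u[, "false_loser"] < config$p_false_loser
  claim[false_loser] <- 0L
  cheater <- as.integer(claim != won)

  technique <- c("DQ", "CM", "UQ", "FR")[
    findInterval(u[, "arm"], cumsum(config$arm_probs), left.open = TRUE) + 1L]

  beh_par <- function(field) {
    vapply(config$behavior, `[[`, numeric(1), field)[technique]
  }
  p_conf <- beh_par("p_instrument_confusion")
  p_sp <- beh_par("p_self_protective")
  behavior <- ifelse(u[, "behavior"] < p_conf, "confused",
                     ifelse(u[, "behavior"] < p_conf + p_sp, "self_protective",
                            "compliant"))

  intend_for <- function(truth, u_int) {
    p_yes <- ifelse(truth == 1, beh_par("p_truthful_cheater"),
                    beh_par("p_false_admit_noncheater"))
    as.integer(u_int < p_yes)
  }

  # Shared device outcomes: the UQ digit (an acquaintance's house number)
  # and the FR field are chosen once per respondent and reused across items;
  # CM draws a fresh unrelated question per item.
  is_cm <- technique == "CM"; is_uq <- technique == "UQ"; is_fr <- technique == "FR"
  benford_digit <- ifelse(is_uq, benford_from_u(u[, "device"]), NA_integer_)
  p_u <- config$designs$UQ$p_u
  routed_sensitive <- is_uq & u[, "device"] < (1 - p_u)
  p_yes_fr <- config$designs$FR$p_yes
  p_no_fr <- config$designs$FR$p_no
  fr_field <- ifelse(is_fr, as.integer(ceiling(u[, "device"] * 12)), NA_integer_)
  fr_instruction <- ifelse(!is_fr, NA_character_,
                           ifelse(u[, "device"] < p_yes_fr, "yes",
                                  ifelse(u[, "device"] < p_yes_fr + p_no_fr, "no",
                                         "answer")))

  observe_item <- function(truth, u_int, u_pair, u_z, u_resp) {
    intended <- intend_for(truth, u_int)
    y <- integer(n)
    label <- ifelse(behavior == "compliant",
                    ifelse(intended == truth, "honest", "liar"), behavior)
    for (kind in c("DQ", "CM", "UQ", "FR")) {
      sel <- technique == kind
      if (!any(sel)) next
      des <- config$designs[[kind]]
      device <- switch(kind,
        DQ = list(),
        CM = list(z = draw_unrelated(des, u_pair[sel], u_z[sel])$z),
        UQ = list(routed_sensitive = routed_sensitive[sel],
                  z = draw_unrelated(des, u_pair[sel], u_z[sel])$z),
        FR = list(instruction = fr_instruction[sel])
      )
      y[sel] <- apply_response_instrument(intended[sel], des, device,
                                          label[sel], u = u_resp[sel])
    }
    list(y = y, label = label)
  }

  cheat_item <- observe_item(cheater, u[, "intent"], u[, "pair"], u[, "z2"],
                             u[, "resp"])
  # Record the cheating item's unrelated-question draw for CM respondents.
  cm_draw <- draw_unrelated(config$designs$CM, u[, "pair"], u[, "z2"])

  out <- tibble::tibble(
    id = seq_len(n),
    completed = completed,
    screener_passed = screener_passed,
    roll_recorded = roll_recorded,
    game = game,
    technique = technique,
    die = ifelse(roll_recorded, die, NA_integer_),
    won = ifelse(roll_recorded, won, NA_integer_),
    claim = ifelse(roll_recorded, claim, NA_integer_),
    cheater = ifelse(roll_recorded, cheater, NA_integer_),
    benford_digit = benford_digit,
    uq_routed = ifelse(is_uq, routed_sensitive, NA),
    fr_field = fr_field,
    fr_instruction = fr_instruction,
    cm_question = ifelse(is_cm, cm_draw$question, NA_character_),
    cm_z = ifelse(is_cm, cm_draw$z, NA_integer_),
    behavior = cheat_item$label,
    resp_cheating = ifelse(completed, 1L - cheat_item$y, NA_integer_)
  )

  for (it in items) {
    truth <- as.integer(u[, paste0(it, ".true")] < config$item_prevalence[[it]])
    obs <- observe_item(truth, u[, paste0(it, ".intent")],
                        u[, paste0(it, ".pair")], u[, paste0(it, ".z")],
                        u[, paste0(it, ".resp")])
    y <- obs$y
    # Survey polarity: the non-voting question asks "did you vote?".
    resp <- if (it == "non_voting") 1L - y else y
    out[[paste0("true_", it)]] <- truth
    out[[paste0("resp_", it)]] <- ifelse(completed, resp, NA_integer_)
  }
  out
}
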