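# Three-stage analysis pipeline: exclusions and recoding, comparative
# analysis, aggregate-level validation, individual-level validation.

#' Apply sample exclusion rules
#'
#' Restricts a raw respondent table to analyzable records, attributing each
#' removal to the first rule it fails, in the study's order: keep only
#' respondents who completed the sensitive part, then remove screener
#' failures, then respondents without a recorded die roll, then false
#' losers (roll-a-six winners who did not claim the bonus — excluded to
#' keep assumption A1 clean). The returned tibble carries an
#' `exclusion_ledger` attribute whose counts conserve the total.
#'
#' @param data Raw respondent table with logical columns `completed`,
#'   `screener_passed`, `roll_recorded` and (for the false-loser rule)
#'   `game`, `won`, `claim`.
#' @param rules Character subset of
#'   `c("screener", "no_roll", "false_loser")`; the empty set keeps all
#'   completed records.
#' @return The filtered tibble, with attribute `exclusion_ledger`; see
#'   [exclusion_ledger()].
#' @examples
#' dat <- simulate_survey(simulation_config(n = 1000, seed = 1))
#' kept <- apply_exclusions(dat)
#' exclusion_ledger(kept)
#' @export
apply_exclusions <- function(data,
                             rules = c("screener", "no_roll", "false_loser")) {
  if (length(rules)) {
    rules <- match.arg(rules, c("screener", "no_roll", "false_loser"),
                       several.ok = TRUE)
  }
  needed <- c("completed", "screener_passed", "roll_recorded")
  if ("false_loser" %in% rules) needed <- c(needed, "game", "won", "claim")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    abort(sprintf("Missing required column(s): %s.", paste(missing, collapse = ", ")))
  }
  total <- nrow(data)
  d <- dplyr::filter(data, .data$completed)
  completed_n <- nrow(d)
  removed <- c(screener = 0L, no_roll = 0L, false_loser = 0L)
  for (r in c("screener", "no_roll", "false_loser")) {
    if (!r %in% rules) next
    fails <- switch(r,
      screener = !d$screener_passed,
      no_roll = !d$roll_recorded,
      false_loser = d$game == "roll_a_six" & !is.na(d$won) & !is.na(d$claim) &
        d$won == 1 & d$claim == 0
    )
    removed[[r]] <- sum(fails)
    d <- d[!fails, , drop = FALSE]
  }
  ledger <- tibble::tibble(
    total_recruited = total,
    completed_sensitive_part = completed_n,
    removed_screener = removed[["screener"]],
    removed_no_roll = removed[["no_roll"]],
    removed_false_loser = removed[["false_loser"]],
    final_n = nrow(d)
  )
  stopifnot(ledger$completed_sensitive_part - sum(removed) == ledger$final_n)
  attr(d, "exclusion_ledger") <- ledger
  d
}

#' Retrieve the exclusion ledger of a filtered table
#'
#' @param data A tibble returned by [apply_exclusions()].
#' @return A one-row tibble of exclusion counts.
#' @export
exclusion_ledger <- function(data) {
  ledger <- attr(data, "exclusion_ledger")
  if (is.null(ledger)) abort("`data` carries no exclusion ledger; run apply_exclusions().")
  ledger
}

#' Recode reverse-coded items to sensitive polarity
#'
#' Flips the observed responses of items whose questionnaire wording is
#' reversed relative to the sensitive trait (by default the non-voting item,
#' "did you vote?", and the dice-game honesty item, "did you honestly
#' report?"), so that 1 always means the sensitive answer. Applying the
#' function twice restores the input (involution).
#'
#' @param data Respondent table.
#' @param reverse Character vector of response columns to flip.
#' @return `data` with the named columns flipped (`NA`s preserved).
#' @export
recode_items <- function(data, reverse = c("resp_non_voting", "resp_cheating")) {
  missing <- setdiff(reverse, names(data))
  if (length(missing)) {
    abort(sprintf("Unknown item column(s): %s.", paste(missing, collapse = ", ")))
  }
  for (col in reverse) data[[col]] <- 1L - data[[col]]
  data
}

detect_items <- function(data) {
  cols <- grep("^resp_", names(data), value = TRUE)
  setNames(cols, sub("^resp_", "", cols))
}

new_analysis_table <- function(tbl, stage) {
  structure(tbl, class = c("rrt_analysis", class(tbl)), stage = stage)
}

arm_designs <- function(data, designs) {
  kinds <- intersect(c("DQ", "CM", "UQ", "FR"), unique(data$technique))
  if (!length(kinds)) abort("No recognised technique arms in `data`.")
  designs[kinds]
}

#' Comparative analysis: prevalence per technique and differences vs DQ
#'
#' Estimates the prevalence of every sensitive item under every technique
#' arm present in the data, and — when a DQ arm exists alongside at least
#' one indirect arm — the difference of each indirect technique against
#' direct questioning with a two-sided Wald z-test (the more-is-better
#' comparison: for an underreported trait, a valid indirect technique
#' should estimate more).
#'
#' `data` must already be recoded so 1 = sensitive answer (see
#' [recode_items()]).
#'
#' @param data Respondent table with a `technique` column and `resp_*`
#'   item columns.
#' @param designs Named design catalogue (see [default_designs()]).
#' @param items Named character vector mapping item labels to response
#'   columns; defaults to all `resp_*` columns.
#' @param conf_level Confidence level for Wald intervals.
#' @return An analysis tibble (`item`, `technique`, `game`, `metric`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `n`, `p_value`).
#' @export
comparative_analysis <- function(data, designs = default_designs(),
                                 items = NULL, conf_level = 0.95) {
  items <- items %||% detect_items(data)
  designs <- arm_designs(data, designs)
  rows <- purrr::map_dfr(names(items), function(item) {
    col <- items[[item]]
    ests <- purrr::map(names(designs), function(kind) {
      arm <- data[data$technique == kind, , drop = FALSE]
      estimate_prevalence(arm, designs[[kind]], .data[[col]],
                          conf_level = conf_level, item = item)
    })
    names(ests) <- names(designs)
    prev <- purrr::map_dfr(names(ests), function(kind) {
      e <- ests[[kind]]
      tibble::tibble(item = item, technique = kind, game = "all",
                     metric = "prevalence", estimate = e$pi_hat, se = e$se,
                     ci_low = e$ci_low, ci_high = e$ci_high, n = e$n,
                     p_value = NA_real_)
    })
    diffs <- NULL
    if ("DQ" %in% names(ests) && length(ests) > 1L) {
      diffs <- purrr::map_dfr(setdiff(names(ests), "DQ"), function(kind) {
        d <- arm_difference(ests[[kind]], ests$DQ, conf_level)
        tibble::tibble(item = item, technique = kind, game = "all",
                       metric = "difference_vs_DQ", estimate = d$pi_hat,
                       se = d$se, ci_low = d$ci_low, ci_high = d$ci_high,
                       n = d$n, p_value = d$p_value)
      })
    }
    dplyr::bind_rows(prev, diffs)
  })
  new_analysis_table(rows, "comparative")
}

true_cheat_rate <- function(data, game, win_prob, conf_level) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  d <- data[data$game == game, , drop = FALSE]
  n <- nrow(d)
  if (n < 2L) abort(sprintf("Too few records in game `%s`.", game))
  if (game == "roll_a_six") {
    if (anyNA(d$won)) abort("`won` must be complete for the roll-a-six game.")
    p <- mean(d$claim == 1 & d$won == 0)
    se <- sqrt(p * (1 - p) / (n - 1))
  } else {
    cl <- mean(d$claim)
    p <- cl - win_prob
    se <- sqrt(cl * (1 - cl) / (n - 1))
  }
  tibble::tibble(estimate = p, se = se,
                 ci_low = p - z * se, ci_high = p + z * se, n = n)
}

#' Aggregate-level validation: estimates against true cheating rates
#'
#' Computes the true cheating rate of each dice game — by direct count of
#' false winners in the roll-a-six game, and as
#' \eqn{\widehat{\Pr}(X = 1) - 1/6} in the prediction game — and the bias
#' of every technique's cheating-prevalence estimate against it
#' (estimate minus true rate, with propagated Wald interval).
#'
#' @inheritParams comparative_analysis
#' @param cheating_col Recoded cheating-item response column.
#' @param win_prob Design win probability (1/6).
#' @return An analysis tibble with metrics `true_rate`, `prevalence` and
#'   `bias` per game (technique `"all"` for true rates).
#' @export
aggregate_validation <- function(data, designs = default_designs(),
                                 cheating_col = "resp_cheating",
                                 win_prob = 1 / 6, conf_level = 0.95) {
  if (!all(c("game", "claim") %in% names(data))) {
    abort("`data` must carry `game` and `claim` columns.")
  }
  designs <- arm_designs(data, designs)
  z <- qnorm(1 - (1 - conf_level) / 2)
  rows <- purrr::map_dfr(unique(data$game), function(g) {
    truth <- true_cheat_rate(data, g, win_prob, conf_level)
    truth_row <- tibble::tibble(
      item = "cheating", technique = "all", game = g, metric = "true_rate",
      estimate = truth$estimate, se = truth$se, ci_low = truth$ci_low,
      ci_high = truth$ci_high, n = truth$n, p_value = NA_real_)
    per_tech <- purrr::map_dfr(names(designs), function(kind) {
      arm <- data[data$technique == kind & data$game == g, , drop = FALSE]
      e <- estimate_prevalence(arm, designs[[kind]], .data[[cheating_col]],
                               conf_level = conf_level, item = "cheating")
      bias <- e$pi_hat - truth$estimate
      bias_se <- sqrt(e$se^2 + truth$se^2)
      dplyr::bind_rows(
        tibble::tibble(item = "cheating", technique = kind, game = g,
                       metric = "prevalence", estimate = e$pi_hat, se = e$se,
                       ci_low = e$ci_low, ci_high = e$ci_high, n = e$n,
                       p_value = NA_real_),
        tibble::tibble(item = "cheating", technique = kind, game = g,
                       metric = "bias", estimate = bias, se = bias_se,
                       ci_low = bias - z * bias_se, ci_high = bias + z * bias_se,
                       n = e$n,
                       p_value = 2 * pnorm(-abs(bias / bias_se)))
      )
    })
    dplyr::bind_rows(truth_row, per_tech)
  })
  new_analysis_table(rows, "aggregate")
}

#' Individual-level validation: TPR, FPR and CCR per technique and game
#'
#' Routes each game to the appropriate identification strategy —
#' [validate_observed_truth()] for the roll-a-six game (recorded rolls) and
#' [validate_latent_truth()] for the prediction game (assumptions A1 + A2
#' or A1 + A2') — and returns true positive, false positive, correct
#' classification and cheat rates per technique with standard errors and
#' FPR truncation flags.
#'
#' @inheritParams aggregate_validation
#' @param assumption Latent-truth assumption set for the prediction game.
#' @param variance `"delta"` or `"bootstrap"`.
#' @param ... Passed to the validation functions (`B`, `seed`).
#' @return An analysis tibble with metrics `tpr`, `fpr`, `ccr`,
#'   `cheat_rate` and a `fpr_truncated` column.
#' @export
individual_validation <- function(data, designs = default_designs(),
                                  cheating_col = "resp_cheating",
                                  assumption = c("A1_A2", "A1_A2prime"),
                                  variance = c("delta", "bootstrap"),
                                  win_prob = 1 / 6, conf_level = 0.95, ...) {
  assumption <- match.arg(assumption)
  variance <- match.arg(variance)
  designs <- arm_designs(data, designs)
  rows <- purrr::map_dfr(unique(data$game), function(g) {
    purrr::map_dfr(names(designs), function(kind) {
      arm <- data[data$technique == kind & data$game == g, , drop = FALSE]
      v <- if (g == "roll_a_six") {
        validate_observed_truth(arm, designs[[kind]],
                                response = .data[[cheating_col]],
                                claim = claim, truth = won,
                                variance = variance, conf_level = conf_level,
                                win_prob = win_prob, ...)
      } else {
        validate_latent_truth(arm, designs[[kind]],
                              response = .data[[cheating_col]],
                              claim = claim, assumption = assumption,
                              variance = variance, conf_level = conf_level,
                              win_prob = win_prob, ...)
      }
      td <- tidy(v)
      tibble::tibble(item = "cheating", technique = kind, game = g,
                     metric = td$metric, estimate = td$estimate, se = td$se,
                     ci_low = td$ci_low, ci_high = td$ci_high, n = v$n,
                     p_value = NA_real_,
                     assumption = v$assumption,
                     fpr_truncated = v$fpr_truncated)
    })
  })
  new_analysis_table(rows, "individual")
}

#' Run the full three-stage analysis
#'
#' Applies the sample exclusions and item recoding, then produces the
#' comparative, aggregate-level and individual-level analysis tables from
#' a raw respondent table (real or synthetic).
#'
#' @param data Raw respondent table (survey polarity), e.g. from
#'   [simulate_survey()] or [read_survey_csv()].
#' @inheritParams individual_validation
#' @param reverse Reverse-coded response columns passed to [recode_items()].
#' @return A list of class `rrt_results`: `comparative`, `aggregate`,
#'   `individual` analysis tibbles plus the exclusion `ledger`.
#' @examples
#' dat <- simulate_survey(simulation_config(n = 3000, seed = 42))
#' res <- run_analysis(dat)
#' res$ledger
#' @export
run_analysis <- function(data, designs = default_designs(),
                         assumption = "A1_A2",
                         reverse = c("resp_non_voting", "resp_cheating"),
                         win_prob = 1 / 6, conf_level = 0.95, ...) {
  kept <- apply_exclusions(data)
  ledger <- exclusion_ledger(kept)
  rec <- recode_items(kept, reverse = intersect(reverse, names(kept)))
  structure(
    list(
      comparative = comparative_analysis(rec, designs, conf_level = conf_level),
      aggregate = aggregate_validation(rec, designs, win_prob = win_prob,
                                       conf_level = conf_level),
      individual = individual_validation(rec, designs, assumption = assumption,
                                         win_prob = win_prob,
                                         conf_level = conf_level, ...),
      ledger = ledger
    ),
    class = "rrt_results"
  )
}

#' @export
print.rrt_results <- function(x, ...) {
  cat("<rrt_results>\n\nExclusion ledger:\n")
  print(x$ledger)
  cat("\nIndividual-level validation:\n")
  print(tibble::as_tibble(x$individual), n = 32)
  invisible(x)
}
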