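# Question-technique designs and their misclassification parameters.

#' Construct a sensitive-question technique design
#'
#' A design describes one of the four questioning techniques used to ask a
#' sensitive yes/no question and carries the randomizer parameters that
#' determine how the observed response relates to the true answer:
#'
#' * `"DQ"` — direct questioning; no randomizer, no misclassification.
#' * `"CM"` — crosswise model: the respondent reports whether their answers to
#'   the sensitive question and an unrelated question (with known
#'   "yes"-probability `p_z`) are the same or different.
#' * `"UQ"` — unrelated-question RRT: a private random digit routes the
#'   respondent to the sensitive question (probability `1 - p_u`) or to an
#'   unrelated question with "yes"-probability `p_z`.
#' * `"FR"` — forced-response RRT: with probability `p_yes` (`p_no`) the
#'   respondent is instructed to answer "yes" ("no") unconditionally,
#'   otherwise to answer the sensitive question.
#'
#' Only the fields relevant to `kind` may be supplied. Identifiability
#' requires `p_z != 1/2` for CM, `p_u < 1` for UQ, and `p_yes + p_no < 1`
#' for FR.
#'
#' @param kind One of `"DQ"`, `"CM"`, `"UQ"`, `"FR"`.
#' @param p_z Probability in (0, 1) that the answer to the unrelated
#'   non-sensitive question is "yes" (CM, UQ).
#' @param p_u Probability in (0, 1) that a UQ respondent is routed to the
#'   unrelated question instead of the sensitive one.
#' @param p_yes,p_no Probabilities of a forced unconditional "yes" / "no"
#'   answer (FR).
#' @param unrelated_question Optional identifier (or vector of identifiers)
#'   of the catalogued unrelated question(s); see [theoretical_pz()].
#'
#' @return An object of class `rrt_design`.
#' @seealso [misclassification_probs()], [default_designs()]
#' @examples
#' rrt_design("CM", p_z = 1/6)
#' rrt_design("FR", p_yes = 2/12, p_no = 2/12)
#' @export
rrt_design <- function(kind, p_z = NULL, p_u = NULL, p_yes = NULL, p_no = NULL,
                       unrelated_question = NULL) {
  kind <- match.arg(kind, c("DQ", "CM", "UQ", "FR"))
  chk_prob <- function(x, nm, open = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
      abort(sprintf("`%s` must be a single probability.", nm))
    }
    ok <- if (open) x > 0 && x < 1 else x >= 0 && x <= 1
    if (!ok) abort(sprintf("`%s` = %g is outside the admissible range.", nm, x))
    x
  }
  allowed <- switch(kind,
    DQ = character(),
    CM = "p_z",
    UQ = c("p_z", "p_u"),
    FR = c("p_yes", "p_no")
  )
  given <- c(
    p_z = !is.null(p_z), p_u = !is.null(p_u),
    p_yes = !is.null(p_yes), p_no = !is.null(p_no)
  )
  extra <- setdiff(names(given)[given], allowed)
  if (length(extra)) {
    abort(sprintf("Field(s) %s are not applicable to a %s design.",
                  paste0("`", extra, "`", collapse = ", "), kind))
  }
  missing <- setdiff(allowed, names(given)[given])
  if (length(missing)) {
    abort(sprintf("A %s design requires %s.", kind,
                  paste0("`", missing, "`", collapse = ", ")))
  }
  if (kind %in% c("CM", "UQ")) p_z <- chk_prob(p_z, "p_z")
  if (kind == "CM" && abs(p_z - 0.5) < 1e-12) {
    abort("CM design with `p_z` = 1/2 is not identified (2*p_z - 1 = 0).")
  }
  if (kind == "UQ") {
    p_u <- chk_prob(p_u, "p_u")
  }
  if (kind == "FR") {
    p_yes <- chk_prob(p_yes, "p_yes", open = FALSE)
    p_no <- chk_prob(p_no, "p_no", open = FALSE)
    if (p_yes + p_no >= 1) {
      abort("FR design requires `p_yes` + `p_no` < 1 (someone must answer the question).")
    }
  }
  fields <- list(p_z = p_z, p_u = p_u, p_yes = p_yes, p_no = p_no)
  structure(
    c(list(kind = kind),
      fields[allowed],
      list(unrelated_question = unrelated_question)),
    class = "rrt_design"
  )
}

#' @export
print.rrt_design <- function(x, ...) {
  pars <- setdiff(names(x), c("kind", "unrelated_question"))
  parstr <- if (length(pars)) {
    paste(sprintf("%s = %.4g", pars, unlist(x[pars])), collapse = ", ")
  } else {
    "no randomizer"
  }
  cat(sprintf("<rrt_design %s: %s>\n", x$kind, parstr))
  invisible(x)
}

#' Misclassification probabilities implied by a design
#'
#' Maps a technique design to the misclassification pair
#' \eqn{p_{1|1} = \Pr(Y = 1 \mid Y^* = 1)} and
#' \eqn{p_{1|0} = \Pr(Y = 1 \mid Y^* = 0)} relating the observed response
#' \eqn{Y} to the true answer \eqn{Y^*}:
#'
#' * DQ: \eqn{p_{1|1} = 1}, \eqn{p_{1|0} = 0};
#' * CM: \eqn{p_{1|1} = p_Z}, \eqn{p_{1|0} = 1 - p_Z};
#' * UQ: \eqn{p_{1|1} = 1 - p_U (1 - p_Z)}, \eqn{p_{1|0} = p_U p_Z};
#' * FR: \eqn{p_{1|1} = 1 - p_{no}}, \eqn{p_{1|0} = p_{yes}}.
#'
#' @param design An [rrt_design()].
#' @return A one-row tibble with columns `kind`, `p11`, `p10`.
#' @examples
#' misclassification_probs(rrt_design("CM", p_z = 1/6))
#' @export
misclassification_probs <- function(design) {
  stopifnot(inherits(design, "rrt_design"))
  pair <- switch(design$kind,
    DQ = c(1, 0),
    CM = c(design$p_z, 1 - design$p_z),
    UQ = c(1 - design$p_u * (1 - design$p_z), design$p_u * design$p_z),
    FR = c(1 - design$p_no, design$p_yes)
  )
  if (abs(pair[1] - pair[2]) < 1e-12) {
    culprit <- switch(design$kind, CM = "p_z", UQ = "p_u", FR = "p_yes/p_no", "design")
    abort(sprintf(
      "Design %s is not identified: p11 == p10 (check `%s`).", design$kind, culprit))
  }
  tibble::tibble(kind = design$kind, p11 = pair[1], p10 = pair[2])
}

#' Cumulative Benford first-digit probability
#'
#' Probability that a first significant digit drawn from Benford's law,
#' \eqn{\Pr(d) = \log_{10}(1 + 1/d)}, is at most `d_max`. With `d_max = 5`
#' this is the routing probability of the unrelated-question RRT
#' implementation that sends respondents with house-number first digit
#' 1–5 to the sensitive question: 0.778.
#'
#' @param d_max Integer digit(s) in 1..9 (vectorized).
#' @return Probability (or vector of probabilities).
#' @examples
#' benford_first_digit_probability(5) # 0.778
#' @export
benford_first_digit_probability <- function(d_max) {
  if (!is.numeric(d_max) || any(is.na(d_max)) ||
      any(d_max != floor(d_max)) || any(d_max < 1) || any(d_max > 9)) {
    abort("`d_max` must be integer(s) between 1 and 9.")
  }
  log10(d_max + 1)
}

# Benford point masses for digits 1..9.
benford_pmf <- function() log10(1 + 1 / (1:9))

# Catalogue of unrelated birthday questions with theoretical "yes" probabilities
# under uniform birthdays (365.25-day year, 12 equal months of 30.4375 days).
.pz_catalogue <- c(
  jan_feb          = 2 / 12,        # CM: born in January or February
  day_1_6          = 72 / 365.25,   # CM: born between the 1st and the 6th
  jan_jun          = 6 / 12,        # UQ: born January-June
  even_month       = 6 / 12,        # UQ: born in an even-numbered month
  first_half_month = 15 / 30.4375,  # UQ: born in the first half of the month
  even_day         = 15 / 30.4375,  # UQ: born on an even-numbered day
  even_year        = 1 / 2          # UQ: born in an even-numbered year
)

#' Theoretical "yes" probability of a catalogued unrelated question
#'
#' The unrelated non-sensitive questions ask about a parent's birthday.
#' Assuming uniformly distributed birthdays (365.25-day year, twelve equal
#' months), each question has a known theoretical "yes" probability used as
#' \eqn{p_Z}. Catalogued identifiers:
#' `"jan_feb"`, `"day_1_6"` (crosswise model) and `"jan_jun"`,
#' `"even_month"`, `"first_half_month"`, `"even_day"`, `"even_year"`
#' (unrelated-question RRT).
#'
#' Empirically estimated probabilities (e.g. a survey-side Benford check)
#' can be used instead of these theoretical values by passing an explicit
#' `p_z` to [rrt_design()].
#'
#' @param unrelated_question Character identifier(s) from the catalogue.
#' @return Named numeric vector of "yes" probabilities.
#' @examples
#' theoretical_pz("jan_jun")
#' theoretical_pz(c("jan_feb", "day_1_6"))
#' @export
theoretical_pz <- function(unrelated_question) {
  unknown <- setdiff(unrelated_question, names(.pz_catalogue))
  if (length(unknown)) {
    abort(sprintf("Unknown unrelated question(s): %s. Catalogued: %s.",
                  paste(unknown, collapse = ", "),
                  paste(names(.pz_catalogue), collapse = ", ")))
  }
  .pz_catalogue[unrelated_question]
}

# Question identifiers paired (uniformly at random per respondent) with the
# sensitive questions, by technique.
cm_questions <- function() c("jan_feb", "day_1_6")
uq_questions <- function() c("jan_jun", "even_month", "first_half_month",
                             "even_day", "even_year")

#' Default design catalogue
#'
#' The four techniques with their study parameters: DQ; CM with the mean
#' theoretical \eqn{p_Z} of its two birthday questions (pairing is uniform
#' per respondent and the misclassification pair is linear in \eqn{p_Z}, so
#' the catalogue mean inverts the mixed sample exactly in expectation); UQ
#' with Benford routing (\eqn{p_U = 1 - 0.778}) and the mean \eqn{p_Z} of
#' its five birthday questions; FR with 2/12 forced-"yes" and 2/12
#' forced-"no" fields.
#'
#' @return Named list of [rrt_design()] objects (`DQ`, `CM`, `UQ`, `FR`).
#' @examples
#' purrr::map(default_designs(), misclassification_probs)
#' @export
default_designs <- function() {
  list(
    DQ = rrt_design("DQ"),
    CM = rrt_design("CM", p_z = mean(theoretical_pz(cm_questions())),
                    unrelated_question = cm_questions()),
    UQ = rrt_design("UQ",
                    p_u = 1 - benford_first_digit_probability(5),
                    p_z = mean(theoretical_pz(uq_questions())),
                    unrelated_question = uq_questions()),
    FR = rrt_design("FR", p_yes = 2 / 12, p_no = 2 / 12)
  )
}
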