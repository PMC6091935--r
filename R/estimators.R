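# Misclassification-corrected prevalence estimation.

# Core inversion on a sample mean. Returns the one-row estimate tibble.
# V(ybar) = ybar(1 - ybar)/(n - 1); V(pi_hat) = V(ybar)/(p11 - p10)^2.
prevalence_core <- function(y, mp, conf_level = 0.95, item = NA_character_) {
  n <- length(y)
  if (n < 2L) abort("At least 2 non-missing responses are needed (variance undefined).")
  ybar <- mean(y)
  delta <- mp$p11 - mp$p10
  pi_hat <- (ybar - mp$p10) / delta
  se <- sqrt(ybar * (1 - ybar) / (n - 1)) / abs(delta)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    item = item, kind = mp$kind, n = n, y_bar = ybar,
    pi_hat = pi_hat, se = se,
    ci_low = pi_hat - z * se, ci_high = pi_hat + z * se
  )
}

resolve_response <- function(data, quo_resp) {
  y <- eval_tidy(quo_resp, data)
  if (is.logical(y)) y <- as.integer(y)
  keep <- !is.na(y)
  y <- y[keep]
  if (!all(y %in% c(0, 1))) abort("Responses must be binary (0/1).")
  y
}

#' Estimate the prevalence of a sensitive trait
#'
#' Inverts the misclassification relation
#' \eqn{\Pr(Y = 1) = p_{1|1}\Pr(Y^* = 1) + p_{1|0}\Pr(Y^* = 0)} to estimate
#' the prevalence of the sensitive answer from observed responses:
#' \deqn{\hat\pi = \frac{\bar Y - p_{1|0}}{p_{1|1} - p_{1|0}},\qquad
#'       V(\hat\pi) = \frac{\bar Y (1-\bar Y)/(n-1)}{(p_{1|1}-p_{1|0})^2},}
#' with a Wald confidence interval. Estimates outside \eqn{[0, 1]} are
#' returned unmodified: a significantly negative estimate is a diagnostic
#' for non-compliance with the technique's instructions. Missing responses
#' are dropped listwise.
#'
#' @param data A data frame with one row per respondent.
#' @param design The [rrt_design()] under which `response` was collected.
#' @param response Column of observed binary responses, recoded so 1 is the
#'   sensitive answer ("yes", or "the same" for CM). Tidy-evaluated.
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @param item Optional item label carried into the output.
#' @return A one-row tibble: `item`, `kind`, `n`, `y_bar`, `pi_hat`, `se`,
#'   `ci_low`, `ci_high`.
#' @examples
#' d <- tibble::tibble(y = rbinom(500, 1, 0.3))
#' estimate_prevalence(d, rrt_design("DQ"), y)
#' @export
estimate_prevalence <- function(data, design, response = y, conf_level = 0.95,
                                item = NA_character_) {
  stopifnot(is.data.frame(data))
  y <- resolve_response(data, enquo(response))
  mp <- misclassification_probs(design)
  prevalence_core(y, mp, conf_level, item)
}

#' Prevalence within a subsample
#'
#' [estimate_prevalence()] restricted to the rows selected by `mask` — the
#' building block for conditional prevalences such as
#' \eqn{\Pr(Y^* = 1 \mid X = x)} used in individual-level validation.
#'
#' @inheritParams estimate_prevalence
#' @param mask A logical/binary vector of length `nrow(data)`, or an
#'   expression evaluated in `data` yielding one.
#' @return A one-row tibble as in [estimate_prevalence()].
#' @examples
#' d <- tibble::tibble(y = rbinom(500, 1, 0.3), g = rbinom(500, 1, 0.5))
#' conditional_prevalence(d, rrt_design("DQ"), g == 1, y)
#' @export
conditional_prevalence <- function(data, design, mask, response = y,
                                   conf_level = 0.95, item = NA_character_) {
  stopifnot(is.data.frame(data))
  m <- eval_tidy(enquo(mask), data)
  if (is.numeric(m)) m <- m != 0
  if (!is.logical(m) || length(m) != nrow(data)) {
    abort("`mask` must be a logical or 0/1 vector of length nrow(data).")
  }
  sub <- data[which(m), , drop = FALSE]
  if (nrow(sub) == 0L) abort("`mask` selects an empty subsample.")
  estimate_prevalence(sub, design, {{ response }}, conf_level, item)
}

#' Difference between two independent prevalence estimates
#'
#' Computes `a - b` with standard error \eqn{\sqrt{se_a^2 + se_b^2}}, a Wald
#' interval and a two-sided z-test p-value, for comparing technique arms
#' (e.g. an indirect technique against direct questioning under the
#' more-is-better assumption).
#'
#' @param a,b One-row estimate tibbles from [estimate_prevalence()].
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `item`, `kind` (`"a_kind - b_kind"`), `n`,
#'   `pi_hat`, `se`, `ci_low`, `ci_high`, `p_value`.
#' @export
arm_difference <- function(a, b, conf_level = 0.95) {
  stopifnot(is.data.frame(a), is.data.frame(b),
            nrow(a) == 1L, nrow(b) == 1L)
  diff <- a$pi_hat - b$pi_hat
  se <- sqrt(a$se^2 + b$se^2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  zstat <- if (se > 0) diff / se else NA_real_
  tibble::tibble(
    item = a$item, kind = paste(a$kind, "-", b$kind),
    n = a$n + b$n, pi_hat = diff, se = se,
    ci_low = diff - z * se, ci_high = diff + z * se,
    p_value = if (is.na(zstat)) NA_real_ else 2 * pnorm(-abs(zstat))
  )
}
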