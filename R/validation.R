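# Individual-level validation: TPR / FPR / CCR identification under observed
# truth (roll-a-six game) or latent truth (prediction game, assumptions
# A1 + A2 or A1 + A2'), with delta-method and bootstrap standard errors.
#
# All estimators are smooth functions of three per-respondent means,
#   observed truth:  A = 1{X != X*},  B = Y * A,        C = Y * (1 - A)
#   latent truth:    A = X,           B = Y * X,        C = Y * (1 - X)
# whose joint covariance is estimated from the data ("joint mean
# estimation"); standard errors follow by the delta method with analytic
# gradients. Inversion constants: delta = p11 - p10, p10 from the design.

# ---- point estimators + analytic jacobians -------------------------------

# Each est_* returns list(est = named c(tpr, fpr, ccr, cheat_rate),
# jac = 4x3 matrix of d est / d (A, B, C), fpr_truncated = flag).
# CCR always uses the truncated (non-negative) FPR; the reported fpr keeps
# the raw value.

est_observed <- function(A, B, C, p10, delta) {
  if (A <= 0 || A >= 1) abort("Empty cheater or non-cheater group.")
  tpr <- (B / A - p10) / delta
  fpr <- (C / (1 - A) - p10) / delta
  trunc <- fpr < 0
  fpr_c <- max(fpr, 0)
  ccr <- tpr * A + (1 - fpr_c) * (1 - A)
  g_tpr <- c(-B / (A^2 * delta), 1 / (A * delta), 0)
  g_fpr <- c(C / ((1 - A)^2 * delta), 0, 1 / ((1 - A) * delta))
  g_ccr <- if (trunc) {
    c(-p10 / delta - 1, 1 / delta, 0)
  } else {
    c(-1 - 2 * p10 / delta, 1 / delta, -1 / delta)
  }
  list(
    est = c(tpr = tpr, fpr = fpr, ccr = ccr, cheat_rate = A),
    jac = rbind(tpr = g_tpr, fpr = g_fpr, ccr = g_ccr, cheat_rate = c(1, 0, 0)),
    fpr_truncated = trunc
  )
}

est_latent <- function(A, B, C, p10, delta, w, prime = FALSE) {
  if (A >= 1) abort("Empty claimed-loss group (X = 0).")
  if (A <= 0) abort("Empty claimed-win group (X = 1).")
  D <- A - w
  if (D <= 0) {
    abort(sprintf(
      "No identifiable cheating mass: Pr(X = 1) = %.4f <= win probability %.4f.", A, w))
  }
  q0 <- (C / (1 - A) - p10) / delta          # Pr(Y* = 1 | X = 0)
  g_q0 <- c(C / ((1 - A)^2 * delta), 0, 1 / ((1 - A) * delta))
  if (!prime) {
    # A1 + A2: winner FPR equals true-loser FPR (= q0).
    fpr <- q0
    g_fpr <- g_q0
    N <- (B - p10 * A) / delta - w * q0
    g_N <- c(-p10 / delta - w * g_q0[1], 1 / delta, -w * g_q0[3])
  } else {
    # A1 + A2': winner FPR is zero; the joint winner term drops from the
    # TPR numerator and the overall FPR reweights true losers only.
    V <- delta * (1 - A + w)
    U <- C - p10 * (1 - A)
    fpr <- U / V
    g_fpr <- c((p10 * V + U * delta) / V^2, 0, 1 / V)
    N <- (B - p10 * A) / delta
    g_N <- c(-p10 / delta, 1 / delta, 0)
  }
  tpr <- N / D
  g_tpr <- c((g_N[1] * D - N) / D^2, g_N[2] / D, g_N[3] / D)
  trunc <- fpr < 0
  fpr_c <- max(fpr, 0)
  share0 <- 1 - A + w                         # Pr(X = X*) under A1
  ccr <- tpr * D + (1 - fpr_c) * share0       # tpr * D == N
  g_ccr <- if (trunc) {
    c(g_N[1] - 1, g_N[2], g_N[3])
  } else if (!prime) {
    c(g_N[1] - g_q0[1] * share0 + (1 - q0) * (-1) + 0, g_N[2], g_N[3] - g_q0[3] * share0)
  } else {
    c(-1 - 2 * p10 / delta, 1 / delta, -1 / delta)
  }
  list(
    est = c(tpr = tpr, fpr = fpr, ccr = ccr, cheat_rate = D),
    jac = rbind(tpr = g_tpr, fpr = g_fpr, ccr = g_ccr, cheat_rate = c(1, 0, 0)),
    fpr_truncated = trunc
  )
}

validation_point <- function(y, x, xstar = NULL, mp, assumption = "A1_A2",
                             win_prob = 1 / 6) {
  delta <- mp$p11 - mp$p10
  if (is.null(xstar)) {
    a <- x
  } else {
    a <- as.numeric(x != xstar)
  }
  A <- mean(a); B <- mean(y * a); C <- mean(y * (1 - a))
  fit <- if (is.null(xstar)) {
    est_latent(A, B, C, mp$p10, delta, win_prob, prime = identical(assumption, "A1_A2prime"))
  } else {
    est_observed(A, B, C, mp$p10, delta)
  }
  fit$means <- c(A = A, B = B, C = C)
  fit$components <- cbind(a = a, b = y * a, c = y * (1 - a))
  fit
}

# ---- delta method --------------------------------------------------------

#' Delta-method standard errors
#'
#' First-order variance propagation: given estimated component means with
#' joint covariance matrix `vcov` and the Jacobian of the target statistics
#' with respect to those means, returns
#' \eqn{se_k = \sqrt{(J \Sigma J^\top)_{kk}}}.
#'
#' This is the generic propagation step used for the TPR/FPR/CCR
#' identification formulas, whose gradients the package derives
#' analytically; it is exported so the same machinery can be applied to any
#' smooth function of jointly estimated means.
#'
#' @param means Named numeric vector of component means (used for length
#'   checking only).
#' @param vcov Covariance matrix of `means` (p x p).
#' @param jacobian q x p matrix: row k holds the gradient of statistic k.
#' @return Named numeric vector of standard errors (names from
#'   `rownames(jacobian)`).
#' @export
delta_method_se <- function(means, vcov, jacobian) {
  p <- length(means)
  jacobian <- rbind(jacobian)
  if (!is.matrix(vcov) || nrow(vcov) != p || ncol(vcov) != p) {
    abort("`vcov` must be a square matrix conformable with `means`.")
  }
  if (ncol(jacobian) != p) abort("`jacobian` must have one column per mean.")
  v <- diag(jacobian %*% vcov %*% t(jacobian))
  v[v < 0 & v > -1e-12] <- 0
  setNames(sqrt(v), rownames(jacobian))
}

component_vcov <- function(components) {
  n <- nrow(components)
  cov(components) / n
}

# ---- bootstrap -----------------------------------------------------------

#' Nonparametric bootstrap standard errors for validation estimates
#'
#' Resamples respondents with replacement within the technique arm,
#' re-estimates TPR, FPR, CCR and the cheat rate, and reports the standard
#' deviation across replicates. Degenerate resamples (an empty comparison
#' group, or no identifiable cheating mass in latent mode) are redrawn and
#' counted; more than 1% redraws triggers a warning. Deterministic given
#' `seed`.
#'
#' @param data Data frame of respondents (one arm).
#' @param design The arm's [rrt_design()].
#' @param response,claim,truth Columns for the observed response \eqn{Y}
#'   (1 = admits cheating), the claim \eqn{X} (1 = claimed win) and, for the
#'   observed-truth mode, the recorded win \eqn{X^*}. Tidy-evaluated;
#'   pass `truth = NULL` for the latent-truth mode.
#' @param assumption `"A1_A2"` or `"A1_A2prime"` (latent mode only).
#' @param B Number of bootstrap replicates (>= 200).
#' @param seed Integer seed for the resampling.
#' @param win_prob Design win probability of the dice game (default 1/6).
#' @return Named numeric vector of standard errors (`tpr`, `fpr`, `ccr`,
#'   `cheat_rate`) with attribute `redraws`.
#' @export
bootstrap_se <- function(data, design, response = y, claim = claim, truth = NULL,
                         assumption = c("A1_A2", "A1_A2prime"), B = 2000,
                         seed = NULL, win_prob = 1 / 6) {
  assumption <- match.arg(assumption)
  if (B < 200) abort("`B` must be at least 200.")
  yv <- resolve_response(data, enquo(response))
  if (length(yv) != nrow(data)) abort("Bootstrap requires complete responses.")
  xv <- as.numeric(eval_tidy(enquo(claim), data))
  tq <- enquo(truth)
  xs <- if (quo_is_null(tq)) NULL else as.numeric(eval_tidy(tq, data))
  mp <- misclassification_probs(design)
  n <- length(yv)
  if (!is.null(seed)) set.seed(seed)
  reps <- matrix(NA_real_, B, 4)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- tryCatch(
        validation_point(yv[idx], xv[idx], if (is.null(xs)) NULL else xs[idx],
                         mp, assumption, win_prob),
        error = function(e) NULL
      )
      if (!is.null(fit)) break
      redraws <- redraws + 1L
      if (redraws > 100L * B) abort("Bootstrap resampling degenerate; giving up.")
    }
    reps[b, ] <- fit$est
  }
  if (redraws > 0.01 * B) {
    warn(sprintf("%d degenerate bootstrap resamples were redrawn (> 1%% of B).", redraws))
  }
  out <- apply(reps, 2, sd)
  names(out) <- c("tpr", "fpr", "ccr", "cheat_rate")
  attr(out, "redraws") <- redraws
  out
}

# ---- user-facing validation ---------------------------------------------

new_rrt_validation <- function(fit, se, mp, assumption, variance_method, n,
                               conf_level, redraws = NULL) {
  structure(
    list(
      estimates = fit$est, se = se[names(fit$est)],
      fpr_truncated = fit$fpr_truncated,
      assumption = assumption, variance_method = variance_method,
      kind = mp$kind, n = n, conf_level = conf_level,
      means = fit$means, redraws = redraws
    ),
    class = "rrt_validation"
  )
}

#' Validate a technique against observed truth (roll-a-six game)
#'
#' In the roll-a-six game the recorded die roll makes each respondent's
#' cheating observable: a cheater is a respondent with \eqn{X = 1} (claimed
#' a win) but \eqn{X^* = 0} (did not roll a six). The true positive rate is
#' the misclassification-inverted share of cheaters admitting it,
#' \deqn{TPR = \frac{\Pr(Y = 1 \mid X \ne X^*) - p_{1|0}}{p_{1|1} - p_{1|0}},}
#' the false positive rate is the analogous quantity among non-cheaters
#' (\eqn{X = X^*}), and the correct classification rate is
#' \eqn{CCR = TPR \cdot \Pr(X \ne X^*) + (1 - FPR)\Pr(X = X^*)}, where a
#' negative FPR is set to zero inside the CCR (and flagged) while the
#' reported FPR keeps its raw, possibly negative, diagnostic value.
#'
#' @inheritParams bootstrap_se
#' @param variance `"delta"` (default) for analytic delta-method standard
#'   errors, or `"bootstrap"`.
#' @param conf_level Confidence level for Wald intervals in [tidy()].
#' @param ... Passed to [bootstrap_se()] (`B`, `seed`).
#' @return An object of class `rrt_validation`; see [tidy.rrt_validation()]
#'   and [glance.rrt_validation()].
#' @examples
#' cfg <- simulation_config(n = 4000, game_split = 0, seed = 7)
#' dat <- simulate_survey(cfg)
#' arm <- dplyr::filter(dat, technique == "DQ")
#' validate_observed_truth(arm, rrt_design("DQ"),
#'   response = 1 - resp_cheating, claim = claim, truth = won)
#' @export
validate_observed_truth <- function(data, design, response = y, claim = claim,
                                    truth = won,
                                    variance = c("delta", "bootstrap"),
                                    conf_level = 0.95, win_prob = 1 / 6, ...) {
  variance <- match.arg(variance)
  yv <- resolve_response(data, enquo(response))
  if (length(yv) != nrow(data)) {
    keep <- !is.na(eval_tidy(enquo(response), data))
    data <- data[keep, , drop = FALSE]
  }
  xv <- as.numeric(eval_tidy(enquo(claim), data))
  xs <- as.numeric(eval_tidy(enquo(truth), data))
  if (anyNA(xv) || anyNA(xs)) abort("`claim` and `truth` must be complete.")
  mp <- misclassification_probs(design)
  fit <- validation_point(yv, xv, xs, mp, win_prob = win_prob)
  if (variance == "delta") {
    se <- delta_method_se(fit$means, component_vcov(fit$components), fit$jac)
    redraws <- NULL
  } else {
    d2 <- data; d2$.y <- yv; d2$.x <- xv; d2$.xs <- xs
    se <- bootstrap_se(d2, design, response = .y, claim = .x, truth = .xs,
                       win_prob = win_prob, ...)
    redraws <- attr(se, "redraws")
  }
  new_rrt_validation(fit, se, mp, "observed_truth", variance, length(yv),
                     conf_level, redraws)
}

#' Validate a technique against latent truth (prediction game)
#'
#' In the prediction game the private prediction makes cheating latent:
#' only the claim \eqn{X} is observed, but the design win probability
#' \eqn{\Pr(X^* = 1) = 1/6} identifies the cheat rate as
#' \eqn{\Pr(X = 1) - 1/6} under assumption A1 (no false losers). Under A2
#' (true winners and true losers share the same false positive rate) the
#' FPR is identified from the claimed losers,
#' \eqn{FPR = (\Pr(Y = 1 \mid X = 0) - p_{1|0}) / (p_{1|1} - p_{1|0})},
#' and the TPR as
#' \deqn{TPR = \frac{\Pr(X=1)\,\widehat{\Pr}(Y^*=1 \mid X=1) -
#'   \tfrac16\,\widehat{\Pr}(Y^*=1 \mid X=0)}{\Pr(X=1) - \tfrac16},}
#' with \eqn{CCR = TPR(\Pr(X=1) - 1/6) + (1 - FPR)(\Pr(X=0) + 1/6)}.
#' Under the stricter A2' (true winners never falsely "admit") the winner
#' joint term drops from the TPR numerator and the overall FPR reweights
#' true losers only: \eqn{FPR' = FPR \cdot \Pr(X=0) / (\Pr(X=0) + 1/6)}.
#'
#' Errors if the estimated claim rate does not exceed `win_prob` (no
#' identifiable cheating mass).
#'
#' @inheritParams validate_observed_truth
#' @param assumption `"A1_A2"` (default) or `"A1_A2prime"`.
#' @return An object of class `rrt_validation`.
#' @examples
#' cfg <- simulation_config(n = 4000, game_split = 1, seed = 7,
#'   cheat_propensity_prediction = 0.3)
#' dat <- simulate_survey(cfg)
#' arm <- dplyr::filter(dat, technique == "DQ")
#' validate_latent_truth(arm, rrt_design("DQ"),
#'   response = 1 - resp_cheating, claim = claim)
#' @export
validate_latent_truth <- function(data, design, response = y, claim = claim,
                                  assumption = c("A1_A2", "A1_A2prime"),
                                  variance = c("delta", "bootstrap"),
                                  conf_level = 0.95, win_prob = 1 / 6, ...) {
  assumption <- match.arg(assumption)
  variance <- match.arg(variance)
  yv <- resolve_response(data, enquo(response))
  if (length(yv) != nrow(data)) {
    keep <- !is.na(eval_tidy(enquo(response), data))
    data <- data[keep, , drop = FALSE]
  }
  xv <- as.numeric(eval_tidy(enquo(claim), data))
  if (anyNA(xv)) abort("`claim` must be complete.")
  mp <- misclassification_probs(design)
  fit <- validation_point(yv, xv, NULL, mp, assumption, win_prob)
  if (variance == "delta") {
    se <- delta_method_se(fit$means, component_vcov(fit$components), fit$jac)
    redraws <- NULL
  } else {
    d2 <- data; d2$.y <- yv; d2$.x <- xv
    se <- bootstrap_se(d2, design, response = .y, claim = .x, truth = NULL,
                       assumption = assumption, win_prob = win_prob, ...)
    redraws <- attr(se, "redraws")
  }
  new_rrt_validation(fit, se, mp, assumption, variance, length(yv),
                     conf_level, redraws)
}

#' @export
print.rrt_validation <- function(x, ...) {
  cat(sprintf("<rrt_validation %s | %s | n = %d | %s SEs>\n",
              x$kind, x$assumption, x$n, x$variance_method))
  print(tidy(x), ...)
  if (x$fpr_truncated) {
    cat("Note: negative FPR set to zero inside the CCR.\n")
  }
  invisible(x)
}

#' Tidy a validation result
#'
#' @param x An `rrt_validation` object.
#' @param ... Unused.
#' @return A tibble with one row per metric (`tpr`, `fpr`, `ccr`,
#'   `cheat_rate`): `estimate`, `se`, Wald `ci_low`/`ci_high`.
#' @method tidy rrt_validation
#' @export
tidy.rrt_validation <- function(x, ...) {
  z <- qnorm(1 - (1 - x$conf_level) / 2)
  tibble::tibble(
    metric = names(x$estimates),
    estimate = unname(x$estimates),
    se = unname(x$se),
    ci_low = unname(x$estimates - z * x$se),
    ci_high = unname(x$estimates + z * x$se)
  )
}

#' One-row summary of a validation result
#'
#' @param x An `rrt_validation` object.
#' @param ... Unused.
#' @return A one-row tibble: `kind`, `assumption`, `variance_method`, `n`,
#'   `cheat_rate`, `ccr`, `fpr_truncated`.
#' @method glance rrt_validation
#' @export
glance.rrt_validation <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, assumption = x$assumption,
    variance_method = x$variance_method, n = x$n,
    cheat_rate = unname(x$estimates["cheat_rate"]),
    ccr = unname(x$estimates["ccr"]),
    fpr_truncated = x$fpr_truncated
  )
}
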