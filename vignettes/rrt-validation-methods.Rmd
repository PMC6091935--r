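---
title: "Methods: misclassification designs, identification, and the synthetic survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: misclassification designs, identification, and the synthetic survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrtvalidate)
```

This vignette is the package's account of its statistical machinery: the
misclassification model behind each question technique, the identification
of individual-level error rates with and without observed truth, the
variance estimators, the synthetic survey generator and its assumptions,
and the numerical and design choices a maintainer should know about.

## 1. Question techniques as misclassification designs

All four techniques are special cases of one two-parameter misclassification
model linking the unobserved true answer $Y^*$ to the observed response $Y$
through $p_{1|1} = \Pr(Y=1 \mid Y^*=1)$ and $p_{1|0} = \Pr(Y=1 \mid Y^*=0)$:

$$\Pr(Y=1) = p_{1|1}\,\pi + p_{1|0}\,(1-\pi), \qquad \pi = \Pr(Y^*=1).$$

Direct questioning has $(1, 0)$. The crosswise model, which asks whether the
answers to the sensitive question and an unrelated birthday question (with
known "yes"-probability $p_Z$) are *the same*, has $(p_Z,\, 1-p_Z)$; it is
identified whenever $p_Z \ne 1/2$, and with the birthday questions used here
($p_Z \approx 0.18$) the denominator $p_{1|1}-p_{1|0}$ is *negative* — the
inversion is monotone decreasing in $\bar Y$, which is perfectly valid and
handled uniformly. The unrelated-question design routes a respondent to the
sensitive question unless their private Benford digit exceeds 5
($p_U = 1 - \log_{10} 6 \approx 0.222$), giving
$(1 - p_U(1-p_Z),\, p_U p_Z)$. The forced-response design instructs a random
$p_{yes}$ ($p_{no}$) share to tick yes (no) unconditionally, giving
$(1-p_{no},\, p_{yes})$.

**Unrelated-question probabilities.** The catalogued birthday questions get
theoretical "yes"-probabilities under uniformly distributed birthdays, using
a single documented convention: a 365.25-day year divided into twelve equal
months of 30.4375 days. Hence "born between the 1st and the 6th" is
$72/365.25$ and "first half of the month" and "even-numbered day" are both
$15/30.4375$. Any $p_Z$ can be overridden with an empirical estimate (for
example from a survey-side device check) via `rrt_design()`.

**Per-respondent pairing.** The survey pairs each sensitive item with one of
the technique's unrelated questions uniformly at random per respondent.
Because both $p_{1|1}$ and $p_{1|0}$ are linear in $p_Z$, analyzing the
pooled arm with the catalogue-*mean* $p_Z$ inverts the mixture exactly in
expectation; `default_designs()` therefore carries the mean.

**Forced-response field allocation.** The twelve-field layout defaults to
8/12 "answer the question", 2/12 forced yes, 2/12 forced no. The allocation
is a configuration parameter (`rrt_design("FR", p_yes =, p_no =)`) rather
than a constant, since implementations vary.

## 2. Prevalence estimation

`estimate_prevalence()` inverts the mixture at the sample mean and carries
the variance through the linear transform:

$$\hat\pi = \frac{\bar Y - p_{1|0}}{p_{1|1}-p_{1|0}}, \qquad
  \widehat V(\hat\pi) = \frac{\bar Y(1-\bar Y)/(n-1)}{(p_{1|1}-p_{1|0})^2},$$

with 95% Wald intervals ($z = 1.96$). Three deliberate choices:

* the $(n-1)$ denominator is used exactly as written above;
* estimates outside $[0,1]$ are **not** truncated at the estimation layer.
  A significantly negative estimate is informative — it indicates
  non-compliance with the instrument (self-protective "no"-saying can push
  the response mean below the forced-yes floor). Truncation happens in one
  place only (the CCR, below);
* item nonresponse is handled by per-item listwise deletion, adequate when
  missingness is negligible.

## 3. Individual-level validation

The validation games both have win probability $w = 1/6$. Writing $X$ for
the claim and $X^*$ for the true win, a cheater is $X \ne X^*$ (false
losers, $X=0 \wedge X^*=1$, are removed by an exclusion rule rather than
modeled).

**Observed truth.** With recorded rolls, TPR and FPR are
misclassification-inverted conditional prevalences among cheaters and
non-cheaters, and
$CCR = TPR\cdot\Pr(X\ne X^*) + (1-FPR)\Pr(X=X^*)$.

**Latent truth.** With private predictions, identification rests on
assumption A1 (no false losers, so $\Pr(X\ne X^*) = \Pr(X=1) - w$) and A2
(true winners and true losers share one false positive rate, so the FPR is
identified from claimed losers). The TPR follows from decomposing the joint
probability of cheating and admitting:

$$TPR = \frac{\Pr(X=1)\,\widehat{\Pr}(Y^*{=}1\mid X{=}1)
             - w\,\widehat{\Pr}(Y^*{=}1\mid X{=}0)}{\Pr(X=1)-w}.$$

Under the stricter A2$'$ (winners never falsely admit) the winner term in
the numerator is dropped and the overall FPR reweights true losers only:
$FPR' = FPR \cdot \Pr(X=0)/(\Pr(X=0)+w)$, which is never larger than the A2
value. We verified this algebra by construction rather than against a
published supplementary derivation, and the test suite checks both the
reweighting identity and the simulation-based equivalence of the latent and
observed routes when A1 + A2 hold by construction.

Estimation fails loudly, by design, when $\widehat{\Pr}(X=1) \le w$: there
is then no identifiable cheating mass and the denominator is non-positive.

**Truncation.** A negative estimated FPR is set to zero *only inside the
CCR* (and flagged via `fpr_truncated`); the reported FPR keeps the raw
value because its sign is diagnostic. With the truncated FPR, the CCR lies
in $[0,1]$ whenever the TPR does.

## 4. Variances

All validation statistics are smooth functions of three per-respondent
means — $A$ (cheater indicator or claim), $B = YA$, $C = Y(1-A)$ — so
standard errors come from joint mean estimation plus the delta method. The
$3\times3$ covariance is the sample covariance of the indicator columns
divided by $n$ (which reproduces the $\bar Y(1-\bar Y)/(n-1)$ convention in
the linear case), and gradients are analytic. Two simplifications make the
gradients reliable: $TPR \cdot (A - w)$ is linear in $(A, B)$, and the
untruncated CCR collapses to a fully linear function of $(A, B, C)$ in the
observed-truth and A2$'$ cases. When the FPR is truncated the CCR gradient
drops the FPR term (the statistic is locally constant in it). The test
suite checks every gradient against central finite differences and the
resulting SEs against empirical SDs over 2,000 replications and against a
seeded nonparametric bootstrap (`bootstrap_se()`, which resamples
respondents within the arm, redraws degenerate resamples with a counter,
and warns if redraws exceed 1% of replicates). Delta is the default;
bootstrap is the cross-check. Technique arms are treated as independent.

A knife-edge case worth knowing: the delta SE of the TPR degrades as
$\widehat{\Pr}(X=1) \to w$ (the identification denominator vanishes);
nothing in the package hides that — the SE simply grows.

## 5. The synthetic survey generator

`simulate_survey()` instantiates the data-generating story the analysis
assumes, per respondent and in order: game assignment → uniform die roll →
win/lose → cheat decision (losers only, per-game propensity) → technique
assignment → device outcome → behavior draw → observed response.

Defaults are the study conditions: arm allocation $1/8, 3/8, 2/8, 2/8$
(DQ, CM, UQ, FR); $w = 1/6$; cheat propensity among losers 0.3 in the
prediction game and 0.06 in the roll-a-six game, chosen so the implied
overall cheating rates are about 25% and 5% — the magnitudes a detectable
versus undetectable cheating opportunity produces; attrition rates matching
the recruitment accounting (completion 6473/6505, screener failure
205/6473, unrecorded roll 115/6268); no false losers unless the
`p_false_loser` switch is enabled (A1 holds by construction). The three
additional norm items default to plausible prevalences (shoplifting 0.40,
tax evasion 0.25, non-voting 0.40) — synthetic choices for exercising the
comparative stage, not estimates of anything.

**Behavior model.** Four labels per respondent: *honest* and *liar* come
from the intent parameters (a cheater intends the truthful "yes" with
probability `p_truthful_cheater`, the behavioral TPR\*; a non-cheater
intends a false "yes" with `p_false_admit_noncheater`, the behavioral
FPR\*) and comply with the instrument; *confused* respondents answer
uniformly at random regardless of the instrument; *self-protective*
respondents always emit the design's safe response — "no" for DQ/UQ/FR.
The crosswise model has no unambiguously safe option (that is one of its
selling points), so CM self-protective responding is modeled as uniform as
well; little is known about what confused CM respondents actually do, and
uniform responding is a modeling choice, flagged as such. Raising CM
confusion from 0 with FPR\* $= 0$ produces a strictly positive estimated
FPR — the false-positive mechanism the individual-level validation is built
to detect.

**Devices.** The UQ digit (an acquaintance's house number, Benford) and the
FR field are drawn once per respondent and reused across items; CM draws a
fresh unrelated question per item. Routing uses the same uniform that
generates the Benford digit, so with the default $p_U$ the digits 1–5 route
to the sensitive question exactly.

**Randomness discipline.** One master seed fills an $n \times K$ uniform
matrix row-wise; each respondent owns a fixed block of the stream. Changing
allocation probabilities, behavior parameters or attrition rates
reinterprets a respondent's own uniforms without reshuffling anyone else's
draws, and identical seeds give bit-identical tables.

**Polarity.** Responses are emitted in survey polarity (answers to the
questionnaire wording): the honesty and voting questions are reverse-coded
relative to the sensitive trait, and `recode_items()` flips them (an
involution) before analysis. The generator simulates the instruments on the
recoded orientation, which for DQ and CM coincides exactly with flipping
the recorded response (CM is symmetric in same/different); for UQ and FR it
amounts to defining the catalogue parameters relative to the recoded
question, which is how the inversion formulas expect them.

**What the generator does not emulate.** Real covariate structure
(demographics are absent), covariate-dependent behavior (the behavior model
is constant within technique), non-uniform birthdays, device
misreporting correlated with the sensitive trait, and respondent-specific
randomizer distributions. Passing tests therefore show that the estimators
and identification formulas are correct *under the stated model*, not that
any real population satisfies A1/A2 or the behavior taxonomy.

## 6. Pipeline conventions

Exclusions are applied in a fixed order (completion, screener, unrecorded
roll, false loser) with per-rule attribution — a record failing two rules
counts at the first — and a ledger whose counts conserve the total.
Comparative differences use two-sided Wald $z$-tests; no multiple-testing
correction is applied (none is standard for this three-arm comparison, and
the output carries raw p-values). Non-cheating items flow through the
comparative stage only; they have no truth criterion. The deposited-data
path is a CSV reader with a user-editable codebook mapping rather than
hard-coded column names; native Stata-13 ingestion is out of scope.

## 7. Problem sizes used in tests and the acceptance script

Simulation-backed checks use $n = 10^5$ respondents for parameter-recovery
assertions (Monte-Carlo SEs small enough that a 3-SE band is a sharp test),
2,000 replications of $n = 2{,}000$ for the variance validity check, 2,000
replications of $n = 1{,}000$ for interval coverage, and $B = 2{,}000$
bootstrap replicates — sizes at which the Monte-Carlo noise of the check is
a few percent, comfortably inside the 10% agreement bands being asserted.
All stochastic tests fix seeds; the acceptance script derives every stream
from its `--seed` argument.

## 8. Known limitations

* Identification near $\widehat{\Pr}(X=1) = w$ is fragile by nature; the
  package errors rather than reporting an unstable ratio.
* The A2$'$ algebra follows the stated contract (winner joint term zero,
  loser-only reweighting); alternative published parameterizations of the
  same idea may differ in finite samples.
* Wald intervals can undercover for prevalences very near 0 or 1 at small
  $n$; the coverage guarantee is demonstrated at $\pi = 0.3$, $n = 1{,}000$.
* The bootstrap resamples within arms independently and does not model the
  joint randomization of arm assignment.
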