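---
title: "Interval coded scoring: models, tuning and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval coded scoring: models, tuning and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icscore)
```

## The model

Clinical score cards assign integer points to value ranges of a few
variables; the summed points map to a risk. `icscore` learns such
systems from binary-labelled data. Each variable $x^p$ is discretised
into $N_p$ intervals by thresholds $\tau^p$ placed at training-sample
percentiles, capped at `max_bins` intervals and constrained so that
every interval holds at least five training points (the interval count
is decremented until this holds; duplicated thresholds from heavy ties
are collapsed). Ordinal thresholds are rounded to integers; binary and
categorical variables use their observed levels as intervals. A
two-way interaction is the Cartesian grid of its two variables'
intervals.

The one-hot expansion $\tilde Z$ places a single 1 per effect at the
interval an observation occupies (intervals are lower-closed,
upper-open, the outermost open to $\pm\infty$); interaction grids are
vectorised column-major. Two convex estimators produce interval
weights $\tilde w$:

**LP route.** A soft-margin program with a total-variation penalty,
$$\min_{\tilde w, b, \varepsilon}\ \|\chi D \tilde w\|_1 +
\gamma\,\mathbf 1^\top \varepsilon
\quad\text{s.t.}\quad Y(\tilde Z \tilde w + b) \ge \mathbf 1 -
\varepsilon,\ \varepsilon \ge 0,$$
where $D$ takes differences between adjacent intervals of one effect
(both grid directions for interactions) and the hinge slack
$\varepsilon$ is traded off by $\gamma > 0$. The $\ell_1$ norm on
differences drives the weight profile piecewise constant. The
linearised program (one auxiliary variable per difference row) is
solved by an in-package sparse primal–dual interior-point method
(Mehrotra predictor–corrector, iterative refinement of the Newton
solves, tolerance $10^{-9}$ on the relative duality gap and residuals).
LP optima can be non-unique; downstream logic therefore never depends
on which optimum is returned.

**Elastic-net route.** A cumulative encoding $\hat Z$ activates an
observation's interval and all preceding ones, so coefficients
$\hat w$ live in the difference domain and $\tilde w = R\hat w$ with
$R$ the block cumulative-sum (lower-triangular-of-ones) operator. The
estimator is a budget-form elastic net regression on the $\pm 1$
labels,
$$\min_{\hat w, b}\ \|\hat Z \hat w + b - y\|_2^2 +
\epsilon\|\hat w\|_2^2
\quad\text{s.t.}\quad \|\hat w\|_1 \le t,$$
with $\epsilon = 0.05$ fixed and the budget $t$ tuned. It is solved in
the penalized form by cyclic coordinate descent (exact
soft-thresholding, compiled inner loop) with a bisection on the
penalty to meet the budget; the pure ridge solution is returned when
the constraint is inactive. This route supports main effects only —
an interaction would turn the reparameterised problem into a
generalized elastic net. Categorical variables have no natural order;
their cumulative encoding follows the catalogued
(first-appearance) level order, which also fixes the adjacency their
implicit difference penalty acts on.

**Iterative reweighting.** Both routes re-solve with weights derived
from the current solution to push more differences (LP) or
coefficients (EN) to exactly zero. The LP uses
$\chi_{ii} = 1/(\epsilon_1 + a\,|(D\tilde w)_i|)$ with
$\epsilon_1 = 5\cdot 10^{-4}$, at most 10 iterations; the EN rescales
columns by $\hat\chi_{ii} = a\,|\hat w_i|$ (columns at zero stay
trapped at zero), at most 25 iterations; both stop early when the mean
absolute coefficient change falls below $\epsilon_2 = 10^{-8}$. The
reweighting value $a$ is the user-facing complexity dial; $a = -1$
means no reweighting. Note that under the EN rule the budget applies
to the rescaled variable, so small $a$ tightens and large $a$ loosens
the effective budget — with $a \le 1/t$ per retained coefficient the
model can collapse entirely. This follows the update rule as stated;
the tuning curve makes the consequences visible.

## Pipeline

`run_ics()` chains: threshold construction → encoding → hyperparameter
selection → reweighting-value selection → fit → prune →
repeat-until-stable → integer rounding and merging → logistic risk
calibration.

*Pruning.* An effect whose interval weights are all equal (tolerance
$10^{-5}$ relative to the weight scale) carries no information under a
difference penalty: its common value is absorbed into the offset and
the effect removed. All-zero blocks are the special case; testing for
constancy rather than zero is what makes pruning fire at all for the
LP route, where constant blocks are an unidentifiable gauge.

*Hyperparameter selection.* $\gamma$ (grid `0.1, 1, 10, 100`) or $t$
(20 log-spaced values from 0.01 up to the unconstrained solution's
$\ell_1$ norm) is chosen first, by stratified cross-validated AUC at
$a = -1$ under the one-standard-error rule: the simplest setting whose
mean CV AUC is within one SE of the best. The 1-SE rule matters in
practice — a plain arg-max routinely admits marginal noise effects
into the budget. The reweighting value is then tuned with the
hyperparameter fixed; tuning both jointly would square the grid for
little benefit at these problem sizes.

*The tuning curve.* For every $a$ in the grid the package reports CV
AUC, the CV calibration slope and bias of out-of-fold risk
predictions, and the complexity (variables, intervals) of the
full-data model at that $a$. The automatic choice takes the fewest
intervals among the grid points whose CV AUC reaches
`cutoff[2]` × the maximum, breaking ties toward larger $a$, then
toward calibration slope closest to 1. With `cutoff[2] = 1` this
reduces to arg-max AUC with a sparsity tie-break. The default 0.80
buys simplicity aggressively: on the package's own synthetic benchmark
it typically halves the model (one variable instead of two) at a cost
of roughly 0.07 AUC. Users who want fidelity first should raise the
cutoff or pick from the printed curve (`auto = FALSE`,
`choose_weight`).

*Rounding.* Each retained effect's weights are centred so its minimum
interval is 0 points (the minima are offset, re-estimated by the final
calibration anyway). A multiplier grid (50 log-spaced values spanning
$[0.5, 10]/\max|\tilde w|$) is searched for the smallest multiplier
whose rounded integer points (i) keep at least 90% of the unrounded
training AUC, (ii) keep every point within $\pm 10$, and (iii) keep
every non-constant effect non-constant. Condition (iii) is this
package's addition: without it the smallest admissible multiplier can
round a genuinely informative but weaker effect to all-zero while the
AUC bound still holds. If no multiplier satisfies all three, the
AUC-maximising one is used. Adjacent equal-point intervals of
continuous and ordinal effects are then merged (their thresholds
removed — provably score-preserving), and effects rounding to all-zero
are dropped.

*Risk calibration.* A two-parameter logistic regression of the class
on the total score, fitted by Newton iteration with a ridge of
$1/2000$ on the slope so the fit stays finite under complete
separation (intercept unpenalized). The risk table enumerates every
achievable total score. With a single distinct score the profile
degenerates to the prevalence, with a warning.

*Preselection* (optional) screens effects before the main fit: a
linear-kernel SVM (fixed $C = 1$; the soft margin is not tuned here)
on the one-hot expansion gives interval coefficients $\omega$; each
effect is summarised by the trend column $\tilde Z^p \omega^p$; a
cross-validated binomial elastic net on that trend matrix keeps the
effects with nonzero coefficients at the sparsest penalty retaining
`cutoff[1]` of the maximum CV AUC. Screening operates on whole
effects, so it can discard variables whose signal only shows at the
interval level — the same trade-off applies as in the original
formulation.

## Assessment

`assess_model()` reports the Mann–Whitney AUC (ties get half credit;
the trapezoidal area under the reported ROC curve equals it exactly),
accuracy at the risk-0.5 threshold, and the calibration summary: a
weighted least-squares line of empirical versus predicted risk, with
groups formed by distinct predicted risk (equivalently, by total
score — the model's natural bins) and weighted by group size. Group
counts, not inverse variances, are the weights; with small groups the
two can differ. The calibration error
$e = \int_0^1 |(a_{cal}-1)p + b_{cal}|\,dp$ is evaluated in closed
form (one or two triangles).

## The synthetic generator

`ics_truth()` describes a population whose log-odds are an additive
piecewise-constant function of the covariates — the exact model family
a score card can represent — so recovery has a well-defined target and
the Bayes AUC ceiling is computable by Monte Carlo
(`bayes_reference()`). Continuous variables are uniform so percentile
thresholds land at predictable places. The default truth is the
package's recovery benchmark: two step variables (thresholds 0.4 and
0.6, log-odds steps $\pm 1.2$ and $\pm 1.0$ — moderate effects of the
size one sees in single clinical markers) plus three noise variables;
the benchmark trains on $n = 600$ and evaluates on 4,000 held-out
draws, across ten independent replicates. The acceptance script runs
this benchmark with the elastic-net route and fidelity-first tuning
(`cutoff = c(0.75, 1)`), a scale chosen to keep the full experiment in
the order of minutes on one core.

What passing this benchmark does and does not show: the generator
draws independent uniform covariates with exactly piecewise-constant
effects and no label noise beyond the logistic link. Real tabular data
have correlated covariates, smooth effects that a step function only
approximates, missingness (out of scope here — records should be
complete), and class imbalance beyond what stratified CV absorbs.
Recovery on the benchmark therefore validates the machinery —
binning, both solvers, reweighting, pruning, rounding, calibration —
not performance claims on any particular clinical dataset.

## Numerical choices and degenerate inputs

- Interior-point tolerances: relative gap and residuals $10^{-9}$; a
  complementarity-based stop handles degenerate optimal faces where
  the dual iterate jitters after the gap has closed; the best iterate
  by a merit of gap and residuals is returned. Reweighted LPs are
  solved after normalising the row weights (the argmin is invariant),
  keeping the normal equations well scaled even when $\chi$ spans four
  orders of magnitude.
- Coordinate descent: convergence at $10^{-13}$ relative coefficient
  change; the budget bisection stops at $10^{-10}$ on the $\ell_1$
  norm with a final exact rescale onto the budget.
- Constant variables yield a single interval (with a warning) and are
  pruned; a fully constant design yields an intercept-only model whose
  risk is the prevalence.
- Unseen categorical levels at prediction time contribute zero points,
  with a warning.
- Labels may use any two values; the numerically (or lexically) larger
  value becomes the positive class, recorded in the model and used to
  report predicted classes in the original coding.
- Serialization writes 17 significant digits so a reloaded model's
  predictions are bit-identical.

## A worked example

```{r example, eval = FALSE}
truth <- ics_truth()                      # the recovery benchmark truth
d <- make_piecewise_dataset(truth, 600)
prob <- ics_problem(d$x, d$y, method = "en",
                    options = ics_options(seed = 1, cutoff = c(0.75, 1)))
model <- run_ics(prob)
model
test <- make_piecewise_dataset(truth, 4000, seed_offset = 55)
assess_model(model, test$x, test$y, split = "test")
cat(render_scorecard(model, "txt"), sep = "\n")
```

## Known limitations

- The elastic-net route cannot model interactions; the LP route can,
  at higher computational cost (interior-point solves grow with the
  training size and the expanded dimension).
- The automatic complexity rule inherits the bluntness of a single
  cutoff; the tuning curve exists precisely so a user can overrule it.
- Preselection decides at the effect level and can discard variables
  informative only within narrow intervals.
- Missing values are not handled; complete cases are expected.
- The reweighting update for the elastic-net route couples the
  reweighting value to the effective budget (see above); interpreting
  the $a$ grid as a pure sparsity dial is only accurate for the LP
  route.
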