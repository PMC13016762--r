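---
title: "Ancestral state estimation for hierarchical characters on fossil time trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral state estimation for hierarchical characters on fossil time trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`aseval` is a workbench for estimating ancestral states of complex discrete
characters — characters with ambiguous codings, hierarchical dependencies
among states, and non-linear paths of permitted transitions — on
a-posteriori time-scaled fossil phylogenies, and for deciding *which* of the
many defensible analysis set-ups (outgroup, branch lengths, coding
granularity, evolutionary model) to believe. The motivating application is
the evolution of feather morphotypes on the avian stem lineage, where the
literature disagrees about whether filamentous integument arose once or
several times; the machinery is generic.

# The model

A discrete character with $k$ observed states evolves along a rooted tree
with branch lengths in millions of years (myr) under a continuous-time
Markov chain with generator $Q$: off-diagonal entries are transition rates
(events/myr), rows sum to zero, and the probability of change over a branch
of duration $t$ is $P(t) = e^{Qt}$. The likelihood of the tip data is
computed by Felsenstein pruning; marginal ancestral estimates at a node are
the posterior state probabilities integrating over all other nodes.

Rate *templates* describe families of such generators: an integer matrix in
which zero marks a forbidden transition and equal positive indices mark
transitions constrained to share a rate parameter. Three sharing schemes
are provided throughout — ER (one rate), SYM (forward and backward share),
ARD (all rates different) — crossed with seven architectures on the
six-state feather coding:

* **unordered / ordered Mk** — all transitions, or only adjacent steps on
  the complexity chain scales → monofilament → basally joined → central
  filament → pennaceous → asymmetrical pennaceous. The chain order follows
  the developmental-complexity gradient; whether intermediate morphotypes
  may be skipped is unknowable from the data, so the ordered model assumes
  strict adjacency.
* **ED (embedded dependency)** — the hierarchy of binary characters
  (feathers present? if so, increasingly complex elaborations) amalgamated
  into a single character over observable combinations only. The
  qualitative variant (QL) lets a gain land in any dependent configuration
  (a trait is born *with* its properties); the birth–death variant (BD)
  forbids transitions requiring two or more simultaneous trait births,
  while a single loss may cascade (losing the controlling trait removes its
  dependents). For the three-state coding this reduces to the classic
  tail-colour matrices; the extension to the six-state nested chain is this
  package's documented choice, since only the three-state case has a
  published worked example.
* **SMM (structured Markov model)** — the same hierarchy amalgamated over
  the *full* Cartesian product of the binary characters, retaining
  unobserved combinations as hidden states ("absence with a liability
  toward pennaceous"). Only one character may change at a time. `ind`
  makes each character's rates independent of the others' states; `switch`
  gives a dependent character separate parameters for each state of its
  controller. Schemes act per binary sub-character, so ER and SYM coincide
  for SMM templates (a binary character has one symmetric pair); ARD
  separates gain from loss. This is the parameterization that makes the
  coding-2 independent model the two-parameter "one rate per character"
  amalgamation; the exact parameter-sharing of the original switch models
  is not published, so the template is exposed for inspection
  (`template_to_list()`) rather than guessed at silently.
* **HRM (hidden rates)** — observed states duplicated across 2 or 3 latent
  rate categories; within-category transitions get category-specific
  parameter sets, and a state may switch category without changing its
  observed state. Category switches share one parameter per unordered
  category pair under ER/SYM and per ordered pair under ARD — this keeps
  the ER hidden-rates model identifiable and mirrors common hidden-rates
  practice. Counting parameters this way, the 3-category ARD model on six
  states has 96 free parameters; a published account of the same model
  counts 94 (equal to its tip count). The difference lies in conventions
  for the category-switch block; both counts trigger the same AICc
  exclusion below, so no reported quantity depends on it.

The grid of 7 architectures × 3 schemes is `model_grid()` (21 templates);
crossed with three time-scalings it gives the 63 tree/model combinations
the evaluation layer is designed to compare.

# Time-scaling fossil trees

Tips are dated at their first appearance datum (FAD): the oldest plausible
age, the convention of the standard a-posteriori scaling tools (the LAD is
retained in the age table for reporting and simulation realism). Placing
each internal node at the age of its oldest descendant creates zero-length
branches wherever a node and its oldest tip coincide; the two scalers
remove them differently:

* `timescale_equal()` first extends the root age by `root_length`
  (default 1 myr) and then lets zero-length branches take an equal share of
  the first preceding branch of positive length. Two ordering dialects are
  provided because the two reference implementations of this method are
  known to produce different trees from the same input: `basal_first`
  resolves one zero branch at a time from the root toward the tips (each
  taking half its donor), `legacy` spaces each maximal run of zero branches
  evenly over the run plus its donor, visiting runs in cladewise input
  order. The originals' internals are not published; these two dialects are
  documented choices that both satisfy the contract (strictly positive
  branch lengths, tips at their calibration ages, idempotent on their own
  output), not reconstructions.
* `timescale_mbl()` pushes parents back in time, bottom-up, until every
  branch is at least `min_length` (default 1 myr, configurable; the
  published analyses state only the root length).

Ages are on the geological scale (Ma, increasing into the past); branch
lengths are age differences, so trees with extinct tips are not
ultrametric and no code path assumes they are.

# Likelihood, fitting, and marginal reconstruction

Ambiguous codings (`"a&b"`) put unit likelihood on each member state;
`"?"` is an all-ones vector; hidden-state models copy each observed value
onto all of its hidden preimages. Transition matrices use an
eigendecomposition fast path with a dense scaling-and-squaring fallback
(`Matrix::expm`) when the generator is close to defective (condition number
above $10^8$); partial likelihoods are rescaled at every node with
accumulated log factors, which keeps 32-state models finite on branches
spanning 0.1–100 myr.

The root prior defaults to flat over *model* states, with `stationary` and
`fitzjohn` options. The two reference toolchains used for analyses of this
kind default differently here, and the choice measurably moves node
estimates near the root — this is the main obstacle to digit-exact
reproduction of published tables, so the option is explicit rather than
buried.

Rates are fitted by bounded multi-start optimization on the log scale
(L-BFGS-B; bounds $[10^{-9}, 100]$ events/myr; default 10 starts, the
first from a one-change-per-tree-depth heuristic, the rest log-uniform,
all driven by a recorded seed). Hidden-state likelihood surfaces are
multimodal; the multi-start default is deliberately conservative, and
every heavy analysis in the package passes an explicit smaller
`n_starts`/`maxit` suited to its size. AIC is $-2\ln L + 2k$; AICc adds
$2k(k+1)/(n-k-1)$ with $n$ = number of tips, and is flagged undefined
(excluded from AICc rankings, not from bundles) when $n - k - 1 \le 0$.

Marginals are computed by the standard two-pass algorithm: the pruning
pass collects subtree partials, a root-to-tip pass propagates the
likelihood flow from the rest of the tree, and their product (times the
root prior at the root) is normalized per node. Hidden states are
collapsed onto observed states by summation for all reporting. Tip
marginals are available too; known tips are clamped to their observed
vectors by default and re-estimated as unknowns inside cross-validation.
Ties in "highest marginal state" are broken by state order, which affects
only the bookkeeping of the uncertainty metric.

# The evaluation layer

* **Raw uncertainty**: $100\,(1 - \overline{\max_s p_s})$, the mean taken
  over internal nodes only — the metric is about ancestral estimates, and
  tip marginals are mostly clamped observations. Its ceiling is
  $100\,(1 - 1/k)$; `proportion_of_max()` normalizes by it so codings with
  different state counts can be compared.
* **Mutual information**: per node, $\log_2 k - H(\text{marginal})$ bits,
  with the unconditional entropy fixed at $\log_2 k$ (it is set by the
  state space and identical at every node; with six states,
  $\log_2 6 \approx 2.585$ bits is the ceiling), and $0 \log 0 := 0$.
  Totals are sums over internal nodes, each counted once.
* **LOOCV**: for each scored tip — drop it, refit the rates, restore it as
  unknown, estimate its marginal under the saved rates, and score
  $1 - p(\text{true state})$; for a tip whose true coding is an ambiguity
  set, the predicted mass of the whole set counts as correct (consistent
  with "summing the likelihoods of the incorrect states"). Folds refit
  from the full-data MLE as a warm start plus restarts, which is a
  documented speed/stability choice since fold-level strategy is otherwise
  unconstrained; failed folds are flagged and excluded from means with a
  warning. The ingroup variant drops and scores only ingroup taxa, making
  trees that differ in outgroup composition comparable.
* **Weights and averaging**: Akaike weights
  $w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$; error weights
  $(1 - e_i)/\sum_j (1 - e_j)$; model-averaged marginal tables are convex
  combinations per node. `select_generalizable()` keeps combinations
  within 10% (configurable) of the lowest mean LOOCV error.

# Synthetic data

The generator emulates the statistical structure the analysis assumes: a
birth–death tree over 150 myr with extinct (fossil) tips (defaults
birth 0.06, death 0.03 per lineage-myr target ~94 tips), FAD/LAD ranges
drawn uniformly within 5 myr of the true tip ages (wide enough to exercise
zero-length-branch handling), a six-state character simulated under a
low-rate ordered chain (0.02 events/myr, ~3 expected steps per root-to-tip
path) so pennaceous-grade states cluster in derived clades, a configurable
ambiguity fraction (default 10%, half `?` and half adjacent-state sets),
and the earliest-diverging tips marked as outgroup. All randomness flows
from the recorded seed; generators never consume global random state.

What passing tests on these data do **not** show: real morphological
matrices have correlated missingness, non-random fossil sampling, and
coding disagreements between workers; none of these are modeled, so
recovery rates here are upper bounds on what comparable empirical data
could support.

# Problem sizes and numerical choices in the test battery

The suite verifies exactness where exactness is checkable (brute-force
enumeration over all node-state assignments on 4–5-tip trees, to $10^{-8}$;
the two-state cherry closed form across a rate × branch-length grid) and
uses simulation for the statistical claims: ER rate recovery on 200-tip
trees (20 seeds, median relative error ≤ 25%), AICc family ranking over
the 21-model grid on 30-tip trees (20 seeds; AICc-undefined models
excluded, duplicate templates fitted once), and LOOCV preference for the
generating model over a forbidden-transition (ordered-chain)
misspecification on 40-tip trees with short terminal branches (20 seeds) —
the regime in which held-out tips are predictable at all and the forbidden
direct transitions actually occur; on sparser trees or at saturated rates
cross-validation cannot separate the models, which is itself a documented
property of reconstruction-error-based selection on small data. The grid and cross-validation sizes are the package's
own choices to keep the battery re-runnable in minutes on one CPU; the
200-tip size is retained where the claim is about per-parameter accuracy.
Capped optimizer settings (`n_starts = 1`–2, `maxit` 50–200) are used in
these batteries and are part of the reported conditions.

# Known limitations

* Digit-exact reproduction of the published feather tables requires the
  deposited 94-taxon dataset (not redistributable here) *and* matching the
  original toolchain's root-prior and optimizer conventions; residual
  discrepancies should be traced to those conventions via the explicit
  `root_prior` option.
* The ordered six-state chain and the ED/SMM extensions beyond the
  three-state worked example are documented design choices, as is the
  HRM category-switch parameter sharing.
* Joint (max-posterior) reconstruction, stochastic character mapping,
  Bayesian tip dating and polymorphic-state models are out of scope.

# A worked example

```{r, eval = FALSE}
library(aseval)

dat <- fixture_dataset()              # 12-tip synthetic feather-like data
tt  <- timescale_equal(dat$tree, dat$ages)
codes <- recode(dat$codes, 2)         # three-state coding
tpl <- mk_template(3, "SYM", states = attr(codes, "states"))
tm  <- encode_tips(codes, tpl, tt)
fit <- fit_model(tt, tpl, tm, n_starts = 4, seed = 1)
m   <- marginal_ancestral(tt, build_Q(tpl, fit$rates), tm, template = tpl)
raw_uncertainty(m)
mutual_information(m, 3)$total
loocv(tt, tpl, tm, full_fit = fit)$mean_error
```
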