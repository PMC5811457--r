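---
title: "Methods: demographic and stoichiometric analysis of P-limitation feeding trials"
author: "stoichdemo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographic and stoichiometric analysis of P-limitation feeding trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoichdemo)
library(dplyr)
```

## The scientific problem

Phosphorus-limited phytoplankton is poor food for zooplankton grazers, but
for two distinct reasons. The *direct*, stoichiometric reason is elemental:
P-limited algae carry too little phosphorus per unit carbon, so a grazer
assembling P-rich ribosomal machinery runs an elemental deficit. The
*indirect*, non-stoichiometric reasons are everything else a history of
P-limited growth does to a cell — altered biochemistry (e.g. fatty-acid
profiles), thicker cell walls, larger cells — which degrade food quality
even after the elemental deficit is repaired.

A P-supplementation design separates the two with three arms:

* **HP** — algae grown P-replete (molar C:P ≈ 112),
* **LP** — algae grown P-limited (molar C:P ≈ 631),
* **LP+P** — P-limited algae spiked with inorganic phosphate just before
  feeding (molar C:P ≈ 113): HP elemental composition, LP growth history.

The LP+P vs HP contrast then isolates the indirect effect, and the
LP vs LP+P contrast the direct effect. `stoichdemo` implements the full
analysis pipeline for such a trial on a rotifer (*Brachionus calyciflorus*)
grazer: individual-based life-table records, age-classed schedules, the
Euler–Lotka intrinsic rate of increase, serial-transfer census growth
rates, morphometric volumes, molar C:N:P ratios, and the decomposition of
every trait response into its direct and indirect components.

## The models and estimators

### Life-table schedules from interval-censored events

Individuals are checked every `w` = 2 h; an event is discovered at the
first check at or after its true time, so all recorded times are rounded
*up* to the grid. Age class *j* spans ages $((j-1)w,\; jw]$: an event
recorded at a check belongs to the class ending at that check, because it
happened at some point since the previous one.

Survivorship is product-limit over classes,
$l_{j+1} = l_j\,(1 - d_j / n_j)$, with $l_1 = 1$, where $d_j$ are deaths
recorded in class $j$ and $n_j$ the individuals at risk entering it.
Censored individuals (male-egg producers, horizon-truncated records,
completed monitoring) leave the risk set without counting as deaths —
standard right-censoring, the defensible default where the field protocol
is silent. Fecundity $m_j$ counts *hatched neonates* (not laid eggs) per
individual at risk in class $j$, scored at hatching. Counting at hatch
makes egg mortality reduce $m_x$, which is how it actually reduces
population growth; it also makes the total reproductive output
$\sum_j m_j n_j$ invariant to the class width, a property the test suite
checks.

Both denominators use the current risk set (survivor-based); an
initial-cohort denominator can be recovered from the reported `n_risk`
column if wanted.

### Intrinsic rate of increase

The Euler–Lotka equation
$$1 = \sum_x l_x m_x e^{-r x}$$
defines $r$ implicitly. Ages enter at class midpoints (unbiased if events
are uniform within a class) and are converted to days, so $r$ is per day.
The left side is strictly decreasing in $r$ whenever some reproduction
occurs at a positive age, so the root is unique; `euler_lotka_r()` finds
it by bracketed bisection starting from $[-5, 5]\ \mathrm{d^{-1}}$ with
automatic bracket doubling, derivative-free and robust. The residual
tolerance defaults to $10^{-10}$; `stats::uniroot()` serves as an
independent oracle in the tests. Sign behaviour is pinned to the net
reproductive rate $R_0 = \sum l_x m_x$: $r>0 \iff R_0>1$.

LP records are monitored only for 62 h while HP and LP+P records run to
the fourth neonate. Schedules from truncated records are solved as-is and
flagged `truncated` in the output: the missing late-life reproduction
biases LP's $r$ downward, and since the LP arm also reproduces latest,
the truncation hits it hardest. The trial protocol computes $r$ for all
arms despite unequal horizons; we reproduce that and surface the flag
rather than invent a correction.

### Census growth rate

Serial-transfer units restart each day at $N_0 = 10$ individuals; with
counts $N_t$ after each 24-h period the per-day rate is
$R = (\ln N_t - \ln N_0)/t$ with $t = 1$ d, averaged per unit over the
final 16 scored days (days 7–22 of a 22-day series), the window over
which growth has stabilised. Days ending at zero cannot enter a
log-ratio; they are excluded and counted in `n_excluded`.

### Volumes and somatic growth

Body volume at first reproduction uses
$V_b = \pi L_b (W_b/2)^2$ and egg volume the ellipsoid
$V_e = \tfrac43 \pi (L_e/2)(W_e/2)^2$, dimensions in µm. Somatic growth is
$(V_b - V_{e,\mathrm{first}})/\Delta t$ over the maturation interval.
Where an individual lacks an egg measurement its replicate-mean egg
volume is substituted and the row flagged — this keeps replicate means
estimable; whether the original protocol did per-individual or mean
substitution is unknowable from the trial report, so the flag preserves
the audit trail.

### Stoichiometry

Molar ratios use atomic masses C 12.011, N 14.007, P 30.974 (five
significant figures, fixed constants — consistency matters more than the
fifth digit). Pooled samples (150 individuals) divide through to
per-individual content.

### The decomposition

For each trait with treatment means $\bar y_{HP}, \bar y_{LP+P},
\bar y_{LP}$:

$$\text{indirect} = 100\,\frac{\bar y_{LP+P} - \bar y_{HP}}{\bar y_{HP}},
\qquad
\text{direct} = 100\,\frac{\bar y_{LP} - \bar y_{LP+P}}{\bar y_{LP+P}},$$

i.e. each contrast is scaled by its own comparison baseline. The two
compound exactly: $(1+i/100)(1+d/100) = \bar y_{LP}/\bar y_{HP}$.
Mortality-type traits are decomposed on survival $=1-$ mortality: a
zero-mortality baseline (the HP arm, typically) would otherwise make the
relative difference undefined, and the survival convention reproduces the
canonical egg-mortality result (indirect 0.0%, direct −23.1% for
mortalities 0%, 0%, 23.1%). An equally self-consistent alternative —
sign-flipped percentage-point differences — is *not* used; the survival
convention is the one that compounds.

Trait means are computed per chemostat replicate first and then averaged,
because the phytoplankton chemostats, not the individual animals, are the
true unit of replication. Scenario labels classify each trait: **I**
direct-only, **III** indirect-only, **II** both. Empirical components are
never exactly zero, so classification needs a tolerance (default 5
percentage points, user-settable).

Uncertainty comes from a percentile bootstrap that resamples chemostat
replicates with replacement within treatment — the resampling respects
the replication unit. With only 5 replicates per arm, percentile
intervals undercover noticeably (simulated coverage ≈ 0.88 at 5
replicates, rising to ≈ 0.93 at 15 against a nominal 0.95); the test
suite therefore checks coverage at 15 replicates against nominal minus a
small-sample allowance, and 5-replicate intervals should be read as
approximate. Mixed-model or ANOVA inference on the exported
replicate-level tables is deliberately left to downstream tools.

## The synthetic-data generator

No individual-level data are deposited for trials of this kind, so the
package ships a generator that emulates the design: 3 treatments × 5
chemostat replicates × 15 individuals for the life table (225 units), 5
individuals per replicate for morphometrics (75 units), 3 clones × 3
treatments × 5 replicates for the census (45 units), 2 clones for the
elemental cohort (30 pooled samples).

Mechanics, chosen as the simplest models consistent with the reported
aggregates:

* Latent maturation, inter-egg and egg-development times are Gaussian
  around treatment means, truncated at zero; observed times are the
  first 2-h check at or after the latent time (rounded up, because an
  event is first *seen* at the following check).
* Adult death is a per-check Bernoulli hazard; egg death a single
  Bernoulli at laying; a male egg right-censors its mother at laying.
* HP and LP+P individuals are monitored to the fourth hatched neonate,
  LP individuals for 62 h.
* Census counts are lognormal around $N_0 e^{r}$ (mean-zero noise on the
  log scale keeps the per-day log-ratio unbiased for the configured
  rate), rounded to integers and floored at zero.
* Algal C:P batches are Normal around the treatment centre with sd
  $\mathrm{SE}\times\sqrt{25}$, 25 being the default number of batch
  measurements behind a reported treatment SE (5 replicates × 5
  sampling occasions).

Each experimental unit draws from its own RNG substream derived from the
master seed and a stable hash of the unit's identity, so shrinking the
design never changes a retained unit's data and identical seeds give
byte-identical output.

Treatment centres for algal C:P (112 ± 2.6, 631 ± 14.9, 113 ± 2.7 SE),
egg mortality (0.231 in LP, 0 elsewhere) and the monitoring rules are the
trial's stated conditions. Trait means (maturation, inter-egg interval,
egg development, sizes, elemental content) are published only graphically
for this kind of trial, so the defaults are plausible values for
*B. calyciflorus* at 23 °C chosen once to reproduce the qualitative
ordering — HP fastest, LP+P intermediate, LP slowest — and ratio patterns
typical of such trials; they are illustrative, not calibrated to any
digitised figure.

What the generator does *not* emulate: mechanistic algal physiology
(C:P is sampled, not grown), sexual dynamics beyond male-egg censoring,
observer error in counts or measurements, and any correlation between an
individual's traits (a fast maturer is not made a fast layer). Passing
tests therefore demonstrate that the estimators recover known parameters
under the design's censoring and rounding structure — not that real
rotifer data are this clean.

## Numerical choices and degenerate inputs

* Bisection: initial bracket $[-5,5]\ \mathrm{d^{-1}}$, doubled up to 60
  times, 200 iterations max; residual tolerance $10^{-10}$.
* $R_0=0$ raises a no-reproduction error; reproduction at age 0 (possible
  only with pathological schedules, not grid data) is rejected because the
  Euler–Lotka sum would not decrease in $r$.
* Grid rounding uses a $10^{-9}$-hour guard so latent times already on
  the grid stay put.
* Egg production rate needs at least two laying events; otherwise it is
  `NA`, never an error. Unresolved and male eggs are excluded from
  egg-mortality denominators so truncation does not bias the proportion.
* Readers are strict by default and list every offending row; the lenient
  mode drops and reports them.
* Zero reference means in the decomposition yield `NA` components with a
  warning (mortality traits avoid this by the survival convention).

## Problem sizes used by the test suite

The suite exercises the estimators at sizes chosen to keep Monte-Carlo
error well below the assertion tolerances: 1000-individual cohorts for
parameter recovery (compared to analytic grid-rounded expectations within
3 standard errors), 1000 random schedules for the Euler–Lotka residual
bound, 1000 random mean triples for the decomposition identities, 200
simulations × 199 draws for bootstrap coverage, and ≥ 10 000 simulated
eggs for the egg-mortality recovery bound.

## Known limitations

* LP intrinsic rates are biased low by the 62-h horizon (flagged, not
  corrected); comparisons of $r$ across arms inherit that bias, as in the
  original protocol.
* Percentile bootstrap intervals from 5 replicates undercover (see
  above).
* The generator's trait means are illustrative; only C:P centres,
  mortality rates and the design structure are pinned to stated values.
* `mx` uses the survivor-based denominator by default; the alternative
  (initial-cohort) convention can be derived from the emitted counts but
  is not the default path.
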