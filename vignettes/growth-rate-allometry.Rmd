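---
title: "Methods: maximum-growth-rate allometry and its diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-growth-rate allometry and its diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomax)
library(dplyr)
```

`allomax` implements the statistics behind comparative studies of maximum
somatic growth rate: how the peak rate of mass gain scales with body size
across vertebrate groups, and whether those scalings can be used to infer
metabolic state. This vignette records the models, the tunable parameters
and their defaults, what the synthetic-data generators emulate, the
numerical choices, and the design decisions taken where the problem was
genuinely open. It states no empirical result that the test suite and the
acceptance script do not themselves compute.

## The dimensionless growth framework

Dimensional analysis puts every determinate growth trajectory in the form

$$ m(t) = M f(s) + M_c, \qquad s = k (t - t_c), $$

with asymptotic mass $M$ (g), growth constant $k$ (1/day), inflection-age
offset $t_c$ (day), and a dimensionless sigmoid $f$. The three standard
choices are

* logistic: $f(s) = 1/(1 + e^{-s})$,
* Gompertz: $f(s) = e^{-e^{-s}}$,
* von Bertalanffy: $f(s) = (1 - e^{-s})^3$.

Three constants summarise each model: $C = \max_s f'(s)$, the inflection
mass fraction $d = f(s^\*)$ at the maximiser, and $D = C/d$. By the chain
rule the peak growth rate is $G_{\max} = M k C$ (g/day); the mass-specific
peak rate is $k_C = G_{\max}/M = kC$ (1/day, the fractional growth per day
at peak); body mass at maximum growth is $\mathrm{BMatMG} = M d$; and the
alternative normalisation is $k_D = G_{\max}/\mathrm{BMatMG} = kC/d = kD$.

```{r}
model_constants(c("logistic", "gompertz", "von_bertalanffy"))
```

The closed forms are $C = \{1/4, 1/e, 4/9\}$ and $d = \{1/2, 1/e, 8/27\}$,
so the inflection sits at 50%, 37% and ~30% of asymptotic mass
respectively, and $D = C/d = \{1/2, 1, 3/2\}$. Note that $D$ for the
logistic is $1/2$ — it is fixed by the identity $D = C/d$ that also gives
the Gompertz and von Bertalanffy values, and the package asserts in its
tests that the closed forms agree with direct numerical maximisation of
$f'(s)$ to $10^{-6}$ relative. The von Bertalanffy form is a mass sigmoid
only for $s > 0$ (its cube is negative below $t_c$), so all numerical work
on that model is restricted to the positive-$s$ growth domain.

`time_to_fraction()` inverts $f$ to give the time spent between two mass
fractions. Closed-form inverses are used for the logistic
($s = \mathrm{logit}\,p$) and Gompertz ($s = -\log(-\log p)$); for von
Bertalanffy the root is bracketed and bisected to $10^{-9}$ relative (the
closed form exists and serves as the test oracle). One consequence worth
keeping in mind when interpreting $t_M = 1/k_C$: real trajectories do not
stay at peak rate, so the time from 1% to 90% of $M$ is about $1.7\,t_M$
for the logistic model.

## Curve fitting for sparse series

`fit_growth_curve()` estimates $(M, k, t_c)$ by least squares with $M_c$
fixed at 0 (the reanalysed compilations do not use a mass offset; supplying
one is a data-preparation step, not a fitting option). Sparse fossil series
have genuine local minima, so the fit is multi-start: seven starting points
derived from the data span ($M_0 = 1.05 \times$ max mass, $k_0$ from the
log-slope across the series, $t_{c,0}$ at the age midpoint, with
multiplicative jitter), each run through Levenberg–Marquardt
(`minpack.lm::nlsLM`) and polished by Nelder–Mead on $(\log M, \log k,
t_c)$ with relative tolerance $10^{-10}$ on the objective; the smallest RSS
wins. Two constraints mirror the practices used for fossil taxa whose
specimens span only part of the lifespan: `fix_asymptote` pins $M$ to a
literature value (removing it from the free set), and `add_neonate`
appends a hypothetical neonate point flagged in the output. The neonate
pair is always explicit user input — the empirical neonate-mass formula
used by one source study is not restated in accessible form, and inventing
an equation would be worse than requiring one.

The generator `generate_age_mass()` makes the matching synthetic series:
ages spaced over a span given in units of $1/k$ around the inflection,
multiplicative Gaussian noise on mass. Truncating the span to
pre-inflection ages reproduces the extrapolation problem: the test suite
shows that free-asymptote fits on such series misestimate $M$ badly
(median error above 10% at 2% noise) while fixed-asymptote fits keep $k$
estimable — which is exactly why the constraint is used, and why rates
derived under it inherit the assumed asymptote.

## Log-log regression and the shear transformation

All allometric fits are ordinary least squares on $\log_{10}$ coordinates
(base 10 throughout: slopes are base-invariant, intercepts are reported in
log10 units). Weighted fits give each taxon total weight 1 split equally
over its rows, implemented as weighted least squares; R² for weighted fits
is $1 - \mathrm{wRSS}/\mathrm{wTSS}$ about the weighted mean, and
parameter intervals use the $t$ distribution with $n-2$ degrees of freedom
(the convention adopted here; a normal-quantile variant would differ only
in the third decimal at the compilation sizes involved). Phylogenetic
regression is deliberately out of scope.

Because $G_{\max} = M k_C$, the choice of dependent variable is a shear of
the log-log plane, $(x, y) \mapsto (x, x + y)$. Fitting both ways on the
same points gives slopes differing by exactly 1, identical intercepts,
identical residuals and identical interval widths — but different R²,
since the shear adds the regressor's variance to the total sum of squares.
Algebraically, R² rises under the shear precisely when the fitted
$G_{\max}$ slope exceeds $1/2$, i.e. $S_{xx}(1 + 2\hat b_{k_C}) > 0$. That
inequality is a property of the fitted slope, not a theorem about all
data: with a true $k_C$ slope near $-0.25$, sampling noise can push
$\hat b$ below $-1/2$ in small, narrow-range samples. The package's
1000-dataset property test therefore draws from the regime real
compilations occupy — 60–100 species over 4–5 mass decades with log-scatter
up to 0.3 and true $G_{\max}$ exponents 0.66–0.8 — where the event has
negligible probability; the shear identities themselves (slope difference,
residuals, CI widths) are checked to $10^{-12}$ unconditionally.

Two bands accompany each fit. The confidence band constrains the mean
response — the group's central tendency; the single-prediction band
constrains one new observation and is the statistically correct region for
classifying an individual species. The prediction band contains the
confidence band pointwise, and the contrast between the two is the
ecological fallacy in geometric form. Band segments beyond the fitted mass
range are computed but flagged `extrapolated`.

`fixed_slope_adjust()` performs the one-dimensional reduction: with a fixed
exponent $b$ (0.75 by convention, 0.66 as the alternative), every rate is
adjusted to a 1 g body mass, $\log_{10} r - b \log_{10} M$, and group
distributions of the adjusted values are compared directly; the reported
overlap interval is the intersection of per-group ranges.

## Overlap and classification diagnostics

Species-level overlap is measured three ways, from tightest to loosest:

1. **Nearest regression line** (`nearest_line_classification()`):
   perpendicular Euclidean distance in log-log coordinates by default
   (vertical distance as an option — the choice is not determined by the
   problem, so both are provided); ties go to the point's own group when it
   is among the tied candidates, otherwise to the first group in order, and
   are logged.
2. **Convex hulls** (`hull_membership_matrix()`): the hull is the region a
   group's species actually occupy; membership counts of each group's
   points in each group's hull, with boundary points counted inside at a
   tolerance of $10^{-9}$ log units (boundary handling is unstated in the
   sources; counting boundaries as inside is the inclusive choice and the
   tolerance is far below data precision). Hulls come from
   `grDevices::chull`; degenerate sets (fewer than three non-collinear
   points) are segments or points, with membership by distance at the same
   tolerance. The test suite checks all membership counts against a
   brute-force supporting-line oracle.
3. **Residual parallelograms** (`residual_parallelogram()`): the regression
   line shifted through the extreme residuals over the group's mass range;
   contains the hull by construction, hence yields at least as much
   overlap.

`pooled_overlap()` applies the same machinery after pooling all points into
endotherm/ectotherm groups. Its overlap fraction is the rasterized hull
intersection area divided by the union area on a 512×512 grid over the
joint bounding box — a convenience metric (the sources print no area), so
grid resolution only needs to be fine enough for two stable digits.

## Curvature analysis by AICc

Whether log-log growth allometry is a straight line at all is tested by
fitting the seven intercept-containing polynomial families in powers of
$x = \log_{10} M$ — linear $\{x\}$, quadratic1 $\{x, x^2\}$, quadratic2
$\{x^2\}$, cubic1 $\{x, x^2, x^3\}$, cubic2 $\{x, x^3\}$, cubic3
$\{x^2, x^3\}$, cubic4 $\{x^3\}$ — and ranking by the Gaussian
small-sample corrected AIC,

$$ \mathrm{AICc} = n \log(\mathrm{RSS}/n) + 2k + \frac{2k(k+1)}{n-k-1}, $$

with $k$ counting coefficients plus one for the residual variance, and
weighted RSS when taxa carry weights. The seven labels are mapped to the
seven nonempty subsets of $\{x, x^2, x^3\}$; the mapping is overridable via
`poly_family()` since the source studies' exact label definitions are in an
inaccessible supplement. $\Delta\mathrm{AICc} = 0$ marks the best model
(exact ties broken toward fewer parameters and flagged);
$\Delta\mathrm{AICc} < 2$ marks strong support. One selection subtlety is
documented by the tests rather than assumed: the probability that a
higher-order model takes $\Delta\mathrm{AICc} = 0$ under a linear truth is
*not* monotone in $n$ — the correction term already crushes complex models
at $n = 10$, and AIC-type selection is not consistent as $n$ grows — so the
suite asserts strong support for the generating model at every sample size,
and $\ge 90\%$ family recovery at $n = 40$ with low noise.

## Growth–metabolism tests

Metabolic compilations measure BMR (W) at bench mass $M_{met}$, usually
below adult mass. Assuming the interspecific scaling also holds through
ontogeny, `bmr_adjust()` projects to adult mass,
$\mathrm{BMR}_{adj} = \mathrm{BMR} (M/M_{met})^{0.75}$ — an assumption, not
a fact, which is why the exponent is an argument. Records with
$M_{met} > M$ are kept with a warning; real compilations contain them.

`direct_test()` evaluates the proportionality claim
$\mathrm{BMR} = c\,G_{\max}$ record by record and reports the worst
over-prediction factor, worst under-prediction factor, and their product.
The constant $c$ (default 0.6, the published value) absorbs the unit
bridge between watts and g/day exactly as the source compilation used it;
the factors are invariant to any common rescaling of BMR and $c$, so the
bridge does not affect them. Ectotherm temperature standardisation (27 °C)
is assumed already applied in the input.

`transitivity_report()` fits the three pairwise regressions $k_C \sim M$,
$\mathrm{BMR} \sim M$, $\mathrm{BMR} \sim k_C$. Composing the first two
power laws into a growth–metabolism law treats statistical correlations as
equalities — the fallacy of averages. Correlation is not transitive: when
the two log-scale noises are independent, the generating model implies
$R^2(\mathrm{BMR}, k_C) = R^2(\mathrm{BMR}, M) \cdot R^2(k_C, M)$, which is
small whenever the marginals are moderate.

### Generator calibration for the non-transitivity demonstration

`generate_metabolic()` draws
$\mathrm{BMR} = a_1 M^{b_1} 10^{\epsilon_B}$ and
$k_C = a_2 M^{b_2 - 1} 10^{\epsilon_G}$ with independent noises over five
mass decades, defaults $b_1 = b_2 = 0.75$ (Kleiber-type scaling for both).
The scatter defaults are `sd_bmr = 2.0` and `sd_growth = 0.7` log10 units.
These are chosen from the closed-form algebra above, not fitted to any
compilation: the demonstration target is the regime in which the
cross-correlation falls below a third of either marginal, and since
$R^2_{cross} = R^2_1 R^2_2$ under independent noises, that requires both
marginal $R^2$ below $1/3$. With $\mathrm{Var}(x) = 25/12$ over five
decades, the defaults put $R^2(\mathrm{BMR} \sim M) \approx 0.23$ and
$R^2(k_C \sim M) \approx 0.21$, hence $R^2(\mathrm{BMR} \sim k_C) \approx
0.05$, with enough margin that a seeded draw of a few thousand records
verifies all three against the closed form. The scatter is therefore
deliberately larger than empirical BMR compilations show — the generator
isolates the shared-mass-driver geometry rather than mimicking compilation
noise. Real compilations differ in a second, stronger way the generator
does not emulate: their observed cross-correlation sits far below even the
product of the marginals, because group structure and measurement
heterogeneity add variation that shared mass dependence cannot explain. A
passing demonstration here therefore shows the geometry of the fallacy of
averages, not the full weakness of the empirical growth–metabolism link.

```{r}
set.seed(1)
met <- generate_metabolic(10^runif(2000, 0, 5), seed = 1)
transitivity_report(met)
```

## The ecological-fallacy bootstrap

The scalar analogue: adult human body mass, with printed sex-specific
means 83.1 kg (male) and 72.0 kg (female). Given a sample known to be all
one group, `minimal_group_size()` finds the smallest $N$ at which
bootstrap classification succeeds at the required confidence for every
hypothesis. The underlying microdata are not bundled, so the shipped
distributions are explicit stand-ins: `trait_normal()` takes the printed
means with a user-supplied spread, and `trait_empirical()` accepts any
sample. Consequently the published minimal sizes are not reproduction
targets; the reproducible properties are (i) agreement with the
normal-theory requirement $N \ge (2\sigma z_{0.95}/\Delta)^2$ for normal
stand-ins, (ii) $N = 1$ for disjoint distributions, and (iii) a strictly
larger $N$ when an equal-probability mixed group is admitted as a third
hypothesis — the ordering that matters, since it shows how weakening the
composition constraint erodes classification until, with unknown
composition, it becomes impossible for any $N$.

The default procedure (the sources say only that the calculation is a
simple bootstrap): resample $n$ values from the true hypothesis, classify
by nearest hypothesis mean (a likelihood-ratio rule is available for
normal hypotheses), require the per-hypothesis correct rate to reach the
confidence level over 10,000 replicates, and search by doubling then
bisection. The mixture hypothesis draws each value's source group
independently with probability 1/2 and carries the equal-weight mixture
mean. An accuracy plateau below the confidence level is reported as
unattainable rather than searched forever. All searches are
seed-deterministic.

## Synthetic rate tables and the default scenario

`generate_group()` draws $\log_{10} M$ uniformly over a group-specific
range (uniform-in-log matches the log-log design; masses enter the
analysis only through $\log M$), puts lognormal scatter on $k_C$ about a
power law, and derives every other rate column exactly — so the identities
$G_{\max} = k_C M$, $\mathrm{BMatMG} = dM$, $k_D = k_C/d$ hold without
independent noise, as they do for rates derived from one fitted curve.
`default_scenario()` stacks four groups in the published geometry: two
endothermic groups with higher mass-specific intercepts and two
ectothermic groups with lower ones, scatter 0.4 log10 units, intercepts
set so a 10 kg mammal-like species has $k_C \approx 0.005$/day and the
endotherm–ectotherm gap is about 1.3 decades — enough separation for the
group regressions to differ cleanly while the hulls overlap. The
generators emulate the statistical structure of compilations (power laws,
lognormal scatter, group-specific mass ranges) and none of their
biological structure (no phylogenetic covariance, no behavioural
subgroups, no measurement heterogeneity); green tests certify the
statistical machinery, not conclusions about real taxa.

## Problem sizes and numerical choices

The shipped test suite uses 1000 datasets for the shear identities, 100
grouped datasets against the brute-force hull oracle, 200 seeds each for
CI coverage and model-family recovery, a few thousand records for the
transitivity closed-form match, and bootstrap searches at 2000–4000
replicates; the whole suite runs in about a minute on one CPU, and the
sizes were chosen so Monte-Carlo error is several times smaller than every
asserted margin. Remaining numerical conventions, collected: boundary
tolerance $10^{-9}$ log units for hull membership; nearest-line tie
tolerance $10^{-12}$; growth-fit convergence $10^{-10}$ relative on RSS
with seven starts; bisection to $10^{-9}$ relative for the von Bertalanffy
inverse; AICc inadmissible (NA) when $n \le k + 1$; rank-deficient
polynomial designs are an input error naming the cause; all randomized
stages take explicit seeds and the pipeline bundle records its seed and a
hash of its inputs.

## Known limitations

* OLS only; phylogenetic non-independence is out of scope by design.
* Point estimates of rates feed the allometry; fit covariance is not
  propagated.
* The corrected fossil compilations and the BMR compilation are not
  distributable with the package; `scripts/validate-external.R` reproduces
  the published full-data statistics when those tables are supplied in the
  documented schemas, and the corresponding reproduction test in the suite
  stays red until a transcription is provided.
* The hull overlap fraction is a grid approximation and the bootstrap
  search resolves $N$ only to Monte-Carlo precision near the confidence
  threshold.
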