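---
title: "Statistical models and design choices in certifyr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical models and design choices in certifyr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(certifyr)
```

`certifyr` implements the statistical chain of a reference-material
certification: homogeneity of the bottled batch, stability over the planned
lifetime, evaluation of the collaborative study, assembly of the uncertainty
budget, and monitoring after release.  This vignette is the package's own
account of the models, the defaults, and the places where a genuine design
choice had to be made.

## Homogeneity: nested-design ANOVA

The homogeneity study measures the property in N bottles, n times each,
under repeatability conditions.  A one-way analysis of variance partitions
the dispersion into mean squares between and within bottles.  The
between-bottle standard deviation is

$$ s_{bb} = \sqrt{\frac{M_{between} - M_{within}}{n_0}}, $$

with the effective replicate count
$n_0 = (N_{tot} - \sum n_i^2/N_{tot})/(N-1)$ for unbalanced designs
(reducing to $n$ when balanced).  When $M_{within} \ge M_{between}$ the
between-bottle effect cannot be distinguished from repeatability noise;
`evaluate_homogeneity()` then sets $s_{bb} = 0$ and flags the case as
*masked*.  In that situation the largest between-bottle variation that the
repeatability could hide,

$$ s_{bb,min} = \sqrt{M_{within}/n_0}\,\left(2/df_{within}\right)^{1/4}, $$

is the honest lower bound on what the study can exclude, and the budget
contribution `u_bb` is defined as $\max(s_{bb}, s_{bb,min})$ — so a
perfectly homogeneous-looking batch still carries the uncertainty its study
design cannot rule out.  Both quantities are reported relative to the grand
mean, in percent.  The boundary case $M_{between} = M_{within}$ is treated
as masked; this is the conservative reading and changes nothing
numerically ($s_{bb} = 0$ either way at the boundary).  The ANOVA F test
and its p-value are computed and exported alongside, although the
dispersion measures, not the test, drive the budget.

## Stability: drift model and accelerated (Arrhenius) analysis

The classical study regresses dated measurements on elapsed months.  The
calendar axis is normalized as `months = (date − first date)/365.25 × 12`,
so a study re-encoded on a monthly grid (reference day, mid-month for
half-month samples, and so on) reproduces its intended 0, 0.5, 1, ... month
axis to within calendar granularity (a 14-day offset maps to 0.46 months).
Whether or not the slope differs significantly from zero, the contribution

$$ u_{stab} = |t_{cert} \cdot s(b_1)| $$

is available for transfer, where $t_{cert}$ is the planned lifetime in
months.  It scales exactly linearly in $t_{cert}$.  The transfer into the
budget uses the relative form, consistent with all other budget terms.

The accelerated study stores samples at several temperatures.  For each
stressed level the log-ratio of the measurements to the mean of the
reference level (the coldest temperature, assumed inert) is regressed on
elapsed months; first-order kinetics makes the negative slope the effective
rate $k_{eff}(T)$.  Levels with fewer than two time points, or whose rate
estimate is non-positive (no observable degradation), are excluded from the
subsequent fit with a recorded reason rather than entering as $|slope|$ —
a negative rate estimate is evidence of noise, not of degradation, and
$\ln k$ would be undefined.  The included rates enter an unweighted OLS fit
of $\ln k$ on $1/T$ (kelvin); the activation energy is $E_a = -bR$.
Weighting by $1/se^2$ was considered and rejected as the default: with the
3–5 levels typical of such studies the weights are themselves noisy, and
the unweighted fit is the simpler defensible choice.

Prospective shelf life at storage temperature T converts the rate into the
time after which the accumulated first-order loss exhausts the relative
uncertainty budget: $months = (U_{abs}/\mu_c)/k^*$.  By default $k^*$ is
taken from the upper bound of the *prediction* interval of $\ln k$ at
$1/T$ (95 %), the conservative reading of an uncertainty band on a future
rate; the point-estimate variant is a switch away.  Temperatures outside
the studied range are refused — the Arrhenius line is an interpolation
device here, not a license to extrapolate.

## Certification study: the test battery

Laboratory means (every laboratory weighted equally) are screened with
tests of normality (Lilliefors-corrected Kolmogorov–Smirnov, standardized
third- and fourth-moment tests), variance homogeneity (Bartlett),
compatibility (Scheffé simultaneous pairwise bounds), deviating means
(single and double Grubbs, Dixon) and deviating variances (Cochran).
Verdicts follow the convention of interlaboratory practice: significant at
5 % but not 1 % is a *straggler*, significant at 1 % an *outlier*.  A
verdict never removes a laboratory: exclusion is an explicit, ordered user
decision, excluded laboratories keep their data, and re-running the battery
after re-inclusion reproduces the original results exactly.  Because one
extreme laboratory inflates the spread against which the others are judged,
a second, milder outlier often becomes significant only after the first has
been excluded — which is why the battery is designed around sequential,
user-driven exclusion rather than one-shot screening.

Critical values:

* **Single Grubbs** and **Cochran** use exact closed forms.  The Cochran
  form $C_{crit} = [1 + (N-1)/F_{1-\alpha/N}(\nu, (N-1)\nu)]^{-1}$ is valid
  for any number of laboratories, removing the usual N ≤ 30/40 table limit.
  With unbalanced replicate counts the minimum replicate degrees of freedom
  is used, which is conservative, and a warning is raised.
* **Dixon** (variant r10/r11/r21/r22 selected by N, both ends always
  examined) and **double Grubbs** (SS-ratio of the sample with the two most
  extreme values at one end removed) use critical tables calibrated once by
  Monte-Carlo simulation (2×10⁵ standard-normal replicates per N, fixed
  seed).  The Dixon values are therefore *two-sided* — null quantiles of
  the larger of the two one-ended ratios — matching how the battery applies
  the test; they agree with the published two-sided tables where those are
  printed.  The test suite cross-checks both tables against fresh
  simulations, and beyond N = 40 the double-Grubbs value falls back to an
  on-the-fly deterministic simulation.
* The moment-based normality statistics are the standardized sample
  skewness and excess kurtosis referred to the standard normal; the KS test
  applies the Lilliefors correction (parameters estimated from the data).
  Both choices are labelled in the output.

The Nalimov test is deliberately absent: its commonly tabulated critical
values are a historical misreading, and the defensible version of the
procedure is already covered by the Grubbs test.

## Uncertainty budget and presentation rounding

The certified value $\mu_c$ is the unweighted mean of the included
laboratory means; its characterization uncertainty is
$u_{char} = sd(\text{lab means})/\sqrt p$ relative to $\mu_c$ (the plain
standard uncertainty of a mean of p equally weighted values — no
$p-1$ refinements).  Transferred terms (`u_bb`, optionally `u_stab`, a
user-supplied `u_rep` for which no formula is imposed) combine as a root
sum of squares, expand with $k$ (default 2), and are rounded for
presentation following the DIN 1333 convention: the rounding place is the
position of the first significant digit of $U_{abs}$, one further place
when that digit is 1 or 2 (so 0.1686 presents as 0.17, keeping two
significant digits, while 0.41 presents as 0.5); the uncertainty always
rounds **up**, the value half away from zero at the same place.  A digits
override preserves the user's authority over the certificate entry.

## Post-certification monitoring

Quick control: the SK criterion compares the monitoring mean against the
certified value, $SK = |\mu_c - \mu_m|/\sqrt{u_c^2 + u_m^2}$ with
$u_c = u_{com}\,\mu_c$ (unexpanded) and $u_m = s/\sqrt m$; the material
passes while $SK < k$.  The denominator uses the two *uncertainties* — a
rendering of this criterion with the means themselves under the radical
circulates, but is dimensionally inconsistent and is not implemented.
Whether $u_m$ should be the standard uncertainty of the mean or the raw
spread is arguable for small m; the mean-based form is the default and the
raw-sd form is exposed as an option.

Long-term stability (LTS): monitoring values regress on months since
certification, and the intercept is reported with the offset adjustment
$b_0' = b_0 + \mu_{LTS} - \mu_c$ between the mean of the recorded data and
the certified value, as conventional in this workflow; for an unbiased
monitoring laboratory ($\mu_{LTS} \approx \mu_c$) the adjustment vanishes.
Shelf life is the earliest non-negative month at which the adjusted line —
or, for the stricter estimate, its 95 % confidence band — leaves
$\mu_c \pm U$.  The point-line crossing is solved analytically; the band
crossing is found by bracketing on a monthly grid and bisection to 10⁻⁶
month, because the band edge is not linear in time.  A flat line whose band
stays inside the interval up to the search horizon (100 years) returns an
unbounded sentinel (`Inf`).  Monitoring data are append-only: dates and
values are sealed with a checksum at import, only comments are editable,
and any out-of-band modification is rejected by every downstream
computation.

## Session persistence and templates

All imported tables, the ordered exclusion record, transferred terms, k,
rounding override and file provenance live in one session object that
serializes to versioned JSON with a SHA-256 payload checksum; loading
verifies the version and checksum and reproduces the saved state exactly
(numbers at full IEEE precision).  JSON was chosen over a binary container
deliberately: the session is an audit artifact and should be inspectable.

The spreadsheet templates are tidy long-format sheets (header row, one
record per row, a key/value metadata sheet where needed) and exist in two
byte-equivalent serializations, `.xlsx` and `.csv` (metadata as leading
`# key: value` lines).  The package writes workbooks with a minimal
built-in SpreadsheetML writer (inline strings, uncompressed container), so
templates and fixtures can be produced without any external spreadsheet
dependency; `readxl` handles reading.  Laboratory identity comes from the
`Lab` metadata key when present, otherwise from the sanitized file-name
stem — multi-file import keeps each expert laboratory's workbook, and its
name, intact.  The monitoring template's uncertainty declaration is
converted to an absolute single standard deviation as: `1s` as is, `2s`
halved, `1sx`/`2sx` scaled by the certified value (and halved), and `CI`
halved under the interpretation of a k = 2 expanded half-width — the
interval's construction is not recorded in the template, so this
interpretation is flagged in the imported metadata rather than applied
silently.

## The synthetic campaigns: what they emulate, and what they do not

`make_fixture()` draws complete campaigns with known ground truth.  The
canned specifications are the package's study conditions:

* `fixture_spec_soil_hg()` — a soil trace-metal certification: 12 bottles
  × 4 replicates (true between-bottle RSD 1.2 %, repeatability 2 %),
  16 laboratories × 5 replicates (between-lab RSD 5.5 %, within-lab 2 %),
  one laboratory with an exact mean bias of 8 between-lab SDs and one with
  an 8-fold inflated within-lab SD, a drift-free monthly stability series,
  and a quarterly monitoring series with a mild drift (0.002 units/month).
  The grand mean is 4 mg/kg.  Planted biases are deterministic — the shift
  *is* the truth — so the sequential-flagging phenomenon is a property of
  the design, not of a lucky draw.
* `fixture_spec_two_element()` — two elements across 15 laboratories with
  a graded outlier pair (+12 and −7 between-lab SDs on opposite ends),
  sized so that the milder laboratory is masked by the extreme one and
  becomes significant only after its exclusion.
* `fixture_spec_arrhenius()` — a reference level at −80 °C and four
  stressed levels (10, 25, 40, 55 °C) at five time points (0.5–6 months,
  duplicate measurements, 1 % log-scale noise), degrading first-order with
  $E_a = 80$ kJ/mol and $k(25\,°C) = 0.02$/month.  Across repeated draws
  the fitted CI covers the true activation energy at its nominal rate.

These sizes keep every simulation-based test and the acceptance script in
the seconds-to-minutes range while leaving the planted effects
unambiguous.  What passing them shows is that the implementation recovers
known truth under its own model assumptions — normal lab effects,
independent replicates, exact first-order kinetics, linear drift.  What
they do not show: robustness to the non-normal, correlated, or
heteroscedastic behaviour of real interlaboratory data, to calibration
drift shared across laboratories, or to kinetics of other orders.  Real
campaigns should be evaluated with the same scrutiny the battery is built
for, not waved through because the synthetic checks pass.

## Known limitations

* Only the nested homogeneity design is supported; other designs from the
  homogeneity literature (e.g. split-level) are out of scope.
* Kinetic orders other than first, and isochronous-study bookkeeping beyond
  what the date column encodes, are not modelled.
* Consensus-value estimators beyond the unweighted mean of lab means
  (weighted means, random-effects estimators) are intentionally absent.
* The Dixon table stops at N = 30 (the classical range); larger studies
  should rely on the Grubbs and Cochran tests, which have closed forms.
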