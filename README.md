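# certifyr

Statistical evaluation of reference material (RM) production data in R:
homogeneity, stability, interlaboratory certification, uncertainty budgets
and post-certification monitoring — as a scriptable, pipe-friendly package
with spreadsheet template I/O, a lossless session container and HTML
reporting.

## Who this is for

Producing a certified reference material (CRM) requires a chain of
statistical decisions that accredited producers must document end to end:
is the batch homogeneous across bottles, is the property stable over the
planned lifetime, which expert laboratories of the collaborative study are
statistical outliers, what certified value and expanded uncertainty go on
the certificate, and does the material stay within its certified interval
after release.  `certifyr` implements that workflow for the analyst
responsible for an RM project, with every user decision (exclusions,
transferred uncertainty terms, expansion factor, rounding) recorded in a
persistent session for traceability.

## The statistics at the core

* **Homogeneity (H)**: one-way ANOVA over the nested design (N bottles × n
  replicates) yields mean squares `M_between`, `M_within`; the
  between-bottle relative standard deviation is
  `s_bb = sqrt((M_between − M_within)/n₀)`, set to 0 when masked
  (`M_within ≥ M_between`), in which case the maskable bound
  `s_bb,min = sqrt(M_within/n₀)·(2/df_within)^¼` is reported.  The budget
  receives `u_bb = max(s_bb, s_bb,min)`.
* **Stability (S)**: OLS drift model per analyte with
  `u_stab = |t_cert · s(b₁)|`; accelerated studies regress the log-ratio to
  the reference level per storage temperature, giving rates `k_eff(T)`
  combined in an Arrhenius fit `ln k = a + b/T`, from which prospective
  expiry times `(U_abs/µ_c)/k*` follow at any studied temperature (with
  `k*` from the upper prediction bound for the conservative estimate).
* **Certification (C)**: per-laboratory means and a test battery —
  Lilliefors KS, skewness/kurtosis, Bartlett, Scheffé, single/double
  Grubbs, Dixon, Cochran — with straggler (5 %) and outlier (1 %) verdicts.
  Exclusion is never automatic; it is an ordered user decision.  The
  Cochran and single-Grubbs critical values are exact closed forms (valid
  for any N), Dixon and double-Grubbs use simulation-calibrated tables.
* **Value assignment**: `µ_c` is the unweighted mean of laboratory means,
  `u_char = sd(means)/√p` (relative), terms combine as a root sum of
  squares, expand with `k` (default 2), and round per DIN 1333 (uncertainty
  up at its leading significant place, two digits when that digit is 1 or
  2).
* **Post-certification monitoring (PCM)**: the SK criterion
  `|µ_c − µ_m|/sqrt(u_c² + u_m²) < k` for quick control measurements, and
  long-term stability (LTS) regression on months since certification with
  the intercept adjustment `b0′ = b0 + µ_LTS − µ_c` and shelf life from the
  crossing of `µ_c ± U` (optionally by the confidence band).

## Worked example

All template dialects can be generated synthetically with known ground
truth; the soil-Hg campaign below emulates a 16-laboratory trace-metal
certification with one deviating mean (L4) and one deviating variance
(L14):

```r
library(certifyr)
fx <- make_fixture(fixture_spec_soil_hg(), seed = 1, dir = tempdir())

cert <- read_certification(fx$paths$certification)
evaluate_battery(cert, "Hg") |> tidy() |>
  dplyr::select(test, lab, statistic, verdict)
#> 5 Grubbs (single)  L4   3.24    outlier     <- deviating mean
# after the user excludes L4, the battery is re-run:
evaluate_battery(cert, "Hg", exclusions = "L4") |> tidy()
#> 8 Cochran          L14  0.914   outlier     <- deviating variance

homog <- read_homogeneity(fx$paths$homogeneity)
hres  <- evaluate_homogeneity(homog, "Hg")
sm    <- lab_summaries(cert, "Hg", exclusions = c("L4", "L14"))
uncertainty_budget(sm, transferred = c(u_bb(hres), u_rep = 0.5), k = 2)
#> <uncertainty_budget> mu_c = 3.9783 (p = 14 labs)
#>   terms [%]: u_char = 1.68, u_bb = 1.1, u_rep = 0.5
#>   u_com = 2.07%, k = 2, U = 4.14% (abs 0.1649)
#>   certified: 3.98 +/- 0.17 (rounded at 2 decimal place(s))
```

The certified value is the unweighted mean of the 14 retained laboratory
means; the three relative uncertainty terms combine to `u_com`, are
expanded with `k = 2` and rounded per DIN 1333 to the certificate entry.
`autoplot()` methods render the standard figures (per-bottle box plots,
lab-mean distribution with greyed exclusions, Arrhenius line with its
band, monitoring chart), and `render_report(session)` writes a
self-contained HTML report of everything a session contains.

A thin command-line wrapper exposing the same workflow
(`fixture`, `homogeneity`, `stability`, `arrhenius`, `certify`, `budget`,
`pcm`, `lts`, `session`, `report`) ships in `inst/cli/certifyr.R`:

```sh
Rscript inst/cli/certifyr.R certify --input L1.csv --input L2.csv ... \
    --analyte Hg --exclude L4 --exclude L14 --transfer u_rep=0.5 --out out/
```

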