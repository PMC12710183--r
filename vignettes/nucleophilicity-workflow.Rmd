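---
title: "From stopped-flow traces to nucleophilicity parameters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From stopped-flow traces to nucleophilicity parameters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diazokin)
```

## The problem

When an electron-rich heteroarene such as 3-aminothiophene attacks a
benzenediazonium cation, the azo coupling proceeds as a classical
electrophilic aromatic substitution: reversible addition of the
electrophile at the ring carbon gives a cationic Wheland-type
intermediate, which then re-aromatizes by losing the ring proton.
Quantifying how fast this happens — and how the rate responds to the
electronics of both partners — is what places a nucleophile on a
quantitative reactivity scale and lets one *predict* rate constants for
untested partner combinations.

This package implements the complete inference chain for that kind of
study:

1. extraction of pseudo-first-order rate constants from stopped-flow
   absorbance traces,
2. second-order rate constants from their concentration dependence,
3. correction for acid–base speciation of the nucleophile,
4. kinetic isotope effect (KIE) ratios,
5. Hammett, Yukawa–Tsuno and Mayr–Patz linear free-energy fits,
6. a σ⁺-based linear model that predicts nucleophilicity parameters for
   structural analogs, validated by forward rate prediction.

It also ships a mechanistic simulator of the underlying two-step pathway
so that every stage of the chain can be audited by parameter recovery
against known ground truth.

## Kinetic model

Under a large excess of nucleophile (pseudo-first-order conditions) the
two-step mechanism

$$\mathrm{E} + \mathrm{Nu} \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}}
\mathrm{I}^{+} \overset{k_2}{\rightarrow} \mathrm{P}$$

with a quasi-steady-state intermediate gives the observed relaxation rate

$$k_\mathrm{obsd} = \frac{k_1 k_2}{k_{-1} + k_2}\, f(\mathrm{pH})\,
[\mathrm{Nu}]_\mathrm{tot},$$

where $f(\mathrm{pH}) = 1/(1 + 10^{pK_a - \mathrm{pH}})$ is the fraction
of nucleophile present as the reactive free base (`free_base_fraction()`,
default $pK_a = 3.38$).  When re-aromatization is much faster than
reversion ($k_2 \gg k_{-1}$) — the regime indicated experimentally by
KIE ratios indistinguishable from 1 — this reduces to
$k_\mathrm{obsd} = k_1 f\,[\mathrm{Nu}]_\mathrm{tot}$, so the slope of
$k_\mathrm{obsd}$ versus total concentration is the apparent second-order
constant $k$, and $k_1 = k/f$ is pH-independent.  `steady_state_kobsd()`
implements the full expression; `to_k1()` the speciation correction.
Only the free base is treated as reactive: this is the only reading under
which the packaged $k \to k_1$ arithmetic is consistent across both
working pH values, and we verified that numerically on the shipped table.

The absorbance of the growing azo adduct follows a single exponential,

$$A(t) = A_\infty - (A_\infty - A_0)\,e^{-k_\mathrm{obsd} t},$$

equivalently $\ln(A_\infty - A_t) = -k_\mathrm{obsd}\,t +
\ln(A_\infty - A_0)$.

## Trace fitting: two estimators

`fit_kobsd()` offers:

* **`"guggenheim-linear"`** (default): OLS of $\ln(A_\infty - A_t)$ on
  $t$.  This is the field's classical treatment and is exact on clean
  data.  Its weakness is that the log transform amplifies noise where
  the amplitude $A_\infty - A_t$ approaches the noise floor; points at
  or beyond $A_\infty$ (whose log is undefined) are dropped with a
  warning, and a fit is refused when fewer than 5 usable points remain
  or when the fitted decay does not progress measurably over the
  observation window ("no relaxation detected").
* **`"exp-nonlinear"`**: direct Levenberg–Marquardt fit of the
  exponential with $(A_0, A_\infty, k_\mathrm{obsd})$ free, started from
  the linear estimate.  It is insensitive to tail noise and is the
  better choice for noisy single traces.

On noiseless traces the two agree to well below 0.5% across
$k_\mathrm{obsd}$ from $10^{-2}$ to $10^{2}\,\mathrm{s}^{-1}$.  At the
simulator's default noise (0.002 AU) the nonlinear estimator recovers
the generating rate within ~0.5% per trace, while the log-linear
estimator is unbiased but scatters by a few percent per trace; that
scatter averages out at the next stage, where the slope over a
concentration series — not any single trace — carries the result.
$A_\infty$ is taken from the trace's recorded equilibrium value by
default, since stopped-flow instruments measure it directly; passing
`A_inf = "tail"` instead estimates it as the mean of the final 5% of
points for data without a recorded endpoint.

## What the simulator emulates, and what it does not

`generate_campaign()` produces the synthetic analogue of a full kinetic
study: for each electrophile of known $E$, a ground-truth
$k_1 = 10^{s_N (E + N)}$, apparent constants at each pH via $f$, and one
noisy trace per (electrophile, pH, concentration) cell.  The defaults
mirror the real working conditions: nucleophile total concentrations
$10^{-3}$–$2.8\times10^{-2}$ mol L⁻¹ (seven levels), electrophile
$5\times10^{-5}$ mol L⁻¹ (enforced ≥ 20-fold excess), pH 1 and 2,
$pK_a$ 3.38, absorbance window 0.05–0.80 AU.

Noise is i.i.d. Gaussian on absorbance with sd 0.002 AU.  That value is
a design choice: reported stopped-flow regressions of this kind have
correlation coefficients above 0.97, and 0.002 AU on a 0.75 AU amplitude
reproduces that fit quality; we did not attempt to model drift,
photobleaching, mixing artifacts, or heteroscedastic detector noise.
Consequently, passing recovery tests show the *inference chain* is
correct and well-conditioned at realistic noise — they do not certify
robustness against structured instrumental error, ionic-strength or
temperature variation (both held constant here), or deviations from
single-exponential behaviour (biphasic kinetics are out of scope).
Randomness is controlled by one campaign seed from which per-trace
substreams are derived deterministically, so campaigns are exactly
reproducible.

The mechanistic ODE integrator (`simulate_mechanism_ode()`, stiff lsoda
with mass-balance conservation to $10^{-9}$) exists to validate the
steady-state algebra itself: whenever $(k_{-1}+k_2) \ge 100\,
k_\mathrm{obsd}$ the integrated electrophile decay is single-exponential
at the steady-state rate to within 1%.

## The LFER layer

All regressions are unweighted OLS on base-10 logarithms; no weighting
scheme is applied anywhere.  Because $k_1$ is pH-independent by
construction, the two determinations at pH 1 and 2 are replicates, and
the fits use the mean of the two $\log_{10} k_1$ values per electrophile
(`average_log_rate()`).  This convention reproduces the headline
constants of the packaged dataset to their reported precision, whereas
single-pH fits drift in the last digit.

* **Hammett** (`hammett_fit()`): $\log k_1 = \log k_0 + \rho\sigma$ on
  either the $\sigma_p$ or the $\sigma_p^+$ scale.  On the packaged
  data the $\sigma_p^+$ fit ($\rho = 2.48$, intercept 2.91) correlates
  better than the $\sigma_p$ fit, the signature of through-resonance
  stabilisation by electron donors.
* **Yukawa–Tsuno** (`yukawa_tsuno_fit()`):
  $\log k = c + \rho[\sigma + r(\sigma^+ - \sigma)]$.  The default
  `"joint-bilinear"` estimator fits $c$, $b_1 = \rho$, $b_2 = \rho r$ by
  two-regressor OLS and reports $r = b_2/b_1$; it is the global
  least-squares optimum, which we verify in tests against a brute-force
  $200 \times 200$ $(\rho, r)$ grid with the intercept profiled out.
  The `"grid-conditional"` estimator scans $r$ over $[-1, 3]$ in steps
  of 0.01 and fits the one-regressor model on
  $\sigma_\mathrm{eff}(r)$; it is retained as a diagnostic because it
  mirrors how such fits are often done by hand.  A step of 0.01 matches
  the precision at which $r$ is conventionally quoted.  On the packaged
  table the joint optimum is $\rho \approx 2.9$, $r \approx 0.49$ —
  a genuinely different optimum from historically quoted values for
  fits of this type, which is why the package always reports both
  estimators with their SSE; see "Known data notes" below.
* **Mayr–Patz** (`mayr_fit()`): OLS of $\log_{10} k_1$ on $E$; the slope
  is $s_N$ and $N = \mathrm{intercept}/s_N$ exactly.  Records without a
  tabulated $E$ are excluded (one of the eight shipped electrophiles,
  the *p*-fluoro salt).  A non-positive slope is refused as a scale
  inversion.  `n_from_single_rate()` provides the complementary
  one-point calibration $N = \log_{10}(k)/s_N - E$ with the
  conventional $s_N = 1$.
* **σ⁺ prediction model** (`fit_sigma_plus_model()`, `predict_N()`,
  `predict_rate()`): OLS of measured $N$ on the σ⁺ constant of the ring
  substituent, then forward evaluation $k = 10^{s_N(E+N)}$.
  `validate_predictions()` compares predicted with measured rates and
  flags whether every deviation factor (the ratio or its reciprocal,
  whichever exceeds 1) stays within 100, the conventional confidence
  window for reactivity-scale extrapolations.

## Numerical and interface choices

* Missing values (an electrophile without $E$, absent deuterio
  measurements) are `NA` — R's explicit not-available marker — never 0
  and never a NaN smuggled in as data; every fit drops incomplete
  points explicitly and reports the `n` it used.
* CSV (RFC-4180, "." decimal separator, scientific notation accepted)
  is the single tabular interchange format, with a fixed,
  case-insensitively matched column vocabulary
  (`read_rate_table()` / `write_rate_table()`); round trips preserve
  full double precision.  Campaigns serialise as one CSV per trace plus
  a JSON manifest holding design, seed and ground truth.
* Default trace grid: 200 points spanning $5/k_\mathrm{obsd}$, which
  captures more than 99% of the relaxation amplitude.
* The intercept of $k_\mathrm{obsd}$ versus concentration is fitted,
  not forced through zero: the simplified rate law predicts zero, so
  the fitted intercept is a mechanistic diagnostic.
* KIE ratios are computed on the speciation-corrected $k_1$ values,
  paired by (electrophile label, pH); on the packaged data this
  reproduces the expected near-unity range 0.96–1.14, and pairing on
  the apparent $k$ instead would not.
* All rate constants are stored in M⁻¹ s⁻¹ exactly as measured; there
  is no unit-conversion layer.
* $R^2$ values are reported to 4 decimals but are never used as
  pass/fail criteria against externally quoted figures: refits of
  rounded tables legitimately differ in the third decimal from fits of
  the original unrounded rates.

## Problem sizes used by the test suite

The suite regenerates all synthetic data at run time: campaigns of
7 electrophiles × 2 pH × 7 concentrations × 200-point traces, with 20
seeded replicates for the end-to-end recovery property ($s_N$ and $N$
recovered within 5% at default noise in every replicate).  These sizes
were chosen so that concentration-series slopes are determined by ~7
points each, as in real practice, while the whole suite stays
interactive-fast.

## Known data notes and limitations

* One cell of the shipped rate table is internally rounded: for the
  *p*-methyl electrophile at pH 1, the printed $k = 0.240$ and
  $k_1 = 58.8$ disagree by 1.7% under the speciation identity (every
  other of the 16 pairs agrees well within 1%); $k$ was evidently
  rounded after $k_1$ was computed.  The package ships the values as
  printed rather than "fixing" either one.
* Mean $\log k_1$ is strictly increasing in $\sigma_p$ and in $E$
  across the shipped table, but the $\sigma_p^+$ ordering has one
  inversion at the near-degenerate F/H pair ($\sigma^+ = -0.07$ vs 0).
* The σ⁺ prediction line is fitted on three points; its value lies in
  the validated forward predictions (deviation factors 8–16, well
  inside the factor-100 window), not in the three-point $R^2$.
  Predicted $N$ values quoted to two decimals are conventionally
  evaluated from the two-decimal coefficients of the fitted line;
  evaluating with full-precision coefficients can differ in the last
  digit (e.g. 7.348 vs 7.343 at $\sigma^+ = -0.31$).
* No uncertainty propagation beyond OLS is attempted, no multi-solvent
  or temperature extrapolation of $N$/$s_N$, and no structure-based
  (SMILES/InChI) handling: records are identified by label and
  substituent text.

## A compact worked example

```{r example}
tab <- load_table1()
log_k1 <- average_log_rate(tab$k1_pH1, tab$k1_pH2)
mayr_fit(log_k1, tab$E)
hammett_fit(log_k1, tab$sigma_p_plus, "sigma_plus")

t2 <- load_table2()
amino <- !is.na(t2$sigma_plus_C3)
model <- fit_sigma_plus_model(t2$N_exp[amino], t2$sigma_plus_C3[amino])
predict_N(model, c(-0.78, -0.31, 0))
```

And the synthetic round trip:

```{r roundtrip}
truth <- list(N_true = 9.37, sN_true = 1.18,
              E = c(-8.4, -7.7, -7.2, -6.7, -5.7, -5.5, -5.1))
camp <- generate_campaign(truth, experiment_design(noise_sd = 0), seed = 1)
rates <- extract_campaign_rates(camp)
avg <- aggregate(log10(k1) ~ label, rates, mean)
mayr_fit(avg$`log10(k1)`, camp$manifest$E[match(avg$label,
                                               camp$manifest$labels)])
```
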