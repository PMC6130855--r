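---
title: "Detecting and quantifying chlorinated volatiles in SIFT-MS headspace spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying chlorinated volatiles in SIFT-MS headspace spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siftvoc)
```

## The problem

When sodium hypochlorite (NaOCl), the standard root-canal irrigant, meets
natural organic matter — dentine, bacterial biomass, serum proteins — it
forms volatile disinfection by-products, most notably the trihalomethane
chloroform, alongside nitrogenous volatiles such as acetonitrile. Selected
ion flow tube mass spectrometry (SIFT-MS) can detect and quantify these in
the sample headspace in real time: a mass-selected reagent ion (H₃O⁺, NO⁺
or O₂⁺) is injected into a helium flow tube, the headspace gas is admitted
through a calibrated capillary, and the product ("analyte") ions are
counted by a downstream quadrupole. The m/z of the analyte ion identifies
the neutral compound; its count rate quantifies it.

`siftvoc` implements the interpretive machinery this kind of study relies
on — unit-resolution ion arithmetic, chlorine isotopologue pattern
matching, hydrate-ladder recognition, kinetics-based quantification, and
study-level aggregation and comparison — together with a forward simulator
so the whole chain can be exercised and validated without an instrument.

## The identification rules

**Chlorine multiplets.** Chlorine has two stable isotopes, ³⁵Cl and ³⁷Cl,
whose abundance ratio is statistically 3:1. An ion carrying $n$ chlorine
atoms therefore appears as $n+1$ peaks spaced 2 m/z apart, with relative
abundances following the binomial law

$$f_j = \binom{n}{j} p^j (1-p)^{n-j}, \qquad j = 0,\dots,n,$$

where $p$ is the heavy-isotope probability. With $p = 0.25$ a
one-chlorine ion shows 75%:25% and a two-chlorine ion 9:6:1, i.e.
56.25%:37.5%:6.25%. The dichloromethyl cation CHCl₂⁺ — the O₂⁺ product of
chloroform, and the only plausible dichlorinated ion at that mass — sits
at m/z 83/85/87. `chlorine_envelope()` computes the envelope with an
explicit binomial product (exact in double precision for the dyadic
default $p$); `detect_chlorine_patterns()` searches a spectrum for
above-LOD peak groups spaced 2 m/z whose observed fractions all fall
within a tolerance (default 0.10, absolute) of the envelope.

Why a tolerance window rather than a formal χ² test? Observed multiplets
drift from the ideal ratios by more than Poisson counting error alone
(quadrupole mass discrimination, overlapping fragment peaks): a strict
counting-statistics test rejects perfectly genuine chlorine patterns,
including most of the reference count triplets shipped with this package.
The 0.10 window operationalises the "close to the statistical ratio"
judgement an analyst applies by eye. Overlapping candidate groups are
resolved in favour of the largest chlorine count, then the smallest
maximum deviation.

**Hydrate ladders.** Under humid H₃O⁺ chemistry many protonated analytes
ligand-switch with water, producing cluster series M·H⁺(H₂O)₀..₃ spaced
18 m/z apart. Protonated acetonitrile appears at m/z 42/60/78/96.
`detect_hydrate_series()` reports maximal chains of above-LOD peaks
spaced exactly 18; a chain is never extended through a below-LOD gap, and
chains need at least two members.

**Assignment.** `assign_compounds()` gives every above-LOD peak exactly
one interpretation, with pattern evidence taking precedence over direct
kinetics-library matches. Two deliberate rules:

* Ambiguity is preserved, never resolved silently. The even-m/z
  nitrogen-compound ions at m/z 88 (+ monohydrate 106) and m/z 102
  (+ 120) are carried as the unresolved candidate sets
  pentylamine|butyramide and dipropylamine|pentanamide throughout,
  including quantification (one combined concentration per set).
* A chlorine-carrying channel is never assigned from a bare m/z
  coincidence. Without its Δ2 isotopologue pattern, a lone peak at m/z 83
  stays unassigned — a single above-background fluctuation must not
  become a chloroform call. This is what keeps the false-positive rate
  at zero on clean control spectra.

## The forward model and its inversion

Quantification in SIFT-MS rests on pseudo-first-order kinetics in the
low-depletion limit. For an analyte at headspace concentration $c$
(mg per litre of headspace gas, the convention used for the reference
concentrations this package ships), molar mass $M$:

$$n_\mathrm{hs} = \frac{c\,N_A}{10^6 M}\ \mathrm{cm^{-3}}, \qquad
  n_\mathrm{ft} = \varphi\, n_\mathrm{hs}, \qquad
  I_p = I_r\,k\,n_\mathrm{ft}\,t_r,$$

with $I_r$ the reagent-ion count rate, $k$ the ion–molecule rate
coefficient, $t_r$ the reaction time and $\varphi$ the effective dilution
of headspace gas into the flow tube. The product flux $I_p$ is split
across a compound's channels (branching), each channel's chlorine
isotopologues (binomial envelope) and, for hydrating channels, the
water-cluster ladder; rates from distinct compounds sharing an m/z add.
Because each partition sums to one, summing all of a compound's channels
and inverting the same formula (`concentration_from_counts()`) recovers
the concentration exactly in the noise-free limit — a property the test
suite asserts to 1 part in 10¹⁰ for every library compound — and with
Poisson noise the recovery is unbiased with spread at the counting limit
$1/\sqrt{N}$ for $N$ total counts.

Parameters that matter, with defaults:

| parameter | default | meaning |
|---|---|---|
| `I_r` | 10⁶ c/s | reagent-ion count rate |
| `t_r` | 10⁻³ s | flow-tube reaction time |
| `phi` | 0.01 (`instrument_config()`); 10⁻⁷ (`default_study_config()`) | effective headspace→flow-tube dilution |
| `background` | 1 c/s | mean background per m/z channel |
| `k` | 1.5–5.1 × 10⁻⁹ cm³ s⁻¹ | per-reaction rate coefficients (library file) |
| `cl_tolerance` | 0.10 | isotopologue fraction window |
| LOD | background + 3√background | per-channel detection limit |

The study configuration's `phi = 10⁻⁷` folds the capillary sample-flow
fraction and the roughly thousand-fold pressure drop from the atmospheric
headspace to the ~1 mbar flow tube into one factor; it was chosen so that
analytes at a few mg L⁻¹ produce count rates of order 10²–10³ c/s, the
scale of the dichloromethyl counts in the reference data. Only the
product $I_r k t_r \varphi$ matters to the forward/inverse pair, so this
choice affects realism of simulated counts, not correctness of recovery.
The shipped rate coefficients are literature-scale values, not
instrument calibrations; they are flagged as such in the library file and
set only the absolute concentration scale, which simulation and
quantification share consistently.

## What the simulator emulates — and what it does not

`simulate_study()` reproduces the shape of a five-group headspace study:
a water-only control and four NaOCl + organic-matter groups, each
incubated aerobically and anaerobically in triplicate, scanned under all
three reagent ions (90 spectra). Default cell means are the reference
concentration table shipped in
`inst/extdata/group_voc_profiles.csv`: common biogenic volatiles
(ammonia, acetaldehyde, acetone, methanol, ethanol, acetic acid) in every
group, and the hypochlorite reaction products — chloroform, acetonitrile
and the minor amine/amide candidate sets — only in groups 1–4. The
reference table lists a trace control acetonitrile mean (0.009 mg L⁻¹,
range n/d–0.017); the generator treats this sub-LOD trace as absent so
that the control is a true negative for both marker compounds. The
amine/amide channels have no reference concentrations; the defaults
(0.02 mg L⁻¹ in groups 1 and 4, 0.04 in groups 2 and 3, half that for
the minor set) reproduce their qualitative pattern — present in all
experimental groups, strongest in groups 2 and 3.

Replicate-to-replicate variation is lognormal with CV 0.35 (mean
preserved), which reproduces the order-of-magnitude min–max spreads of
real replicate tables without claiming their generative mechanism. Counts
are Poisson draws around the expected rate plus a flat background
(mean 1 c/s on every channel of the m/z 10–200 scan). All randomness
derives from one master seed: replicate composition draws and
per-spectrum sub-seeds come from a single seeded stream, each spectrum
records its sub-seed, and identical seed + configuration give
byte-identical output.

The simulator deliberately does **not** model: reagent-ion depletion
(trace levels justify the linear limit), differential quadrupole mass
discrimination, ¹³C/²H/¹⁵N/¹⁸O isotope satellites (the identification
rules use chlorine only, and modelling ¹³C satellites would blur the
3:1 / 9:6:1 ratio tests), capillary flow physics beyond the single
dilution factor, humidity-dependent hydrate equilibria (fractions fixed
at 0.4/0.3/0.2/0.1 for the 0–3 water ladder, the decreasing pattern
seen in humid-headspace hydronium spectra), or the O₂⁺ fragmentation
clutter of real spectra (the O₂⁺ library carries only the channels the
emulated study interprets: ammonia at m/z 17 and chloroform's CHCl₂⁺ at
83/85/87). Passing tests therefore demonstrate the correctness of the
analysis chain under the stated model, not robustness to every artefact
of real instrument data — in particular, real "busy" O₂⁺ spectra can
place fragment peaks 2 m/z apart, and the tolerance window's specificity
against that interference is untested here.

## Study-level statistics

`analyze_study()` aggregates replicate concentrations into mean and
[min–max] summaries, counting non-detects as zero in the mean and showing
"n/d" as the lower range bound when any replicate was below the LOD (the
convention of headspace concentration tables). Percentages of the
m/z 83/85/87 triplet are computed as 100·count/total with half-up
rounding to integers, and rows are not forced to sum to 100.

For the aerobic-versus-anaerobic contrast the emulated study reports "no
significant differences … with the exception of acetone" without naming a
test. With triplicates, a within-group permutation test has a minimum
two-sided p of 0.1 and can never reject at α = 0.05, so
`compare_conditions()` uses a **group-stratified** permutation test per
compound: condition labels are shuffled within each group, the statistic
is the mean over groups of the difference between condition means, and
the two-sided p-value is $(1 + \#\{|T^\*| \ge |T|\})/(B+1)$ with
$B = 999$. Stratification means group-to-group level differences cannot
masquerade as condition effects; pooling five groups gives the test
resolution and power. Per-group anaerobic/aerobic concentration ratios
carry bootstrap percentile intervals, and Benjamini–Hochberg adjustment
across compounds controls the family-wise flagging rate — the adjusted
calls are what "flags acetone and only acetone" refers to. Calibration
is part of the test suite: over 200 simulated null studies the raw
per-compound rejection rate stays within binomial 3σ of the nominal 0.05.

## Numerical and degenerate-input choices

* Integer nominal masses only (H=1, C=12, N=14, O=16, Cl=35); every m/z
  in this domain is an integer and the instrument is unit-resolution.
  Only C/H/N/O/Cl are supported; unsupported elements error by name.
* Heavy-chlorine probability defaults to the idealised 0.25; natural
  abundance (0.2423) is available as `CL37_NATURAL_ABUNDANCE`. All the
  printed signature ratios (75/25, 56/38/6) use the 3:1 idealisation.
* The binomial envelope is computed as an explicit
  $\binom{n}{j}p^j(1-p)^{n-j}$ product: for dyadic $p$ and small $n$
  every term is exact in double precision, so 37.5% rounds half-up to
  38 rather than suffering a one-ulp downward error.
* Percent/molarity conversions treat labelled "% v/v" hypochlorite as
  % w/v (10 g L⁻¹ per percent, NaOCl molar mass 74.44 g mol⁻¹): only
  that reading makes a 2.5% solution 0.34 M.
* Ties in `top_peaks()` break by ascending m/z. A negative
  background-subtracted total clamps to "n/d" with a warning. An empty
  spectrum is a valid input everywhere and yields empty results.
* Detection runs on raw count fractions (no background subtraction):
  pattern ratios are scale-invariant above the LOD, and subtracting a
  1 c/s background from 10²–10³ c/s peaks changes fractions by less than
  a part in a hundred of the tolerance window.

## Problem sizes used in validation

The shipped tests validate the chain at deliberately modest sizes: the
brute-force isotopologue oracle enumerates all $2^{n}$ labelings up to
$n = 6$ chlorines; Monte-Carlo recovery uses 200 draws at expected totals
of 10², 10³ and 10⁴ counts; detector specificity and sensitivity use 100
simulated control and 100 group-4 spectra; type-I calibration uses 200
simulated null studies with 999 permutations each; pipeline tests run the
full 5 × 2 × 2–3 × 3 design. These sizes give the assertions comfortable
statistical resolution (binomial 3σ bands, 3σ Poisson bands) while
keeping the whole suite fast.

## A worked example

```{r example}
# the reference dichloromethyl triplet for group 4, aerobic
sp <- read_spectrum(system.file("extdata", "group4_air_o2_example.csv",
                                package = "siftvoc"))
detect_chlorine_patterns(sp)[, c("base_mz", "n_cl", "max_abs_deviation",
                                 "passes")]
relative_percentages(spectrum_counts(sp, c(83, 85, 87)))

# end-to-end simulated study (2 replicates for brevity)
report <- run_study(default_study_design(replicates = 2), seed = 1,
                    n_perm = 499)
subset(report$summary, compound == "chloroform",
       select = c(group, condition, label))
report$comparison$per_compound
```

## Known limitations

* Absolute concentrations depend on the non-authoritative library rate
  coefficients and the effective dilution; cross-study comparison of
  absolute values requires instrument calibration. Relative structure
  (ratios, patterns, detection) does not.
* The reference count triplets and their printed concentrations are not
  mutually consistent across groups (per-sample reagent-ion rates were
  evidently not constant), so printed chloroform concentrations cannot be
  reproduced from printed counts; the package reproduces the ratio
  structure and round-trips its own forward model instead.
* Three of the 24 printed reference percentage cells differ by exactly 1
  from any consistent rounding of their printed counts (printing
  inconsistencies in the source table); the recomputation matches the
  remaining 21 exactly and never deviates by more than 1.
* The permutation comparison assumes exchangeable replicates within a
  group × condition cell; it is the package's disclosed choice, not a
  reconstruction of whatever test the emulated study used.
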