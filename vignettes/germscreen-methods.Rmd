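---
title: "Models and methods behind germscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind germscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germscreen)
```

# The screening readout

In self-fertilising *C. elegans* hermaphrodites, male (X0) offspring arise
only through X-chromosome nondisjunction in the germline, normally at a rate
below 0.2%. A male-specific promoter driving GFP marks male-destined embryos
in utero, so a gravid mother with GFP⁺ embryos reports a recent germline
segregation error. A large-object cytometer reads each sorted object's
time-of-flight (ToF, proportional to length) and GFP peak height, turning
male frequency into a high-throughput per-worm measurement. `germscreen`
implements both a generative model of this experiment and the analysis that
converts raw event streams into ranked chemical hits, together with the
follow-up assays used to characterise hits mechanistically.

# The generative model

The simulator is the single source of all test inputs for the package. It
is deliberately structural rather than mechanistic: each preset constant is
an interpretable biological quantity, and all stochastic draws come from R's
global RNG stream so that one `set.seed()` call reproduces an entire run
bit-for-bit.

## Strains

`strain_preset()` encodes the genetic backgrounds used in this kind of
study: the cuticle-permeable screening strain (baseline male probability
`p_male = 0.001`, i.e. 0.1%, inside the reported <0.2% range), the *him-8*
positive calibration strain (`p_male = 0.367`), a p53/*cep-1* mutant without
damage-induced apoptosis, a *rad-54* mutant in which RAD-51 is trapped at
break sites, a *spo-11*-depleted background without meiotic double-strand
breaks, and a temperature-sensitive germline-less background (germline
present at 15 °C, absent at 25 °C). Cuticle permeability is folded into the
effective dose as a multiplier (1 for the screening strain); no separate
uptake model is attempted.

## Dose–response

All exposure endpoints follow a Hill curve on external dose,
$E(d) = E_{\max}\, d^n / (EC_{50}^n + d^n)$: zero at dose 0, monotone,
saturating at $E_{\max}$. Only discrete dose series (1/10/100/500 µM) are
available to anchor these curves, so the presets are chosen so the
qualitative dose pattern holds: embryonic lethality becomes appreciable from
100 µM for DBP and permethrin and from 10 µM for TCMTB
(`hill_params(150, 2, 0.4)` and `hill_params(30, 1.5, 0.35)` increments over
a 0.5% baseline); brood size falls by half at 500 µM DBP/permethrin
(`hill_params(500, 2, 1)`, which is exactly 50% at 500 µM) and across
100–500 µM for TCMTB (`hill_params(60, 2, 0.55)`, giving 40–54% over that
range); damage apoptosis and break load activate with
`hill_params(40, 2, ·)` (DBP/permethrin) or `hill_params(4, 2, ·)` (TCMTB),
placing the 2–3-fold corpse increase at the working doses of 100, 100 and
10 µM. Nondisjunction increments (`emax` 0.0035–0.004) yield roughly
three-to-four-fold GFP⁺ enrichment at working doses, in the range the screen
is designed to detect.

## Sorter physics

Each event draws a developmental stage from a mixture (default: 60% adults,
15% L4, the rest younger larvae and debris), then a stage-specific lognormal
ToF (medians 30 for debris up to 650 for adults; `sim_constants()`).
Adults carry an in-utero embryo load $N \sim \text{Poisson}(\mu)$ with
$\mu = 12$ — a value chosen as a realistic gravid load and left
configurable, since no count is reported — and each embryo is independently
male-destined with the strain/exposure probability $p$. GFP peak height is
lognormal gut autofluorescence (median 5 units) plus a fixed per-embryo
brightness of 30 units per GFP⁺ embryo. Brightness and autofluorescence are
free parameters of the instrument model; they were fixed once at values that
make the negative and positive calibration populations overlap slightly
(≈1% of each misclassified), which is the regime in which threshold
calibration is non-trivial but solvable. By Poisson thinning, the fraction
of adults with at least one GFP⁺ embryo has the closed form
$1 - e^{-\mu p}$, which the tests use as an independent oracle for the whole
classify–score path.

## Germline cytology

Per-nucleus RAD-51 focus counts are Poisson with zone-specific rates over
the seven equal gonad zones, low in the mitotic tip (z1–z2), rising from
meiotic entry (z3), peaking at mid-pachytene (z5) and falling by late
pachytene (z7): baseline λ = (0.15, 0.2, 0.8, 1.8, 2.6, 1.9, 0.9). Chemical
exposure multiplies the *meiotic* zone rates by $1 + E_{dsb}(d)$, leaving
the mitotic zones untouched, because the chemically induced breaks are
SPO-11-dependent: without SPO-11 the meiotic zones collapse to the mitotic
background and no chemical elevation appears. In the *rad-54* background
foci report cumulative break formation, so z3–z7 rates are the running sum
of per-zone increments — non-decreasing by construction, which makes the
directionality testable exactly on the rate parameters rather than only in
expectation.

Corpse counts are Poisson with rate
$\lambda_{phys} + [\text{cep-1}^+](\lambda_{DMSO} + \lambda_{dmg} E_{apo}(d))$
with $\lambda_{phys} = 1.2$, $\lambda_{DMSO} = 0.6$ and
$\lambda_{dmg} = 3.5$. The solvent term models the known basal DMSO
toxicity, and both it and the damage term are gated on CEP-1 function, so
the *cep-1* mutant shows only physiological apoptosis. A Poisson form was
chosen because only means ± SEM are reported for corpse counts; it keeps the
vehicle mean (1.8) under the "fewer than three corpses" control behaviour
while giving the chemical presets a 2.7-fold elevation at working dose.

Diakinesis oocytes (the last two per gonad) carry six DAPI bodies
(bivalents) unless meiotic breaks are absent, in which case all twelve
univalents appear; defect classes (fragments, bridges, frayed) are drawn
from a categorical distribution whose increments over the vehicle baseline
scale with the apoptosis Hill curve. Fragmented oocytes carry 7–12 bodies.
Pachytene gonad-defect flags (gaps, aggregates, leptotene/zygotene-like
organisation) are Bernoulli with exposure-specific target probabilities at
the reference dose (e.g. 30.2% gaps under DBP versus 10.9% under vehicle).

## qPCR

Each well's Ct is a gene-specific baseline minus the true log2 expression
change, plus a per-sample plate offset (SD 0.3 cycles, shared by every well
of a biological replicate, hence cancelled exactly by ΔCt) plus technical
noise (SD 0.2 cycles). Expression changes are split into germline and soma
components; the germline component contributes only when a germline is
present at the rearing temperature. The reference gene *gpd-1* is never
affected by exposure. The model does not represent the change in *absolute*
abundance of germline-enriched transcripts between germline-bearing and
germline-less animals; this is deliberate, because all reported folds are
within-temperature comparisons against the matched vehicle.

# Calibration and classification

`fit_adult_gate()` takes the 0.5th–99.5th ToF percentiles of labelled
adults, then raises the lower bound until at most 1% of labelled L4 events
fall inside. If no bound satisfies the criterion while retaining at least
half of the adults, the run is flagged inseparable (the gate is still
returned with its achieved rates); the 50% retention rule is what lets
genuinely identical distributions trip the flag while a normal separated run
never does. The gate is one-dimensional in ToF: only ToF bounds are
recoverable from the calibration design, and GFP enters downstream through
the threshold instead.

`fit_gfp_threshold()` scans every midpoint between adjacent sorted unique
GFP values from both reference runs (plus sentinels beyond the extremes) and
minimises FPR + FNR, treating all negative-strain gated adults as negative
and all positive-strain adults as positive. The symmetric objective is a
design choice: it is deterministic, oracle-checkable by exhaustive scan, and
indifferent to the (unknown) relative costs of the two error types. Ties
break toward the larger threshold, the conservative direction for calling
positives. Two known biases are accepted rather than corrected: a small
fraction of *him-8* adults genuinely carry no GFP⁺ embryo
($e^{-12 \times 0.367} \approx 0.4\%$), and a similar fraction of
negative-strain adults genuinely carry one; both act as label noise of under
2%. If even the best candidate misclassifies nearly everything
(FPR + FNR ≥ 0.95) the two runs are statistically identical and calibration
errors out rather than returning an arbitrary threshold. Positivity is
strict (`gfp_peak > τ`), so an event exactly at the threshold is negative.

# Screen statistics

The well statistic is the fraction of gated adults classified GFP⁺ —
worm-level counting, not integrated intensity, consistent with the per-worm
dot-plot framing of the readout. Fold increase per biological replicate is
$(f_{chem} + \varepsilon)/(f_{DMSO} + \varepsilon)$ with
$\varepsilon = 1/(2 n_{DMSO})$; the continuity constant keeps folds bounded
when the vehicle well records zero positives and its bias vanishes at
screening well sizes (300 gated adults give ε ≈ 0.0017). The paired unit is
the biological replicate batch (chemical well against that batch's vehicle
well), and the replicate fractions feed a paired two-tailed t-test; when
every paired difference is zero the statistic is undefined and p = 1 by
convention. Hits are strict mean-fold exceedances of the benchmark chemical
(BPA), with rank ties broken alphabetically. No multiple-testing correction
is applied across chemicals, matching how such screens are conventionally
reported; the hit rule is a ranking device, not an error-controlled
discovery procedure.

# Nonparametric tests

The Mann–Whitney implementation uses mid-ranks for ties and computes the
exact permutation distribution of U — equivalent to enumerating all
$\binom{n_1+n_2}{n_1}$ labelings — via a subset-sum dynamic programme on the
doubled (hence integer) ranks whenever the number of arrangements is at most
$10^6$; otherwise it falls back to the normal approximation with tie and
continuity corrections, and records which method was used. The exact
two-tailed p-value is the null probability of a U at least as far from its
mean $n_1 n_2/2$ as observed (with $10^{-9}$ slack against floating-point
ties). An in-package implementation is needed because the standard library
refuses exact p-values under ties, and tied counts are the norm for corpse
and focus data; the test suite verifies exact equality against brute-force
`combn()` enumeration.

The Fisher test is the probability-mass two-sided definition: the sum of
hypergeometric probabilities of all tables (margins fixed) no more probable
than the observed one, with $10^{-7}$ relative slack. This matches the
standard R definition and is verified against both independent table
enumeration and `fisher.test()`. The doubling alternative
(2 × one-sided) is *not* provided to avoid silently inconsistent p-values
across the package.

The qPCR comparison uses Welch's unpaired two-tailed t-test (R's default
form of the unpaired t-test) on per-biological-replicate ΔCt values;
amplification efficiency is fixed at 2 with no standard-curve correction,
and technical replicates are averaged before ΔCt. Germline attribution is a
decision rule on the two temperatures: significant at 15 °C and not at
25 °C → germline-specific; significant at 25 °C → somatic; otherwise none.

# Numerical conventions and degenerate inputs

* Zone binning: `floor(7 * position) + 1` on a half-open normalised axis
  `[0, 1)`, distal tip at 0; position 1 is rejected, not clamped.
* Zero denominators: lethality fractions are `NA` (not errors) for
  zero-egg or zero-hatchling mothers; wells with zero gated adults are hard
  errors (a failed well, not a zero).
* Probability compositions are clipped to [0, 1] after summing baseline and
  exposure effects, but a composition outside [0, 1] before clipping beyond
  numerical noise signals a mis-set preset and raises an error.
* Molar masses use IUPAC conventional atomic weights abridged to five
  significant figures; formulas are plain Hill notation without isotopes,
  charges or hydrates, which covers every library chemical (polymers carry
  repeat-unit formulas, documented as such in the library file).
* µM→µg/ml and its inverse round-trip to within $10^{-9}$ relative
  tolerance by construction.

# Problem sizes

The package's own verification runs at desk scale: male-frequency checks
pool ≈10⁵ simulated progeny (450 mothers at a 250-egg mean brood); the
ranking-recovery check screens 46 simulated chemicals at ≈5,000 worms each
over three replicates; cytology checks use 1,000 gonads per arm for preset
means and 30 per arm for power; null calibration of the zone tests uses
1,000 vehicle-versus-vehicle repetitions; qPCR label-recovery uses 400
repetitions at 3–4 biological replicates. These sizes were chosen so each
stochastic check has comfortable statistical margin. Where several
simultaneous interval checks share one seed (the three-point male-fraction
recovery), a 3-standard-error band is used instead of 1.96 to account for
the multiplicity.

# What passing tests do and do not show

The simulator encodes the biological structure the analysis assumes:
Poisson embryo loads, lognormal ToF and autofluorescence, independent
per-embryo male fates, Poisson focus and corpse counts, Gaussian Ct noise.
Passing recovery tests therefore demonstrates internal consistency — the
analysis recovers what the generative model planted, at realistic effect
sizes and sample sizes — not field validity on instrument data. Real sorter
streams have features the model omits: optical coincidence (two worms in
the flow cell), ToF drift within runs, intensity saturation, non-Poisson
embryo retention under strong exposure, plate-position effects beyond a
shared offset, and chemical autofluorescence. The calibration artifacts are
serialisable precisely so that per-session recalibration against such drift
is possible.

# Known limitations

* Dose–response presets are anchored to a four-point dose series; between
  anchors the Hill interpolation is an assumption.
* The per-chemical nondisjunction effect sizes of the full 46-chemical
  library are not published in machine-readable form; the bundled
  per-replicate fold table is synthetic, constrained to the documented
  outcome (19 chemicals above BPA, mercury ranked first), and is labelled
  synthetic in its filename and header.
* Meiotic mechanism (recombination maps, synapsis dynamics, checkpoint
  kinetics) is out of scope; chromosome-level events enter only as rates
  and class probabilities. Synapsis is assumed unaffected by the chemical
  presets, mirroring the documented no-effect observation.
* The CLI is a thin wrapper over `run_pipeline()`; orchestration beyond a
  single machine (schedulers, instrument I/O) is out of scope.
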